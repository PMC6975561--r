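#' Assemble a 5C forward x reverse primer count matrix
#'
#' @param counts non-negative integer matrix, forward primers in rows and
#'   reverse primers in columns.
#' @param forward,reverse data.frames describing the primers, with columns
#'   `id`, `chrom`, `start`, `end` (1-based closed) and logical `desert`
#'   marking the gene-desert control primers used for efficiency
#'   normalization.
#' @return Object of class `fivec_matrix`.
#' @export
fivec_matrix <- function(counts, forward, reverse) {
  need <- c("id", "chrom", "start", "end", "desert")
  for (m in list(forward, reverse)) {
    miss <- setdiff(need, names(m))
    if (length(miss)) stop("primer manifest lacks columns: ",
                           paste(miss, collapse = ", "))
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(forward) || ncol(counts) != nrow(reverse)) {
    stop("count matrix dimensions do not match primer manifests")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!any(forward$desert) || !any(reverse$desert)) {
    stop("need at least one desert primer on each axis for normalization")
  }
  rownames(counts) <- forward$id
  colnames(counts) <- reverse$id
  structure(list(counts = counts, forward = forward, reverse = reverse),
            class = "fivec_matrix")
}

#' Read a 5C matrix from a primer manifest and a count TSV
#'
#' The manifest TSV needs a header `id, chrom, start, end, orientation,
#' desert` (coordinates 1-based closed; orientation `F`/`R`); the count
#' TSV has forward primer ids as row names and reverse primer ids as
#' column names.
#' @param matrix_path count TSV path.
#' @param manifest_path primer manifest TSV path.
#' @return A `fivec_matrix`.
#' @export
read_fivec <- function(matrix_path, manifest_path) {
  man <- read.table(manifest_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end", "orientation", "desert")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("primer manifest lacks columns: ",
                         paste(miss, collapse = ", "))
  man$desert <- as.logical(man$desert)
  counts <- as.matrix(read.table(matrix_path, header = TRUE, sep = "\t",
                                 row.names = 1L, check.names = FALSE))
  fwd <- man[man$orientation == "F", , drop = FALSE]
  rev <- man[man$orientation == "R", , drop = FALSE]
  fwd <- fwd[match(rownames(counts), fwd$id), , drop = FALSE]
  rev <- rev[match(colnames(counts), rev$id), , drop = FALSE]
  if (any(is.na(fwd$id)) || any(is.na(rev$id))) {
    stop("count matrix row/column names do not match the manifest")
  }
  fivec_matrix(counts, fwd, rev)
}

#' Normalize a 5C matrix against gene-desert control primers
#'
#' Per-primer efficiency factors are estimated as the mean raw count of the
#' primer against all desert primers of the opposite orientation. The
#' default `"desert"` rule is the double ratio
#' `raw(F,R) * mean(desert-desert raw) / (factor(F) * factor(R))`: it
#' reduces to `raw / c` when every desert interaction equals `c`, and it
#' cancels multiplicative per-primer efficiency biases exactly (each
#' factor is proportional to its primer's efficiency, and the
#' desert-desert mean restores the scale counted twice in the product).
#' `mode = "geometric"` divides by `sqrt(factor(F) * factor(R))` instead;
#' it leaves a residual square-root efficiency bias and is kept for
#' sensitivity analysis. Desert-desert cells are excluded (`NA`) in the
#' output; primers with no positive desert coverage are dropped with a
#' warning. Both modes are scale-equivariant: multiplying the whole raw
#' matrix by k leaves all between-cell ratios unchanged.
#'
#' @param fm a [fivec_matrix()].
#' @param mode `"desert"` (default) or `"geometric"`.
#' @return Object of class `normalized_contacts`: `values` (matrix over
#'   kept primers, desert-desert cells `NA`), `factor_forward`,
#'   `factor_reverse`, `forward`, `reverse` (kept manifests), `dropped`,
#'   `mode`.
#' @export
normalize_5c <- function(fm, mode = c("desert", "geometric")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fm, "fivec_matrix"))
  counts <- fm$counts
  fd <- fm$forward$desert
  rd <- fm$reverse$desert
  fF <- rowMeans(counts[, rd, drop = FALSE])
  fR <- colMeans(counts[fd, , drop = FALSE])
  dd_mean <- mean(counts[fd, rd])
  keep_f <- fF > 0
  keep_r <- fR > 0
  dropped <- c(fm$forward$id[!keep_f], fm$reverse$id[!keep_r])
  if (length(dropped)) {
    warning("dropped primer(s) with zero desert coverage: ",
            paste(dropped, collapse = ", "))
  }
  counts <- counts[keep_f, keep_r, drop = FALSE]
  fF <- fF[keep_f]
  fR <- fR[keep_r]
  values <- if (mode == "geometric") {
    counts / outer(sqrt(fF), sqrt(fR))
  } else {
    counts * dd_mean / outer(fF, fR)
  }
  values[fd[keep_f], rd[keep_r]] <- NA_real_
  structure(list(values = values, factor_forward = fF, factor_reverse = fR,
                 forward = fm$forward[keep_f, , drop = FALSE],
                 reverse = fm$reverse[keep_r, , drop = FALSE],
                 dropped = dropped, mode = mode),
            class = "normalized_contacts")
}

#' Bin normalized 5C contacts over genomic regions
#'
#' Sums normalized primer-pair values over every region pair (including
#' self pairs): cell (i, j) collects the pairs whose forward primer falls
#' in region i and reverse primer in region j. Binning conserves mass:
#' the matrix total equals the total normalized signal over primer pairs
#' whose primers were both assigned.
#'
#' @param nc a `normalized_contacts` object.
#' @param regions non-overlapping `GRanges`; region names are taken from a
#'   `name` metadata column when present.
#' @return list with `matrix` (regions x regions), `leftover_forward`,
#'   `leftover_reverse` (primer ids assigned to no region).
#' @export
bin_contacts <- function(nc, regions) {
  stopifnot(inherits(nc, "normalized_contacts"))
  if (length(regions) > 1L &&
      sum(width(reduce(granges(regions)))) < sum(width(regions))) {
    stop("regions must be non-overlapping")
  }
  rname <- mcols(regions)$name
  if (is.null(rname)) rname <- sprintf("region_%d", seq_along(regions))
  .assign <- function(man) {
    gr <- GRanges(man$chrom, IRanges(man$start, man$end))
    suppressWarnings(  # primer and region seqlevels legitimately differ
      findOverlaps(gr, regions, select = "first", ignore.strand = TRUE))
  }
  fa <- .assign(nc$forward)
  ra <- .assign(nc$reverse)
  nr <- length(regions)
  mat <- matrix(0, nr, nr, dimnames = list(rname, rname))
  for (i in seq_len(nr)) {
    fi <- which(!is.na(fa) & fa == i)
    if (!length(fi)) next
    for (j in seq_len(nr)) {
      rj <- which(!is.na(ra) & ra == j)
      if (!length(rj)) next
      mat[i, j] <- sum(nc$values[fi, rj], na.rm = TRUE)
    }
  }
  list(matrix = mat,
       leftover_forward = nc$forward$id[is.na(fa)],
       leftover_reverse = nc$reverse$id[is.na(ra)])
}
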