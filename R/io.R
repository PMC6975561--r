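#' Construct a peak set
#'
#' Convenience constructor for a set of signal-carrying genomic peaks.
#' Coordinates are 1-based closed (the R/Bioconductor convention); use
#' [read_peaks()] for BED-family files, which are converted on read.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start >= 1`, `end >= start`.
#' @param name peak identifiers; autogenerated when `NULL`.
#' @param signal non-negative per-peak signal (tag density, arbitrary units).
#' @param site_class optional label per peak, one of `"persistent"`,
#'   `"transient"`, `"minus_unique"`, `"unclassified"`.
#' @param condition optional condition label stored in the object metadata.
#' @return A `GRanges` with metadata columns `name`, `signal` and (if given)
#'   `site_class`, sorted by (chrom, start, end).
#' @export
peak_set <- function(chrom, start, end, name = NULL, signal = NA_real_,
                     site_class = NULL, condition = NULL) {
  if (length(chrom) == 0L) {
    gr <- GRanges()
    mcols(gr)$name <- character(0)
    mcols(gr)$signal <- numeric(0)
  } else {
    if (any(end < start)) {
      stop("rejected record: end < start at index ",
           which(end < start)[1L])
    }
    if (any(start < 1L)) stop("start must be >= 1 (1-based coordinates)")
    gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)))
    mcols(gr)$name <- if (is.null(name)) sprintf("peak_%d", seq_along(gr))
                      else as.character(name)
    mcols(gr)$signal <- as.numeric(signal)
    if (!is.null(site_class)) mcols(gr)$site_class <- as.character(site_class)
  }
  if (!is.null(condition)) S4Vectors::metadata(gr)$condition <- condition
  sort_peaks(gr)
}

#' Sort a peak set by genomic position
#'
#' Sorting is by (chrom, start, end) and is idempotent. All pipeline
#' functions accept unsorted input and sort internally.
#' @param gr a `GRanges`.
#' @return the sorted `GRanges`.
#' @export
sort_peaks <- function(gr) {
  gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
}

.read_fields <- function(path, min_fields) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list(fields = list(), lineno = integer(0)))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected >= %d fields, found %d",
                 lineno[bad[1L]], path, min_fields, nf[bad[1L]]))
  }
  list(fields = fields, lineno = lineno)
}

.num_field <- function(fields, lineno, i, path, what = "coordinate") {
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  bad <- which(is.na(x))
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: non-numeric %s in field %d",
                 lineno[bad[1L]], path, what, i))
  }
  x
}

#' Read a peak file (BED or narrowPeak)
#'
#' BED coordinates (0-based half-open) are converted to the internal 1-based
#' closed convention; writing with [write_peaks()] restores them bit-exactly.
#' For narrowPeak the `signalValue` column (7) becomes `signal`; for plain
#' BED the score column (5), when present, is used as `signal`.
#'
#' @param path file path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @param condition optional condition label stored in metadata.
#' @return A sorted `GRanges` with `name` and `signal` metadata columns.
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak"),
                       condition = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  min_fields <- if (format == "narrowPeak") 7L else 3L
  parsed <- .read_fields(path, min_fields)
  fields <- parsed$fields
  lineno <- parsed$lineno
  if (length(fields) == 0L) {
    return(peak_set(character(0), integer(0), integer(0),
                    condition = condition))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- .num_field(fields, lineno, 2L, path, "start")
  end0 <- .num_field(fields, lineno, 3L, path, "end")
  bad <- which(end0 <= start0)
  if (length(bad)) {
    stop(sprintf("rejected record at line %d in %s: end (%g) <= start (%g)",
                 lineno[bad[1L]], path, end0[bad[1L]], start0[bad[1L]]))
  }
  nf <- lengths(fields)
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                  ""), NA_character_)
  if (all(is.na(name))) name <- NULL
  signal <- NA_real_
  sig_col <- if (format == "narrowPeak") 7L else 5L
  if (all(nf >= sig_col)) {
    signal <- .num_field(fields, lineno, sig_col, path, "signal")
  }
  peak_set(chrom, start0 + 1L, end0, name = name, signal = signal,
           condition = condition)
}

#' Write a peak set as BED or narrowPeak
#'
#' Inverse of [read_peaks()]: the 1-based closed internal coordinates are
#' written back as 0-based half-open.
#'
#' @param gr a `GRanges` with `name`/`signal` metadata columns.
#' @param path output path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(gr, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  sig <- if (!is.null(mcols(gr)$signal)) mcols(gr)$signal else
    rep(0, length(gr))
  sig[is.na(sig)] <- 0  # BED score column cannot hold NA
  nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
    sprintf("peak_%d", seq_along(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr), name = nm,
                   stringsAsFactors = FALSE)
  if (format == "bed") {
    df$score <- sig
  } else {
    df$score <- 0L
    df$strand <- "."
    df$signalValue <- sig
    df$pValue <- -1
    df$qValue <- -1
    df$peak <- -1L
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read paired interactions (BEDPE)
#'
#' @param path BEDPE file: chrom1 start1 end1 chrom2 start2 end2
#'   \[name score\]. Coordinates are converted from 0-based half-open.
#' @return data.frame with 1-based closed columns `chrom1,start1,end1,
#'   chrom2,start2,end2` plus `name` and `score` when present.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- .read_fields(path, 6L)
  fields <- parsed$fields
  lineno <- parsed$lineno
  if (length(fields) == 0L) {
    return(data.frame(chrom1 = character(0), start1 = integer(0),
                      end1 = integer(0), chrom2 = character(0),
                      start2 = integer(0), end2 = integer(0)))
  }
  s1 <- .num_field(fields, lineno, 2L, path); e1 <- .num_field(fields, lineno, 3L, path)
  s2 <- .num_field(fields, lineno, 5L, path); e2 <- .num_field(fields, lineno, 6L, path)
  bad <- which(e1 <= s1 | e2 <= s2)
  if (length(bad)) {
    stop(sprintf("rejected record at line %d in %s: anchor end <= start",
                 lineno[bad[1L]], path))
  }
  nf <- lengths(fields)
  df <- data.frame(
    chrom1 = vapply(fields, `[[`, "", 1L), start1 = as.integer(s1 + 1L),
    end1 = as.integer(e1),
    chrom2 = vapply(fields, `[[`, "", 4L), start2 = as.integer(s2 + 1L),
    end2 = as.integer(e2), stringsAsFactors = FALSE)
  if (all(nf >= 7L)) df$name <- vapply(fields, `[[`, "", 7L)
  if (all(nf >= 8L)) df$score <- .num_field(fields, lineno, 8L, path, "score")
  df
}

#' Write paired interactions as BEDPE
#' @param pairs data.frame as returned by [read_bedpe()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(pairs, path) {
  df <- data.frame(pairs$chrom1, pairs$start1 - 1L, pairs$end1,
                   pairs$chrom2, pairs$start2 - 1L, pairs$end2)
  extra <- setdiff(names(pairs),
                   c("chrom1", "start1", "end1", "chrom2", "start2", "end2"))
  for (col in extra) df[[col]] <- pairs[[col]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Build gene models with transcription start sites
#'
#' The TSS is the interval start for `+` strand genes and the interval end
#' for `-` strand genes.
#'
#' @param chrom,start,end 1-based closed gene body coordinates.
#' @param strand `"+"` or `"-"` per gene.
#' @param name gene identifiers.
#' @return A `GRanges` with `name` and `tss` metadata columns.
#' @export
gene_models <- function(chrom, start, end, strand, name = NULL) {
  stopifnot(all(strand %in% c("+", "-")))
  gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)),
                strand = strand)
  mcols(gr)$name <- if (is.null(name)) sprintf("gene_%d", seq_along(gr))
                    else as.character(name)
  mcols(gr)$tss <- ifelse(strand == "+", start(gr), end(gr))
  gr
}

#' Read gene models from a TSV
#'
#' Expects a header with columns `chrom, start, end, strand, name`
#' (1-based closed coordinates).
#' @param path TSV path.
#' @return A `GRanges` as from [gene_models()].
#' @export
read_gene_models <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "name")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene model TSV lacks columns: ",
                         paste(miss, collapse = ", "))
  gene_models(df$chrom, df$start, df$end, df$strand, df$name)
}
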