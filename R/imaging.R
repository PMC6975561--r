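#' FISH enrichment ratios and colocalization calls
#'
#' The normalized intensity (enrichment ratio) of a FISH spot is the mean
#' protein-channel intensity within the spot divided by the mean intensity
#' of the corresponding nucleus; a spot is called colocalized when the
#' ratio reaches the threshold (inclusive, default 1.4). Ratios are
#' invariant to global rescaling of a cell's intensities.
#'
#' @param spots data.frame with columns `spot_mean`, `nucleus_mean`
#'   (positive) and optionally `condition`, `cell`, `spot`.
#' @param threshold colocalization threshold on the ratio.
#' @return list with `calls` (the input rows plus `ratio` and
#'   `colocalized`), `summary` (per-condition n, percent colocalized,
#'   median ratio), `threshold`, `n_rejected` (non-positive nucleus
#'   intensity).
#' @export
fish_enrichment <- function(spots, threshold = 1.4) {
  need <- c("spot_mean", "nucleus_mean")
  miss <- setdiff(need, names(spots))
  if (length(miss)) stop("spots lacks columns: ", paste(miss, collapse = ", "))
  ok <- spots$nucleus_mean > 0
  n_rejected <- sum(!ok)
  if (n_rejected) warning(n_rejected,
                          " record(s) rejected: non-positive nucleus intensity")
  calls <- spots[ok, , drop = FALSE]
  calls$ratio <- calls$spot_mean / calls$nucleus_mean
  calls$colocalized <- calls$ratio >= threshold
  cond <- if ("condition" %in% names(calls)) calls$condition else
    rep("all", nrow(calls))
  summ <- do.call(rbind, lapply(split(seq_len(nrow(calls)), cond),
                                function(i) {
    data.frame(condition = cond[i[1L]], n = length(i),
               pct_colocalized = 100 * mean(calls$colocalized[i]),
               median_ratio = median(calls$ratio[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(calls = calls, summary = summ, threshold = threshold,
       n_rejected = n_rejected)
}

# Disc of pixel offsets for a given radius in pixels.
.disc_offsets <- function(radius_px) {
  r <- max(0L, floor(radius_px))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius_px^2, , drop = FALSE]
}

#' Random-ROI null distribution of enrichment ratios
#'
#' Draws circular regions of interest at random positions fully inside
#' each nucleus and computes their enrichment ratio exactly as
#' [fish_enrichment()] does (ROI mean over nucleus mean). On a homogeneous
#' nucleus the null ratios concentrate at 1.
#'
#' @param cells list of per-cell intensity matrices (`NA` outside the
#'   nucleus mask).
#' @param n_roi ROIs per cell.
#' @param roi_diameter ROI diameter in micrometres.
#' @param pixel_size pixel edge length in micrometres.
#' @param seed RNG seed.
#' @param observed_ratios optional observed enrichment ratios to compare
#'   against the null (rank-sum test).
#' @return list with `null` (data.frame `cell`, `ratio`), `null_mean`,
#'   `comparison` (NULL or the rank-sum result vs `observed_ratios`),
#'   `n_skipped` (cells too small to fit the ROI).
#' @export
random_roi_null <- function(cells, n_roi = 100L, roi_diameter = 1.0,
                            pixel_size = 0.1, seed = 1L,
                            observed_ratios = NULL) {
  radius_px <- (roi_diameter / 2) / pixel_size
  offs <- .disc_offsets(radius_px)
  n_skipped <- 0L
  out <- vector("list", length(cells))
  .with_seed(seed, {
    for (ci in seq_along(cells)) {
      M <- cells[[ci]]
      ok <- !is.na(M)
      nuc_mean <- mean(M[ok])
      nr <- nrow(M); ncl <- ncol(M)
      eligible <- which(ok, arr.ind = TRUE)
      inside <- rep(TRUE, nrow(eligible))
      for (k in seq_len(nrow(offs))) {
        rr <- eligible[, 1L] + offs$dr[k]
        cc <- eligible[, 2L] + offs$dc[k]
        inb <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncl
        inside <- inside & inb
        inside[inside] <- ok[cbind(rr[inside], cc[inside])]
      }
      centers <- eligible[inside, , drop = FALSE]
      if (nrow(centers) == 0L) {
        n_skipped <- n_skipped + 1L
        next
      }
      pick <- centers[sample.int(nrow(centers), n_roi, replace = TRUE), ,
                      drop = FALSE]
      ratios <- vapply(seq_len(n_roi), function(i) {
        rr <- pick[i, 1L] + offs$dr
        cc <- pick[i, 2L] + offs$dc
        mean(M[cbind(rr, cc)]) / nuc_mean
      }, 0)
      out[[ci]] <- data.frame(cell = ci, ratio = ratios)
    }
  })
  null_df <- do.call(rbind, out)
  if (is.null(null_df)) null_df <- data.frame(cell = integer(0),
                                              ratio = numeric(0))
  comparison <- NULL
  if (!is.null(observed_ratios) && nrow(null_df) >= 2L &&
      length(observed_ratios) >= 2L) {
    wt <- suppressWarnings(wilcox.test(observed_ratios, null_df$ratio))
    comparison <- list(observed_mean = mean(observed_ratios),
                       null_mean = mean(null_df$ratio),
                       statistic = unname(wt$statistic),
                       p_value = wt$p.value)
  }
  list(null = null_df, null_mean = mean(null_df$ratio),
       comparison = comparison, n_skipped = n_skipped)
}

#' Normalize a FRAP trace and estimate the recovery plateau
#'
#' Per frame, the background intensity is subtracted from the bleached-ROI
#' intensity and the difference divided by the whole-cell intensity; the
#' curve is rescaled so the pre-bleach mean is 1 (making it invariant to
#' global intensity rescaling). The plateau — the mobile-fraction estimate
#' under complete bleaching — is the mean of the final 10\% of frames. The
#' unbleached-ROI curve, normalized the same way, is returned as the
#' acquisition-bleaching control when present.
#'
#' @param trace data.frame with columns `time`, `roi`, `background`,
#'   `whole_cell` and optionally `unbleached`.
#' @param bleach_frame index of the first post-bleach frame (>= 4, so at
#'   least 3 pre-bleach frames exist).
#' @return list with `time`, `curve`, `control_curve` (or NULL),
#'   `plateau`, `bleach_frame`, `prebleach_mean_raw`.
#' @export
frap_normalize <- function(trace, bleach_frame) {
  need <- c("time", "roi", "background", "whole_cell")
  miss <- setdiff(need, names(trace))
  if (length(miss)) stop("trace lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(trace)
  if (bleach_frame < 4L || bleach_frame > n) {
    stop("bleach_frame must allow >= 3 pre-bleach frames and lie in the trace")
  }
  if (any(trace$whole_cell <= 0)) {
    stop("whole-cell intensity must be positive at every frame")
  }
  raw <- (trace$roi - trace$background) / trace$whole_cell
  pre <- mean(raw[seq_len(bleach_frame - 1L)])
  if (pre <= 0) stop("non-positive pre-bleach mean")
  curve <- raw / pre
  control <- NULL
  if ("unbleached" %in% names(trace)) {
    c_raw <- (trace$unbleached - trace$background) / trace$whole_cell
    c_pre <- mean(c_raw[seq_len(bleach_frame - 1L)])
    control <- c_raw / c_pre
  }
  n_tail <- max(1L, ceiling(0.1 * n))
  plateau <- mean(tail(curve, n_tail))
  list(time = trace$time, curve = curve, control_curve = control,
       plateau = plateau, bleach_frame = bleach_frame,
       prebleach_mean_raw = pre)
}

#' Single-exponential fit of a normalized FRAP recovery
#'
#' Fits `I(t) = I_inf - (I_inf - I_0) * exp(-(t - t_b) / tau)` to the
#' post-bleach portion of a normalized curve and reports the classical
#' mobile fraction `(I_inf - I_0) / (1 - I_0)` (equal to `I_inf` under
#' complete bleaching).
#'
#' @param fr a [frap_normalize()] result.
#' @return list with `I0`, `Iinf`, `tau`, `mobile_fraction`.
#' @export
frap_fit <- function(fr) {
  post <- seq(fr$bleach_frame, length(fr$curve))
  t <- fr$time[post] - fr$time[fr$bleach_frame]
  y <- fr$curve[post]
  fit <- nlsLM(y ~ Iinf - (Iinf - I0) * exp(-t / tau),
               start = list(I0 = y[1L], Iinf = fr$plateau,
                            tau = max(diff(range(t)) / 5, 1e-3)),
               lower = c(-1, 0, 1e-6), upper = c(1.5, 2, Inf))
  cf <- coef(fit)
  list(I0 = unname(cf["I0"]), Iinf = unname(cf["Iinf"]),
       tau = unname(cf["tau"]),
       mobile_fraction = unname((cf["Iinf"] - cf["I0"]) / (1 - cf["I0"])))
}
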