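#' Score scans against the smoothed aggregate of their measurement
#'
#' Builds a reference spectrum — the mean of the moving-median smoothed
#' series — and scores every scan by its cosine similarity to that
#' reference. Because the reference is formed from medians, isolated
#' artifact scans do not contaminate it, so their low scores stand out.
#' Degenerate (all-zero) scans receive score 0 and are flagged.
#'
#' @param series a [binned_series()].
#' @param smoothing a [smoothing_config()]; the series must be at least
#'   `window` scans long.
#' @return An object of class `scan_qc`: `scores` (per scan, in `[0, 1]`),
#'   `degenerate` (logical per scan), `reference` (the smoothed-aggregate
#'   [binned_spectrum()]), `smoothing`, and unset `threshold` / `keep` —
#'   call [apply_threshold()] to set them.
#' @export
score_scans <- function(series, smoothing = smoothing_config()) {
  stopifnot(inherits(series, "binned_series"))
  sm <- moving_median(series, smoothing)
  ref <- aggregate_spectrum(sm, mode = "mean")
  n <- length(series$spectra)
  scores <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    s <- cosine(series$spectra[[i]], ref)
    degen[i] <- is_degenerate(s)
    scores[i] <- as.double(s)
  }
  structure(list(scores = scores, degenerate = degen, reference = ref,
                 smoothing = smoothing, threshold = NA_real_,
                 rule = NA_character_, keep = rep(NA, n)),
            class = "scan_qc")
}

#' Apply a significance threshold to scan QC scores
#'
#' A scan is kept when its score is at least the threshold and it is not
#' degenerate; degenerate (all-zero) scans are always rejected. The
#' threshold may be a fixed value in `[0, 1]` or `"auto"`, which uses the
#' robust rule `min(median(scores) - 3 * mad(scores), median(scores)/2)`
#' (scale-consistent MAD, as in [stats::mad()]), clamped to `[0, 1]`.
#' The MAD term adapts to the score spread of the instrument and sample at
#' hand; the `median/2` cap keeps the rule from rejecting scans that still
#' share at least half the typical similarity with the reference, which
#' happens when bin-boundary flicker of strong peaks makes the score
#' distribution heavy-tailed or multimodal (such scans are not artifacts).
#'
#' @param r a `scan_qc` object from [score_scans()].
#' @param threshold `"auto"` (default) or a number in `[0, 1]`.
#' @return The `scan_qc` object with `threshold`, `rule` and `keep` set.
#' @export
apply_threshold <- function(r, threshold = "auto") {
  stopifnot(inherits(r, "scan_qc"))
  if (identical(threshold, "auto")) {
    med <- stats::median(r$scores)
    thr <- min(med - 3 * stats::mad(r$scores), med / 2)
    thr <- min(max(thr, 0), 1)
    r$rule <- "min(median - 3*MAD, median/2)"
  } else {
    thr <- as.double(threshold)
    if (is.na(thr) || thr < 0 || thr > 1) {
      stop("threshold must be 'auto' or a number in [0, 1]")
    }
    r$rule <- "fixed"
  }
  r$threshold <- thr
  r$keep <- r$scores >= thr & !r$degenerate
  r
}

#' @export
print.scan_qc <- function(x, ...) {
  n <- length(x$scores)
  cat(sprintf("<scan_qc> %d scans, scores %.4f-%.4f\n",
              n, min(x$scores), max(x$scores)))
  if (is.na(x$threshold)) {
    cat("  threshold not set; call apply_threshold()\n")
  } else {
    cat(sprintf("  threshold %.4f (%s): %d kept, %d rejected (%d degenerate)\n",
                x$threshold, x$rule, sum(x$keep), sum(!x$keep),
                sum(x$degenerate)))
  }
  invisible(x)
}

#' @export
summary.scan_qc <- function(object, ...) {
  data.frame(
    scan_index = seq_along(object$scores) - 1L,
    score = object$scores,
    degenerate = object$degenerate,
    kept = object$keep
  )
}

#' Consensus spectrum from QC-surviving scans
#'
#' Aggregates only the scans kept by [apply_threshold()], producing the
#' filtered profile assigned to the measurement. Filtering before averaging
#' keeps artifact scans from distorting the profile.
#'
#' @param series the [binned_series()] that was scored.
#' @param r a thresholded `scan_qc` for that series.
#' @param mode `"mean"` (default) or `"sum"`.
#' @return A [binned_spectrum()].
#' @export
consensus_spectrum <- function(series, r, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "binned_series"), inherits(r, "scan_qc"))
  if (anyNA(r$keep)) stop("threshold not applied; call apply_threshold() first")
  if (length(r$keep) != length(series$spectra)) {
    stop("QC result does not match series length")
  }
  if (!any(r$keep)) stop("all scans rejected")
  kept <- binned_series(series$label, series$spectra[r$keep])
  aggregate_spectrum(kept, mode = mode)
}

#' Write a scan QC report
#'
#' Writes a per-scan CSV (`scan_index,score,degenerate,kept`) and a JSON
#' summary with the threshold, rule, smoothing parameters and counts.
#'
#' @param r a thresholded `scan_qc`.
#' @param path output CSV path; the JSON summary goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(r, path) {
  stopifnot(inherits(r, "scan_qc"))
  utils::write.csv(summary(r), path, row.names = FALSE, quote = FALSE)
  side <- list(
    threshold = r$threshold,
    rule = r$rule,
    window = r$smoothing$window,
    step = r$smoothing$step,
    n_scans = length(r$scores),
    n_kept = sum(r$keep),
    n_rejected = sum(!r$keep),
    n_degenerate = sum(r$degenerate)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a consensus spectrum as a two-column peak list
#'
#' Rows are `mz,intensity` with m/z at bin centers.
#'
#' @param b a [binned_spectrum()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(b, path) {
  stopifnot(inherits(b, "binned_spectrum"))
  mz <- b$config$mz_min + (b$bin + 0.5) * b$config$bin_width
  utils::write.csv(data.frame(mz = mz, intensity = b$value), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
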