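#' Moving-median smoothing parameters
#'
#' `window` is the number of consecutive scans whose per-bin median forms one
#' smoothed spectrum; it must be odd, so the median is a single observed
#' value and an isolated run of up to `floor(window/2)` artifact scans
#' cannot move it. `step` is the shift between successive windows: 1 keeps
#' full temporal detail, `window` gives non-overlapping summaries for global
#' sample grouping, and `ceiling(window/2)` is the usual compromise.
#'
#' @param window odd integer >= 1; 51 by default (about one minute of
#'   acquisition at typical ~1 Hz scan rates).
#' @param step integer >= 1; defaults to `window` (non-overlapping).
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(window = 51L, step = window) {
  window <- as.integer(window)
  step <- as.integer(step)
  if (is.na(window) || window < 1L) stop("window must be a positive integer")
  if (window %% 2L == 0L) stop("window must be odd")
  if (is.na(step) || step < 1L) stop("step must be a positive integer")
  structure(list(window = window, step = step), class = "smoothing_config")
}

#' @export
print.smoothing_config <- function(x, ...) {
  cat(sprintf("<smoothing_config> window %d, step %d\n", x$window, x$step))
  invisible(x)
}

#' Moving median over a binned scan series
#'
#' Slides a leading window of `window` consecutive scans along the series in
#' increments of `step`; output spectrum k is the per-bin median of input
#' scans `[(k-1)*step + 1, (k-1)*step + window]`. Only full windows are
#' emitted, so the output length is `floor((n - window)/step) + 1`. Bins
#' absent from a scan count as zeros in the median, without ever
#' materializing the dense grid: a bin present in fewer than half the
#' window's scans has median 0 and stays absent.
#'
#' Unlike a moving average, the median ignores outlying values entirely: any
#' artifact run of at most `floor(window/2)` consecutive scans leaves the
#' smoothed output unchanged.
#'
#' @param series a [binned_series()] with at least `window` spectra.
#' @param config a [smoothing_config()].
#' @return A [binned_series()] of smoothed spectra; attribute `"spans"`
#'   holds a data frame with the input-scan span (`from`, `to`, 1-based)
#'   of each output spectrum.
#' @export
moving_median <- function(series, config = smoothing_config()) {
  stopifnot(inherits(series, "binned_series"),
            inherits(config, "smoothing_config"))
  n <- length(series$spectra)
  w <- config$window
  if (n < w) stop("series shorter than window (", n, " < ", w, ")")
  step <- config$step
  n_out <- (n - w) %/% step + 1L
  half <- (w + 1L) %/% 2L

  out <- vector("list", n_out)
  from <- integer(n_out)
  for (k in seq_len(n_out)) {
    i0 <- (k - 1L) * step + 1L
    from[k] <- i0
    members <- series$spectra[i0:(i0 + w - 1L)]
    idx <- unlist(lapply(members, `[[`, "bin"), use.names = FALSE)
    if (length(idx) == 0L) {
      out[[k]] <- binned_spectrum(series$config)
      next
    }
    val <- unlist(lapply(members, `[[`, "value"), use.names = FALSE)
    o <- order(idx, val)
    idx <- idx[o]
    val <- val[o]
    r <- rle(idx)
    cnt <- r$lengths
    starts <- cumsum(cnt) - cnt + 1L
    # median over w values of which (w - cnt) are implicit zeros:
    # nonzero iff the bin appears in more than half the window
    keep <- cnt >= half
    rank_in_nonzero <- half - (w - cnt[keep])
    med <- val[starts[keep] + rank_in_nonzero - 1L]
    out[[k]] <- binned_spectrum(series$config, r$values[keep], med)
  }
  res <- binned_series(series$label, out)
  attr(res, "spans") <- data.frame(from = from, to = from + w - 1L)
  attr(res, "smoothing") <- config
  res
}

#' Aggregate a binned series into a single spectrum
#'
#' The conventional single profile assigned to a measurement: the per-bin
#' sum of all scans, or the mean (sum divided by the scan count, so bins
#' absent from some scans are averaged with zeros).
#'
#' @param series a [binned_series()].
#' @param mode `"sum"` or `"mean"`.
#' @return A [binned_spectrum()].
#' @export
aggregate_spectrum <- function(series, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "binned_series"))
  idx <- unlist(lapply(series$spectra, `[[`, "bin"), use.names = FALSE)
  val <- unlist(lapply(series$spectra, `[[`, "value"), use.names = FALSE)
  if (length(idx) == 0L) return(binned_spectrum(series$config))
  agg <- rowsum(val, group = idx)
  v <- as.double(agg[, 1])
  if (mode == "mean") v <- v / length(series$spectra)
  binned_spectrum(series$config, as.integer(rownames(agg)), v)
}

#' Write a smoothed series with its provenance sidecar
#'
#' Same sparse triplet CSV as [write_binned_series()], plus a JSON sidecar
#' recording the window, the step, and the input-scan span behind each
#' smoothed spectrum.
#'
#' @param series a series returned by [moving_median()].
#' @param path output CSV path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_smoothed_series <- function(series, path) {
  write_binned_series(series, path)
  cfg <- attr(series, "smoothing")
  side <- list(
    window = if (is.null(cfg)) NA else cfg$window,
    step = if (is.null(cfg)) NA else cfg$step,
    spans = attr(series, "spans")
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
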