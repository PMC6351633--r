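#' Fixed-width m/z binning grid
#'
#' Defines the grid that turns a centroided scan into a fixed-dimension
#' intensity vector. Bins are half-open intervals
#' `[mz_min + i*bin_width, mz_min + (i+1)*bin_width)` so every in-range m/z
#' maps to exactly one bin. The defaults (m/z 100-1300, 0.01 Da bins,
#' 120000 bins) suit high-resolution lipid profiling where mass precision
#' is on the order of 2 ppm.
#'
#' @param mz_min lower edge of the grid (Da).
#' @param mz_max upper edge of the grid (Da, exclusive).
#' @param bin_width bin width (Da).
#' @return An object of class `bin_config` with fields `mz_min`, `mz_max`,
#'   `bin_width` and the dense dimension `n_bins`.
#' @export
bin_config <- function(mz_min = 100, mz_max = 1300, bin_width = 0.01) {
  if (!(mz_min < mz_max)) stop("mz_min must be < mz_max")
  if (!(bin_width > 0)) stop("bin_width must be > 0")
  n <- round((mz_max - mz_min) / bin_width)
  if (n < 1 || abs(n * bin_width - (mz_max - mz_min)) > 1e-6 * bin_width * n) {
    stop("(mz_max - mz_min) must be an integer multiple of bin_width")
  }
  structure(list(mz_min = as.double(mz_min), mz_max = as.double(mz_max),
                 bin_width = as.double(bin_width), n_bins = as.integer(n)),
            class = "bin_config")
}

#' @export
print.bin_config <- function(x, ...) {
  cat(sprintf("<bin_config> m/z [%g, %g), width %g Da, %d bins\n",
              x$mz_min, x$mz_max, x$bin_width, x$n_bins))
  invisible(x)
}

same_config <- function(a, b) {
  isTRUE(all.equal(a$mz_min, b$mz_min)) &&
    isTRUE(all.equal(a$mz_max, b$mz_max)) &&
    isTRUE(all.equal(a$bin_width, b$bin_width))
}

#' Construct a binned spectrum directly from sparse bin values
#'
#' Mostly useful for tests and toy examples; [bin_scan()] is the normal
#' entry point. Zero values are dropped; duplicate bins are summed.
#'
#' @param config a [bin_config()].
#' @param bin integer vector of bin indices (0-based, in `[0, n_bins)`).
#' @param value numeric vector of intensities (>= 0).
#' @return An object of class `binned_spectrum` with sorted unique 0-based
#'   `bin` indices and strictly positive `value` entries; zeros are implicit.
#' @export
binned_spectrum <- function(config, bin = integer(), value = double()) {
  stopifnot(inherits(config, "bin_config"), length(bin) == length(value))
  bin <- as.integer(bin)
  value <- as.double(value)
  if (any(value < 0)) stop("negative bin value")
  if (length(bin) > 0L && (min(bin) < 0L || max(bin) >= config$n_bins)) {
    stop("bin index outside [0, n_bins)")
  }
  keep <- value > 0
  bin <- bin[keep]
  value <- value[keep]
  if (anyDuplicated(bin)) {
    agg <- rowsum(value, group = bin)
    bin <- as.integer(rownames(agg))
    value <- as.double(agg[, 1])
  }
  o <- order(bin)
  structure(list(config = config, bin = bin[o], value = value[o],
                 dropped_peaks = 0L, dropped_intensity = 0),
            class = "binned_spectrum")
}

#' @export
print.binned_spectrum <- function(x, ...) {
  cat(sprintf("<binned_spectrum> %d/%d non-empty bins, total intensity %.4g\n",
              length(x$bin), x$config$n_bins, sum(x$value)))
  invisible(x)
}

#' Bin one scan onto a fixed m/z grid
#'
#' Each peak with m/z in `[mz_min, mz_max)` is assigned to bin
#' `floor((mz - mz_min) / bin_width)`; intensities of peaks falling in the
#' same bin are summed, so the in-range TIC is conserved. Peaks outside the
#' grid are dropped and tallied in the `dropped_peaks` / `dropped_intensity`
#' fields of the result.
#'
#' @param s an [ms_scan()].
#' @param config a [bin_config()].
#' @return A [binned_spectrum()].
#' @export
bin_scan <- function(s, config = bin_config()) {
  stopifnot(inherits(s, "ms_scan"), inherits(config, "bin_config"))
  inr <- s$mz >= config$mz_min & s$mz < config$mz_max
  idx <- as.integer(floor((s$mz[inr] - config$mz_min) / config$bin_width))
  # guard against float round-up at the top edge
  idx[idx >= config$n_bins] <- config$n_bins - 1L
  b <- binned_spectrum(config, idx, s$intensity[inr])
  b$dropped_peaks <- sum(!inr)
  b$dropped_intensity <- sum(s$intensity[!inr])
  b
}

#' Construct a binned series from a list of binned spectra
#'
#' @param label measurement label.
#' @param spectra list of [binned_spectrum()] objects sharing one config.
#' @return An object of class `binned_series`.
#' @export
binned_series <- function(label, spectra) {
  if (length(spectra) < 1L) stop("a binned series needs at least one spectrum")
  config <- spectra[[1]]$config
  ok <- vapply(spectra, function(b) same_config(b$config, config), logical(1))
  if (!all(ok)) stop("all spectra in a series must share one bin_config")
  structure(list(label = as.character(label), spectra = spectra,
                 config = config),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("<binned_series> '%s': %d spectra on %d bins\n",
              x$label, length(x$spectra), x$config$n_bins))
  invisible(x)
}

#' @export
length.binned_series <- function(x) length(x$spectra)

#' Bin every scan of a measurement
#'
#' @param m an [ms_measurement()].
#' @param config a [bin_config()].
#' @return A [binned_series()] with one spectrum per scan, in scan order.
#' @export
bin_measurement <- function(m, config = bin_config()) {
  stopifnot(inherits(m, "ms_measurement"))
  binned_series(m$label, lapply(m$scans, bin_scan, config = config))
}

#' Normalize a binned spectrum to its total ion current
#'
#' Scales the bin values so they sum to 1. Both similarity metrics are
#' invariant under this rescaling, so normalization is cosmetic for metric
#' computation but convenient for plotting and export.
#'
#' @param b a [binned_spectrum()].
#' @return The rescaled [binned_spectrum()].
#' @export
normalize_tic <- function(b) {
  stopifnot(inherits(b, "binned_spectrum"))
  tot <- sum(b$value)
  if (tot <= 0) stop("cannot normalize empty spectrum")
  b$value <- b$value / tot
  b
}

#' Dense vector view of a binned spectrum
#'
#' Materializes the implicit zeros; intended for small grids (tests, toy
#' examples) — the default grid has 120000 bins.
#'
#' @param b a [binned_spectrum()].
#' @return A dense numeric vector of length `n_bins`.
#' @export
as_dense <- function(b) {
  stopifnot(inherits(b, "binned_spectrum"))
  v <- numeric(b$config$n_bins)
  v[b$bin + 1L] <- b$value
  v
}

# one sparse column matrix (n_bins x n_scans) for a list of spectra
series_sparse_matrix <- function(spectra, config) {
  i <- unlist(lapply(spectra, function(b) b$bin + 1L), use.names = FALSE)
  j <- rep.int(seq_along(spectra),
               vapply(spectra, function(b) length(b$bin), integer(1)))
  x <- unlist(lapply(spectra, function(b) b$value), use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(config$n_bins, length(spectra)))
}

#' Write a binned series as sparse triplet CSV
#'
#' One row per non-empty bin: `scan_index,bin_index,value`, both indices
#' 0-based, scans numbered by their position in the series.
#'
#' @param series a [binned_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_binned_series <- function(series, path) {
  stopifnot(inherits(series, "binned_series"))
  rows <- do.call(rbind, lapply(seq_along(series$spectra), function(k) {
    b <- series$spectra[[k]]
    if (length(b$bin) == 0L) return(NULL)
    data.frame(scan_index = k - 1L, bin_index = b$bin, value = b$value)
  }))
  if (is.null(rows)) rows <- data.frame(scan_index = integer(),
                                        bin_index = integer(), value = double())
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
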