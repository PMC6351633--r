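# sparse dot product of two binned spectra (bins sorted, unique)
sparse_dot <- function(x, y) {
  m <- match(x$bin, y$bin)
  ok <- !is.na(m)
  if (!any(ok)) return(0)
  sum(x$value[ok] * y$value[m[ok]])
}

degenerate_value <- function() {
  structure(0, degenerate = TRUE)
}

#' Is a metric value flagged as degenerate?
#'
#' Metric functions return 0 with a degeneracy flag — rather than `NaN` —
#' when a vector is all-zero (cosine) or constant over the grid (Pearson).
#' This keeps similarity matrices renderable and makes degenerate scans
#' visible as low-similarity bands instead of poisoning downstream medians.
#'
#' @param x a value returned by [pearson_r()] or [cosine()].
#' @return `TRUE` if the value was flagged degenerate.
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

#' Pearson's r between two binned spectra
#'
#' Computes the centered correlation
#' \deqn{r = \frac{\sum (X-\bar X)(Y-\bar Y)}
#'           {\sqrt{\sum (X-\bar X)^2}\sqrt{\sum (Y-\bar Y)^2}}}
#' over the full dense grid: the mean \eqn{\bar X} is taken over all
#' `n_bins` coordinates, zeros included. On the usual sparse spectra this
#' mean is close to zero, which is why r closely tracks the cosine measure.
#' Sparse algebra reproduces dense semantics exactly via
#' \eqn{\sum(X-\bar X)(Y-\bar Y) = \sum XY - N\bar X\bar Y}.
#'
#' @param x,y [binned_spectrum()] objects sharing one [bin_config()].
#' @return The correlation in `[-1, 1]`; 0 with a degeneracy flag (see
#'   [is_degenerate()]) if either vector has zero variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(inherits(x, "binned_spectrum"), inherits(y, "binned_spectrum"))
  if (!same_config(x$config, y$config)) stop("spectra have different bin configs")
  n <- as.double(x$config$n_bins)
  if (n < 2) stop("Pearson's r needs a grid of at least 2 bins")
  mx <- sum(x$value) / n
  my <- sum(y$value) / n
  sxx <- sum(x$value^2) - n * mx^2
  syy <- sum(y$value^2) - n * my^2
  # cancellation can leave tiny negatives for (near-)constant vectors
  if (sxx <= 1e-14 * sum(x$value^2) || syy <= 1e-14 * sum(y$value^2) ||
      sxx <= 0 || syy <= 0) {
    return(degenerate_value())
  }
  sxy <- sparse_dot(x, y) - n * mx * my
  sxy / (sqrt(sxx) * sqrt(syy))
}

#' Cosine measure between two binned spectra
#'
#' Computes the cosine of the angle between the two spectrum vectors,
#' \deqn{c = \frac{\sum XY}{\sqrt{\sum X^2}\sqrt{\sum Y^2}},}
#' which lies in `[0, 1]` for nonnegative spectra and is invariant to any
#' positive rescaling (TIC normalization included). It needs no mean
#' subtraction, making it the cheaper and preferred metric on
#' high-dimensional bin vectors.
#'
#' @param x,y [binned_spectrum()] objects sharing one [bin_config()].
#' @return The cosine similarity; 0 with a degeneracy flag if either vector
#'   is all-zero.
#' @export
cosine <- function(x, y) {
  stopifnot(inherits(x, "binned_spectrum"), inherits(y, "binned_spectrum"))
  if (!same_config(x$config, y$config)) stop("spectra have different bin configs")
  nx <- sqrt(sum(x$value^2))
  ny <- sqrt(sum(y$value^2))
  if (nx == 0 || ny == 0) return(degenerate_value())
  sparse_dot(x, y) / (nx * ny)
}

#' Pairwise similarity matrix over one or more binned series
#'
#' Concatenates the series (in the given order) into one global scan index
#' and computes the chosen metric for every scan pair. Group spans record
#' which rows/columns belong to which measurement, so within- and
#' between-measurement blocks can be summarized and drawn.
#'
#' @param series a [binned_series()] or a list of them, all sharing one
#'   [bin_config()].
#' @param metric `"cosine"` (default) or `"pearson"`.
#' @return An object of class `similarity_matrix`: `values` (dense n x n
#'   matrix), `metric`, `groups` (data frame `label`, `start`, `end`;
#'   1-based inclusive spans), and `degenerate` (logical per scan).
#' @export
similarity_matrix <- function(series, metric = c("cosine", "pearson")) {
  metric <- match.arg(metric)
  if (inherits(series, "binned_series")) series <- list(series)
  stopifnot(length(series) >= 1L,
            all(vapply(series, inherits, logical(1), "binned_series")))
  config <- series[[1]]$config
  ok <- vapply(series, function(s) same_config(s$config, config), logical(1))
  if (!all(ok)) stop("all series must share one bin_config")

  counts <- vapply(series, function(s) length(s$spectra), integer(1))
  ends <- cumsum(counts)
  groups <- data.frame(
    label = vapply(series, function(s) s$label, character(1)),
    start = c(1L, utils::head(ends, -1L) + 1L),
    end = ends
  )
  spectra <- unlist(lapply(series, function(s) s$spectra), recursive = FALSE)
  n <- length(spectra)
  X <- series_sparse_matrix(spectra, config)
  G <- as.matrix(Matrix::crossprod(X))
  sumsq <- diag(G)

  if (metric == "cosine") {
    degen <- sumsq == 0
    nrm <- sqrt(sumsq)
    nrm[degen] <- 1
    vals <- G / outer(nrm, nrm)
  } else {
    N <- as.double(config$n_bins)
    mu <- Matrix::colSums(X) / N
    varv <- sumsq - N * mu^2
    degen <- varv <= 1e-14 * sumsq | varv <= 0
    C <- G - N * outer(mu, mu)
    sd <- sqrt(pmax(varv, 0))
    sd[degen] <- 1
    vals <- C / outer(sd, sd)
  }
  vals[degen, ] <- 0
  vals[, degen] <- 0
  d <- diag(vals)
  d[!degen] <- 1
  diag(vals) <- d
  structure(list(metric = metric, values = vals, groups = groups,
                 degenerate = degen),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("<similarity_matrix> %s, %d x %d scans, %d group(s)\n",
              x$metric, n, n, nrow(x$groups)))
  off <- x$values[upper.tri(x$values)]
  if (length(off) > 0) {
    cat(sprintf("  off-diagonal: mean %.4f, min %.4f, max %.4f\n",
                mean(off), min(off), max(off)))
  }
  for (k in seq_len(nrow(x$groups))) {
    cat(sprintf("  group '%s': scans %d-%d\n", x$groups$label[k],
                x$groups$start[k], x$groups$end[k]))
  }
  invisible(x)
}

#' Block-wise summary of a grouped similarity matrix
#'
#' Summarizes the similarity values within each measurement (diagonal
#' excluded) and between each pair of measurements — the numbers a
#' reproducibility report quotes: how self-similar each measurement is and
#' how similar measurements are to each other.
#'
#' @param m a [similarity_matrix()].
#' @return A data frame of class `block_summary` with one row per ordered
#'   group pair: `group_row`, `group_col`, `mean`, `min`, `max`, `n_pairs`.
#' @export
block_summary <- function(m) {
  stopifnot(inherits(m, "similarity_matrix"))
  g <- m$groups
  spans <- lapply(seq_len(nrow(g)), function(k) g$start[k]:g$end[k])
  if (anyDuplicated(unlist(spans)) || length(unlist(spans)) != nrow(m$values)) {
    stop("group spans must partition the matrix")
  }
  rows <- list()
  for (a in seq_len(nrow(g))) {
    for (b in seq_len(nrow(g))) {
      block <- m$values[spans[[a]], spans[[b]], drop = FALSE]
      if (a == b) {
        vals <- block[row(block) != col(block)]
        if (length(vals) == 0L) vals <- diag(block) # single-scan group
      } else {
        vals <- as.vector(block)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group_row = g$label[a], group_col = g$label[b],
        mean = mean(vals), min = min(vals), max = max(vals),
        n_pairs = length(vals)
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("block_summary", "data.frame")
  out
}

#' Write a similarity matrix as CSV plus a JSON sidecar
#'
#' The CSV holds the raw n x n values (negatives from Pearson's r are kept;
#' clamping happens only at display time). The sidecar records the metric
#' and the group spans.
#'
#' @param m a [similarity_matrix()].
#' @param path output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(m, path) {
  stopifnot(inherits(m, "similarity_matrix"))
  utils::write.table(m$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(metric = m$metric,
               n = nrow(m$values),
               groups = m$groups,
               degenerate_scans = which(m$degenerate) - 1L)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
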