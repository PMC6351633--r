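#' Pipeline run configuration
#'
#' Bundles everything one QC run needs: the input measurements (file paths
#' with labels), the binning grid, the smoothing parameters, the metric,
#' the threshold rule, the output directory and the plot style.
#'
#' @param inputs named character vector of input paths (`label = path`);
#'   files ending in `.mzml` (case-insensitive) are read with [read_mzml()],
#'   anything else with [read_peaktable()].
#' @param out_dir output directory, created if missing.
#' @param bin a [bin_config()].
#' @param smoothing a [smoothing_config()].
#' @param metric `"cosine"` or `"pearson"` for the similarity matrices.
#' @param threshold `"auto"` or a fixed value in `[0, 1]`.
#' @param style a [plot_style()].
#' @param drop_empty_scans drop scans with zero in-range peaks before
#'   analysis instead of retaining them (they are then flagged degenerate
#'   and rejected downstream). Default `FALSE`: retain and flag.
#' @return An object of class `run_config`.
#' @export
run_config <- function(inputs, out_dir,
                       bin = bin_config(),
                       smoothing = smoothing_config(),
                       metric = c("cosine", "pearson"),
                       threshold = "auto",
                       style = plot_style(),
                       drop_empty_scans = FALSE) {
  metric <- match.arg(metric)
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    names(inputs) <- sub("\\.[^.]*$", "", basename(inputs))
  }
  structure(list(inputs = inputs, out_dir = out_dir, bin = bin,
                 smoothing = smoothing, metric = metric,
                 threshold = threshold, style = style,
                 drop_empty_scans = drop_empty_scans),
            class = "run_config")
}

read_input <- function(path, label) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    read_mzml(path, label = label)
  } else {
    read_peaktable(path, label = label)
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full scan-QC pipeline
#'
#' For each input measurement: bin the scans, score them against the
#' smoothed aggregate, apply the threshold, write the QC report and the
#' consensus spectrum, and plot the TIC trace. Across measurements: compute
#' the raw and smoothed similarity matrices with group structure, their
#' block summaries, and heatmaps. A machine-readable report JSON listing
#' all parameters, outputs and per-measurement kept/rejected counts is
#' written to `report.json` in the output directory.
#'
#' @param cfg a [run_config()].
#' @param measurements optional list of [ms_measurement()] objects to use
#'   directly instead of reading `cfg$inputs` (used by the simulate
#'   subcommand and by tests).
#' @return The report, invisibly (a list).
#' @export
run_pipeline <- function(cfg, measurements = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)

  if (is.null(measurements)) {
    measurements <- stage("read", {
      lapply(seq_along(cfg$inputs), function(i) {
        read_input(cfg$inputs[[i]], names(cfg$inputs)[i])
      })
    })
  }

  binned <- stage("binning", lapply(measurements, bin_measurement,
                                    config = cfg$bin))
  if (cfg$drop_empty_scans) {
    binned <- lapply(binned, function(s) {
      keep <- vapply(s$spectra, function(b) length(b$bin) > 0L, logical(1))
      if (!any(keep)) stop("all scans empty in '", s$label, "'")
      binned_series(s$label, s$spectra[keep])
    })
  }

  files <- character()
  per_meas <- list()
  for (i in seq_along(binned)) {
    b <- binned[[i]]
    m <- measurements[[i]]
    qc <- stage("smoothing", score_scans(b, cfg$smoothing))
    qc <- stage("qc", apply_threshold(qc, cfg$threshold))
    cons <- stage("qc", consensus_spectrum(b, qc, mode = "mean"))
    f_qc <- out(paste0(b$label, "_qc.csv"))
    f_cons <- out(paste0(b$label, "_consensus.csv"))
    f_tic <- out(paste0(b$label, "_tic.png"))
    f_ticcsv <- out(paste0(b$label, "_tic.csv"))
    write_qc_report(qc, f_qc)
    write_consensus(cons, f_cons)
    write_tic_trace(m, f_ticcsv)
    plot_tic(m, f_tic, qc = qc, style = cfg$style)
    files <- c(files, f_qc, paste0(f_qc, ".json"), f_cons, f_ticcsv, f_tic)
    per_meas[[b$label]] <- list(
      label = b$label,
      n_scans = length(b$spectra),
      n_kept = sum(qc$keep),
      n_rejected = sum(!qc$keep),
      n_degenerate = sum(qc$degenerate),
      threshold = qc$threshold
    )
  }

  sim_raw <- stage("similarity", similarity_matrix(binned, cfg$metric))
  smoothed <- stage("smoothing", lapply(binned, moving_median,
                                        config = cfg$smoothing))
  sim_sm <- stage("similarity", similarity_matrix(smoothed, cfg$metric))
  f_raw <- out("similarity_raw.csv")
  f_sm <- out("similarity_smoothed.csv")
  f_praw <- out("similarity_raw.png")
  f_psm <- out("similarity_smoothed.png")
  write_similarity_matrix(sim_raw, f_raw)
  write_similarity_matrix(sim_sm, f_sm)
  plot_similarity_matrix(sim_raw, f_praw, style = cfg$style)
  plot_similarity_matrix(sim_sm, f_psm, style = cfg$style)
  f_blocks <- out("block_summary.csv")
  utils::write.csv(block_summary(sim_sm), f_blocks, row.names = FALSE,
                   quote = FALSE)
  files <- c(files, f_raw, paste0(f_raw, ".json"), f_sm,
             paste0(f_sm, ".json"), f_praw, f_psm, f_blocks)

  report <- list(
    parameters = list(
      mz_min = cfg$bin$mz_min, mz_max = cfg$bin$mz_max,
      bin_width = cfg$bin$bin_width,
      window = cfg$smoothing$window, step = cfg$smoothing$step,
      metric = cfg$metric,
      threshold = if (identical(cfg$threshold, "auto")) "auto"
                  else as.double(cfg$threshold),
      drop_empty_scans = cfg$drop_empty_scans
    ),
    measurements = per_meas,
    outputs = basename(files)
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
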