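# run code with a local, restorable RNG state (single Mersenne-Twister stream)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Configuration for the synthetic measurement generator
#'
#' Describes one emulated direct-infusion measurement: a stable multi-peak
#' lipid-like profile sampled repeatedly over ~300 scans with multiplicative
#' intensity noise, per-scan total-signal fluctuation, optional slow profile
#' drift, m/z jitter at the instrument's mass precision, and optional
#' artifact scans. Defaults mirror a typical ambient-ionization acquisition:
#' 300 scans over m/z 100-1300 with 2 ppm mass precision.
#'
#' @param n_scans number of scans per measurement (default 300).
#' @param n_peaks number of profile peaks (default 50).
#' @param mz_min,mz_max m/z range the peaks are drawn from (Da).
#' @param noise_sigma sd (log scale) of the per-peak multiplicative
#'   log-normal intensity noise (default 0.1).
#' @param scale_sigma sd (log scale) of the per-scan log-normal total-signal
#'   fluctuation, emulating spray-current variation (default 0.2).
#' @param drift_rate fractional profile change per scan: the profile moves
#'   linearly toward a second, independently drawn profile at this rate
#'   (default 0, no drift; reaches the second profile at scan
#'   `1/drift_rate`).
#' @param artifact_indices integer vector of 0-based scan indices to replace
#'   with artifact scans (default none).
#' @param artifact_kind `"foreign_profile"` (an unrelated random profile,
#'   emulating contamination/unstable spray), `"tic_spike"` (10x signal
#'   plus extra random peaks, an anomalous TIC maximum) or `"tic_dropout"`
#'   (signal scaled by 0.01, an anomalous TIC minimum).
#' @param mz_jitter_ppm uniform per-peak m/z jitter bound in ppm
#'   (default 2); at the default 0.01 Da bins jittered peaks stay in their
#'   bin at low m/z but can hop bins near m/z 1300, exercising bin-boundary
#'   robustness.
#' @param seed integer seed; all randomness derives from this one stream.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_scans = 300L, n_peaks = 50L,
                             mz_min = 100, mz_max = 1300,
                             noise_sigma = 0.1, scale_sigma = 0.2,
                             drift_rate = 0,
                             artifact_indices = integer(),
                             artifact_kind = c("foreign_profile",
                                               "tic_spike", "tic_dropout"),
                             mz_jitter_ppm = 2, seed = 1L) {
  artifact_kind <- match.arg(artifact_kind)
  n_scans <- as.integer(n_scans)
  n_peaks <- as.integer(n_peaks)
  artifact_indices <- sort(unique(as.integer(artifact_indices)))
  if (n_scans < 1L || n_peaks < 1L) stop("n_scans and n_peaks must be >= 1")
  if (noise_sigma < 0 || scale_sigma < 0) stop("noise sds must be >= 0")
  if (drift_rate < 0) stop("drift_rate must be >= 0")
  if (length(artifact_indices) > 0 &&
      (min(artifact_indices) < 0L || max(artifact_indices) >= n_scans)) {
    stop("artifact_indices must lie in [0, n_scans)")
  }
  structure(list(n_scans = n_scans, n_peaks = n_peaks,
                 mz_min = as.double(mz_min), mz_max = as.double(mz_max),
                 noise_sigma = noise_sigma, scale_sigma = scale_sigma,
                 drift_rate = drift_rate,
                 artifact_indices = artifact_indices,
                 artifact_kind = artifact_kind,
                 mz_jitter_ppm = mz_jitter_ppm,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# draw a lipid-like profile: peak positions and log-normal intensities
draw_profile <- function(cfg) {
  list(
    mz = sort(stats::runif(cfg$n_peaks, cfg$mz_min, cfg$mz_max)),
    intensity = stats::rlnorm(cfg$n_peaks, meanlog = log(100), sdlog = 1)
  )
}

#' Generate one synthetic measurement with ground truth
#'
#' Deterministic given the seed. Normal scans are the (possibly drifting)
#' sample profile times a per-scan log-normal scale and per-peak log-normal
#' noise, with m/z jittered within `mz_jitter_ppm`. Scans listed in
#' `artifact_indices` are replaced according to `artifact_kind`.
#'
#' @param cfg a [generator_config()].
#' @param label measurement label (default `"synthetic"`).
#' @param profile optional list with elements `mz`, `intensity` (and
#'   optionally `target`) overriding the randomly drawn base profile — used
#'   by [generate_study()] to share one profile across fragments.
#' @return A list with elements `measurement` (an [ms_measurement()]) and
#'   `truth`: `mz` (true peak positions), `profile` (n_peaks x n_scans
#'   matrix of noiseless sample intensities per scan, after drift),
#'   `scale` (per-scan scale factors) and `artifact_indices` (0-based).
#' @export
generate_measurement <- function(cfg, label = "synthetic", profile = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    base <- if (is.null(profile)) draw_profile(cfg) else profile
    target <- if (!is.null(profile) && !is.null(profile$target)) {
      profile$target
    } else {
      draw_profile(cfg)$intensity
    }
    n <- cfg$n_scans
    np <- cfg$n_peaks
    truth_profile <- matrix(0, nrow = np, ncol = n)
    scale <- numeric(n)
    is_artifact <- logical(n)
    is_artifact[cfg$artifact_indices + 1L] <- TRUE
    scans <- vector("list", n)
    jit <- cfg$mz_jitter_ppm * 1e-6
    for (t in seq_len(n)) {
      w <- min(cfg$drift_rate * (t - 1L), 1)
      prof_t <- (1 - w) * base$intensity + w * target
      truth_profile[, t] <- prof_t
      s <- stats::rlnorm(1, 0, cfg$scale_sigma)
      if (is_artifact[t]) {
        kind <- cfg$artifact_kind
        if (kind == "foreign_profile") {
          foreign <- draw_profile(cfg)
          mz <- foreign$mz * (1 + stats::runif(np, -jit, jit))
          inten <- foreign$intensity * s *
            stats::rlnorm(np, 0, cfg$noise_sigma)
        } else if (kind == "tic_spike") {
          extra <- draw_profile(cfg)
          keep_extra <- seq_len(max(1L, np %/% 2L))
          mz <- c(base$mz, extra$mz[keep_extra])
          s <- s * 10
          inten <- c(prof_t, extra$intensity[keep_extra]) * s *
            stats::rlnorm(length(mz), 0, cfg$noise_sigma)
          mz <- mz * (1 + stats::runif(length(mz), -jit, jit))
        } else { # tic_dropout
          s <- s * 0.01
          mz <- base$mz * (1 + stats::runif(np, -jit, jit))
          inten <- prof_t * s * stats::rlnorm(np, 0, cfg$noise_sigma)
        }
      } else {
        mz <- base$mz * (1 + stats::runif(np, -jit, jit))
        inten <- prof_t * s * stats::rlnorm(np, 0, cfg$noise_sigma)
      }
      scale[t] <- s
      scans[[t]] <- ms_scan(mz, inten, scan_index = t - 1L, time = t - 1)
    }
    list(
      measurement = ms_measurement(label, scans),
      truth = list(mz = base$mz, profile = truth_profile, scale = scale,
                   artifact_indices = cfg$artifact_indices)
    )
  })
}

#' Binned spectrum of a ground-truth profile
#'
#' Bins the noiseless sample profile — by default averaged over all scans —
#' onto a grid, for comparing consensus spectra against the truth.
#'
#' @param truth the `truth` element returned by [generate_measurement()].
#' @param config a [bin_config()].
#' @param scans which scans (1-based columns) to average; default all.
#' @return A [binned_spectrum()].
#' @export
truth_spectrum <- function(truth, config = bin_config(), scans = NULL) {
  if (is.null(scans)) scans <- seq_len(ncol(truth$profile))
  inten <- rowMeans(truth$profile[, scans, drop = FALSE])
  bin_scan(ms_scan(truth$mz, inten, scan_index = 0L), config)
}

#' Generate a multi-sample, multi-fragment synthetic study
#'
#' Emulates a tissue-profiling design: each sample has one underlying
#' molecular profile, measured independently on several fragments. All
#' fragments of a sample share the sample's base profile but get fresh
#' noise, scale fluctuations and (if configured) artifacts; distinct
#' samples get independently drawn profiles.
#'
#' @param samples a list; each element is a list with `label` (sample name),
#'   `n_fragments` (integer >= 1) and `config` (a [generator_config()]; its
#'   `seed` identifies the sample and seeds both the shared profile and,
#'   offset by the fragment number, each fragment's noise).
#' @return A list with `measurements` (flat list of [ms_measurement()],
#'   labelled `<sample><fragment letter>`) and `truths` (matching list of
#'   ground truths).
#' @export
generate_study <- function(samples) {
  measurements <- list()
  truths <- list()
  for (s in samples) {
    stopifnot(inherits(s$config, "generator_config"))
    base <- with_seed(s$config$seed, {
      p <- draw_profile(s$config)
      p$target <- draw_profile(s$config)$intensity
      p
    })
    for (f in seq_len(s$n_fragments)) {
      cfg_f <- s$config
      cfg_f$seed <- s$config$seed + 101L * f
      lab <- paste0(s$label, letters[f])
      res <- generate_measurement(cfg_f, label = lab, profile = base)
      measurements[[lab]] <- res$measurement
      truths[[lab]] <- res$truth
    }
  }
  list(measurements = measurements, truths = truths)
}
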