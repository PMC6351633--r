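test_that("the generator is deterministic given its seed", {
  cfg <- generator_config(n_scans = 30, seed = 7,
                          artifact_indices = c(3L, 17L))
  a <- generate_measurement(cfg)
  b <- generate_measurement(cfg)
  expect_identical(a$measurement, b$measurement)
  expect_identical(a$truth, b$truth)
  c <- generate_measurement(generator_config(n_scans = 30, seed = 8,
                                             artifact_indices = c(3L, 17L)))
  expect_false(identical(a$measurement, c$measurement))
})

test_that("noise-free, drift-free, artifact-free scans are identical after binning", {
  cfg <- generator_config(n_scans = 12, n_peaks = 20, noise_sigma = 0,
                          scale_sigma = 0, drift_rate = 0,
                          mz_jitter_ppm = 0, seed = 2)
  g <- generate_measurement(cfg)
  series <- bin_measurement(g$measurement)
  first <- series$spectra[[1]]
  for (b in series$spectra[-1]) {
    expect_equal(b$bin, first$bin)
    expect_equal(b$value, first$value)
  }
  sm <- similarity_matrix(series, "cosine")
  expect_equal(sm$values, matrix(1, 12, 12), ignore_attr = TRUE)
})

test_that("ground truth is consistent with the emitted measurement", {
  cfg <- generator_config(n_scans = 25, n_peaks = 15, seed = 11,
                          artifact_indices = c(4L, 9L), scale_sigma = 0.2)
  g <- generate_measurement(cfg)
  expect_equal(dim(g$truth$profile), c(15L, 25L))
  expect_length(g$truth$scale, 25L)
  expect_equal(g$truth$artifact_indices, c(4L, 9L))
  # normal scans: intensities = profile * scale * lognormal noise, so
  # log(intensity) - log(profile * scale) should be small at sigma 0.1
  t <- 2L # scan index 1 (0-based), not an artifact
  s <- g$measurement$scans[[t]]
  expect_length(s$mz, 15L)
  ratio <- log(s$intensity / (g$truth$profile[, t] * g$truth$scale[t]))
  expect_true(all(abs(ratio) < 6 * 0.1))
  # m/z jittered by at most 2 ppm around the true positions
  expect_true(all(abs(s$mz / g$truth$mz - 1) <= 2e-6 + 1e-12))
})

test_that("artifact kinds produce their distinctive signatures", {
  base <- function(kind, idx = 10L) {
    generate_measurement(generator_config(
      n_scans = 21, n_peaks = 20, seed = 5, scale_sigma = 0,
      artifact_indices = idx, artifact_kind = kind
    ))
  }
  tics <- function(g) tic_trace(g$measurement)$tic

  spike <- base("tic_spike")
  expect_gt(tics(spike)[11], 5 * median(tics(spike)[-11]))

  drop <- base("tic_dropout")
  expect_lt(tics(drop)[11], 0.05 * median(tics(drop)[-11]))

  foreign <- base("foreign_profile")
  series <- bin_measurement(foreign$measurement)
  ref <- truth_spectrum(foreign$truth)
  # normal scans stay close to the truth (bin-boundary flicker allows some
  # loss); the foreign scan is far from it
  expect_lt(as.double(cosine(series$spectra[[11]], ref)), 0.3)
  expect_gt(as.double(cosine(series$spectra[[1]], ref)), 0.7)
})

test_that("drift morphs the profile over the run", {
  cfg <- generator_config(n_scans = 80, n_peaks = 25, seed = 13,
                          noise_sigma = 0, scale_sigma = 0,
                          mz_jitter_ppm = 0, drift_rate = 1 / 80)
  g <- generate_measurement(cfg)
  series <- bin_measurement(g$measurement)
  first <- series$spectra[[1]]
  expect_lt(as.double(cosine(first, series$spectra[[80]])),
            as.double(cosine(first, series$spectra[[2]])))
  # within-measurement similarity decays with time separation
  sm <- similarity_matrix(series, "cosine")
  expect_lt(sm$values[1, 80], sm$values[1, 10])
})

test_that("a study shares profiles within samples and separates samples", {
  study <- generate_study(list(
    list(label = "A", n_fragments = 2,
         config = generator_config(n_scans = 30, seed = 100)),
    list(label = "B", n_fragments = 2,
         config = generator_config(n_scans = 30, seed = 200))
  ))
  expect_named(study$measurements, c("Aa", "Ab", "Ba", "Bb"))
  # fragments of one sample share true peak positions; samples do not
  expect_equal(study$truths$Aa$mz, study$truths$Ab$mz)
  expect_false(isTRUE(all.equal(study$truths$Aa$mz, study$truths$Ba$mz)))
  # fragments have distinct noise realizations
  expect_false(identical(study$measurements$Aa$scans[[1]]$intensity,
                         study$measurements$Ab$scans[[1]]$intensity))
  expect_length(generate_study(list()), 2L)

  series <- lapply(study$measurements, bin_measurement)
  bs <- block_summary(similarity_matrix(unname(series), "cosine"))
  within <- bs$mean[bs$group_row == bs$group_col]
  same_sample <- bs$mean[bs$group_row == "Aa" & bs$group_col == "Ab"]
  diff_sample <- bs$mean[bs$group_row == "Aa" & bs$group_col == "Ba"]
  expect_gt(same_sample, diff_sample)
  expect_true(all(within > diff_sample))
})
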