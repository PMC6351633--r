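test_that("hand-checkable metric values", {
  # perfect linear relation
  expect_equal(pearson_r(toy_spectrum(c(1, 2, 3)), toy_spectrum(c(2, 4, 6))),
               1.0, tolerance = 1e-12)
  # two-point anti-correlation
  expect_equal(pearson_r(toy_spectrum(c(1, 0)), toy_spectrum(c(0, 1))),
               -1.0, tolerance = 1e-12)
  # direct evaluation of the centered formula gives 4/5
  expect_equal(pearson_r(toy_spectrum(c(1, 2, 3, 4)),
                         toy_spectrum(c(1, 3, 2, 4))),
               0.8, tolerance = 1e-12)
  # identical direction, orthogonal, and 24/(5*5)
  x <- toy_spectrum(c(3, 4))
  expect_equal(cosine(x, x), 1.0, tolerance = 1e-12)
  expect_equal(cosine(toy_spectrum(c(1, 0)), toy_spectrum(c(0, 1))), 0.0)
  expect_equal(cosine(toy_spectrum(c(3, 4)), toy_spectrum(c(4, 3))),
               0.96, tolerance = 1e-12)
})

test_that("sparse metrics match dense oracles on random sparse vectors", {
  set.seed(123)
  for (rep in 1:50) {
    n <- sample(10:1000, 1)
    cfg <- toy_config(n)
    vx <- random_sparse_values(n, sample.int(min(n, 40), 1))
    vy <- random_sparse_values(n, sample.int(min(n, 40), 1))
    x <- toy_spectrum(vx, cfg)
    y <- toy_spectrum(vy, cfg)
    expect_equal(as.double(pearson_r(x, y)), oracle_pearson(vx, vy),
                 tolerance = 1e-12)
    expect_equal(as.double(cosine(x, y)), oracle_cosine(vx, vy),
                 tolerance = 1e-12)
    # symmetry
    expect_equal(as.double(pearson_r(y, x)), as.double(pearson_r(x, y)))
    expect_equal(as.double(cosine(y, x)), as.double(cosine(x, y)))
  }
})

test_that("Pearson equals cosine on mean-zero vectors and both are scale invariant", {
  set.seed(5)
  for (rep in 1:25) {
    n <- 50
    cfg <- toy_config(n)
    vx <- random_sparse_values(n, 10)
    vy <- random_sparse_values(n, 10)
    # center to mean zero (dense); note: centered vectors have negatives,
    # allowed by the algebra even if real spectra are nonnegative
    cx <- vx - mean(vx)
    cy <- vy - mean(vy)
    expect_equal(oracle_pearson(cx, cy), oracle_cosine(cx, cy),
                 tolerance = 1e-12)
    expect_equal(as.double(pearson_r(toy_spectrum(vx, cfg),
                                     toy_spectrum(vy, cfg))),
                 oracle_cosine(cx, cy), tolerance = 1e-12)
    # invariance to positive rescaling and TIC normalization
    c1 <- runif(1, 0.1, 50)
    x <- toy_spectrum(vx, cfg)
    y <- toy_spectrum(vy, cfg)
    xs <- toy_spectrum(c1 * vx, cfg)
    expect_equal(as.double(cosine(xs, y)), as.double(cosine(x, y)),
                 tolerance = 1e-12)
    expect_equal(as.double(pearson_r(xs, y)), as.double(pearson_r(x, y)),
                 tolerance = 1e-12)
    expect_equal(as.double(cosine(normalize_tic(x), normalize_tic(y))),
                 as.double(cosine(x, y)), tolerance = 1e-9)
    expect_equal(as.double(pearson_r(normalize_tic(x), normalize_tic(y))),
                 as.double(pearson_r(x, y)), tolerance = 1e-9)
  }
})

test_that("degenerate vectors give flagged zeros, not NaN", {
  cfg <- toy_config(4)
  zero <- toy_spectrum(numeric(4), cfg)
  x <- toy_spectrum(c(1, 2, 0, 0), cfg)
  const <- toy_spectrum(c(3, 3, 3, 3), cfg)
  for (val in list(cosine(zero, x), pearson_r(zero, x),
                   pearson_r(const, x))) {
    expect_identical(as.double(val), 0)
    expect_true(is_degenerate(val))
  }
  expect_false(is_degenerate(cosine(x, x)))
  expect_error(cosine(x, toy_spectrum(c(1, 2, 3))), "different bin configs")
})

test_that("similarity_matrix matches brute-force double loop and is well-formed", {
  set.seed(99)
  cfg <- toy_config(200)
  for (metric in c("cosine", "pearson")) {
    mats <- lapply(1:2, function(k) replicate(4, random_sparse_values(200, 15)))
    series <- list(toy_series(mats[[1]], "a", cfg),
                   toy_series(mats[[2]], "b", cfg))
    sm <- similarity_matrix(series, metric)
    dense <- cbind(mats[[1]], mats[[2]])
    n <- ncol(dense)
    oracle <- if (metric == "cosine") oracle_cosine else oracle_pearson
    brute <- outer(1:n, 1:n, Vectorize(function(i, j) {
      oracle(dense[, i], dense[, j])
    }))
    expect_equal(sm$values, brute, tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(isSymmetric(sm$values, tol = 1e-12))
    expect_equal(diag(sm$values), rep(1, n), ignore_attr = TRUE)
    expect_true(all(sm$values >= -1 - 1e-12 & sm$values <= 1 + 1e-12))
    expect_equal(sm$groups$start, c(1L, 5L))
    expect_equal(sm$groups$end, c(4L, 8L))
  }
})

test_that("identical spectra give an all-ones matrix; orthogonal groups a block matrix", {
  cfg <- toy_config(6)
  one <- toy_series(matrix(rep(c(1, 2, 3, 0, 0, 0), 3), ncol = 3), "a", cfg)
  sm <- similarity_matrix(one, "cosine")
  expect_equal(sm$values, matrix(1, 3, 3), ignore_attr = TRUE)

  other <- toy_series(matrix(rep(c(0, 0, 0, 5, 1, 2), 2), ncol = 2), "b", cfg)
  sm2 <- similarity_matrix(list(one, other), "cosine")
  expect_equal(sm2$values[1:3, 4:5], matrix(0, 3, 2), ignore_attr = TRUE)
  expect_equal(sm2$values[4:5, 4:5], matrix(1, 2, 2), ignore_attr = TRUE)
})

test_that("an all-zero scan yields a zero row/column (low-similarity band)", {
  cfg <- toy_config(4)
  mat <- cbind(c(1, 2, 0, 0), c(0, 0, 0, 0), c(1, 2, 0, 0))
  sm <- similarity_matrix(toy_series(mat, "a", cfg), "cosine")
  expect_equal(sm$values[2, ], c(0, 0, 0))
  expect_equal(sm$values[, 2], c(0, 0, 0))
  expect_equal(sm$degenerate, c(FALSE, TRUE, FALSE))
})

test_that("block_summary equals direct block averaging and flags bad groups", {
  vals <- matrix(c(1, .9, .2, .1,
                   .9, 1, .3, .2,
                   .2, .3, 1, .8,
                   .1, .2, .8, 1), 4, 4, byrow = TRUE)
  m <- structure(list(metric = "cosine", values = vals,
                      groups = data.frame(label = c("g", "h"),
                                          start = c(1L, 3L), end = c(2L, 4L)),
                      degenerate = rep(FALSE, 4)),
                 class = "similarity_matrix")
  bs <- block_summary(m)
  expect_s3_class(bs, "block_summary")
  within_g <- bs[bs$group_row == "g" & bs$group_col == "g", ]
  expect_equal(within_g$mean, 0.9) # diagonal excluded
  between <- bs[bs$group_row == "g" & bs$group_col == "h", ]
  expect_equal(between$mean, mean(c(.2, .1, .3, .2)))
  expect_equal(between$min, 0.1)
  expect_equal(between$max, 0.3)

  # identical spectra: within mean exactly 1
  sm1 <- similarity_matrix(toy_series(matrix(rep(c(1, 2), 3), ncol = 3)),
                           "cosine")
  expect_equal(block_summary(sm1)$mean, 1)

  m$groups$end[1] <- 3L # overlap
  expect_error(block_summary(m), "partition")
})

test_that("matrix CSV + JSON sidecar round-trips values, metric and groups", {
  set.seed(3)
  sm <- similarity_matrix(toy_series(replicate(3, random_sparse_values(20, 5)),
                                     config = toy_config(20)), "pearson")
  f <- withr::local_tempfile(fileext = ".csv")
  write_similarity_matrix(sm, f)
  vals <- as.matrix(read.csv(f, header = FALSE))
  expect_equal(unname(vals), unname(sm$values), tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$metric, "pearson")
  expect_equal(side$groups$start, 1L)
})
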