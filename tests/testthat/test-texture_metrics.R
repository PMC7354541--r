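test_that("degenerate regions return flagged zeros", {
  m <- make_map(matrix(5, 12, 12))
  tv <- compute_metrics(m, full_mask(m), erode = FALSE, min_pixels = 10)
  expect_equal(tv$mean, 5)
  expect_equal(tv$sd, 0)
  expect_equal(tv$entropy, 0)
  expect_equal(tv$mpp, 5)
  expect_equal(tv$skewness, 0)
  expect_equal(tv$kurtosis, 0)
  expect_true("zero_variance" %in% tv$flags)

  neg <- make_map(matrix(rep(c(-2, -1), 72), 12, 12))
  tv2 <- compute_metrics(neg, full_mask(neg), erode = FALSE, min_pixels = 10)
  expect_equal(tv2$mpp, 0)
  expect_true("no_positive_pixels" %in% tv2$flags)

  half <- make_map(matrix(rep(c(-1, 1), 72), 12, 12))
  tv3 <- compute_metrics(half, full_mask(half), erode = FALSE, min_pixels = 10)
  expect_equal(tv3$mean, 0)
  expect_equal(tv3$sd, 1)
  expect_equal(tv3$mpp, 1)
})

test_that("all six metrics match the brute-force oracle to 1e-12 relative", {
  set.seed(301)
  for (rep in 1:25) {
    n <- sample(60:90, 1)
    vals <- switch(1 + rep %% 3,
                   matrix(rnorm(n * n, sd = runif(1, 0.5, 20)), n, n),
                   matrix(rexp(n * n, rate = 0.2) - 3, n, n),
                   matrix(rt(n * n, df = 5) * 4 + runif(1, -5, 5), n, n))
    m <- make_map(vals)
    mask <- matrix(runif(n * n) < runif(1, 0.2, 0.9), n, n)
    if (sum(mask) < 60) mask[1:8, 1:8] <- TRUE
    rmask <- roi_mask(mask, "whole_liver",
                      make_slice(matrix(0, n, n)))
    tv <- compute_metrics(m, rmask, erode = FALSE)
    ora <- oracle_metrics(vals[mask])
    for (nm in c("mean", "sd", "entropy", "mpp", "skewness", "kurtosis")) {
      expect_equal(tv[[nm]], ora[[nm]], tolerance = 1e-12,
                   label = sprintf("%s (rep %d)", nm, rep))
    }
  }
})

test_that("moments agree with e1071 and a large normal sample is near-Gaussian", {
  skip_if_not_installed("e1071")
  set.seed(302)
  vals <- matrix(rnorm(10000), 100, 100)
  m <- make_map(vals)
  tv <- compute_metrics(m, full_mask(m), erode = FALSE)
  v <- as.vector(vals)
  expect_equal(tv$skewness, e1071::skewness(v, type = 1), tolerance = 1e-12)
  expect_equal(tv$kurtosis, e1071::kurtosis(v, type = 1), tolerance = 1e-12)
  expect_lt(abs(tv$skewness), 0.1)
  expect_lt(abs(tv$kurtosis), 0.1)
  expect_equal(tv$mean, mean(v), tolerance = 1e-12)
})

test_that("shift and scale equivariances hold", {
  set.seed(303)
  vals <- matrix(abs(rnorm(64 * 64)) + 1, 64, 64)  # strictly positive
  m0 <- make_map(vals)
  base <- compute_metrics(m0, full_mask(m0), erode = FALSE)
  cshift <- 7.25
  shifted <- compute_metrics(make_map(vals + cshift), full_mask(m0), erode = FALSE)
  expect_equal(shifted$mean, base$mean + cshift, tolerance = 1e-10)
  expect_equal(shifted$mpp, base$mpp + cshift, tolerance = 1e-10)
  expect_equal(shifted$sd, base$sd, tolerance = 1e-10)
  expect_equal(shifted$skewness, base$skewness, tolerance = 1e-9)
  expect_equal(shifted$kurtosis, base$kurtosis, tolerance = 1e-9)
  expect_equal(shifted$entropy, base$entropy, tolerance = 1e-9)

  a <- 3.5
  scaled <- compute_metrics(make_map(a * vals), full_mask(m0), erode = FALSE)
  expect_equal(scaled$sd, a * base$sd, tolerance = 1e-10)
  expect_equal(scaled$skewness, base$skewness, tolerance = 1e-9)
  expect_equal(scaled$kurtosis, base$kurtosis, tolerance = 1e-9)
  expect_equal(scaled$entropy, base$entropy, tolerance = 1e-9)
})

test_that("erosion shrinks the sample and tiny samples are refused", {
  set.seed(304)
  sl <- make_slice(matrix(runif(64 * 64, 0, 100), 64, 64))
  mask <- roi_mask({
    m <- matrix(FALSE, 64, 64); m[20:45, 20:45] <- TRUE; m
  }, "segment7", sl)
  fm <- filter_slice(sl, 6)
  full <- compute_metrics(fm, mask, erode = FALSE)
  eroded <- compute_metrics(fm, mask, erode = TRUE)
  expect_lt(eroded$n_pixels, full$n_pixels)

  tiny <- roi_mask({
    m <- matrix(FALSE, 64, 64); m[30:32, 30:32] <- TRUE; m
  }, "segment7", sl)
  expect_error(compute_metrics(fm, tiny, erode = FALSE),
               class = "eqctta_sampling_error")
  expect_error(compute_metrics(fm, tiny, erode = TRUE),
               class = "eqctta_geometry_error")
})

test_that("subtraction features are metric-wise, antisymmetric and flag-unioning", {
  set.seed(305)
  sl_pre <- make_slice(matrix(runif(48 * 48, 20, 80), 48, 48), phase = "pre")
  sl_eq <- make_slice(sl_pre$pixels + 15 + matrix(rnorm(48 * 48), 48, 48),
                      phase = "eq")
  mask <- full_mask(make_map(sl_pre$pixels))
  tv_pre <- compute_metrics(filter_slice(sl_pre, 4), mask)
  tv_eq <- compute_metrics(filter_slice(sl_eq, 4), mask)
  d <- subtract_features(tv_eq, tv_pre)
  expect_identical(d$phase, "diff")
  expect_equal(d$mean, tv_eq$mean - tv_pre$mean, tolerance = 1e-12)
  expect_equal(d$sd, tv_eq$sd - tv_pre$sd, tolerance = 1e-12)
  rev <- subtract_features(tv_pre, tv_eq)
  for (nm in c("mean", "sd", "entropy", "mpp", "skewness", "kurtosis")) {
    expect_equal(d[[nm]], -rev[[nm]], tolerance = 1e-12)
  }
  self0 <- subtract_features(tv_eq,
                             within_phase <- {
                               x <- tv_eq; x$phase <- "pre"; x
                             })
  expect_true(all(abs(unlist(self0[c("mean", "sd", "entropy", "mpp",
                                     "skewness", "kurtosis")])) == 0))

  tv_other <- compute_metrics(filter_slice(sl_pre, 6), mask)
  expect_error(subtract_features(tv_eq, tv_other), class = "eqctta_pairing_error")
  expect_error(subtract_features(tv_eq, tv_eq), class = "eqctta_pairing_error")
})
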