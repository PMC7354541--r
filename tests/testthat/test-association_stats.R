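test_that("perfect monotone and antitone vectors give r_s = +/-1 with the permutation bound", {
  up <- spearman_cor(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(up$r_s, 1)
  expect_equal(up$p_value, 2 / factorial(5), tolerance = 1e-12)
  expect_true("exact_bound" %in% up$flags)
  down <- spearman_cor(c(1, 2, 3), c(3, 2, 1))
  expect_equal(down$r_s, -1)
  expect_equal(down$p_value, 2 / factorial(3), tolerance = 1e-12)
})

test_that("tie handling and p-values match independent oracles to 1e-12", {
  cases <- list(
    list(x = c(1, 1, 2, 3), y = c(2, 1, 4, 4)),
    list(x = c(5, 5, 5, 1, 2, 2, 9), y = c(3, 1, 4, 4, 2, 2, 8)),
    list(x = c(0.1, 0.1, 0.1, 0.2, 0.7, 0.7), y = c(1, 2, 3, 3, 2, 1))
  )
  for (cs in cases) {
    got <- spearman_cor(cs$x, cs$y)
    ora <- oracle_spearman(cs$x, cs$y)
    expect_equal(got$r_s, ora$r_s, tolerance = 1e-12)
    expect_equal(got$p_value, ora$p_value, tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(cs$x, cs$y, method = "spearman",
                                    exact = FALSE))
    expect_equal(got$r_s, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-12)
  }
  set.seed(501)
  for (rep in 1:20) {
    x <- sample(1:6, 15, replace = TRUE)
    y <- x + sample(-2:2, 15, replace = TRUE)
    got <- spearman_cor(x, y)
    ora <- oracle_spearman(x, y)
    expect_equal(got$r_s, ora$r_s, tolerance = 1e-12)
    if (abs(got$r_s) < 1 - 1e-14) {
      expect_equal(got$p_value, ora$p_value, tolerance = 1e-12)
    }
  }
})

test_that("r_s is invariant under strictly monotone transforms", {
  set.seed(502)
  x <- rnorm(25)
  y <- 0.6 * x + rnorm(25)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$r_s, base$r_s, tolerance = 1e-12)
  expect_equal(spearman_cor(x, y^3)$r_s, base$r_s, tolerance = 1e-12)
  expect_equal(spearman_cor(rank(x), atan(y))$r_s, base$r_s, tolerance = 1e-12)
})

test_that("exact permutation p-values enumerate correctly for small n", {
  r <- spearman_cor(1:4, 1:4, exact = TRUE)
  expect_equal(r$p_value, 2 / 24, tolerance = 1e-12)  # identity + reversal
  expect_true("exact_permutation" %in% r$flags)
  expect_error(spearman_cor(1:20, 20:1, exact = TRUE),
               class = "eqctta_input_error")
})

test_that("degenerate inputs are rejected", {
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), class = "eqctta_input_error")
  expect_error(spearman_cor(c(1, 2), c(1, 2)), class = "eqctta_input_error")
  expect_error(spearman_cor(c(1, 2, NA), c(1, 2, 3)), class = "eqctta_input_error")
})

test_that("correlate_features covers pairs, handles missing phases and constants", {
  set.seed(503)
  n <- 12
  ids <- sprintf("p%02d", 1:n)
  marker <- rnorm(n)
  ft <- data.frame(patient_id = ids,
                   whole_liver_pre_ssf0_mean = marker,          # identical to marker
                   whole_liver_pre_ssf2_sd = rnorm(n),
                   whole_liver_diff_ssf2_mean = c(rnorm(n - 4), rep(NA, 4)),
                   segment7_pre_ssf0_entropy = rep(1.5, n))      # constant
  clin <- data.frame(patient_id = ids, elf = marker)
  expect_message(ct <- correlate_features(ft, clin, markers = "elf"),
                 "constant")
  expect_equal(ct$r_s[ct$metric == "mean" & ct$phase == "pre"], 1)
  expect_equal(ct$n[ct$phase == "diff"], n - 4)          # pairwise-complete
  expect_false("entropy" %in% ct$metric)                 # constant skipped
  ct_bh <- correlate_features(ft, clin, markers = "elf", p_adjust = TRUE)
  expect_true(all(ct_bh$p_bh >= ct_bh$p_value - 1e-15))
})

test_that("wide layout carries one r_s and one p row per SSF x marker block", {
  set.seed(504)
  n <- 10
  ids <- sprintf("p%02d", 1:n)
  ft <- data.frame(patient_id = ids)
  for (region in c("whole_liver", "segment7")) {
    for (phase in c("pre", "eq")) {
      for (ssf in c(4, 6)) {
        for (met in c("sd", "entropy", "mpp")) {
          ft[[sprintf("%s_%s_ssf%g_%s", region, phase, ssf, met)]] <- rnorm(n)
        }
      }
    }
  }
  clin <- data.frame(patient_id = ids, cpa_percent = rnorm(n), ecv = rnorm(n))
  ct <- correlate_features(ft, clin, markers = c("cpa_percent", "ecv"))
  wide <- correlation_wide(ct, marker_rows = c("cpa_percent", "ecv"))
  expect_equal(nrow(wide), 2 * 2 * 2)       # 2 SSFs x 2 markers x (r_s, p)
  expect_equal(sum(grepl("_sd$|_entropy$|_mpp$", names(wide))), 12)
  expect_true(all(c("ssf_mm", "marker", "quantity") %in% names(wide)))
})
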