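test_that("phantom generation is bitwise deterministic in its seed", {
  p <- phantom_params(severity = 0.5, seed = 77)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$pre$pixels, b$pre$pixels)
  expect_identical(a$eq$pixels, b$eq$pixels)
  expect_identical(a$masks$segment7$mask, b$masks$segment7$mask)
  expect_identical(a$record, b$record)
  c1 <- generate_phantom(phantom_params(severity = 0.5, seed = 78))
  expect_false(identical(a$pre$pixels, c1$pre$pixels))
})

test_that("a featureless noiseless phantom has constant parenchyma and no texture", {
  p <- phantom_params(severity = 0, seed = 5, noise_sd_hu = 0,
                      mottle_sd_hu = 0, feature_density_base = 0,
                      vessel_count = 0L)
  ph <- generate_phantom(p)
  inside <- ph$masks$whole_liver$mask
  expect_equal(diff(range(ph$pre$pixels[inside])), 0)
  expect_equal(unique(ph$pre$pixels[inside]), 55)
  # texture SD deep inside the parenchyma (clear of the organ edge) is 0
  n <- nrow(inside)
  rowmm <- matrix((seq_len(n) - 0.5), n, n)
  colmm <- t(rowmm)
  deep <- (rowmm - 48)^2 + (colmm - 44)^2 <= 22^2
  deep_mask <- roi_mask(deep, "whole_liver", ph$pre)
  for (ssf in c(2, 4, 6)) {
    tv <- compute_metrics(filter_slice(ph$pre, ssf), deep_mask, erode = FALSE)
    expect_lt(tv$sd, 1e-9)
  }
})

test_that("phantom ECV construction satisfies the partition relation", {
  for (seed in 1:5) {
    ph <- generate_phantom(phantom_params(severity = (seed - 1) / 4, seed = seed))
    r <- ecv_from_slices(ph$pre_sections, ph$eq_sections,
                         ph$masks$whole_liver, ph$masks$aorta,
                         ph$truth$haematocrit)
    expect_lt(abs(r$ecv - ph$truth$ecv_true), 0.02)
  }
})

test_that("blob count grows with severity and markers are monotone links", {
  a <- generate_phantom(phantom_params(severity = 0, seed = 90))
  b <- generate_phantom(phantom_params(severity = 1, seed = 90))
  expect_gt(b$truth$n_blobs, a$truth$n_blobs)

  set.seed(91)
  sv <- runif(100)
  seeds <- sample.int(1e6, 100)
  rec <- t(vapply(seq_along(sv), function(i) {
    ph <- generate_phantom(phantom_params(severity = sv[i], seed = seeds[i]))
    c(elf = ph$record$elf, cpa = ph$record$cpa_percent,
      ishak = ph$record$ishak)
  }, numeric(3)))
  expect_gt(spearman_cor(sv, rec[, "elf"])$r_s, 0.9)
  expect_gt(spearman_cor(sv, rec[, "cpa"])$r_s, 0.9)
  expect_gt(spearman_cor(sv, rec[, "ishak"])$r_s, 0.8)
})

test_that("phantom blobs of diameter d respond most at SSF = d", {
  n <- 96
  rowmm <- matrix((seq_len(n) - 0.5), n, n)
  colmm <- t(rowmm)
  r <- sqrt((rowmm - 48)^2 + (colmm - 44)^2)
  for (d in c(3, 4, 5)) {
    ph <- generate_phantom(phantom_params(
      severity = 0, seed = 11, noise_sd_hu = 0, mottle_sd_hu = 0,
      vessel_count = 0L, feature_density_base = 2, feature_density_gain = 0,
      feature_diameter_mm = d, blob_amplitude_hu = 20))
    cen <- ph$truth$blob_centers_mm
    inblob <- matrix(FALSE, n, n)
    for (i in seq_len(nrow(cen))) {
      inblob <- inblob |
        ((rowmm - cen[i, 1])^2 + (colmm - cen[i, 2])^2 <= (d / 2)^2)
    }
    inblob <- inblob & (r <= 30)  # clear of the organ edge
    resp <- vapply(c(2, 3, 4, 5, 6), function(s) {
      v <- filter_slice(ph$pre, s)$pixels[inblob]
      mean(v[v > 0])
    }, numeric(1))
    expect_identical(c(2, 3, 4, 5, 6)[which.max(resp)], d)
  }
})

test_that("parameter validation rejects impossible settings", {
  expect_error(phantom_params(severity = 1.2), class = "eqctta_parameter_error")
  expect_error(phantom_params(ecv0 = 0.9, ecv_gain = 0.2),
               class = "eqctta_parameter_error")
  expect_error(phantom_params(nonsense_knob = 1),
               class = "eqctta_parameter_error")
  expect_error(phantom_params(delta_hu_blood = -5),
               class = "eqctta_parameter_error")
  expect_error(generate_phantom(phantom_params(parenchyma_mu_hu = 3000,
                                               blob_amplitude_hu = 500,
                                               seed = 2)),
               class = "eqctta_parameter_error")
})

test_that("simulate_cohort writes a deterministic cohort with the requested phase gaps", {
  dir1 <- withr::local_tempdir()
  sim <- simulate_cohort(29, dir1, seed = 7, eq_missing_fraction = 8 / 29)
  expect_equal(nrow(sim$manifest), 29)
  expect_equal(sum(!is.na(sim$manifest$eq_path)), 21)
  expect_true(all(file.exists(sim$manifest$pre_path)))
  expect_true(all(file.exists(na.omit(sim$manifest$eq_path))))
  expect_equal(nrow(sim$clinical), 29)

  dir2 <- withr::local_tempdir()
  sim2 <- simulate_cohort(29, dir2, seed = 7, eq_missing_fraction = 8 / 29)
  expect_identical(sim$clinical, sim2$clinical)
  expect_identical(is.na(sim$manifest$eq_path), is.na(sim2$manifest$eq_path))
  p1 <- read_ct_slice(sim$manifest$pre_path[1], "pre")
  p2 <- read_ct_slice(sim2$manifest$pre_path[1], "pre")
  expect_identical(p1$pixels, p2$pixels)
  expect_error(simulate_cohort(1, dir1), class = "eqctta_parameter_error")
})
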