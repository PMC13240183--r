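test_that("median mixed-layer irradiance follows the attenuation formula", {
  expect_equal(median_mixed_layer_irradiance(40, 0.05, 0), 40)
  expect_equal(median_mixed_layer_irradiance(0, 0.05, 50), 0)
  expect_equal(median_mixed_layer_irradiance(40, 0.05, 40), 40 * exp(-1))
  # vectorizes over arrays and propagates the mask
  a <- array(c(40, NA, 10, 20), c(2, 2))
  out <- median_mixed_layer_irradiance(a, 0.1, 10)
  expect_equal(dim(out), c(2, 2))
  expect_true(is.na(out[2, 1]))
  expect_error(median_mixed_layer_irradiance(-1, 0.05, 10), "non-negative")
  expect_error(median_mixed_layer_irradiance(40, 0, 10), "positive")
})

test_that("shallow-mixing correction is the printed ratio, bounded in (0, 2]", {
  expect_equal(shallow_mixing_correction(0, 0), 1)
  # exponents match when 3 * iml = 0.15 * par
  expect_equal(shallow_mixing_correction(40, 2), 1)
  expect_equal(shallow_mixing_correction(40, 40),
               (1 + exp(-6)) / (1 + exp(-120)))
  expect_error(shallow_mixing_correction(10, 11), "exceed")
  for (par in c(0, 1, 10, 60)) {
    for (frac in c(0, 0.3, 1)) {
      v <- shallow_mixing_correction(par, frac * par)
      expect_gt(v, 0); expect_lte(v, 2)
    }
  }
})

test_that("photoacclimation ratio hits the deep-mixing baseline at 6 optical depths", {
  mld_crit <- 2 * log(20) / 0.05
  for (par in c(0, 5, 40, 70)) {
    expect_equal(theta_photo(par, 0.05, mld_crit), 150)
  }
  expect_equal(theta_photo(0, 0.05, 100), 150)    # dark: correction is 1
  expect_equal(theta_photo(40, 0.05, 0),
               150 * (1 + exp(-6)) / (1 + exp(-120)))
  # clamp flag holds the baseline beyond the deep-mixing criterion
  deep <- 2 * log(20) / 0.05 * 1.5
  expect_equal(theta_photo(40, 0.05, deep, clamp_deep_mixing = TRUE), 150)
  expect_false(theta_photo(40, 0.05, deep) == 150)
})

test_that("observed carbon-to-chlorophyll masks bad cells instead of failing", {
  expect_equal(theta_obs(15, 0.1), 150)
  expect_equal(theta_obs(75, 1.0), 75)
  expect_true(is.na(theta_obs(c(NA, 15), c(0.1, 0.1))[1]))
  expect_true(is.na(suppressWarnings(theta_obs(-1, 0.1))))
  expect_warning(theta_obs(c(-1, NA), c(0.1, 0.2)), "masked")
})

test_that("stress-index variants satisfy their algebraic identities", {
  expect_equal(stress_index(150, 150, "ratio"), 1)
  expect_equal(stress_index(150, 300, "ratio"), 0.5)
  expect_equal(stress_index(150, 300, "inverse"), 2)
  expect_equal(stress_index(150, 300, "normdiff"), 1)
  expect_error(stress_index(150, 300, "banana"))
  tp <- runif(50, 50, 250); to <- runif(50, 50, 250)
  expect_equal(stress_index(tp, to, "ratio") * stress_index(tp, to, "inverse"),
               rep(1, 50))
  expect_equal(stress_index(tp, to, "normdiff"),
               stress_index(tp, to, "inverse") - 1)
})

test_that("a planted stress field is recovered exactly from constructed ratios", {
  set.seed(1)
  s <- matrix(runif(200, 0.3, 3.5), 10, 20)
  tp <- matrix(runif(200, 120, 180), 10, 20)
  to <- tp / s
  expect_equal(stress_index(tp, to, "ratio"), s, tolerance = 1e-14)
})

test_that("nutricline depth interpolates, returns 0 at surface, Inf when absent", {
  expect_equal(nutricline_depth(c(0, 50, 100, 150), c(0, 1, 3, 8)), 100)
  expect_equal(nutricline_depth(c(50, 150), c(1, 5)), 100)
  expect_identical(nutricline_depth(c(0, 100), c(0, 2)), Inf)
  expect_equal(nutricline_depth(c(0, 100), c(4, 8)), 0)
  expect_error(nutricline_depth(c(50, 50), c(1, 5)), "increasing")
  expect_error(nutricline_depth(c(100, 50), c(1, 5)), "increasing")
  # invariant to inserting redundant collinear levels
  d <- c(50, 150); v <- c(1, 5)
  d2 <- c(50, 75, 100, 150); v2 <- approx(d, v, d2)$y
  expect_equal(nutricline_depth(d2, v2), nutricline_depth(d, v))
})

test_that("mixed-layer depth follows the density-threshold criterion", {
  d <- seq(0, 60, by = 5)
  rho <- 1025 + 0.003 * (d - 10)   # rises 0.003 kg m-3 per m below 10 m
  out <- mld_from_density_profile(d, rho)
  expect_equal(out$mld, 20)
  expect_false(out$bottom_limited)
  # uniform density never crosses: bottom-limited at the deepest level
  out2 <- mld_from_density_profile(c(0, 30, 80), rep(1025, 3))
  expect_true(out2$bottom_limited)
  expect_equal(out2$mld, 80)
  # crossing exactly at a node returns that node's depth
  out3 <- mld_from_density_profile(c(0, 10, 40, 50),
                                   c(1025, 1025, 1025.03, 1025.2))
  expect_equal(out3$mld, 40)
  # collinear refinement leaves the answer unchanged
  d2 <- sort(c(d, 12.5, 17.5)); rho2 <- 1025 + 0.003 * (d2 - 10)
  expect_equal(mld_from_density_profile(d2, rho2)$mld, 20)
  expect_error(mld_from_density_profile(c(20, 40), c(1025, 1026)), "span")
})

test_that("K490 to K_PAR conversion is monotone and bypassable", {
  k <- seq(0.02, 0.5, by = 0.01)
  expect_true(all(diff(kpar_from_k490(k)) > 0))
  expect_equal(kpar_from_k490(0.05, passthrough = TRUE), 0.05)
  # clear-water attenuation converts to the same order of magnitude
  expect_gt(kpar_from_k490(0.025), 0.01)
  expect_lt(kpar_from_k490(0.025), 0.1)
  expect_error(kpar_from_k490(0), "positive")
})

test_that("the scene-level wrapper reproduces the planted index field", {
  sc <- tiny_scene(noise_cv = 0)
  sc <- compute_theta_prime(sc)
  expect_equal(sc$fields$theta_prime, sc$fields$s_true, tolerance = 1e-12)
})
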