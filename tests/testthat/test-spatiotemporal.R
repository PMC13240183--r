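years8d <- function(n_years) ((seq_len(round(n_years * 365.25 / 8)) - 0.5) *
                                8) / 365.25

test_that("per-pixel detrending removes exactly the fitted line", {
  t <- years8d(20)
  nt <- length(t)
  f <- array(NA_real_, c(2, 2, nt))
  f[1, 1, ] <- 5                      # constant: zero slope, zero residual
  f[1, 2, ] <- 1 + 0.25 * t           # pure line
  f[2, 1, ] <- 2 + 0.1 * t + 0.5 * sin(2 * pi * t)
  f[2, 2, ] <- NA                     # all-missing pixel stays masked
  dt <- detrend_linear(f, t)
  expect_equal(dt$slope[1, 1], 0, tolerance = 1e-12)
  expect_equal(max(abs(dt$detrended[1, 1, ])), 0, tolerance = 1e-12)
  expect_equal(dt$slope[1, 2], 0.25, tolerance = 1e-12)
  expect_equal(max(abs(dt$detrended[1, 2, ])), 0, tolerance = 1e-10)
  expect_equal(dt$slope[2, 1], 0.1, tolerance = 0.05)
  expect_true(is.na(dt$slope[2, 2]))
  expect_true(all(is.na(dt$detrended[2, 2, ])))
})

test_that("EOF matches a dense eigendecomposition oracle and reconstructs the input", {
  set.seed(71)
  nlat <- 10; nlon <- 8; nt <- 40
  f <- array(rnorm(nlat * nlon * nt), c(nlat, nlon, nt))
  eof <- eof_decompose(f)
  # orthogonality of the principal components
  G <- crossprod(eof$pcs)
  expect_equal(G, diag(ncol(eof$pcs)), tolerance = 1e-10)
  # reconstruction with all modes equals the centered input
  L <- matrix(eof$modes, nlat * nlon, length(eof$d))
  recon <- L %*% t(eof$pcs) + as.vector(eof$center)
  expect_equal(array(recon, dim(f)), f, tolerance = 1e-10)
  # independent oracle: eigenvalues of the pixel covariance
  X <- matrix(f, nlat * nlon, nt)
  X <- X - rowMeans(X)
  ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  expect_equal(eof$varfrac, (ev / sum(ev))[seq_along(eof$varfrac)],
               tolerance = 1e-10)
  expect_equal(sum(eof$varfrac), 1, tolerance = 1e-10)
})

test_that("a planted rank-1 field yields one dominant mode tracking its series", {
  set.seed(72)
  nlat <- 6; nlon <- 9; nt <- 80
  pat <- outer(sin(seq_len(nlat)), cos(seq_len(nlon)))
  ts1 <- sin(2 * pi * seq_len(nt) / 20)
  f <- array(as.vector(pat) %o% ts1, c(nlat, nlon, nt)) +
    array(rnorm(nlat * nlon * nt, 0, 1e-3), c(nlat, nlon, nt))
  eof <- eof_decompose(f, n_modes = 3)
  expect_gt(eof$varfrac[1], 0.99)
  expect_gt(abs(cor(eof$pcs[, 1], ts1)), 0.99)
  # sign convention: the largest-magnitude loading of each mode is positive
  L1 <- eof$modes[, , 1]
  expect_gt(L1[which.max(abs(L1))], 0)
})

test_that("EOF excludes gappy pixels listwise", {
  set.seed(73)
  f <- array(rnorm(5 * 5 * 30), c(5, 5, 30))
  f[1, 1, 1:20] <- NA   # 67% missing: dropped
  f[2, 2, 1:3] <- NA    # 10% missing: retained, gap as zero anomaly
  eof <- eof_decompose(f, max_missing_frac = 0.2)
  expect_false(eof$kept[1, 1])
  expect_true(eof$kept[2, 2])
  expect_true(all(is.na(eof$modes[1, 1, ])))
})

test_that("periodogram finds annual, semiannual, and no spurious peaks", {
  dt <- 8 / 365.25
  t <- years8d(20)
  p1 <- psd_periodogram(sin(2 * pi * t), dt)
  expect_equal(attr(p1, "dominant_freq"), 1, tolerance = 0.06)
  p2 <- psd_periodogram(sin(4 * pi * t), dt)
  expect_equal(attr(p2, "dominant_freq"), 2, tolerance = 0.06)
  # white noise: the rate of spurious 10x-median peaks matches the
  # iid-exponential ordinate oracle (chi-squared_2 periodogram theory)
  n <- 80
  hits <- vapply(1:60, function(i) {
    set.seed(i)
    p <- psd_periodogram(rnorm(n), dt)
    max(p$power) > 10 * median(p$power)
  }, NA)
  set.seed(999)
  m <- nrow(psd_periodogram(rnorm(n), dt))
  oracle <- mean(replicate(4000, {
    x <- rexp(m)
    max(x) > 10 * median(x)
  }))
  expect_lt(abs(mean(hits) - oracle), 0.12)  # binomial noise at 60 seeds
  expect_lt(mean(hits), 0.25)                # spurious peaks stay rare
})

test_that("interannual modes are selected by spectral period, not index", {
  t <- years8d(20)
  nlat <- 4; nlon <- 5; nt <- length(t)
  annual <- outer(runif(nlat * nlon, 0.5, 1), sin(2 * pi * t))
  slow <- outer(rep(c(1, -1), length.out = nlat * nlon) * 0.4,
                sin(2 * pi * t / 4))
  f <- array(annual + slow, c(nlat, nlon, nt))
  eof <- eof_decompose(f, n_modes = 4)
  ia <- select_interannual_modes(eof, 8 / 365.25)
  expect_length(ia, 1)
  expect_gt(abs(cor(eof$pcs[, ia], sin(2 * pi * t / 4))), 0.99)
})

test_that("lowess smoothing is exact on lines and monotone on steps", {
  x <- seq(0, 5, length.out = 100)
  line <- 2 + 3 * x
  expect_equal(lowess_smooth(line), line, tolerance = 1e-8)
  expect_equal(lowess_smooth(rep(4, 60)), rep(4, 60))
  step <- c(rep(0, 50), rep(1, 50))
  sm <- lowess_smooth(step)
  expect_true(all(diff(sm) > -1e-8))
  expect_error(lowess_smooth(1:10, window = 2), "at least 3")
})

test_that("variance partition returns exact fractions on balanced planted designs", {
  t_days <- (seq_len(round(20 * 365.25 / 8)) - 0.5) * 8
  b <- thetaprime:::month_year_bins(t_days)
  # pure deterministic annual cycle: all variance on the month factor
  f1 <- array(rep(sin(2 * pi * t_days / 365.25), each = 4), c(2, 2,
                                                              length(t_days)))
  vp1 <- variance_partition(f1, t_days)
  expect_gt(vp1$seasonal_mean, 0.97)
  expect_lt(vp1$interannual_mean, 0.03)
  # pure year-block shifts: all variance on the year factor
  yr_effect <- rnorm(max(b$year), sd = 1)
  f2 <- array(rep(yr_effect[b$year], each = 4), c(2, 2, length(t_days)))
  vp2 <- variance_partition(f2, t_days)
  expect_equal(vp2$interannual_mean, 1, tolerance = 1e-10)
  expect_equal(vp2$seasonal_mean, 0, tolerance = 1e-10)
  # planted additive 60/40 month/year mix, noise-free and balanced;
  # factor effects scaled so the factor sums of squares are exactly 0.6/0.4
  u <- scale(rnorm(12))[, 1]; u <- u / sqrt(sum(u^2))
  v <- scale(rnorm(20))[, 1]; v <- v / sqrt(sum(v^2))
  mo_eff <- sqrt(0.6 / 20) * u
  yr_eff <- sqrt(0.4 / 12) * v
  y_mt <- mo_eff[b$month] + yr_eff[b$year]
  # make the series constant within each month so binning is lossless
  f3 <- array(rep(y_mt, each = 1), c(1, 1, length(t_days)))
  vp3 <- variance_partition(f3, t_days)
  ssm <- vp3$seasonal_mean; ssy <- vp3$interannual_mean
  expect_equal(ssm / (ssm + ssy), 0.6, tolerance = 1e-10)
  expect_equal(ssy / (ssm + ssy), 0.4, tolerance = 1e-10)
  expect_lt(vp3$seasonal_mean + vp3$interannual_mean, 1 + 1e-10)
})

test_that("anomalies have zero climatology and recover planted phase patterns", {
  s <- tiny_scene(seed = 81)
  f <- s$fields$theta_prime_true
  an <- anomaly(f, s$time_days, "monthly")
  b <- thetaprime:::month_year_bins(s$time_days)
  for (m in c(1, 7)) {
    clim <- apply(an[, , b$month == m], c(1, 2), mean, na.rm = TRUE)
    expect_equal(max(abs(clim), na.rm = TRUE), 0, tolerance = 1e-10)
  }
  cf <- array(3, dim(f))
  expect_equal(max(abs(anomaly(cf, s$time_days, "monthly"))), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(anomaly(cf, s$time_days, "annual"))), 0,
               tolerance = 1e-12)
  # planted warm years recovered by compositing those years
  t_days <- (seq_len(round(6 * 365.25 / 8)) - 0.5) * 8
  byr <- thetaprime:::month_year_bins(t_days)
  warm <- c(2, 5)
  pat <- matrix(runif(12, -1, 1), 3, 4)
  f2 <- array(0, c(3, 4, length(t_days)))
  for (k in which(byr$year %in% warm)) f2[, , k] <- pat
  ann <- anomaly(f2, t_days, "annual")
  comp <- phase_composite(ann, warm)
  expect_gt(cor(as.vector(comp), as.vector(pat)), 0.999)
})

test_that("pixel trends report median and positive-area fraction", {
  t <- years8d(10)
  nt <- length(t)
  f <- array(NA_real_, c(2, 2, nt))
  f[1, 1, ] <- 1 + 0.02 * t; f[1, 2, ] <- 1 + 0.02 * t
  f[2, 1, ] <- 1 - 0.02 * t; f[2, 2, ] <- 1 - 0.02 * t
  tr <- pixel_trend(f, t)
  expect_equal(tr$frac_positive, 0.5)
  expect_equal(sort(unique(round(as.vector(tr$slope), 10))), c(-0.02, 0.02))
  f2 <- f; for (i in 1:2) for (j in 1:2) f2[i, j, ] <- 2 + 0.005 * t
  expect_equal(pixel_trend(f2, t)$median_slope, 0.005, tolerance = 1e-10)
})

test_that("climate-index correlation interpolates onto the PC time base", {
  t_pc <- seq(10, 1000, by = 8)
  t_ix <- seq(0, 1100, by = 30)
  ix <- sin(2 * pi * t_ix / 365.25)
  pc <- approx(t_ix, ix, xout = t_pc)$y
  cc <- climate_index_correlation(t_pc, pc, t_ix, ix)
  expect_equal(cc$r, 1, tolerance = 1e-12)
  cc2 <- climate_index_correlation(t_pc, -pc, t_ix, ix)
  expect_equal(cc2$r, -1, tolerance = 1e-12)
  set.seed(91)
  cc3 <- climate_index_correlation(t_pc, rnorm(length(t_pc)), t_ix, ix)
  expect_lt(abs(cc3$r), 0.25)
})

test_that("region labels split hemisphere by nutricline depth", {
  z <- matrix(c(20, 80, 45, Inf, NA, 60), 2, 3)
  lab <- region_labels(c(10, -10), z, split_m = 50)
  expect_equal(lab[1, 1], "N_highNut")
  expect_equal(lab[2, 1], "S_lowNut")
  expect_equal(lab[1, 2], "N_highNut")
  expect_equal(lab[2, 2], "S_lowNut")   # absent nutricline: lowNut
  expect_true(is.na(lab[1, 3]))
})

test_that("regional bootstrap CIs behave on degenerate and simple inputs", {
  slope <- matrix(c(rep(0.01, 6), rnorm(6, 0, 0.001)), 2, 6, byrow = TRUE)
  labels <- matrix(rep(c("N_highNut", "S_lowNut"), each = 6), 2, 6,
                   byrow = TRUE)
  out <- regional_trend_summary(slope, labels, n_boot = 500, seed = 7)
  expect_equal(nrow(out), 2)
  const <- out[out$region == "N_highNut", ]
  expect_equal(const$lower, const$upper)     # constant region: zero width
  expect_equal(const$mean, 0.01)
  rnd <- out[out$region == "S_lowNut", ]
  expect_true(rnd$lower <= rnd$mean && rnd$mean <= rnd$upper)
  # display scaling multiplies means and bounds alike
  out10 <- regional_trend_summary(slope, labels, n_boot = 500, seed = 7,
                                  scale = 10)
  expect_equal(out10$mean, out$mean * 10)
  expect_equal(out10$lower, out$lower * 10)
})
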