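test_that("matchup means equal a brute-force loop over cells", {
  s <- generate_scene(scene_spec(n_lat = 8, n_lon = 12, n_years = 1,
                                 land = TRUE, seed = 21))
  sam <- sample_biomarkers(s, 12, mode = "uniform", seed = 22)
  for (sp in c("1x1", "3x3", "2deg")) {
    got <- colocate(s, sam, spatial = sp, halfwidth_days = 12)
    want <- colocate_bruteforce(s, sam, sp, 12)
    expect_equal(got$matched, want, tolerance = 1e-12)
  }
  # permutation invariance in sample order
  perm <- sample(nrow(sam))
  got <- colocate(s, sam, "3x3", 12)
  gotp <- colocate(s, sam[perm, ], "3x3", 12)
  expect_equal(gotp$matched, got$matched[perm])
})

test_that("matchup of simple fields gives analytic answers", {
  s <- tiny_scene(seed = 23)
  nlat <- length(s$lat); nlon <- length(s$lon); nt <- length(s$time_days)
  # constant field: every window returns the constant
  s$fields$const <- array(2.5, c(nlat, nlon, nt))
  sam <- sample_biomarkers(s, 8, mode = "uniform", seed = 24)
  for (sp in c("1x1", "5x5", "5deg")) {
    m <- colocate(s, sam, sp, 30, field = "const")
    expect_equal(m$matched, rep(2.5, 8))
  }
  # linear-in-longitude field with a centered 3x3 window: center value
  lin <- array(rep(seq_len(nlon), each = nlat), c(nlat, nlon, nt))
  s$fields$lin <- lin
  mid <- data.frame(lat = s$lat[4], lon = s$lon[6],
                    date_days = mean(s$time_days))
  m <- colocate(s, mid, "3x3", 40, field = "lin")
  expect_equal(m$matched, 6)
  # single-cell window at an exact node returns that cell's series mean
  m1 <- colocate(s, mid, "1x1", 4, field = "lin")
  expect_equal(m1$matched, 6)
})

test_that("gene normalization estimates copies per genome and commutes with rescaling", {
  cov <- rbind(gene_a = c(20, 6, 9), gene_b = c(5, 12, 3))
  sccg <- c(10, 3, 3)
  norm <- normalize_gene_abundance(cov, sccg)
  expect_equal(norm$copies["gene_a", ], c(2, 2, 3))
  expect_equal(rowMeans(norm$z), c(gene_a = 0, gene_b = 0), tolerance = 1e-12)
  expect_equal(apply(norm$z, 1, sd), c(gene_a = 1, gene_b = 1),
               tolerance = 1e-12)
  # doubling a sample's coverages (incl. SCCG) leaves copies unchanged
  cov2 <- cov; cov2[, 2] <- cov2[, 2] * 2
  norm2 <- normalize_gene_abundance(cov2, sccg * c(1, 2, 1))
  expect_equal(norm2$copies, norm$copies)
  expect_warning(normalize_gene_abundance(cov, c(10, 0, 3)), "dropped")
})

test_that("trait correlations recover planted signs and flag degenerate genes", {
  set.seed(31)
  theta <- runif(200, 0.5, 3)
  z <- rbind(
    perfect = as.vector(scale(theta)),
    flat = rep(0, 200),
    noise = rnorm(200)
  )
  res <- trait_correlation(z, theta)
  expect_equal(res$r[res$gene == "perfect"], 1, tolerance = 1e-10)
  expect_true(is.na(res$r[res$gene == "flat"]))
  expect_lt(abs(res$r[res$gene == "noise"]), 0.2)
  # ranked most negative first
  expect_true(!is.unsorted(res$r[!is.na(res$r)]))
})

test_that("variance attribution separates nutricline-only from added biomarker signal", {
  set.seed(41)
  n <- 250
  z_no3 <- runif(n, 20, 180)
  om <- data.frame(omega_nh = runif(n), omega_nm = runif(n),
                   omega_ph = runif(n), omega_feh = runif(n),
                   omega_fem = runif(n))
  # target depends on nutricline alone: the biomarkers add ~nothing
  y1 <- 3 * exp(-z_no3 / 80) + rnorm(n, 0, 0.05)
  att1 <- variance_attribution(y1, z_no3, om, n_trees = 300, seed = 5)
  expect_gt(att1$r2_nutricline_only, 0.8)
  expect_lt(att1$r2_full - att1$r2_nutricline_only, 0.05)
  # two-factor target: biomarkers add a comparable share
  y2 <- 3 * exp(-z_no3 / 80) + 2 * om$omega_nh + rnorm(n, 0, 0.05)
  att2 <- variance_attribution(y2, z_no3, om, n_trees = 300, seed = 5)
  expect_gt(att2$r2_full, att2$r2_nutricline_only + 0.2)
  # determinism under a fixed seed
  att2b <- variance_attribution(y2, z_no3, om, n_trees = 300, seed = 5)
  expect_identical(att2$r2_full, att2b$r2_full)
  expect_error(variance_attribution(y2[1:10], z_no3[1:10], om[1:10, ]),
               "30")
})

test_that("pure-noise predictors do not inflate out-of-bag variance explained", {
  set.seed(51)
  n <- 250
  z_no3 <- runif(n, 20, 180)
  y <- 3 * exp(-z_no3 / 80) + rnorm(n, 0, 0.1)
  junk <- as.data.frame(matrix(rnorm(n * 5), n))
  names(junk) <- paste0("omega_", letters[1:5])
  att <- variance_attribution(y, z_no3, junk, n_trees = 300, seed = 6)
  expect_lt(att$r2_full, att$r2_nutricline_only + 0.05)
})

test_that("timescale scan peaks near the planted biological window", {
  s <- generate_scene(scene_spec(n_lat = 10, n_lon = 20, n_years = 4,
                                 noise_cv = 0.35, land = FALSE, seed = 61))
  sam <- sample_biomarkers(s, 250, rule = biomarker_rule(noise_sd = 0.05),
                           mode = "uniform", seed = 62)
  scan <- timescale_scan(s, sam, spatial_windows = "1x1",
                         halfwidths_days = c(4, 12, 20, 28),
                         n_trees = 200, seed = 63)
  expect_equal(scan$best$halfwidth_days, 20)
  expect_true(all(scan$grid$n == 250))
  expect_error(timescale_scan(s, sam[1:10, ], n_trees = 50), "30")
})
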