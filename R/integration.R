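#' Match point samples to the gridded stress index
#'
#' For each sample, the unweighted mean of all unmasked cells in a
#' spatiotemporal window centered on the sample's position and date.
#' Spatial windows come from the standard menu: pixel blocks (`"1x1"`,
#' `"3x3"`, `"5x5"`, centered on the nearest pixel) or degree boxes
#' (`"1deg"`, `"2deg"`, `"5deg"`, centered on the sample's coordinates, not
#' snapped to pixel boundaries).  Temporally, a composite contributes when its
#' midpoint lies within `±halfwidth_days` of the sampling date.  A window with
#' no unmasked cells yields a missing matchup.
#'
#' @param scene A `gridded_scene` whose `field` is to be matched (the stress
#'   index by default).
#' @param samples Data.frame with `lat`, `lon`, `date_days`.
#' @param spatial One of `"1x1"`, `"3x3"`, `"5x5"`, `"1deg"`, `"2deg"`,
#'   `"5deg"`.
#' @param halfwidth_days Temporal half-width, days (e.g. 20 for the 40-day
#'   characteristic window).
#' @param field Name of the scene field to average.
#' @return Data.frame with `matched` (window mean) and `n_cells`
#'   (contributing unmasked cells), one row per sample.
#' @export
colocate <- function(scene, samples, spatial = "1x1", halfwidth_days = 20,
                     field = "theta_prime_true") {
  stopifnot(inherits(scene, "gridded_scene"), halfwidth_days >= 0)
  arr <- scene$fields[[field]]
  if (is.null(arr)) stop("scene has no field '", field, "'")
  nlat <- length(scene$lat); nlon <- length(scene$lon)
  spatial <- match.arg(spatial,
                       c("1x1", "3x3", "5x5", "1deg", "2deg", "5deg"))
  px <- c("1x1" = 1L, "3x3" = 3L, "5x5" = 5L)
  n <- nrow(samples)
  matched <- rep(NA_real_, n); n_cells <- integer(n)
  for (k in seq_len(n)) {
    tsel <- which(abs(scene$time_days - samples$date_days[k]) <=
                    halfwidth_days)
    if (length(tsel) == 0L) next
    if (spatial %in% names(px)) {
      half <- (px[[spatial]] - 1L) %/% 2L
      if (2L * half + 1L > min(nlat, nlon))
        stop("spatial window larger than the grid")
      i0 <- which.min(abs(scene$lat - samples$lat[k]))
      j0 <- which.min(abs(scene$lon - samples$lon[k]))
      isel <- max(1L, i0 - half):min(nlat, i0 + half)
      jsel <- max(1L, j0 - half):min(nlon, j0 + half)
    } else {
      w <- as.numeric(sub("deg", "", spatial)) / 2
      isel <- which(abs(scene$lat - samples$lat[k]) <= w)
      jsel <- which(abs(scene$lon - samples$lon[k]) <= w)
      if (length(isel) == 0L || length(jsel) == 0L) next
    }
    block <- arr[isel, jsel, tsel]
    ok <- sum(!is.na(block))
    n_cells[k] <- ok
    if (ok > 0L) matched[k] <- mean(block, na.rm = TRUE)
  }
  data.frame(matched = matched, n_cells = n_cells)
}

#' Scan matchup windows for the characteristic biological timescale
#'
#' For every combination of spatial window and temporal half-width, the
#' gridded stress index is matched to the samples, a random forest predicting
#' the matched index from the biomarker (and nutricline) predictors is grown,
#' and its out-of-bag variance explained is recorded.  The window maximizing
#' variance explained estimates the characteristic timescale over which the
#' community's genomic state integrates its nutrient environment.
#'
#' @inheritParams colocate
#' @param samples Data.frame with coordinates, dates, and predictor columns.
#' @param spatial_windows Character vector from the window menu.
#' @param halfwidths_days Numeric vector of temporal half-widths.
#' @param predictors Character vector of predictor column names.
#' @param n_trees Trees per forest.
#' @param seed Integer seed (forests are re-seeded per window so the scan is
#'   deterministic).
#' @return List with `grid` (data.frame of spatial, halfwidth_days,
#'   r2_oob, n) and `best` (the argmax row).
#' @export
timescale_scan <- function(scene, samples, spatial_windows = "1x1",
                           halfwidths_days = seq(2, 30, by = 2),
                           predictors = c("omega_nh", "omega_nm", "omega_ph",
                                          "omega_feh", "omega_fem"),
                           n_trees = 500, seed = 1L,
                           field = "theta_prime_true") {
  if (length(predictors) < 2L) stop("need at least two predictors")
  if (nrow(samples) < 30L) stop("need at least 30 samples")
  grid <- expand.grid(spatial = spatial_windows,
                      halfwidth_days = halfwidths_days,
                      stringsAsFactors = FALSE)
  grid$r2_oob <- NA_real_; grid$n <- NA_integer_
  for (r in seq_len(nrow(grid))) {
    m <- colocate(scene, samples, spatial = grid$spatial[r],
                  halfwidth_days = grid$halfwidth_days[r], field = field)
    dat <- data.frame(y = m$matched, samples[, predictors, drop = FALSE])
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    if (nrow(dat) < 30L) next
    set.seed(seed)
    rf <- randomForest::randomForest(y ~ ., data = dat, ntree = n_trees)
    grid$r2_oob[r] <- 1 - rf$mse[n_trees] / mean((dat$y - mean(dat$y))^2)
    grid$n[r] <- nrow(dat)
  }
  best <- grid[which.max(grid$r2_oob), , drop = FALSE]
  list(grid = grid, best = best)
}

#' Variance in the stress index attributable to nutricline vs biomarkers
#'
#' Two random forests predict the matched stress index: one from nutricline
#' depth alone, one from nutricline depth plus the five genomic biomarkers.
#' Out-of-bag variance explained is the headline statistic (the package
#' default of the forest implementation); in-bag R-squared is reported
#' alongside for transparency.  Complete cases only; no imputation.
#'
#' @param theta Matched stress-index values, one per sample.
#' @param nutricline Nutricline depths, m (`Inf` absent-nutricline sentinels
#'   are dropped unless `absent_as_zero = TRUE` recodes them to 0 m).
#' @param omegas Data.frame/matrix of the genomic biomarker columns.
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @param absent_as_zero Treat absent nutriclines as 0 m instead of dropping.
#' @return List with `r2_nutricline_only`, `r2_full` (both out-of-bag),
#'   `r2_inbag_nutricline_only`, `r2_inbag_full`, `n_samples`, `n_trees`,
#'   `seed`.
#' @export
variance_attribution <- function(theta, nutricline, omegas, n_trees = 500,
                                 seed = 1L, absent_as_zero = FALSE) {
  omegas <- as.data.frame(omegas)
  nutricline <- as.numeric(nutricline)
  if (absent_as_zero) nutricline[is.infinite(nutricline)] <- 0
  dat <- data.frame(y = theta, z_no3 = nutricline, omegas)
  dat <- dat[stats::complete.cases(dat) & is.finite(dat$z_no3), ,
             drop = FALSE]
  if (nrow(dat) < 30L) stop("fewer than 30 complete cases")
  fit <- function(d) {
    set.seed(seed)
    rf <- randomForest::randomForest(y ~ ., data = d, ntree = n_trees)
    vy <- mean((d$y - mean(d$y))^2)
    list(oob = 1 - rf$mse[n_trees] / vy,
         inbag = 1 - mean((stats::predict(rf, d) - d$y)^2) / vy)
  }
  f_nut <- fit(dat[, c("y", "z_no3")])
  f_full <- fit(dat)
  list(r2_nutricline_only = f_nut$oob, r2_full = f_full$oob,
       r2_inbag_nutricline_only = f_nut$inbag, r2_inbag_full = f_full$inbag,
       n_samples = nrow(dat), n_trees = n_trees, seed = seed)
}

#' Normalize gene coverages to copies per genome and z-scores
#'
#' Each flexible gene's coverage is divided by the sample's mean single-copy
#' core-gene (SCCG) coverage, estimating gene copies per individual genome and
#' cancelling per-sample sequencing depth; a z-score is then computed per gene
#' across samples.  Samples with non-positive SCCG coverage are dropped with a
#' warning.
#'
#' @param coverage Genes x samples matrix of flexible-gene coverages.
#' @param sccg_mean Per-sample mean SCCG coverage.
#' @return List with `copies` (genes x samples), `z` (genes x samples,
#'   per-gene mean 0 / sd 1), and `kept` (logical per input sample).
#' @export
normalize_gene_abundance <- function(coverage, sccg_mean) {
  coverage <- as.matrix(coverage)
  stopifnot(ncol(coverage) == length(sccg_mean))
  if (any(coverage < 0, na.rm = TRUE)) stop("coverages must be non-negative")
  kept <- !is.na(sccg_mean) & sccg_mean > 0
  if (!all(kept)) {
    warning(sum(!kept), " sample(s) dropped: non-positive SCCG coverage")
    coverage <- coverage[, kept, drop = FALSE]
    sccg_mean <- sccg_mean[kept]
  }
  copies <- sweep(coverage, 2, sccg_mean, `/`)
  z <- t(scale(t(copies)))
  z[is.nan(z)] <- NA  # constant genes have no z-score
  list(copies = copies, z = z, kept = kept)
}

#' Correlate normalized gene abundances with the stress index
#'
#' Pearson correlation (with two-sided p value) between each gene's z-scored
#' copies-per-genome profile and the matched stress index, ranked most
#' negative first (the ordering used to read off which traits accompany
#' severe stress).  Genes with constant profiles or fewer than three paired
#' observations report a missing correlation.
#'
#' @param z Genes x samples matrix of z-scores (see
#'   [normalize_gene_abundance()]).
#' @param theta Matched stress-index values per sample.
#' @param adjust Optional multiple-testing adjustment method passed to
#'   [stats::p.adjust()] (`"none"` keeps raw p values, the default reporting
#'   convention here).
#' @return Data.frame with `gene`, `r`, `p`, `n`, sorted by `r`.
#' @export
trait_correlation <- function(z, theta, adjust = "none") {
  z <- as.matrix(z)
  stopifnot(ncol(z) == length(theta))
  res <- lapply(seq_len(nrow(z)), function(g) {
    ok <- !is.na(z[g, ]) & !is.na(theta)
    if (sum(ok) < 3L || stats::sd(z[g, ok]) == 0 ||
        stats::sd(theta[ok]) == 0)
      return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- stats::cor.test(z[g, ok], theta[ok])
    c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  out <- data.frame(
    gene = if (!is.null(rownames(z))) rownames(z) else
      sprintf("gene_%03d", seq_len(nrow(z))),
    do.call(rbind, res)
  )
  out$p <- stats::p.adjust(out$p, method = adjust)
  out[order(out$r), , drop = FALSE]
}

#' Partial dependence of a fitted forest on one predictor
#'
#' Generic marginalization utility: the forest's mean prediction over the
#' data with one predictor swept across a grid.
#'
#' @param rf A fitted `randomForest` object.
#' @param data The training data.frame.
#' @param var Predictor name.
#' @param grid_size Number of grid points across the predictor's range.
#' @return Data.frame with the grid and mean predictions.
#' @export
partial_dependence <- function(rf, data, var, grid_size = 25) {
  grid <- seq(min(data[[var]], na.rm = TRUE), max(data[[var]], na.rm = TRUE),
              length.out = grid_size)
  yhat <- vapply(grid, function(v) {
    d <- data; d[[var]] <- v
    mean(stats::predict(rf, d))
  }, 0)
  out <- data.frame(grid, yhat)
  names(out) <- c(var, "yhat")
  out
}
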