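#' Specification for a synthetic ocean scene
#'
#' Defines the statistical structure the generator plants: a smooth
#' nutricline-depth map (deep in subtropical gyre centers, about 175 m,
#' shallow towards upwelling zones, about 30 m), a monotone map from
#' nutricline depth to the mean stress-index level (range roughly 0.5-3.5,
#' elevated above 3 where the nutricline is shallow and below 1 where it is
#' deeper than 150 m), hemispherically opposed annual cycles with a
#' semiannual tropical component, one quasi-oscillatory interannual climate
#' mode with an ENSO-like zonal dipole pattern, a smooth per-pixel long-term
#' trend field, multiplicative lognormal noise, and rectangular land masks.
#'
#' @param n_lat,n_lon Grid size (cell centers of a regular mesh).
#' @param n_years Record length in years.
#' @param step_days Compositing period, days (8-day composites by default).
#' @param lat_range,lon_range Domain extents, degrees.
#' @param seasonal_amp Relative amplitude of the annual cycle at 40 degrees
#'   latitude (scales linearly towards 0 at the equator).
#' @param semiannual_amp Relative amplitude of the tropical semiannual cycle.
#' @param mode_amp Relative amplitude of the interannual mode where its
#'   spatial pattern peaks.
#' @param mode_period_years Period of the planted climate mode, years.
#' @param trend_amp Peak relative trend rate, year^-1 (the planted stress
#'   slope is the pixel's mean level times its relative rate).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on the realized stress index.
#' @param land Logical, mask rectangular continents.
#' @param shallow_dip Logical, add the equatorial suppression dip at the
#'   shallowest nutriclines (iron-stress signature); off by default so the
#'   depth-to-stress map is monotone.
#' @param seed Integer seed; every artifact derives from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_lat = 40, n_lon = 80, n_years = 10, step_days = 8,
                       lat_range = c(-40, 40), lon_range = c(0, 160),
                       seasonal_amp = 0.35, semiannual_amp = 0.15,
                       mode_amp = 0.3, mode_period_years = 10 / 3,
                       trend_amp = 0.004, noise_cv = 0.05,
                       land = TRUE, shallow_dip = FALSE, seed = 1L) {
  stopifnot(n_lat >= 1, n_lon >= 1, n_years > 0, step_days > 0,
            noise_cv >= 0, seed == as.integer(seed))
  structure(
    list(n_lat = n_lat, n_lon = n_lon, n_years = n_years,
         step_days = step_days, lat_range = lat_range, lon_range = lon_range,
         seasonal_amp = seasonal_amp, semiannual_amp = semiannual_amp,
         mode_amp = mode_amp, mode_period_years = mode_period_years,
         trend_amp = trend_amp, noise_cv = noise_cv, land = land,
         shallow_dip = shallow_dip, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# Monotone map from nutricline depth (m) to mean stress-index level.
# Optionally adds the equatorial "dip" at the shallowest nutriclines.
stress_from_nutricline <- function(z, shallow_dip = FALSE) {
  g <- 0.5 + 3.0 * stats::plogis((80 - z) / 25)
  if (shallow_dip) g <- g - 1.2 * exp(-((z - 25) / 12)^2)
  g
}

#' Generate a synthetic gridded ocean scene with planted ground truth
#'
#' Builds the noise-free latent stress index
#' `s_true(x, t) = g(Z(x)) * seasonal(x, t) * mode(x, t) * (1 + r(x) * (t - t_mid))`,
#' emits plausible PAR / K_PAR / MLD / SST / Chl fields with seasonal cycles,
#' evaluates the photoacclimation model on them, and sets the observed
#' carbon-to-chlorophyll field so that the recomputed stress index equals
#' `s_true` times the lognormal noise factor (exactly `s_true` at
#' `noise_cv = 0`).  The planted truth is stored on the scene: `s_true` and
#' `theta_prime_true` (realized, with noise) as fields, the nutricline map,
#' mode pattern and planted slope map as static fields, and the mode index
#' series plus the analytic seasonal/interannual variance shares in `meta`.
#'
#' @param spec A [scene_spec()].
#' @return A `gridded_scene`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$n_lat * spec$n_lon == 1L || spec$n_years * 365.25 < spec$step_days)
    warning("degenerate grid (single pixel or single time step)")
  set.seed(spec$seed)
  lat <- seq(spec$lat_range[1], spec$lat_range[2],
             length.out = spec$n_lat + 1)
  lat <- (lat[-1] + lat[-length(lat)]) / 2
  lon <- seq(spec$lon_range[1], spec$lon_range[2],
             length.out = spec$n_lon + 1)
  lon <- (lon[-1] + lon[-length(lon)]) / 2
  nt <- max(1L, round(spec$n_years * 365.25 / spec$step_days))
  time_days <- (seq_len(nt) - 0.5) * spec$step_days
  t_yr <- time_days / 365.25
  nlat <- spec$n_lat; nlon <- spec$n_lon
  latm <- matrix(lat, nlat, nlon)
  lonm <- matrix(lon, nlat, nlon, byrow = TRUE)
  lon_span <- diff(range(spec$lon_range))

  # --- static structure ----------------------------------------------------
  # nutricline: deep (~175 m) in two subtropical gyre lobes, shallow (~30 m)
  # near the equatorial/eastern upwelling and the poleward edges
  gyre <- exp(-((abs(latm) - 20) / 12)^2) *
    (0.55 + 0.45 * cos(2 * pi * (lonm - spec$lon_range[1]) / lon_span))
  z_no3 <- 30 + 145 * gyre
  g_level <- stress_from_nutricline(z_no3, spec$shallow_dip)

  # ENSO-like zonal dipole confined to the tropics
  mode_pattern <- sin(2 * pi * (lonm - spec$lon_range[1]) / lon_span) *
    exp(-(latm / 18)^2)
  # smooth relative trend field: hemispheric contrast plus a zonal ripple
  trend_rate <- spec$trend_amp *
    (-cos(pi * latm / diff(range(spec$lat_range)) * 2) +
       0.5 * sin(2 * pi * (lonm - spec$lon_range[1]) / lon_span))

  # --- temporal components -------------------------------------------------
  phase <- stats::runif(1, 0, 2 * pi)
  mode_index <- sqrt(2) * sin(2 * pi * t_yr / spec$mode_period_years + phase)

  amp_ann <- spec$seasonal_amp * abs(latm) / max(abs(latm), 1e-9)
  amp_semi <- spec$semiannual_amp * pmax(0, 1 - abs(latm) / 25)
  # northern-hemisphere annual phase; southern hemisphere opposed
  ph_ann <- ifelse(latm >= 0, 0, pi)

  outer_xt <- function(xmat, tvec) {
    array(as.vector(xmat) %o% tvec, dim = c(nlat, nlon, length(tvec)))
  }
  seas <- 1 +
    outer_xt(amp_ann * cos(ph_ann), sin(2 * pi * t_yr)) +
    outer_xt(amp_semi, cos(4 * pi * t_yr))
  mode_term <- 1 + spec$mode_amp * outer_xt(mode_pattern, mode_index)
  t_mid <- mean(t_yr)
  trend_term <- 1 + outer_xt(trend_rate, t_yr - t_mid)
  base <- outer_xt(g_level, rep(1, nt))
  s_true <- base * seas * mode_term * trend_term
  s_true[s_true <= 0.01] <- 0.01   # guard: keep the index positive

  sigma <- sqrt(log(1 + spec$noise_cv^2))
  noise <- if (spec$noise_cv > 0) {
    array(exp(stats::rnorm(nlat * nlon * nt, -sigma^2 / 2, sigma)),
          dim = c(nlat, nlon, nt))
  } else {
    array(1, dim = c(nlat, nlon, nt))
  }
  theta_prime_true <- s_true * noise

  # --- physical driver fields ---------------------------------------------
  par0 <- 45 - 0.25 * abs(latm)
  par <- pmax(outer_xt(par0, rep(1, nt)) +
                outer_xt(12 * (abs(latm) / 40) * cos(ph_ann),
                         sin(2 * pi * t_yr)), 2)
  kpar <- 0.04 + 0.03 * outer_xt(exp(-z_no3 / 60), rep(1, nt))
  # winter-deep mixed layers, opposite phase to PAR
  mld <- pmax(outer_xt(25 + 30 * abs(latm) / 40, rep(1, nt)) -
                outer_xt(20 * (abs(latm) / 40) * cos(ph_ann),
                         sin(2 * pi * t_yr)), 8)
  sst <- outer_xt(29 - 14 * (abs(latm) / 40)^2, rep(1, nt)) +
    outer_xt(2.5 * (abs(latm) / 40) * cos(ph_ann), sin(2 * pi * t_yr)) +
    outer_xt(matrix(0.023, nlat, nlon), t_yr - t_mid)
  chl <- pmax(outer_xt(0.06 + 0.4 * exp(-z_no3 / 50), rep(1, nt)) *
                (1 + 0.2 * outer_xt(amp_ann / max(spec$seasonal_amp, 1e-9),
                                    sin(2 * pi * t_yr))), 0.02)

  th_photo <- theta_photo(par, kpar, mld)
  th_obs <- th_photo / theta_prime_true
  c_phyto <- th_obs * chl

  fields <- list(chl = chl, c_phyto = c_phyto, par = par, kpar = kpar,
                 mld = mld, sst = sst, s_true = s_true,
                 theta_prime_true = theta_prime_true)

  # --- land mask -----------------------------------------------------------
  land_mask <- matrix(FALSE, nlat, nlon)
  if (isTRUE(spec$land)) {
    land_mask <- land_mask |
      (latm > -5 & latm < 25 & lonm > spec$lon_range[1] + 0.18 * lon_span &
         lonm < spec$lon_range[1] + 0.30 * lon_span) |
      (latm > -35 & latm < -20 & lonm > spec$lon_range[1] + 0.62 * lon_span &
         lonm < spec$lon_range[1] + 0.72 * lon_span)
    if (any(land_mask)) {
      idx <- which(land_mask)
      for (nm in names(fields)) {
        f <- fields[[nm]]
        f[as.vector(outer(idx, (seq_len(nt) - 1) * nlat * nlon, `+`))] <- NA
        fields[[nm]] <- f
      }
      z_no3[idx] <- NA
    }
  }

  # --- analytic variance budget (noise-free, monthly-binned, per pixel) ---
  shares <- planted_variance_shares(s_true, time_days)

  # planted trend: closed-form OLS slope of the noise-free latent field
  # (the deterministic trend actually present, including the small
  # contribution of seasonal/mode interactions with time)
  tc <- t_yr - mean(t_yr)
  Sm <- matrix(s_true, nlat * nlon, nt)
  planted_slope <- matrix((Sm %*% tc) / sum(tc^2), nlat, nlon)

  gridded_scene(
    lat, lon, time_days, fields = fields,
    static = list(z_no3 = z_no3, mode_pattern = mode_pattern,
                  planted_slope = planted_slope,
                  land = land_mask + 0),
    meta = list(
      seed = spec$seed, spec = unclass(spec),
      units = list(chl = "mg m-3", c_phyto = "mgC m-3",
                   par = "mol quanta m-2 day-1", kpar = "m-1", mld = "m",
                   sst = "degC", z_no3 = "m"),
      mode_index = mode_index,
      planted_seasonal_share = shares$seasonal,
      planted_interannual_share = shares$interannual
    )
  )
}

# Analytic (noise-free) variance budget: bin the planted index to calendar
# months, then per pixel take the between-month and between-year sums of
# squares over the total; report pixel means.  Deliberately plain group-mean
# arithmetic, independent of the ANOVA machinery used downstream.
planted_variance_shares <- function(s_true, time_days) {
  b <- month_year_bins(time_days)
  dm <- dim(s_true)
  npix <- dm[1] * dm[2]
  flat <- matrix(s_true, npix, dm[3])
  cells <- split(seq_along(time_days), list(b$month, b$year), drop = TRUE)
  monthly <- vapply(cells, function(ii) rowMeans(flat[, ii, drop = FALSE]),
                    numeric(npix))
  monthly <- matrix(monthly, npix, length(cells))
  key <- strsplit(names(cells), "\\.")
  mo <- as.integer(vapply(key, `[`, "", 1))
  yr <- as.integer(vapply(key, `[`, "", 2))
  seas <- inter <- rep(NA_real_, npix)
  for (p in seq_len(npix)) {
    y <- monthly[p, ]
    if (anyNA(y)) next
    gm <- mean(y)
    ssm <- sum(tapply(y, mo, length) * (tapply(y, mo, mean) - gm)^2)
    ssy <- sum(tapply(y, yr, length) * (tapply(y, yr, mean) - gm)^2)
    sst <- sum((y - gm)^2)
    if (sst > 0) { seas[p] <- ssm / sst; inter[p] <- ssy / sst }
  }
  list(seasonal = mean(seas, na.rm = TRUE),
       interannual = mean(inter, na.rm = TRUE))
}

# Calendar-style month (12 equal slices of a 365.25-day year) and year bins
# for composite midpoints.
month_year_bins <- function(time_days) {
  t_yr <- time_days / 365.25
  list(month = pmin(12L, floor((t_yr %% 1) * 12) + 1L),
       year = floor(t_yr) + 1L)
}

#' Sample biomarker observations along synthetic cruise tracks
#'
#' Draws `n` georeferenced samples, by default along contiguous cruise-track
#' segments (mimicking ship-based transect sampling and its spatial
#' autocorrelation), or uniformly at random over unmasked ocean pixels.
#' Genomic stress-index values are logistic functions of the local realized
#' stress index averaged over the planted characteristic timescale (a
#' `±timescale_days` window around the sampling date): markers of nitrogen and
#' iron stress rise where the stress index is low, the medium-intensity and
#' phosphorus markers carry weaker or opposite loadings.  Nutricline depth is
#' read from the planted map.
#'
#' @param scene A `gridded_scene` from [generate_scene()].
#' @param n Number of samples.
#' @param rule Named list: `coef` (named numeric, logistic slope per marker on
#'   the standardized local stress), `noise_sd` (additive noise on the
#'   logistic scale), `timescale_days` (half-width of the biological
#'   integration window).
#' @param mode `"track"` (default) or `"uniform"`.
#' @param seed Integer seed.
#' @return A data.frame with lat, lon, date_days, the five omega markers,
#'   `z_no3`, and the latent standardized stress `z_stress` (kept for
#'   oracle tests).
#' @export
sample_biomarkers <- function(scene, n = 300,
                              rule = biomarker_rule(), mode = c("track",
                                                                "uniform"),
                              seed = 1L) {
  stopifnot(inherits(scene, "gridded_scene"), n >= 1)
  mode <- match.arg(mode)
  set.seed(seed)
  nlat <- length(scene$lat); nlon <- length(scene$lon)
  ocean <- which(!is.na(scene$static$z_no3))
  if (n > 50 * length(ocean))
    stop("requested more samples than the grid can plausibly carry")
  half <- rule$timescale_days
  tmin <- min(scene$time_days) + half
  tmax <- max(scene$time_days) - half
  if (tmax <= tmin) stop("record too short for the biological window")

  if (mode == "uniform") {
    cells <- sample(ocean, n, replace = TRUE)
    dates <- stats::runif(n, tmin, tmax)
  } else {
    cells <- integer(0); dates <- numeric(0)
    seg_len <- 12L
    while (length(cells) < n) {
      start <- sample(ocean, 1)
      i <- ((start - 1) %% nlat) + 1
      j <- ((start - 1) %/% nlat) + 1
      di <- sample(c(-1L, 0L, 1L), 1)
      dj <- sample(c(-1L, 1L), 1)
      t0 <- stats::runif(1, tmin, tmax)
      for (s in seq_len(seg_len)) {
        ii <- i + di * (s - 1); jj <- j + dj * (s - 1)
        if (ii < 1 || ii > nlat || jj < 1 || jj > nlon) break
        cell <- (jj - 1) * nlat + ii
        tt <- t0 + (s - 1) * 2   # ~2 days between stations
        if (!(cell %in% ocean) || tt > tmax) next
        cells <- c(cells, cell); dates <- c(dates, tt)
      }
    }
    keep <- seq_len(n)
    cells <- cells[keep]; dates <- dates[keep]
  }

  ilat <- ((cells - 1) %% nlat) + 1
  ilon <- ((cells - 1) %/% nlat) + 1
  # biological window average of the realized stress index
  tp <- scene$fields$theta_prime_true
  avg <- vapply(seq_len(n), function(k) {
    sel <- abs(scene$time_days - dates[k]) <= half
    mean(tp[ilat[k], ilon[k], sel], na.rm = TRUE)
  }, 0)
  z <- as.vector(scale(log(avg)))

  om <- lapply(rule$coef, function(b) {
    stats::plogis(b * z + stats::rnorm(n, 0, rule$noise_sd))
  })
  data.frame(
    lat = scene$lat[ilat] + stats::runif(n, -0.2, 0.2) * diff(scene$lat[1:2]),
    lon = scene$lon[ilon] + stats::runif(n, -0.2, 0.2) * diff(scene$lon[1:2]),
    date_days = dates,
    omega_nh = om$omega_nh, omega_nm = om$omega_nm, omega_ph = om$omega_ph,
    omega_feh = om$omega_feh, omega_fem = om$omega_fem,
    z_no3 = scene$static$z_no3[cbind(ilat, ilon)],
    z_stress = z
  )
}

#' Default planted biomarker rule
#'
#' High-intensity nitrogen and iron stress markers load negatively on the
#' stress index (they are elevated where the index is low, i.e. under strong
#' stress); medium-intensity markers load weakly; the phosphorus marker loads
#' positively (phosphorus-stressed regions keep a relatively high index).
#'
#' @param noise_sd Logistic-scale noise standard deviation.
#' @param timescale_days Biological integration half-window, days.
#' @return Named list consumed by [sample_biomarkers()].
#' @export
biomarker_rule <- function(noise_sd = 0.25, timescale_days = 20) {
  list(
    coef = c(omega_nh = -1.6, omega_nm = -0.5, omega_ph = 0.9,
             omega_feh = -1.1, omega_fem = -0.4),
    noise_sd = noise_sd,
    timescale_days = timescale_days
  )
}

#' Generate a synthetic gene-coverage table with planted trait effects
#'
#' Per sample, a mean single-copy core-gene (SCCG) coverage is drawn
#' lognormally; each flexible gene's coverage is its copies-per-genome times
#' the SCCG mean times multiplicative noise, with copies driven by a planted
#' per-gene coefficient on the sample's standardized stress (positive,
#' negative, or zero, mirroring trait classes that are enriched under low or
#' high stress).
#'
#' @param samples Output of [sample_biomarkers()] (uses `z_stress`).
#' @param n_genes Number of flexible genes (split roughly into thirds of
#'   positive, negative, and null effects when `planted_effects` is `NULL`).
#' @param planted_effects Optional numeric vector of per-gene coefficients.
#' @param noise_sd Lognormal coverage noise (log scale).
#' @param seed Integer seed.
#' @return List with `coverage` (genes x samples matrix), `sccg_mean`
#'   (per-sample), and `effects` (planted per-gene coefficients).
#' @export
generate_gene_table <- function(samples, n_genes = 30, planted_effects = NULL,
                                noise_sd = 0.2, seed = 1L) {
  set.seed(seed)
  n <- nrow(samples)
  if (is.null(planted_effects)) {
    k <- ceiling(n_genes / 3)
    planted_effects <- c(rep(0.8, k), rep(-0.8, k),
                         rep(0, n_genes - 2 * k))
  }
  stopifnot(length(planted_effects) == n_genes)
  sccg <- exp(stats::rnorm(n, log(10), 0.4))
  copies <- exp(outer(planted_effects, samples$z_stress))
  coverage <- copies * matrix(sccg, n_genes, n, byrow = TRUE) *
    exp(matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n))
  rownames(coverage) <- sprintf("gene_%03d", seq_len(n_genes))
  list(coverage = coverage, sccg_mean = sccg, effects = planted_effects)
}

#' Generate monthly climate-index series aligned with a scene
#'
#' Returns the planted interannual mode index resampled to monthly midpoints
#' over the scene's record, plus optional red-noise distractor indices that
#' are generated independently of the mode.
#'
#' @param scene A `gridded_scene` from [generate_scene()].
#' @param n_distractors Number of AR(1) red-noise distractor series.
#' @param ar Distractor lag-1 autocorrelation (monthly).
#' @param seed Integer seed for the distractors.
#' @return A data.frame with `time_days`, `mode`, and `distractor_k` columns.
#' @export
generate_climate_index <- function(scene, n_distractors = 1, ar = 0.7,
                                   seed = 1L) {
  stopifnot(inherits(scene, "gridded_scene"),
            !is.null(scene$meta$mode_index))
  set.seed(seed)
  monthly_t <- seq(365.25 / 24, max(scene$time_days), by = 365.25 / 12)
  mode_m <- stats::approx(scene$time_days, scene$meta$mode_index,
                          xout = monthly_t, rule = 2)$y
  out <- data.frame(time_days = monthly_t, mode = mode_m)
  for (k in seq_len(n_distractors)) {
    x <- as.numeric(stats::arima.sim(list(ar = ar), length(monthly_t)))
    out[[paste0("distractor_", k)]] <- x / stats::sd(x)
  }
  out
}
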