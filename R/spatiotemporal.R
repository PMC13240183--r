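#' Remove a per-pixel long-term linear trend
#'
#' Ordinary least squares line per pixel over the full record; the detrended
#' field and the per-pixel slope (plus intercept and slope standard error)
#' are returned.  Pixels with fewer than three unmasked time steps are fully
#' masked in the output.
#'
#' @param field 3-D array `[lat, lon, time]`.
#' @param t_years Time stamps in years (e.g. [scene_years()]).
#' @return List with `detrended` (same shape), `slope`, `intercept`,
#'   `slope_se` (matrices, units of the field per year).
#' @export
detrend_linear <- function(field, t_years) {
  dm <- dim(field)
  stopifnot(length(dm) == 3L, dm[3] == length(t_years))
  npix <- dm[1] * dm[2]; nt <- dm[3]
  Y <- matrix(field, npix, nt)
  W <- !is.na(Y)
  Y0 <- Y; Y0[!W] <- 0
  t <- as.numeric(t_years)
  n <- rowSums(W)
  Sx <- W %*% t; Sxx <- W %*% (t^2)
  Sy <- rowSums(Y0); Sxy <- Y0 %*% t
  denom <- n * Sxx - Sx^2
  slope <- as.vector((n * Sxy - Sx * Sy) / denom)
  intercept <- as.vector((Sy - slope * Sx) / n)
  bad <- n < 3 | as.vector(denom) <= 0
  slope[bad] <- NA; intercept[bad] <- NA
  fit <- outer(intercept, rep(1, nt)) + outer(slope, t)
  resid <- Y - fit
  rss <- rowSums(resid^2, na.rm = TRUE)
  se <- sqrt(rss / pmax(n - 2, 1) / (as.vector(Sxx) - as.vector(Sx)^2 /
                                       pmax(n, 1)))
  se[bad] <- NA
  resid[bad, ] <- NA
  list(
    detrended = array(resid, dm),
    slope = matrix(slope, dm[1], dm[2]),
    intercept = matrix(intercept, dm[1], dm[2]),
    slope_se = matrix(se, dm[1], dm[2])
  )
}

#' Empirical orthogonal function decomposition of a gridded anomaly field
#'
#' Singular value decomposition of the (pixels x time) matrix of per-pixel
#' centered series.  Pixels with more than `max_missing_frac` of their time
#' steps masked are excluded listwise; remaining gaps enter as zero
#' anomalies.  Modes are ordered by explained variance and signed so that
#' each spatial pattern's largest-magnitude loading is positive.  Principal
#' components are mutually orthogonal unit vectors; spatial loadings carry
#' the amplitude, so `loadings %*% t(pcs)` reconstructs the centered input on
#' the retained pixels.
#'
#' @param field 3-D array `[lat, lon, time]` (detrend first for interannual
#'   work).
#' @param n_modes Number of modes to retain (`NULL` keeps all non-degenerate
#'   modes).
#' @param max_missing_frac Pixel exclusion threshold on the masked fraction.
#' @return An object of class `eof_result`: `modes` (3-D array
#'   `[lat, lon, mode]` of loadings, `NA` on excluded pixels), `pcs`
#'   (time x mode), `varfrac`, `d` (singular values), `kept` (logical pixel
#'   matrix), `center` (pixel-mean matrix).
#' @export
eof_decompose <- function(field, n_modes = NULL, max_missing_frac = 0.2) {
  dm <- dim(field)
  stopifnot(length(dm) == 3L, dm[1] * dm[2] >= 2L, dm[3] >= 2L)
  npix <- dm[1] * dm[2]; nt <- dm[3]
  Y <- matrix(field, npix, nt)
  missfrac <- rowMeans(is.na(Y))
  kept <- missfrac <= max_missing_frac
  if (sum(kept) < 2L) stop("fewer than two usable pixels for the EOF")
  X <- Y[kept, , drop = FALSE]
  ctr <- rowMeans(X, na.rm = TRUE)
  X <- X - ctr
  X[is.na(X)] <- 0
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[pos]
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  if (!is.null(n_modes)) {
    k <- min(n_modes, length(d))
    d <- d[1:k]; U <- U[, 1:k, drop = FALSE]; V <- V[, 1:k, drop = FALSE]
  }
  loadings <- U %*% diag(d, nrow = length(d))
  # sign convention: largest-|loading| entry of each spatial mode positive
  for (k in seq_along(d)) {
    s <- sign(loadings[which.max(abs(loadings[, k])), k])
    if (s < 0) { loadings[, k] <- -loadings[, k]; V[, k] <- -V[, k] }
  }
  modes <- array(NA_real_, c(npix, length(d)))
  modes[kept, ] <- loadings
  centerm <- rep(NA_real_, npix); centerm[kept] <- ctr
  varfrac <- sv$d[pos]^2 / sum(sv$d[pos]^2)
  structure(
    list(modes = array(modes, c(dm[1], dm[2], length(d))),
         pcs = V, d = d, varfrac = varfrac[seq_along(d)],
         total_var = sum(sv$d[pos]^2),
         kept = matrix(kept, dm[1], dm[2]),
         center = matrix(centerm, dm[1], dm[2])),
    class = "eof_result"
  )
}

#' Raw periodogram of a principal-component series
#'
#' Standard (untapered, unsmoothed) periodogram with the dominant frequency
#' reported.
#'
#' @param x Evenly sampled series.
#' @param dt_years Sampling interval, years.
#' @return Data.frame with `freq` (cycles per year) and `power`; attribute
#'   `dominant_freq` holds the frequency of maximum power.
#' @export
psd_periodogram <- function(x, dt_years) {
  stopifnot(dt_years > 0, length(x) >= 4L)
  sp <- stats::spec.pgram(stats::ts(x, deltat = dt_years), taper = 0,
                          fast = FALSE, detrend = FALSE, demean = TRUE,
                          plot = FALSE)
  out <- data.frame(freq = sp$freq, power = sp$spec)
  attr(out, "dominant_freq") <- sp$freq[which.max(sp$spec)]
  out
}

#' Select interannual EOF modes by their spectral signature
#'
#' Mode numbering in any one decomposition is dataset-dependent, so the
#' interannual modes are identified by criterion rather than index: a mode is
#' interannual when its principal component's dominant periodogram period
#' exceeds `period_cutoff_years`.  Returned in order of explained variance.
#'
#' @param eof An `eof_result`.
#' @param dt_years Sampling interval of the PCs, years.
#' @param period_cutoff_years Dominant-period threshold (default 1.5 years).
#' @return Integer vector of mode indices (possibly empty).
#' @export
select_interannual_modes <- function(eof, dt_years,
                                     period_cutoff_years = 1.5) {
  stopifnot(inherits(eof, "eof_result"))
  dom <- vapply(seq_len(ncol(eof$pcs)), function(k) {
    attr(psd_periodogram(eof$pcs[, k], dt_years), "dominant_freq")
  }, 0)
  which(1 / dom > period_cutoff_years)
}

#' Lowess smoothing with a fixed-size window
#'
#' Local first-degree weighted (tricube) regression over a moving window of
#' `window` points, without robustness iterations — the classic lowess
#' visualization filter.  Lines and constants pass through unchanged.
#'
#' @param x Series to smooth.
#' @param window Window size in points (default 20).
#' @return Smoothed series, same length.
#' @export
lowess_smooth <- function(x, window = 20) {
  n <- length(x)
  if (window < 3) stop("'window' must be at least 3 points")
  stats::lowess(seq_len(n), x, f = min(1, window / n), iter = 0)$y
}

#' Per-pixel seasonal versus interannual variance partition
#'
#' The gridded series is binned to calendar months, then a two-factor
#' fixed-effects variance model with month (12 levels) and year factors is
#' fitted per pixel; the variance fraction attributed to each factor is its
#' sum of squares over the total sum of squares.  Type-II sums of squares
#' (each factor adjusted for the other) handle missing-month imbalance and
#' reduce to the textbook orthogonal decomposition on balanced designs.
#'
#' @param field 3-D array `[lat, lon, time]` at composite resolution.
#' @param time_days Composite midpoints, days since record start.
#' @param lat Optional latitude vector enabling cos-latitude area weighting
#'   of the domain aggregate (unweighted by default).
#' @param area_weight Logical, apply cos-latitude weights to the aggregate.
#' @return List with matrices `seasonal`, `interannual`, `residual`
#'   (per-pixel fractions) and scalars `seasonal_mean`, `interannual_mean`
#'   (domain aggregates over valid pixels).
#' @export
variance_partition <- function(field, time_days, lat = NULL,
                               area_weight = FALSE) {
  dm <- dim(field)
  stopifnot(length(dm) == 3L, dm[3] == length(time_days))
  b <- month_year_bins(time_days)
  if (length(unique(b$year)) < 2L)
    stop("need at least two years of data")
  npix <- dm[1] * dm[2]
  flat <- matrix(field, npix, dm[3])
  cells <- split(seq_along(time_days), list(b$month, b$year), drop = TRUE)
  monthly <- vapply(cells, function(ii) rowMeans(flat[, ii, drop = FALSE]),
                    numeric(npix))
  monthly <- matrix(monthly, npix, length(cells))
  key <- strsplit(names(cells), "\\.")
  mo <- factor(as.integer(vapply(key, `[`, "", 1)))
  yr <- factor(as.integer(vapply(key, `[`, "", 2)))

  seasonal <- interannual <- residual <- rep(NA_real_, npix)
  complete <- !apply(monthly, 1, anyNA)

  if (any(complete)) {
    # shared design => compute the three hat matrices once
    Xf <- stats::model.matrix(~ mo + yr)
    Xm <- stats::model.matrix(~ mo)
    Xy <- stats::model.matrix(~ yr)
    hat <- function(X) X %*% solve(crossprod(X), t(X))
    Hf <- hat(Xf); Hm <- hat(Xm); Hy <- hat(Xy)
    Yc <- monthly[complete, , drop = FALSE]
    rss <- function(H) rowSums((Yc - Yc %*% H)^2)
    rss_f <- rss(Hf); rss_m <- rss(Hm); rss_y <- rss(Hy)
    gm <- rowMeans(Yc)
    sst <- rowSums((Yc - gm)^2)
    ok <- sst > 0
    seasonal[complete][ok] <- ((rss_y - rss_f) / sst)[ok]
    interannual[complete][ok] <- ((rss_m - rss_f) / sst)[ok]
    residual[complete][ok] <- (rss_f / sst)[ok]
  }
  # unbalanced pixels: per-pixel type-II fits on their observed months
  for (p in which(!complete)) {
    y <- monthly[p, ]
    ok <- !is.na(y)
    if (sum(ok) < 15L || length(unique(mo[ok])) < 2L ||
        length(unique(yr[ok])) < 2L) next
    d <- data.frame(y = y[ok], mo = droplevels(mo[ok]),
                    yr = droplevels(yr[ok]))
    rf <- sum(stats::resid(stats::lm(y ~ mo + yr, d))^2)
    rm_ <- sum(stats::resid(stats::lm(y ~ mo, d))^2)
    ry <- sum(stats::resid(stats::lm(y ~ yr, d))^2)
    sst <- sum((d$y - mean(d$y))^2)
    if (sst <= 0) next
    seasonal[p] <- (ry - rf) / sst
    interannual[p] <- (rm_ - rf) / sst
    residual[p] <- rf / sst
  }

  w <- rep(1, npix)
  if (area_weight && !is.null(lat))
    w <- rep(cos(lat * pi / 180), times = dm[2])
  valid <- !is.na(seasonal)
  agg <- function(x) sum((w * x)[valid]) / sum(w[valid])
  list(seasonal = matrix(seasonal, dm[1], dm[2]),
       interannual = matrix(interannual, dm[1], dm[2]),
       residual = matrix(residual, dm[1], dm[2]),
       seasonal_mean = agg(seasonal),
       interannual_mean = agg(interannual))
}

#' Monthly or annual anomalies of a gridded field
#'
#' `"monthly"` subtracts each pixel's month-of-year climatology from every
#' composite; `"annual"` returns each year's mean minus the record mean, one
#' layer per year.
#'
#' @param field 3-D array `[lat, lon, time]`.
#' @param time_days Composite midpoints, days.
#' @param mode `"monthly"` or `"annual"`.
#' @return For `"monthly"`, an array shaped like `field`; for `"annual"`, an
#'   array `[lat, lon, year]` with the year index as `attr(, "years")`.
#' @export
anomaly <- function(field, time_days, mode = c("monthly", "annual")) {
  mode <- match.arg(mode)
  dm <- dim(field)
  b <- month_year_bins(time_days)
  npix <- dm[1] * dm[2]
  flat <- matrix(field, npix, dm[3])
  if (mode == "monthly") {
    for (m in sort(unique(b$month))) {
      sel <- b$month == m
      clim <- rowMeans(flat[, sel, drop = FALSE], na.rm = TRUE)
      flat[, sel] <- flat[, sel, drop = FALSE] - clim
    }
    return(array(flat, dm))
  }
  yrs <- sort(unique(b$year))
  ann <- vapply(yrs, function(yy)
    rowMeans(flat[, b$year == yy, drop = FALSE], na.rm = TRUE),
    numeric(npix))
  ann <- ann - rowMeans(ann, na.rm = TRUE)
  out <- array(ann, c(dm[1], dm[2], length(yrs)))
  attr(out, "years") <- yrs
  out
}

#' Composite of annual anomalies over a set of years
#'
#' Mean of the annual-anomaly layers for the listed years (e.g. the warm or
#' cool phase of a decadal oscillation, supplied by the analyst).
#'
#' @param annual_anom Output of `anomaly(..., mode = "annual")`.
#' @param years Year indices (matching `attr(annual_anom, "years")`).
#' @return Matrix `[lat, lon]`.
#' @export
phase_composite <- function(annual_anom, years) {
  avail <- attr(annual_anom, "years")
  sel <- match(years, avail)
  if (anyNA(sel)) stop("requested year(s) not present in the anomaly record")
  apply(annual_anom[, , sel, drop = FALSE], c(1, 2), mean)
}

#' Per-pixel long-term trends with domain summaries
#'
#' Ordinary least-squares slope per pixel over the full record, the domain
#' median slope, and the fraction of (unmasked) area with a positive slope.
#'
#' @param field 3-D array `[lat, lon, time]`.
#' @param t_years Time stamps, years.
#' @return An object of class `trend_result`: `slope`, `intercept`,
#'   `slope_se` matrices, `median_slope`, `frac_positive`, `n_pixels`.
#' @export
pixel_trend <- function(field, t_years) {
  dt <- detrend_linear(field, t_years)
  ok <- !is.na(dt$slope)
  structure(
    list(slope = dt$slope, intercept = dt$intercept, slope_se = dt$slope_se,
         median_slope = stats::median(dt$slope[ok]),
         frac_positive = mean(dt$slope[ok] > 0),
         n_pixels = sum(ok)),
    class = "trend_result"
  )
}

#' Correlate a principal component with a climate-index series
#'
#' The index is linearly interpolated onto the PC's time stamps and the
#' Pearson correlation computed on the overlapping span.
#'
#' @param pc_time_days,pc PC time stamps (days) and values.
#' @param index_time_days,index Climate-index time stamps (days) and values.
#' @return List with `r`, `p`, `n`.
#' @export
climate_index_correlation <- function(pc_time_days, pc, index_time_days,
                                      index) {
  sel <- pc_time_days >= min(index_time_days) &
    pc_time_days <= max(index_time_days)
  if (sum(sel) < 3L) stop("time spans do not overlap enough")
  ii <- stats::approx(index_time_days, index, xout = pc_time_days[sel])$y
  ct <- stats::cor.test(pc[sel], ii)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(sel))
}

#' Hemisphere-by-nutrient region labels
#'
#' Every unmasked pixel is labelled by hemisphere (N/S) and by nutrient
#' regime: `highNut` where the nutricline is shallower than the split depth
#' (default 50 m), `lowNut` where it is deeper (absent-nutricline sentinels
#' fall in `lowNut`).
#'
#' @param lat Latitude vector (pixel rows).
#' @param z_no3 Nutricline-depth matrix `[lat, lon]` (`NA` masked).
#' @param split_m Depth split, m.
#' @return Character matrix of labels (`"N_highNut"`, ..., `NA` masked).
#' @export
region_labels <- function(lat, z_no3, split_m = 50) {
  stopifnot(length(lat) == nrow(z_no3))
  hemi <- ifelse(matrix(lat, nrow(z_no3), ncol(z_no3)) >= 0, "N", "S")
  nut <- ifelse(z_no3 <= split_m, "highNut", "lowNut")
  out <- matrix(paste(hemi, nut, sep = "_"), nrow(z_no3), ncol(z_no3))
  out[is.na(z_no3)] <- NA
  out
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param x Numeric vector (NAs dropped).
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Optional integer seed.
#' @return Named numeric: `mean`, `lower`, `upper`.
#' @export
boot_ci_mean <- function(x, n_boot = 10000, conf = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(c(mean = NA, lower = NA, upper = NA))
  bm <- colMeans(matrix(sample(x, length(x) * n_boot, replace = TRUE),
                        length(x), n_boot))
  qs <- stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  c(mean = mean(x), lower = qs[1], upper = qs[2])
}

#' Bootstrapped regional mean trends
#'
#' Mean per-pixel slope within each hemisphere-by-nutrient region with a
#' percentile bootstrap confidence interval over pixels (pixels resampled
#' independently).  Stress-index slopes are conventionally displayed scaled
#' by 10 to share an axis with SST trends; set `scale` accordingly.
#'
#' @param slope Per-pixel slope matrix (e.g. from [pixel_trend()]).
#' @param labels Region labels from [region_labels()].
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf Confidence level.
#' @param scale Display multiplier applied to means and CI bounds.
#' @param seed Integer seed.
#' @return Data.frame with `region`, `n_pixels`, `mean`, `lower`, `upper`
#'   (scaled).
#' @export
regional_trend_summary <- function(slope, labels, n_boot = 10000,
                                   conf = 0.95, scale = 1, seed = 1L) {
  stopifnot(identical(dim(slope), dim(labels)))
  set.seed(seed)
  regs <- sort(unique(labels[!is.na(labels)]))
  rows <- lapply(regs, function(rg) {
    x <- slope[!is.na(labels) & labels == rg]
    x <- x[!is.na(x)]
    ci <- boot_ci_mean(x, n_boot = n_boot, conf = conf)
    data.frame(region = rg, n_pixels = length(x),
               mean = scale * ci[["mean"]], lower = scale * ci[["lower"]],
               upper = scale * ci[["upper"]])
  })
  do.call(rbind, rows)
}
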