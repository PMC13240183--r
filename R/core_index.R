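#' Median irradiance within the mixed layer
#'
#' The median light level experienced by cells mixed through a layer of depth
#' `mld` is the surface daily irradiance attenuated to the mid-depth of the
#' layer: `I_ML = PAR * exp(-K_PAR * MLD / 2)`.
#'
#' @param par Daily integrated surface irradiance, mol quanta m^-2 day^-1.
#' @param kpar Diffuse attenuation coefficient for PAR, m^-1.  Must be > 0.
#' @param mld Mixed-layer depth, m.
#'
#' All three arguments vectorize and recycle as arrays; `NA` cells propagate.
#'
#' @return Median mixed-layer irradiance in the units of `par`.
#' @export
median_mixed_layer_irradiance <- function(par, kpar, mld) {
  if (any(par < 0, na.rm = TRUE)) stop("'par' must be non-negative")
  if (any(kpar <= 0, na.rm = TRUE)) stop("'kpar' must be strictly positive")
  if (any(mld < 0, na.rm = TRUE)) stop("'mld' must be non-negative")
  par * exp(-kpar * mld / 2)
}

#' Shallow-mixing correction to the deep-mixing carbon-to-chlorophyll baseline
#'
#' Multiplicative correction applied to the deep-mixing baseline when the
#' mixed layer is shallower than roughly six optical depths:
#' `(1 + exp(-0.15 * PAR)) / (1 + exp(-3 * I_ML))`.
#' It equals 1 when the two exponents agree (`3 * I_ML = 0.15 * PAR`, i.e.
#' `K_PAR * MLD = 2 * log(20)`), and lies in (0, 2] for admissible inputs.
#'
#' @param par Daily integrated surface irradiance, mol quanta m^-2 day^-1.
#' @param iml Median mixed-layer irradiance, same units; `iml <= par`.
#' @return Dimensionless correction factor.
#' @export
shallow_mixing_correction <- function(par, iml) {
  if (any(par < 0, na.rm = TRUE)) stop("'par' must be non-negative")
  if (any(iml < 0, na.rm = TRUE)) stop("'iml' must be non-negative")
  if (any(iml > par * (1 + 1e-12), na.rm = TRUE))
    stop("'iml' cannot exceed 'par' (light does not amplify at depth)")
  (1 + exp(-0.15 * par)) / (1 + exp(-3 * iml))
}

#' Photoacclimation carbon-to-chlorophyll ratio
#'
#' The component of the carbon-to-chlorophyll ratio attributable to
#' photoacclimation alone: a deep-mixing baseline `theta_dm`
#' (default 150 mgC mgChl^-1) times the shallow-mixing correction evaluated at
#' the median mixed-layer irradiance.
#'
#' By default the correction is applied as printed at every mixed-layer depth;
#' it passes through 1 naturally where `kpar * mld = 2 * log(20)` (about six
#' optical depths).  `clamp_deep_mixing = TRUE` instead holds the ratio at the
#' baseline for deeper mixing, the alternative reading of the deep-mixing
#' criterion.
#'
#' @inheritParams median_mixed_layer_irradiance
#' @param theta_dm Deep-mixing baseline, mgC mgChl^-1.
#' @param clamp_deep_mixing Clamp the correction to 1 beyond six optical
#'   depths instead of evaluating the printed expression there.
#' @return Modeled carbon-to-chlorophyll ratio, mgC mgChl^-1.
#' @export
theta_photo <- function(par, kpar, mld, theta_dm = 150,
                        clamp_deep_mixing = FALSE) {
  if (any(theta_dm <= 0)) stop("'theta_dm' must be positive")
  iml <- median_mixed_layer_irradiance(par, kpar, mld)
  dsm <- shallow_mixing_correction(par, iml)
  if (isTRUE(clamp_deep_mixing)) {
    deep <- kpar * mld >= 2 * log(20)
    dsm[which(deep)] <- 1
  }
  theta_dm * dsm
}

#' Observed carbon-to-chlorophyll ratio
#'
#' Direct ratio of retrieved phytoplankton carbon to chlorophyll-a.
#' Non-positive inputs are masked (`NA`) rather than raising an error; if every
#' cell ends up masked a warning is emitted.
#'
#' @param c_phyto Phytoplankton carbon, mgC m^-3.
#' @param chl Chlorophyll-a, mg m^-3.
#' @return Carbon-to-chlorophyll ratio, mgC mgChl^-1, with mask propagated.
#' @export
theta_obs <- function(c_phyto, chl) {
  out <- c_phyto / chl
  bad <- !is.na(out) & (is.na(c_phyto) | is.na(chl) | c_phyto <= 0 | chl <= 0)
  out[which(bad)] <- NA_real_
  out[which(is.na(c_phyto) | is.na(chl))] <- NA_real_
  if (length(out) > 0L && all(is.na(out)))
    warning("all cells masked in theta_obs")
  out
}

#' Nutrient-stress index from modeled and observed carbon-to-chlorophyll
#'
#' The default `"ratio"` variant, modeled over observed
#' (`theta_photo / theta_obs`), is linearly proportional to the
#' nutrient-regulated division rate; low values mean strong nutrient stress.
#' The rejected `"inverse"` (`theta_obs / theta_photo`) and `"normdiff"`
#' (`(theta_obs - theta_photo) / theta_photo`) variants are curvilinear in the
#' division-rate multiplier and are kept for comparison.
#'
#' @param theta_photo Modeled photoacclimation carbon-to-chlorophyll.
#' @param theta_obs Observed carbon-to-chlorophyll.
#' @param variant One of `"ratio"`, `"inverse"`, `"normdiff"`.
#' @return Dimensionless stress index.
#' @export
stress_index <- function(theta_photo, theta_obs,
                         variant = c("ratio", "inverse", "normdiff")) {
  variant <- match.arg(variant)
  if (any(theta_photo <= 0, na.rm = TRUE) || any(theta_obs <= 0, na.rm = TRUE))
    stop("carbon-to-chlorophyll ratios must be positive")
  switch(variant,
    ratio    = theta_photo / theta_obs,
    inverse  = theta_obs / theta_photo,
    normdiff = (theta_obs - theta_photo) / theta_photo
  )
}

#' Nutricline depth from a nitrate profile
#'
#' Shallowest depth at which linear interpolation between bracketing bottle
#' depths crosses the nitrate threshold (default 3 uM).  A surface
#' concentration already at or above the threshold gives 0 m; a profile that
#' never reaches the threshold returns the absent-nutricline sentinel `Inf`
#' (distinct from `NA`, which marks missing data).
#'
#' @param depth Depths, m, non-negative and strictly increasing.
#' @param value Nitrate concentrations, uM, same length.
#' @param threshold Nitrate threshold, uM.
#' @return Nutricline depth in m, 0, or `Inf` when absent.
#' @export
nutricline_depth <- function(depth, value, threshold = 3.0) {
  check_profile(depth, value)
  if (value[1] >= threshold) return(0)
  above <- which(value >= threshold)
  if (length(above) == 0L) return(Inf)
  i <- above[1]
  # linear interpolation between the bracketing levels i-1 and i
  d0 <- depth[i - 1]; d1 <- depth[i]
  v0 <- value[i - 1]; v1 <- value[i]
  d0 + (threshold - v0) / (v1 - v0) * (d1 - d0)
}

#' Mixed-layer depth from a potential-density profile
#'
#' Density-threshold criterion: the shallowest depth where potential density
#' exceeds its value at the reference depth (default 10 m) by `delta`
#' (default 0.03 kg m^-3), located by linear interpolation.  If the threshold
#' is never exceeded the deepest level is returned and flagged bottom-limited.
#'
#' @param depth Depths, m, strictly increasing, spanning `ref_depth`.
#' @param value Potential density, kg m^-3.
#' @param delta Density increment, kg m^-3.
#' @param ref_depth Reference depth, m.
#' @return List with `mld` (m) and logical `bottom_limited`.
#' @export
mld_from_density_profile <- function(depth, value, delta = 0.03,
                                     ref_depth = 10) {
  check_profile(depth, value)
  if (ref_depth < depth[1] || ref_depth > depth[length(depth)])
    stop("profile does not span the reference depth")
  rho_ref <- stats::approx(depth, value, xout = ref_depth)$y
  target <- rho_ref + delta
  below <- depth >= ref_depth
  d <- depth[below]; v <- value[below]
  over <- which(v >= target)
  if (length(over) == 0L)
    return(list(mld = depth[length(depth)], bottom_limited = TRUE))
  i <- over[1]
  if (i == 1L) return(list(mld = d[1], bottom_limited = FALSE))
  mld <- d[i - 1] + (target - v[i - 1]) / (v[i] - v[i - 1]) * (d[i] - d[i - 1])
  list(mld = mld, bottom_limited = FALSE)
}

check_profile <- function(depth, value) {
  if (length(depth) < 2L || length(value) != length(depth))
    stop("profile needs >= 2 matching (depth, value) levels")
  if (any(depth < 0)) stop("depths must be non-negative")
  if (any(diff(depth) <= 0)) stop("depths must be strictly increasing")
  invisible(TRUE)
}

#' Diffuse attenuation for PAR from the 490 nm attenuation coefficient
#'
#' Monotone polynomial conversion of Morel et al. (2007):
#' `K_PAR = 0.0864 + 0.884 * K490 - 0.00137 / K490`.  When a PAR attenuation
#' product is supplied directly, `passthrough = TRUE` returns the input
#' unchanged.
#'
#' @param k490 Diffuse attenuation at 490 nm, m^-1, > 0.
#' @param passthrough Return `k490` untouched (input already K_PAR).
#' @return Diffuse attenuation for PAR, m^-1.
#' @export
kpar_from_k490 <- function(k490, passthrough = FALSE) {
  if (any(k490 <= 0, na.rm = TRUE)) stop("'k490' must be positive")
  if (isTRUE(passthrough)) return(k490)
  0.0864 + 0.884 * k490 - 0.00137 / k490
}

#' Compute the nutrient-stress index fields on a gridded scene
#'
#' Convenience wrapper running the whole index chain on a scene: observed
#' carbon-to-chlorophyll from `c_phyto` and `chl`, the photoacclimation model
#' from `par`, `kpar`, `mld`, and the stress index.  Masked cells propagate.
#'
#' @param scene A `gridded_scene` (see [generate_scene()] / [read_scene()]).
#' @param theta_dm Deep-mixing baseline, mgC mgChl^-1.
#' @param clamp_deep_mixing See [theta_photo()].
#' @param variant Stress-index variant, see [stress_index()].
#' @return The scene with `theta_obs`, `theta_photo` and `theta_prime` fields
#'   added.
#' @export
compute_theta_prime <- function(scene, theta_dm = 150,
                                clamp_deep_mixing = FALSE,
                                variant = "ratio") {
  stopifnot(inherits(scene, "gridded_scene"))
  t_obs <- theta_obs(scene$fields$c_phyto, scene$fields$chl)
  t_pho <- theta_photo(scene$fields$par, scene$fields$kpar, scene$fields$mld,
                       theta_dm = theta_dm,
                       clamp_deep_mixing = clamp_deep_mixing)
  scene$fields$theta_obs <- t_obs
  scene$fields$theta_photo <- t_pho
  scene$fields$theta_prime <- stress_index(t_pho, t_obs, variant = variant)
  scene
}
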