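#' Parametric chlorophyll-to-carbon photoacclimation model
#'
#' Stand-in for laboratory chlorophyll-to-carbon (Chl:C) versus growth
#' irradiance curves used to compare candidate stress-index formulations.
#' The baseline curve is anchored at a single dark value `chlc_dark` to which
#' every nutrient condition converges as irradiance approaches zero (division
#' becomes entirely light-limited there, so nutrient availability is
#' irrelevant), rises steeply over the first few tens of umol photons m^-2 s^-1
#' as division becomes light-regulated, and then shows the familiar
#' photoacclimation decline at high light:
#'
#' `chlc_base(I) = chlc_dark + a * (1 - exp(-I / b_rise)) * exp(-I / b_fall)`
#'
#' Nutrient availability scales the light-dependent part of the curve in
#' direct proportion to the nutrient-regulated division-rate multiplier `f`
#' (`f = 1` baseline, `f > 1` nutrient-replete, `f < 1` nutrient-stressed),
#' keeping the dark anchor common to all conditions.
#'
#' @param chlc_dark Common Chl:C value at zero irradiance, mgChl mgC^-1.
#' @param a Amplitude of the light-dependent Chl:C excursion, mgChl mgC^-1.
#' @param b_rise E-folding irradiance of the low-light rise,
#'   umol photons m^-2 s^-1.
#' @param b_fall E-folding irradiance of the photoacclimation decline,
#'   umol photons m^-2 s^-1.
#' @param mu_sat Light-saturated, nutrient-limited division rate of the
#'   baseline condition, day^-1.
#' @param i_sat Irradiance below which division becomes light-limited,
#'   umol photons m^-2 s^-1.
#' @return An object of class `acclimation_model`.
#' @export
acclimation_model <- function(chlc_dark = 0.005, a = 0.08, b_rise = 15,
                              b_fall = 300, mu_sat = 0.75, i_sat = 200) {
  stopifnot(chlc_dark >= 0, a > 0, b_rise > 0, b_fall > 0,
            mu_sat > 0, i_sat > 0)
  structure(
    list(chlc_dark = chlc_dark, a = a, b_rise = b_rise, b_fall = b_fall,
         mu_sat = mu_sat, i_sat = i_sat),
    class = "acclimation_model"
  )
}

#' Baseline Chl:C versus growth irradiance
#'
#' @param model An [acclimation_model()].
#' @param irradiance Growth irradiance(s), umol photons m^-2 s^-1, >= 0.
#' @return Baseline Chl:C, mgChl mgC^-1.
#' @export
chlc_base <- function(model, irradiance) {
  stopifnot(inherits(model, "acclimation_model"))
  if (any(irradiance < 0)) stop("irradiance must be non-negative")
  model$chlc_dark +
    model$a * (1 - exp(-irradiance / model$b_rise)) *
    exp(-irradiance / model$b_fall)
}

#' Chl:C curve for a given nutrient condition
#'
#' `chlc_dark + f * (chlc_base(I) - chlc_dark)`: all conditions converge on
#' the dark value at zero irradiance and scale in proportion to `f` where the
#' dark contribution is negligible.
#'
#' @inheritParams chlc_base
#' @param f Nutrient-regulated division-rate multiplier, > 0.
#' @return Chl:C, mgChl mgC^-1.
#' @export
chlc_curve <- function(model, irradiance, f) {
  if (any(f <= 0)) stop("'f' must be positive")
  model$chlc_dark + f * (chlc_base(model, irradiance) - model$chlc_dark)
}

#' Division rate under combined light and nutrient regulation
#'
#' `mu = f * mu_sat * ramp(I)`, where the light-limitation ramp is a
#' saturating exponential reaching 1 at `i_sat` and held there above it, so
#' division stays light-saturated down to `i_sat` and falls towards zero in
#' darkness.
#'
#' @inheritParams chlc_curve
#' @return Division rate, day^-1.
#' @export
division_rate <- function(model, irradiance, f) {
  stopifnot(inherits(model, "acclimation_model"))
  if (any(f <= 0)) stop("'f' must be positive")
  if (any(irradiance < 0)) stop("irradiance must be non-negative")
  k <- 3
  ramp <- pmin(1, (1 - exp(-k * irradiance / model$i_sat)) / (1 - exp(-k)))
  f * model$mu_sat * ramp
}

#' Stress-index response of the three candidate formulations
#'
#' For each nutrient multiplier `f`, the observed carbon-to-chlorophyll ratio
#' is taken from the `f` condition and the photoacclimation reference from the
#' baseline (`f = 1`), both at the same (saturating) growth irradiance, and
#' the three index variants are computed.  The ratio variant is linear in `f`
#' (exactly proportional when the dark Chl:C contribution vanishes), while the
#' inverse and normalized-difference variants are convex decreasing /
#' curvilinear, which is why the ratio form is the one retained.
#'
#' @inheritParams chlc_base
#' @param f_grid Nutrient multipliers to evaluate.
#' @param irradiance Single growth irradiance, ideally >= `i_sat`.
#' @return A data.frame with columns `f`, `theta_obs`, `theta_photo`,
#'   `ratio`, `inverse`, `normdiff`, `mu`.
#' @export
index_response <- function(model, f_grid = seq(0.2, 1.6, by = 0.2),
                           irradiance = 400) {
  stopifnot(inherits(model, "acclimation_model"), length(irradiance) == 1L)
  chlc_ref <- chlc_curve(model, irradiance, 1)
  chlc_f <- chlc_curve(model, irradiance, f_grid)
  if (any(chlc_f <= 0)) stop("Chl:C non-positive on the requested f grid")
  th_obs <- 1 / chlc_f
  th_photo <- 1 / chlc_ref
  data.frame(
    f = f_grid,
    theta_obs = th_obs,
    theta_photo = th_photo,
    ratio = stress_index(th_photo, th_obs, "ratio"),
    inverse = stress_index(th_photo, th_obs, "inverse"),
    normdiff = stress_index(th_photo, th_obs, "normdiff"),
    mu = division_rate(model, irradiance, f_grid)
  )
}
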