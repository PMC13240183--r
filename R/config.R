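#' Default pipeline configuration
#'
#' All numeric constants of the method live here with their standard values:
#' the deep-mixing carbon-to-chlorophyll baseline, the nutricline nitrate
#' threshold, the mixed-layer density criterion, the cross-mission bias
#' offsets, the random-forest size, the characteristic matchup window, the
#' regional nutrient split, and the bootstrap count.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    theta_dm = 150,                 # mgC mgChl^-1, deep-mixing baseline
    clamp_deep_mixing = FALSE,
    nutricline_threshold_uM = 3.0,
    mld_delta_kgm3 = 0.03,
    mld_ref_depth_m = 10,
    chl_offset_mgm3 = 0.012,        # companion-mission minus reference
    bbp_offset_m1 = 1.71e-5,
    n_trees = 500,
    matchup_spatial = "2deg",
    matchup_halfwidth_days = 20,    # 40-day characteristic window
    region_nutricline_split_m = 50,
    n_boot = 10000,
    eof_max_missing_frac = 0.2,
    lowess_window = 20,
    interannual_period_years = 1.5  # PSD cutoff separating seasonal modes
  )
}

#' Load a configuration file, filling unspecified keys with defaults
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      warning("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg
}
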