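# Small shared fixtures, all generated in code.

tiny_spec <- function(seed = 11L, ...) {
  args <- list(n_lat = 10, n_lon = 20, n_years = 3, seed = seed,
               land = FALSE)
  args[names(list(...))] <- list(...)
  do.call(scene_spec, args)
}

tiny_scene <- function(seed = 11L, ...) generate_scene(tiny_spec(seed, ...))

# brute-force matchup oracle: explicit loop over every cell
colocate_bruteforce <- function(scene, samples, spatial, halfwidth_days,
                                field = "theta_prime_true") {
  arr <- scene$fields[[field]]
  nlat <- length(scene$lat); nlon <- length(scene$lon)
  px <- c("1x1" = 1, "3x3" = 3, "5x5" = 5)
  out <- rep(NA_real_, nrow(samples))
  for (k in seq_len(nrow(samples))) {
    vals <- c()
    for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
      if (spatial %in% names(px)) {
        i0 <- which.min(abs(scene$lat - samples$lat[k]))
        j0 <- which.min(abs(scene$lon - samples$lon[k]))
        half <- (px[[spatial]] - 1) / 2
        insp <- abs(i - i0) <= half && abs(j - j0) <= half
      } else {
        w <- as.numeric(sub("deg", "", spatial)) / 2
        insp <- abs(scene$lat[i] - samples$lat[k]) <= w &&
          abs(scene$lon[j] - samples$lon[k]) <= w
      }
      if (!insp) next
      for (tt in seq_along(scene$time_days)) {
        if (abs(scene$time_days[tt] - samples$date_days[k]) <=
            halfwidth_days) {
          vals <- c(vals, arr[i, j, tt])
        }
      }
    }
    vals <- vals[!is.na(vals)]
    if (length(vals)) out[k] <- mean(vals)
  }
  out
}
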