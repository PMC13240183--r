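#' Construct a gridded lat/lon/time scene
#'
#' The scene is the pipeline's in-memory cube: coordinate vectors plus named
#' 3-D fields `[lat, lon, time]` (and optional 2-D static fields `[lat, lon]`
#' such as nutricline depth).  Masked cells are `NA`; any arithmetic with a
#' masked cell yields a masked cell and no infilling is performed.
#'
#' @param lat,lon Cell-center coordinates of a regular mesh, degrees.
#' @param time_days Composite-midpoint time stamps, days since record start.
#' @param fields Named list of arrays `[nlat, nlon, ntime]`.
#' @param static Named list of matrices `[nlat, nlon]`.
#' @param meta Named list of free-form provenance entries (seed, units, ...).
#' @return An object of class `gridded_scene`.
#' @export
gridded_scene <- function(lat, lon, time_days, fields = list(),
                          static = list(), meta = list()) {
  dims <- c(length(lat), length(lon), length(time_days))
  for (nm in names(fields)) {
    if (!identical(dim(fields[[nm]]), as.integer(dims)))
      stop(sprintf("field '%s' does not match the (lat, lon, time) grid", nm))
  }
  for (nm in names(static)) {
    if (!identical(dim(static[[nm]]), as.integer(dims[1:2])))
      stop(sprintf("static field '%s' does not match the (lat, lon) grid", nm))
  }
  structure(
    list(lat = as.numeric(lat), lon = as.numeric(lon),
         time_days = as.numeric(time_days),
         fields = fields, static = static, meta = meta),
    class = "gridded_scene"
  )
}

#' @export
print.gridded_scene <- function(x, ...) {
  cat(sprintf("<gridded_scene> %d lat x %d lon x %d time\n",
              length(x$lat), length(x$lon), length(x$time_days)))
  cat("  fields:", paste(names(x$fields), collapse = ", "), "\n")
  if (length(x$static))
    cat("  static:", paste(names(x$static), collapse = ", "), "\n")
  invisible(x)
}

#' Scene time stamps in decimal years
#' @param scene A `gridded_scene`.
#' @return Numeric vector, years since record start (365.25-day years).
#' @export
scene_years <- function(scene) scene$time_days / 365.25

required_scene_vars <- c("chl", "c_phyto", "par", "kpar", "mld")

#' Write a gridded scene to a plain-text JSON file
#'
#' Scenes are serialized as a single JSON document carrying coordinates,
#' fields (with `NA` encoded as `null`), static fields, and metadata, at 15
#' significant digits — exact for single-precision payloads and well beyond
#' retrieval accuracy for anything else; masks round-trip exactly.
#'
#' @param scene A `gridded_scene`.
#' @param path Output file path (conventionally `*.scene.json`).
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "gridded_scene"))
  payload <- list(
    schema = "thetaprime-scene-1",
    lat = scene$lat, lon = scene$lon, time_days = scene$time_days,
    fields = lapply(scene$fields, as.vector),
    static = lapply(scene$static, as.vector),
    meta = scene$meta
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a gridded scene written by [write_scene()]
#'
#' Missing required variables raise a schema error naming the variable; a
#' missing units entry only warns.
#'
#' @param path File path.
#' @param check_required Require the standard variable set (`chl`, `c_phyto`,
#'   `par`, `kpar`, `mld`).
#' @return A `gridded_scene`.
#' @export
read_scene <- function(path, check_required = TRUE) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "thetaprime-scene-1"))
    stop("not a thetaprime scene file: ", path)
  dims <- c(length(payload$lat), length(payload$lon),
            length(payload$time_days))
  fields <- lapply(payload$fields, function(v) array(as.numeric(v), dim = dims))
  static <- lapply(payload$static, function(v)
    matrix(as.numeric(v), nrow = dims[1], ncol = dims[2]))
  if (isTRUE(check_required)) {
    missing_vars <- setdiff(required_scene_vars, names(fields))
    if (length(missing_vars))
      stop("scene file is missing required variable(s): ",
           paste(missing_vars, collapse = ", "))
  }
  meta <- payload$meta
  if (is.null(meta$units)) warning("scene has no units metadata")
  gridded_scene(payload$lat, payload$lon, payload$time_days,
                fields = fields, static = static, meta = meta)
}

#' Down-scale a scene to a coarser grid and longer compositing period
#'
#' Unweighted mean of the contributing finer cells and composites; a coarse
#' cell with no valid contributor is masked.
#'
#' @param scene A `gridded_scene`.
#' @param factor_space Integer block size pooled in both lat and lon.
#' @param factor_time Integer number of composites pooled per output step.
#' @return A coarser `gridded_scene` (static fields pooled spatially).
#' @export
regrid_downscale <- function(scene, factor_space = 1L, factor_time = 1L) {
  stopifnot(inherits(scene, "gridded_scene"),
            factor_space >= 1L, factor_time >= 1L)
  fs <- as.integer(factor_space); ft <- as.integer(factor_time)
  nlat <- length(scene$lat); nlon <- length(scene$lon)
  nt <- length(scene$time_days)
  il <- make_blocks(nlat, fs); jl <- make_blocks(nlon, fs)
  tl <- make_blocks(nt, ft)
  lat2 <- vapply(il, function(ii) mean(scene$lat[ii]), 0)
  lon2 <- vapply(jl, function(jj) mean(scene$lon[jj]), 0)
  t2 <- vapply(tl, function(tt) mean(scene$time_days[tt]), 0)
  pool3 <- function(a) {
    out <- array(NA_real_, dim = c(length(il), length(jl), length(tl)))
    for (i in seq_along(il)) for (j in seq_along(jl)) for (k in seq_along(tl)) {
      block <- a[il[[i]], jl[[j]], tl[[k]]]
      if (any(!is.na(block))) out[i, j, k] <- mean(block, na.rm = TRUE)
    }
    out
  }
  pool2 <- function(m) {
    out <- matrix(NA_real_, length(il), length(jl))
    for (i in seq_along(il)) for (j in seq_along(jl)) {
      block <- m[il[[i]], jl[[j]]]
      if (any(!is.na(block))) out[i, j] <- mean(block, na.rm = TRUE)
    }
    out
  }
  gridded_scene(lat2, lon2, t2,
                fields = lapply(scene$fields, pool3),
                static = lapply(scene$static, pool2),
                meta = c(scene$meta,
                         list(regridded = c(space = fs, time = ft))))
}

make_blocks <- function(n, f) {
  split(seq_len(n), ceiling(seq_len(n) / f))
}

#' Apply cross-mission sensor bias offsets
#'
#' Harmonizes a companion-mission scene onto the reference mission by
#' subtracting the chlorophyll offset and adding the backscattering offset
#' (defaults are the overlap-period mean differences, applied to the
#' companion sensor's products).  A provenance flag guards against applying
#' the correction twice.
#'
#' @param scene A `gridded_scene` with a `chl` field (and optionally
#'   `bbp_443`).
#' @param chl_offset Chlorophyll offset, mg m^-3, subtracted from `chl`.
#' @param bbp_offset Backscattering offset, m^-1, added to `bbp_443`.
#' @return The bias-corrected scene.
#' @export
apply_sensor_bias <- function(scene, chl_offset = 0.012,
                              bbp_offset = 1.71e-5) {
  stopifnot(inherits(scene, "gridded_scene"))
  if (isTRUE(scene$meta$sensor_bias_applied))
    stop("sensor bias already applied to this scene")
  if (!is.null(scene$fields$chl))
    scene$fields$chl <- scene$fields$chl - chl_offset
  if (!is.null(scene$fields$bbp_443))
    scene$fields$bbp_443 <- scene$fields$bbp_443 + bbp_offset
  scene$meta$sensor_bias_applied <- TRUE
  scene$meta$sensor_bias <- c(chl_offset = chl_offset,
                              bbp_offset = bbp_offset)
  scene
}
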