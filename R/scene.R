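#' Scene generator configuration
#'
#' Describes the synthetic coastal scene the generator emulates: a tamarisk
#' reserve on saline-alkali land with a land-to-sea salinity gradient,
#' patchy shrub cover, near-shore water, a smooth aerosol field and thermal
#' contrast between dense and sparse vegetation. Defaults reproduce the
#' study conditions of the September scene the workflow models: AOD between
#' roughly 0.5 and 1.4, land surface temperature between 24.55 and 30.15
#' degrees C, soluble salt up to 15 g/kg.
#'
#' @param rows,cols pixel counts (>= 8).
#' @param pixel_size pixel edge in metres.
#' @param veg_fraction target fraction of *all* pixels whose surface NDVI
#'   exceeds 0.3 (the dense-dark-vegetation threshold).
#' @param salinity_range min/max soluble salt content, g/kg, land to sea.
#' @param aod_field numeric `c(base, amplitude)`: the AOD truth field is
#'   `base + amplitude * s` with a smooth field `s` in [-1, 1].
#' @param lst_range min/max land surface temperature, degrees C.
#' @param noise_sd per-band Gaussian reflectance noise (reflectance units).
#' @param water_fraction fraction of pixels flagged as water (near the sea
#'   edge); `veg_fraction + water_fraction` must be <= 1.
#' @param sea_direction which scene edge is the sea: `"north"`, `"south"`,
#'   `"east"` or `"west"`. Salinity increases toward it.
#' @param geometry named vector `c(theta_s, theta_v, phi)` in degrees, the
#'   constant acquisition geometry used when forward-modelling the
#'   aerosol-sensor bands.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(rows = 128, cols = 128, pixel_size = 10,
                         veg_fraction = 0.5, salinity_range = c(0, 15),
                         aod_field = c(base = 0.95, amplitude = 0.45),
                         lst_range = c(24.55, 30.15), noise_sd = 0.005,
                         water_fraction = 0.08, sea_direction = "north",
                         geometry = c(theta_s = 24, theta_v = 30, phi = 96)) {
  if (rows < 8 || cols < 8)
    stop("scene must be at least 8 x 8 pixels", call. = FALSE)
  for (rg in list(salinity_range, lst_range))
    if (length(rg) != 2 || rg[1] > rg[2] || !all(is.finite(rg)))
      stop("ranges must be ordered (min, max)", call. = FALSE)
  if (veg_fraction < 0 || veg_fraction > 1 ||
      water_fraction < 0 || water_fraction > 1 ||
      veg_fraction + water_fraction > 1)
    stop("veg_fraction and water_fraction must be in [0,1] and sum to <= 1",
         call. = FALSE)
  if (length(aod_field) != 2 || aod_field[1] - abs(aod_field[2]) < 0)
    stop("aod_field must be c(base, amplitude) with base >= amplitude >= 0",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  sea_direction <- match.arg(sea_direction, c("north", "south", "east", "west"))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pixel_size = pixel_size, veg_fraction = veg_fraction,
                 salinity_range = salinity_range,
                 aod_field = unname(aod_field), lst_range = lst_range,
                 noise_sd = noise_sd, water_fraction = water_fraction,
                 sea_direction = sea_direction, geometry = geometry),
            class = "scene_config")
}

# Endmember surface reflectances for linear mixing. Columns are the
# Sentinel-2-style band roles used downstream; rows vegetation / bare
# saline soil / water. Values are implementation defaults chosen to give
# realistic NDVI, wetness and bare-soil-index contrast (dense shrub NDVI
# ~0.8, bare soil ~0.17, water < 0).
.s2_bands <- c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A", "B11", "B12")
.endmembers <- rbind(
  veg   = c(B2 = 0.030, B3 = 0.050, B4 = 0.040, B5 = 0.100, B6 = 0.250,
            B7 = 0.320, B8 = 0.380, B8A = 0.400, B11 = 0.150, B12 = 0.070),
  soil  = c(B2 = 0.120, B3 = 0.160, B4 = 0.200, B5 = 0.220, B6 = 0.240,
            B7 = 0.260, B8 = 0.280, B8A = 0.290, B11 = 0.350, B12 = 0.300),
  water = c(B2 = 0.060, B3 = 0.050, B4 = 0.030, B5 = 0.020, B6 = 0.015,
            B7 = 0.010, B8 = 0.008, B8A = 0.006, B11 = 0.003, B12 = 0.002))
# Aerosol-sensor roles (broad red / blue / NIR)
.aod_endmembers <- rbind(
  veg   = c(blue = 0.025, red = 0.040, nir = 0.350),
  soil  = c(blue = 0.110, red = 0.210, nir = 0.270),
  water = c(blue = 0.050, red = 0.020, nir = 0.008))

# Smooth random field in [0, 1] via repeated separable moving-average
# smoothing of white noise, then rank-uniformized so thresholds at a given
# quantile select exactly the requested pixel count.
smooth_uniform_field <- function(rows, cols, width = max(3L, round(min(rows, cols) / 10))) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  k <- rep(1 / width, width)
  for (i in 1:3) {
    z <- apply(z, 2, function(col) stats::filter(col, k, circular = TRUE))
    z <- t(apply(z, 1, function(row) stats::filter(row, k, circular = TRUE)))
  }
  matrix(rank(z, ties.method = "first") / (rows * cols), rows, cols)
}

# 0 at the landward edge, 1 at the sea edge.
seaward_coordinate <- function(rows, cols, sea_direction) {
  g <- switch(sea_direction,
    north = matrix(rev(seq_len(rows)) - 1, rows, cols) / (rows - 1),
    south = matrix(seq_len(rows) - 1, rows, cols) / (rows - 1),
    east  = matrix(rep(seq_len(cols) - 1, each = rows), rows, cols) / (cols - 1),
    west  = matrix(rep(rev(seq_len(cols)) - 1, each = rows), rows, cols) / (cols - 1))
  g
}

#' Generate a synthetic multiband scene with truth fields
#'
#' Builds surface reflectance for the ten Sentinel-2-style band roles by
#' linear mixing of three endmembers (vegetation, bare saline soil, water),
#' a thermal radiance band synthesized from the temperature truth by the
#' Planck forward model, and top-of-atmosphere red/blue/NIR bands for the
#' aerosol sensor forward-modelled through a lookup table at the aerosol
#' truth. Truth rasters for AOD, salinity and temperature are returned
#' alongside, so every retrieval stage has an exact oracle.
#'
#' Construction details that tests rely on:
#' * the fraction of pixels with surface NDVI > 0.3 equals
#'   `veg_fraction` by construction (up to reflectance noise);
#' * mean salinity over each cross-shore slice increases strictly seaward;
#' * on vegetated pixels the aerosol-sensor surface red/blue ratio is held
#'   exactly at `k_ratio`, the assumption the dark-target retrieval
#'   inverts, so retrieval error isolates the lookup-table step;
#' * bare-soil brightness increases with the local salt content (salt
#'   crusts are bright), which gives the salinity regression its signal.
#'
#' @param config [scene_config()].
#' @param seed integer seed; scenes are bit-identical for equal seeds.
#' @param lut `aod_lut` used to forward-model the aerosol-sensor bands
#'   (default [synthetic_lut()]).
#' @param tau_snap optional numeric grid; when given, the AOD truth is
#'   snapped to the nearest value (used for exact-recovery experiments).
#' @param k_ratio red/blue surface ratio enforced on vegetated pixels.
#' @param lst_params [lst_params()] for the thermal forward model.
#' @return object of class `rsei_scene`: a list with `$reflectance` (named
#'   list of raster_grid, bands B2..B12 plus `red`, `blue`, `nir` TOA),
#'   `$thermal_radiance`, `$truth_aod`, `$truth_salinity`, `$truth_lst`,
#'   `$water_mask`, `$veg_mask`, plus the config, geometry, lut and
#'   calibration used.
#' @export
make_scene <- function(config = scene_config(), seed = 1, lut = NULL,
                       tau_snap = NULL, k_ratio = 1.60,
                       lst_params = rseikit::lst_params()) {
  if (!inherits(config, "scene_config"))
    stop("`config` must be a scene_config", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(lut)) lut <- synthetic_lut()
  rows <- config$rows; cols <- config$cols
  npix <- rows * cols
  geo <- function(m) raster_grid(m, config$pixel_size, c(0, 0), "local")

  g <- seaward_coordinate(rows, cols, config$sea_direction)

  # --- water: seaward-biased smooth blob ---------------------------------
  wscore <- 0.6 * smooth_uniform_field(rows, cols) + 1.4 * g
  n_water <- round(config$water_fraction * npix)
  water <- matrix(FALSE, rows, cols)
  if (n_water > 0)
    water[order(wscore, decreasing = TRUE)[seq_len(n_water)]] <- TRUE

  # --- salinity truth: gradient + slice-centred texture ------------------
  u <- smooth_uniform_field(rows, cols)
  uc <- u
  if (config$sea_direction %in% c("north", "south")) {
    uc <- u - matrix(rowMeans(u), rows, cols)
  } else {
    uc <- u - matrix(rep(colMeans(u), each = rows), rows, cols)
  }
  sr <- config$salinity_range
  salt <- sr[1] + diff(sr) * (0.15 + 0.70 * g) + diff(sr) * 0.30 * uc
  salt <- pmin(pmax(salt, sr[1]), sr[2])
  truth_salinity <- geo(salt)

  # --- vegetation fraction field -----------------------------------------
  # Per-pixel fractional cover fv; the NDVI = 0.3 crossing fv* is solved in
  # closed form per pixel (soil red reflectance depends on local salt), and
  # fv is assigned by rank so that exactly veg_fraction of all pixels lie
  # above fv* before noise.
  salt01 <- (salt - sr[1]) / max(diff(sr), 1e-12)
  bright <- 1 + 0.25 * (salt01 - 0.5)       # salt-crust brightness factor
  soil_red <- .endmembers["soil", "B4"] * bright
  soil_nir <- .endmembers["soil", "B8"]
  thr <- 0.3
  cc <- (1 + thr) / (1 - thr)
  A <- (.endmembers["veg", "B8"] - soil_nir) -
    cc * (.endmembers["veg", "B4"] - soil_red)
  B <- soil_nir - cc * soil_red
  fv_star <- pmin(pmax(-B / A, 0.05), 0.95)

  n_veg <- round(config$veg_fraction * npix)
  land_idx <- which(!water)
  if (n_veg > length(land_idx))
    stop("veg_fraction leaves too few land pixels", call. = FALSE)
  vfield <- smooth_uniform_field(rows, cols)
  ord <- land_idx[order(vfield[land_idx], decreasing = TRUE)]
  veg_idx <- ord[seq_len(n_veg)]
  bare_idx <- ord[-seq_len(n_veg)]
  fv <- matrix(0, rows, cols)
  if (n_veg > 0) {
    t_in <- rev(seq_len(n_veg)) / n_veg          # densest cover first
    fv[veg_idx] <- fv_star[veg_idx] +
      (0.98 - fv_star[veg_idx]) * (0.10 + 0.90 * t_in)
  }
  if (length(bare_idx) > 0) {
    t_out <- rev(seq_along(bare_idx)) / length(bare_idx)
    fv[bare_idx] <- fv_star[bare_idx] * 0.90 * t_out
  }
  veg_mask <- matrix(FALSE, rows, cols); veg_mask[veg_idx] <- TRUE

  # --- surface reflectance, Sentinel-2 roles -----------------------------
  reflectance <- list()
  for (b in .s2_bands) {
    soil_b <- .endmembers["soil", b] *
      (if (b %in% c("B2", "B3", "B4", "B5", "B11", "B12")) bright else 1)
    v <- fv * .endmembers["veg", b] + (1 - fv) * soil_b
    v[water] <- .aod_water_jitter(.endmembers["water", b], sum(water))
    if (config$noise_sd > 0)
      v <- v + stats::rnorm(npix, sd = config$noise_sd)
    reflectance[[b]] <- geo(pmin(pmax(v, 0), 1))
  }

  # --- AOD truth ----------------------------------------------------------
  s <- 2 * smooth_uniform_field(rows, cols) - 1
  tau <- config$aod_field[1] + config$aod_field[2] * s
  if (!is.null(tau_snap)) {
    tau_snap <- sort(tau_snap)
    mids <- utils::head(tau_snap, -1) + diff(tau_snap) / 2
    tau <- matrix(tau_snap[findInterval(tau, mids) + 1L], rows, cols)
  }
  tau <- pmin(pmax(tau, min(lut$axes$tau)), max(lut$axes$tau))
  truth_aod <- geo(tau)

  # --- aerosol-sensor surface bands, ratio enforced on vegetation --------
  aod_surface <- list()
  for (b in c("blue", "red", "nir")) {
    v <- fv * .aod_endmembers["veg", b] + (1 - fv) * .aod_endmembers["soil", b] *
      (if (b != "nir") bright else 1)
    v[water] <- .aod_endmembers["water", b]
    aod_surface[[b]] <- v
  }
  aod_surface$red[veg_mask] <- k_ratio * aod_surface$blue[veg_mask]

  # --- forward to TOA through the LUT ------------------------------------
  gm <- config$geometry
  for (b in c("blue", "red", "nir")) {
    lb <- if (b %in% names(lut$bands)) b else "red"
    co <- lut_interpolate(lut, lb, gm["theta_s"], gm["theta_v"], gm["phi"],
                          as.vector(tau))
    v <- forward_toa(as.vector(aod_surface[[b]]), co$rho_a, co$T, co$S)
    if (config$noise_sd > 0)
      v <- v + stats::rnorm(npix, sd = config$noise_sd)
    reflectance[[b]] <- geo(matrix(pmin(pmax(v, 0), 1), rows, cols))
  }

  # --- temperature truth and thermal radiance ----------------------------
  lr <- config$lst_range
  fv_eff <- fv; fv_eff[water] <- 0.9
  up <- 2 * smooth_uniform_field(rows, cols) - 1
  lst_c <- lr[1] + diff(lr) * (0.05 + 0.90 * (1 - fv_eff)) +
    diff(lr) * 0.05 * up
  truth_lst <- geo(lst_c)
  L <- forward_thermal_radiance(lst_c + 273.15, lst_params)
  thermal <- geo(L)

  structure(list(reflectance = reflectance, thermal_radiance = thermal,
                 truth_aod = truth_aod, truth_salinity = truth_salinity,
                 truth_lst = truth_lst, water_mask = water,
                 veg_mask = veg_mask, fractional_cover = fv,
                 config = config, geometry = gm, lut = lut,
                 k_ratio = k_ratio, lst_params = lst_params,
                 seed = as.integer(seed)),
            class = "rsei_scene")
}

# water pixels share the endmember; tiny deterministic jitter would break
# bit-identical reruns, so none is added
.aod_water_jitter <- function(value, n) rep(value, n)

#' @export
print.rsei_scene <- function(x, ...) {
  cat(sprintf("<rsei_scene> %d x %d @ %g m, seed %d\n", x$config$rows,
              x$config$cols, x$config$pixel_size, x$seed))
  cat(sprintf("  vegetated %.1f%%, water %.1f%%\n",
              100 * mean(x$veg_mask), 100 * mean(x$water_mask)))
  cat(sprintf("  truth AOD [%.3f, %.3f], salt [%.2f, %.2f] g/kg, LST [%.2f, %.2f] C\n",
              min(x$truth_aod$values), max(x$truth_aod$values),
              min(x$truth_salinity$values), max(x$truth_salinity$values),
              min(x$truth_lst$values), max(x$truth_lst$values)))
  invisible(x)
}

#' Sample soil pixels from a scene
#'
#' Draws `n` distinct non-water pixels and reports the salinity truth
#' (plus optional measurement noise) together with the ten-band surface
#' reflectance at each pixel -- the synthetic analogue of a synchronous
#' field sampling campaign.
#'
#' @param scene `rsei_scene`.
#' @param n number of sample points.
#' @param seed integer seed for the pixel draw.
#' @param noise_sd Gaussian noise on the measured salt, g/kg.
#' @return `soil_samples` data.frame: `id`, `row`, `col`, `salt_gkg`,
#'   `B2` ... `B12`.
#' @export
sample_soil <- function(scene, n, seed = 1, noise_sd = 0) {
  stopifnot(inherits(scene, "rsei_scene"))
  avail <- which(!scene$water_mask)
  if (n > length(avail))
    stop("requested ", n, " samples but only ", length(avail),
         " non-water pixels exist", call. = FALSE)
  set.seed(as.integer(seed))
  idx <- sample(avail, n)
  rc <- arrayInd(idx, dim(scene$water_mask))
  salt <- scene$truth_salinity$values[idx]
  if (noise_sd > 0) salt <- pmax(0, salt + stats::rnorm(n, sd = noise_sd))
  out <- data.frame(id = seq_len(n), row = rc[, 1], col = rc[, 2],
                    salt_gkg = salt)
  for (b in .s2_bands) out[[b]] <- scene$reflectance[[b]]$values[idx]
  class(out) <- c("soil_samples", "data.frame")
  out
}

#' Top-of-atmosphere reflectance forward model
#'
#' The single-layer uniform-Lambertian forward model
#' `rho_star = rho_a + T * rho / (1 - S * rho)`: apparent reflectance at
#' the sensor given surface reflectance `rho`, path reflectance `rho_a`,
#' total transmissivity `T` and spherical albedo `S`. This is the equation
#' the aerosol retrieval inverts, and the oracle its tests are built on.
#'
#' @param rho surface reflectance in [0, 1].
#' @param rho_a,T,S atmospheric coefficients (vectors recycled).
#' @return apparent (TOA) reflectance.
#' @export
forward_toa <- function(rho, rho_a, T, S) {
  if (any(S * rho >= 1, na.rm = TRUE))
    stop("S * rho must be < 1", call. = FALSE)
  rho_a + T * rho / (1 - S * rho)
}

#' Thermal calibration and atmospheric parameters
#'
#' Parameters of the single-channel land-surface-temperature model:
#' surface emissivity, atmospheric transmissivity, up/down-welling path
#' radiance (W m-2 sr-1 um-1), the two Planck calibration constants of the
#' thermal band, and the DN-to-radiance calibration. Defaults are a typical
#' Landsat-8 TIRS Band 10 calibration with a clear mid-latitude atmosphere;
#' operationally all of them come from scene metadata and an atmospheric
#' profile, so every field is overridable.
#'
#' @param epsilon surface emissivity in (0, 1].
#' @param tau_atm atmospheric transmissivity in (0, 1].
#' @param l_up,l_down path radiances, W m-2 sr-1 um-1.
#' @param k1 Planck constant, W m-2 sr-1 um-1. `k2` in kelvin.
#' @param k2,gain,offset see above; `gain`/`offset` convert stored DN to
#'   radiance (identity by default, i.e. input already radiance).
#' @return object of class `lst_params`.
#' @export
lst_params <- function(epsilon = 0.986, tau_atm = 0.90, l_up = 1.50,
                       l_down = 2.50, k1 = 774.8853, k2 = 1321.0789,
                       gain = 1, offset = 0) {
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must be in (0,1]", call. = FALSE)
  if (tau_atm <= 0 || tau_atm > 1) stop("tau_atm must be in (0,1]", call. = FALSE)
  if (k1 <= 0 || k2 <= 0) stop("K1 and K2 must be positive", call. = FALSE)
  structure(list(epsilon = epsilon, tau_atm = tau_atm, l_up = l_up,
                 l_down = l_down, k1 = k1, k2 = k2, gain = gain,
                 offset = offset), class = "lst_params")
}

#' Planck-band radiance of a blackbody
#'
#' Band-effective Planck radiance `B(T) = K1 / (exp(K2 / T) - 1)` and the
#' sensor-reaching radiance of the full forward model
#' `L = tau * (eps * B(T) + (1 - eps) * L_down) + L_up`, used to synthesize
#' thermal bands that the LST stage inverts exactly.
#'
#' @param t_kelvin temperature in kelvin.
#' @param k1,k2 Planck calibration constants.
#' @return radiance, W m-2 sr-1 um-1.
#' @export
planck_radiance <- function(t_kelvin, k1, k2) k1 / (exp(k2 / t_kelvin) - 1)

#' @rdname planck_radiance
#' @param p [lst_params()].
#' @export
forward_thermal_radiance <- function(t_kelvin, p) {
  b <- planck_radiance(t_kelvin, p$k1, p$k2)
  p$tau_atm * (p$epsilon * b + (1 - p$epsilon) * p$l_down) + p$l_up
}
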