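#' Normalized difference vegetation index
#'
#' `(NIR - Red) / (NIR + Red)` per pixel; nodata where the sum is zero or
#' either input is nodata. The greenness indicator of the RSEI system.
#'
#' @param red,nir co-registered reflectance raster_grids.
#' @return NDVI raster_grid in [-1, 1].
#' @export
ndvi <- function(red, nir) {
  raster_map(function(r, n) {
    s <- n + r
    out <- (n - r) / s
    out[s == 0] <- NA_real_
    out
  }, red, nir)
}

#' Tasseled cap wetness coefficients
#'
#' The wetness (third tasseled cap component) weights applied to the six
#' reflective roles blue, green, red, NIR, SWIR1, SWIR2. The same numeric
#' weights serve Sentinel-2A (bands 2, 3, 4, 8, 11, 12 of surface
#' reflectance) and Landsat (the corresponding roles of apparent
#' reflectance); `sensor` only changes the band naming.
#'
#' @param sensor `"sentinel2a"` (names B2...B12) or `"landsat"`
#'   (blue...swir2).
#' @return named numeric vector of six weights.
#' @export
tc_wetness_coefficients <- function(sensor = c("sentinel2a", "landsat")) {
  sensor <- match.arg(sensor)
  w <- c(0.1509, 0.1973, 0.3279, 0.3406, -0.7112, -0.4572)
  names(w) <- if (sensor == "sentinel2a")
    c("B2", "B3", "B4", "B8", "B11", "B12")
  else c("blue", "green", "red", "nir", "swir1", "swir2")
  w
}

#' Tasseled cap wetness
#'
#' Per-pixel dot product of the six reflective bands with the wetness
#' weights. Tracks soil and vegetation moisture; the wetness indicator.
#'
#' @param stack named list of co-registered raster_grids containing every
#'   band named in `coefficients`.
#' @param coefficients named weights, see [tc_wetness_coefficients()].
#' @return wetness raster_grid.
#' @export
tc_wetness <- function(stack, coefficients = tc_wetness_coefficients()) {
  miss <- setdiff(names(coefficients), names(stack))
  if (length(miss))
    stop("missing band(s): ", paste(miss, collapse = ", "), call. = FALSE)
  layers <- stack[names(coefficients)]
  do.call(raster_map, c(list(function(...) {
    vals <- list(...)
    out <- 0
    for (i in seq_along(vals)) out <- out + coefficients[i] * vals[[i]]
    out
  }), layers))
}

#' Bare soil index
#'
#' Normalized-difference contrast of (SWIR1 + red) against (NIR + blue):
#' `SI = [(B11 + B4) - (B8 + B2)] / [(B11 + B4) + (B8 + B2)]`,
#' rising with surface bareness. The dryness indicator; spatially it is the
#' approximate inverse of wetness.
#'
#' @param stack named list with co-registered `B2`, `B4`, `B8`, `B11`.
#' @return SI raster_grid in [-1, 1]; nodata where the denominator is 0.
#' @export
bare_soil_index <- function(stack) {
  miss <- setdiff(c("B2", "B4", "B8", "B11"), names(stack))
  if (length(miss))
    stop("missing band(s): ", paste(miss, collapse = ", "), call. = FALSE)
  raster_map(function(b2, b4, b8, b11) {
    a <- b11 + b4; b <- b8 + b2
    out <- (a - b) / (a + b)
    out[(a + b) == 0] <- NA_real_
    out
  }, stack$B2, stack$B4, stack$B8, stack$B11)
}

#' Modified normalized difference water index
#'
#' `(Green - SWIR1) / (Green + SWIR1)`; positive over open water. Used to
#' mask water before composing the ecological index, since water pixels are
#' extreme in wetness, dryness and heat and would otherwise dominate the
#' principal component axis.
#'
#' @param green,swir1 co-registered reflectance raster_grids (Sentinel-2
#'   roles B3 and B11).
#' @return MNDWI raster_grid in [-1, 1].
#' @export
mndwi <- function(green, swir1) {
  raster_map(function(g, s) {
    d <- g + s
    out <- (g - s) / d
    out[d == 0] <- NA_real_
    out
  }, green, swir1)
}

#' @rdname mndwi
#' @param threshold water iff `MNDWI > threshold` (nodata never water).
#' @param x MNDWI raster_grid.
#' @return `detect_water` returns a logical matrix mask.
#' @export
detect_water <- function(x, threshold = 0) {
  stopifnot(is_raster_grid(x))
  m <- x$values > threshold
  m[is.na(m)] <- FALSE
  m
}

#' Single-channel land surface temperature
#'
#' Radiative-transfer atmospheric correction of one thermal band followed
#' by Planck inversion: stored DN is calibrated to radiance
#' `L = gain * DN + offset`, the surface-leaving blackbody radiance is
#' `B = (L - L_up - tau * (1 - eps) * L_down) / (tau * eps)`, and
#' temperature is `T = K2 / ln(K1 / B + 1)` converted to degrees C. Pixels
#' with non-positive `B` become nodata.
#'
#' @param thermal raster_grid of DN or radiance.
#' @param p [lst_params()].
#' @return temperature raster_grid in degrees C. The heat indicator.
#' @export
lst <- function(thermal, p) {
  stopifnot(inherits(p, "lst_params"))
  raster_map(function(dn) {
    L <- p$gain * dn + p$offset
    B <- (L - p$l_up - p$tau_atm * (1 - p$epsilon) * p$l_down) /
      (p$tau_atm * p$epsilon)
    B[!is.na(B) & B <= 0] <- NA_real_
    p$k2 / log(p$k1 / B + 1) - 273.15
  }, thermal)
}
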