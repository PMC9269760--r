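#' Dense-dark-vegetation retrieval configuration
#'
#' Tunables of the dark-target aerosol retrieval: the NDVI threshold that
#' declares a pixel densely vegetated, the assumed surface red/blue
#' reflectance ratio `k` of such pixels, the candidate AOD grid scanned
#' during inversion (defaults to the lookup table's tau axis), and the
#' inverse-distance-weighting / smoothing parameters used to extend the
#' sparse dark-pixel retrievals to the full scene.
#'
#' @param ndvi_threshold dark-pixel NDVI threshold (strict `>`), in (-1, 1).
#' @param k_ratio assumed dark-pixel surface red/blue ratio (1.60 for the
#'   HJ1-CCD sensor).
#' @param tau_candidates increasing candidate AOD grid, or `NULL` to use
#'   the LUT tau axis.
#' @param idw_power inverse-distance exponent.
#' @param idw_max_neighbors number of nearest retrieved pixels averaged.
#' @param smooth_kernel odd width of the post-fill mean filter (1 = none).
#' @return object of class `ddv_config`.
#' @export
ddv_config <- function(ndvi_threshold = 0.3, k_ratio = 1.60,
                       tau_candidates = NULL, idw_power = 2,
                       idw_max_neighbors = 12, smooth_kernel = 3) {
  if (ndvi_threshold <= -1 || ndvi_threshold >= 1)
    stop("ndvi_threshold must be in (-1, 1)", call. = FALSE)
  if (k_ratio <= 0) stop("k_ratio must be positive", call. = FALSE)
  if (!is.null(tau_candidates) &&
      (length(tau_candidates) < 1 || is.unsorted(tau_candidates, strictly = TRUE)))
    stop("tau_candidates must be non-empty and strictly increasing",
         call. = FALSE)
  if (smooth_kernel < 1 || smooth_kernel %% 2 != 1)
    stop("smooth_kernel must be an odd positive width", call. = FALSE)
  structure(list(ndvi_threshold = ndvi_threshold, k_ratio = k_ratio,
                 tau_candidates = tau_candidates, idw_power = idw_power,
                 idw_max_neighbors = as.integer(idw_max_neighbors),
                 smooth_kernel = as.integer(smooth_kernel)),
            class = "ddv_config")
}

#' Invert the TOA reflectance equation for surface reflectance
#'
#' Exact inverse of [forward_toa()]:
#' `rho = (rho_star - rho_a) / (T + S * (rho_star - rho_a))`.
#' Pixels where the inversion is undefined (non-finite inputs or a
#' non-positive denominator) come back `NA` rather than erroring, so a bad
#' candidate only invalidates that pixel.
#'
#' @param rho_star apparent (TOA) reflectance.
#' @param rho_a,T,S atmospheric coefficients at the assumed AOD.
#' @return surface reflectance (NA where invalid).
#' @export
invert_surface_reflectance <- function(rho_star, rho_a, T, S) {
  x <- rho_star - rho_a
  den <- T + S * x
  out <- x / den
  out[!is.finite(out) | den <= 0] <- NA_real_
  out
}

#' Detect dark (densely vegetated) pixels
#'
#' @param ndvi NDVI raster_grid (typically computed from TOA reflectance,
#'   since surface reflectance is not yet available before the retrieval).
#' @param threshold strict threshold: dark iff `NDVI > threshold`. Nodata
#'   pixels are never dark.
#' @return logical matrix mask.
#' @export
detect_dark <- function(ndvi, threshold = 0.3) {
  stopifnot(is_raster_grid(ndvi))
  m <- ndvi$values > threshold
  m[is.na(m)] <- FALSE
  m
}

#' Retrieve AOD at dark pixels by lookup-table scanning
#'
#' For every candidate AOD the apparent red and blue reflectances are
#' atmospherically corrected with the interpolated lookup-table
#' coefficients; the candidate whose corrected red/blue ratio is closest to
#' the assumed dark-target ratio `k` wins (ties to the smaller AOD). The
#' achieved |ratio - k| is reported as the retrieval discrepancy.
#'
#' @param rho_star_red,rho_star_blue TOA reflectance raster_grids.
#' @param dark logical mask from [detect_dark()].
#' @param geometry named `c(theta_s, theta_v, phi)` degrees.
#' @param lut `aod_lut` with `red` and `blue` bands.
#' @param cfg [ddv_config()].
#' @return list: `tau` raster (NA off the mask or where unretrievable),
#'   `discrepancy` raster, logical `unretrieved` matrix, and the candidate
#'   grid used.
#' @export
retrieve_aod <- function(rho_star_red, rho_star_blue, dark, geometry, lut,
                         cfg = ddv_config()) {
  stopifnot_same_grid(rho_star_red, rho_star_blue)
  cand <- cfg$tau_candidates
  if (is.null(cand)) cand <- lut$axes$tau
  idx <- which(dark)
  red <- rho_star_red$values[idx]
  blue <- rho_star_blue$values[idx]
  disc <- matrix(Inf, length(idx), length(cand))
  for (j in seq_along(cand)) {
    cr <- lut_interpolate(lut, "red", geometry["theta_s"],
                          geometry["theta_v"], geometry["phi"], cand[j])
    cb <- lut_interpolate(lut, "blue", geometry["theta_s"],
                          geometry["theta_v"], geometry["phi"], cand[j])
    sr <- invert_surface_reflectance(red, cr$rho_a, cr$T, cr$S)
    sb <- invert_surface_reflectance(blue, cb$rho_a, cb$T, cb$S)
    d <- abs(sr / sb - cfg$k_ratio)
    d[!is.finite(d) | sb <= 0] <- Inf
    disc[, j] <- d
  }
  best <- apply(disc, 1, which.min)     # first minimum = smallest tau on ties
  bestd <- disc[cbind(seq_along(best), best)]
  ok <- is.finite(bestd)
  tau_v <- matrix(NA_real_, nrow(dark), ncol(dark))
  dis_v <- matrix(NA_real_, nrow(dark), ncol(dark))
  tau_v[idx[ok]] <- cand[best[ok]]
  dis_v[idx[ok]] <- bestd[ok]
  unret <- matrix(FALSE, nrow(dark), ncol(dark))
  unret[idx[!ok]] <- TRUE
  g <- rho_star_red
  list(tau = raster_grid(tau_v, g$pixel_size, g$origin, g$crs),
       discrepancy = raster_grid(dis_v, g$pixel_size, g$origin, g$crs),
       unretrieved = unret, tau_candidates = cand)
}

#' @rdname retrieve_aod
#' @param rho_star_red_px,rho_star_blue_px scalar TOA reflectances for a
#'   single dark pixel.
#' @return `retrieve_aod_pixel` returns `list(tau, discrepancy)` (both `NA`
#'   if no candidate is valid).
#' @export
retrieve_aod_pixel <- function(rho_star_red_px, rho_star_blue_px, geometry,
                               lut, cfg = ddv_config()) {
  g1 <- raster_grid(matrix(rho_star_red_px, 1, 1))
  g2 <- raster_grid(matrix(rho_star_blue_px, 1, 1))
  r <- retrieve_aod(g1, g2, matrix(TRUE, 1, 1), geometry, lut, cfg)
  list(tau = r$tau$values[1, 1], discrepancy = r$discrepancy$values[1, 1])
}

# k x k mean filter with edge truncation (NA-aware)
mean_filter <- function(m, k) {
  if (k <= 1) return(m)
  h <- (k - 1) / 2
  acc <- matrix(0, nrow(m), ncol(m))
  cnt <- matrix(0, nrow(m), ncol(m))
  val <- m; val[is.na(m)] <- 0
  has <- !is.na(m)
  for (dr in -h:h) for (dc in -h:h) {
    rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
    rd <- max(1, 1 - dr):min(nrow(m), nrow(m) - dr)
    cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
    cd <- max(1, 1 - dc):min(ncol(m), ncol(m) - dc)
    acc[rd, cd] <- acc[rd, cd] + val[rs, cs]
    cnt[rd, cd] <- cnt[rd, cd] + has[rs, cs]
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Fill a sparse AOD retrieval to a full map
#'
#' Non-retrieved pixels receive the inverse-distance-weighted average of
#' the `idw_max_neighbors` nearest retrieved pixels (power
#' `idw_power`); retrieved values are kept as-is. The completed field is
#' then smoothed with a `smooth_kernel` x `smooth_kernel` mean filter.
#' Output depends only on the set of retrieved pixels and their values,
#' never on traversal order.
#'
#' @param sparse_tau raster_grid with AOD at retrieved pixels, NA elsewhere.
#' @param cfg [ddv_config()].
#' @param dark optional logical mask recorded in the result.
#' @return `aod_map`: list with `tau` raster (complete), `dark` mask and
#'   the config used.
#' @export
fill_aod <- function(sparse_tau, cfg = ddv_config(), dark = NULL) {
  stopifnot(is_raster_grid(sparse_tau))
  v <- sparse_tau$values
  ret <- which(!is.na(v))
  if (length(ret) == 0)
    stop("no retrieved AOD pixels to interpolate from", call. = FALSE)
  mis <- which(is.na(v))
  if (length(mis) > 0) {
    rc_r <- arrayInd(ret, dim(v))
    rc_m <- arrayInd(mis, dim(v))
    vals <- v[ret]
    k <- min(cfg$idw_max_neighbors, length(ret))
    p <- cfg$idw_power
    chunk <- 512L
    fill <- numeric(length(mis))
    for (s in seq(1, length(mis), by = chunk)) {
      e <- min(s + chunk - 1L, length(mis))
      d2 <- outer(rc_m[s:e, 1], rc_r[, 1], "-")^2 +
        outer(rc_m[s:e, 2], rc_r[, 2], "-")^2
      for (i in seq_len(e - s + 1L)) {
        nn <- order(d2[i, ])[seq_len(k)]
        w <- 1 / d2[i, nn]^(p / 2)
        fill[s + i - 1L] <- sum(w * vals[nn]) / sum(w)
      }
    }
    v[mis] <- fill
  }
  v <- mean_filter(v, cfg$smooth_kernel)
  structure(list(tau = raster_grid(v, sparse_tau$pixel_size,
                                   sparse_tau$origin, sparse_tau$crs),
                 dark = dark, config = cfg),
            class = "aod_map")
}

#' Kaufman dark-target surface reflectance relations
#'
#' For sensors with a 2.1 um mid-infrared band, dense-vegetation surface
#' reflectance in the red (0.66 um) and blue (0.47 um) follows the
#' empirical half/quarter relations `rho_0.66 = rho_2.1 / 2` and
#' `rho_0.47 = rho_2.1 / 4`, with the 2.1 um apparent reflectance standing
#' in for its surface value (aerosol is nearly transparent there). The
#' default retrieval path does not use these (the target sensor lacks a
#' 2.1 um band) but they are provided for sensors that have one.
#'
#' @param rho_2p1 apparent reflectance at 2.1 um.
#' @return list with `red` and `blue` dark-target surface reflectances.
#' @export
kaufman_dark_reflectance <- function(rho_2p1) {
  list(red = rho_2p1 / 2, blue = rho_2p1 / 4)
}
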