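#' Build an aerosol lookup table from a long-format table
#'
#' The lookup table (LUT) maps viewing geometry and aerosol optical depth
#' (AOD, tau) to the three atmospheric quantities of the single-layer
#' top-of-atmosphere reflectance equation: path reflectance `rho_a`, total
#' two-way transmissivity `T` and spherical albedo `S`, per spectral band.
#' In operational use such tables are produced offline by a radiative
#' transfer code (e.g. 6S); here they are consumed as data.
#'
#' The long format has columns `rho_a, T, S, theta_s, theta_v, phi, tau`
#' and optionally `band` (default `"red"` applied to every row when
#' absent). Every combination of the four axis values present must occur
#' exactly once per band (a complete grid); axes of length one are treated
#' as constant and ignored during interpolation, which lets a printed
#' excerpt tabulated only in tau act as a one-dimensional table.
#'
#' @param df data.frame in the long format above.
#' @return object of class `aod_lut` with `$axes` (sorted unique grids for
#'   theta_s, theta_v, phi, tau) and `$bands`, a list per band of 4-D
#'   arrays `rho_a`, `T`, `S` indexed `[theta_s, theta_v, phi, tau]`.
#' @export
as_aod_lut <- function(df) {
  df <- as.data.frame(df)
  need <- c("rho_a", "T", "S", "theta_s", "theta_v", "phi", "tau")
  if (!all(need %in% names(df)))
    stop("LUT table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(df$band)) df$band <- "red"
  if (any(df$tau < 0)) stop("tau must be >= 0", call. = FALSE)
  if (any(df$S < 0 | df$S >= 1)) stop("S must lie in [0, 1)", call. = FALSE)
  if (any(df$T <= 0 | df$T > 1)) stop("T must lie in (0, 1]", call. = FALSE)
  axes <- lapply(df[c("theta_s", "theta_v", "phi", "tau")],
                 function(x) sort(unique(x)))
  n <- vapply(axes, length, 1L)
  bands <- list()
  for (b in unique(df$band)) {
    sub <- df[df$band == b, ]
    if (nrow(sub) != prod(n))
      stop("LUT grid for band '", b, "' is incomplete: expected ",
           prod(n), " rows, got ", nrow(sub), call. = FALSE)
    idx <- cbind(match(sub$theta_s, axes$theta_s),
                 match(sub$theta_v, axes$theta_v),
                 match(sub$phi, axes$phi),
                 match(sub$tau, axes$tau))
    if (anyDuplicated(idx)) stop("duplicate LUT nodes for band '", b, "'",
                                 call. = FALSE)
    mk <- function(v) { a <- array(NA_real_, n); a[idx] <- v; a }
    bands[[b]] <- list(rho_a = mk(sub$rho_a), T = mk(sub$T), S = mk(sub$S))
  }
  structure(list(axes = axes, bands = bands), class = "aod_lut")
}

#' @rdname as_aod_lut
#' @param path CSV file with a header row in the long format.
#' @export
read_lut <- function(path) as_aod_lut(utils::read.csv(path))

#' @export
print.aod_lut <- function(x, ...) {
  cat(sprintf("<aod_lut> bands: %s\n", paste(names(x$bands), collapse = ", ")))
  for (ax in names(x$axes))
    cat(sprintf("  %s: %d node(s) in [%g, %g]\n", ax, length(x$axes[[ax]]),
                min(x$axes[[ax]]), max(x$axes[[ax]])))
  invisible(x)
}

#' Multilinear interpolation in an aerosol lookup table
#'
#' Interpolates `(rho_a, T, S)` at arbitrary geometry/AOD inside the axis
#' hulls by multilinear (tensor-product) weighting of the up-to-16
#' surrounding grid nodes. Exact at grid nodes. Axes with a single node are
#' constant and impose no constraint on the query.
#'
#' @param lut `aod_lut`.
#' @param band band name present in `lut`.
#' @param theta_s,theta_v,phi,tau query vectors (recycled to a common
#'   length); degrees for the angles, dimensionless AOD for `tau`.
#' @return data.frame with columns `rho_a`, `T`, `S`, one row per query.
#' @export
lut_interpolate <- function(lut, band, theta_s, theta_v, phi, tau) {
  if (!inherits(lut, "aod_lut")) stop("`lut` must be an aod_lut", call. = FALSE)
  if (!band %in% names(lut$bands))
    stop("band '", band, "' not in LUT", call. = FALSE)
  q <- data.frame(theta_s = unname(theta_s), theta_v = unname(theta_v),
                  phi = unname(phi), tau = unname(tau))
  nq <- nrow(q)
  lo <- matrix(1L, nq, 4); w <- matrix(0, nq, 4)
  active <- logical(4)
  for (d in 1:4) {
    ax <- lut$axes[[d]]
    x <- q[[d]]
    if (length(ax) == 1) next
    active[d] <- TRUE
    if (any(x < min(ax) - 1e-9 | x > max(ax) + 1e-9))
      stop("query outside the '", names(lut$axes)[d], "' axis hull",
           call. = FALSE)
    x <- pmin(pmax(x, min(ax)), max(ax))
    i <- findInterval(x, ax, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(ax) - 1L)
    lo[, d] <- i
    w[, d] <- (x - ax[i]) / (ax[i + 1] - ax[i])
  }
  vals <- lut$bands[[band]]
  dims <- vapply(lut$axes, length, 1L)
  out <- matrix(0, nq, 3, dimnames = list(NULL, c("rho_a", "T", "S")))
  nact <- sum(active)
  corners <- if (nact == 0) matrix(0L, 1, 0) else
    as.matrix(expand.grid(rep(list(0:1), nact)))
  actd <- which(active)
  for (k in seq_len(nrow(corners))) {
    off <- integer(4)
    off[actd] <- corners[k, ]
    wk <- rep(1, nq)
    for (d in actd)
      wk <- wk * if (off[d] == 1) w[, d] else 1 - w[, d]
    idx <- cbind(lo[, 1] + off[1], lo[, 2] + off[2],
                 lo[, 3] + off[3], lo[, 4] + off[4])
    out[, "rho_a"] <- out[, "rho_a"] + wk * vals$rho_a[idx]
    out[, "T"] <- out[, "T"] + wk * vals$T[idx]
    out[, "S"] <- out[, "S"] + wk * vals$S[idx]
  }
  as.data.frame(out)
}

#' Generate a complete synthetic lookup table
#'
#' Fills the standard angular grids (solar zenith 0--70 by 5, satellite
#' zenith 0--40 by 5, relative azimuth 0--180 by 12 degrees) and a
#' configurable AOD axis with a smooth analytic surrogate for a radiative
#' transfer run: path reflectance saturates with the aerosol optical path
#' `tau * m` (air-mass factor `m` from the two zenith angles) and carries a
#' weak azimuth modulation, transmissivity decays exponentially, and the
#' spherical albedo grows and saturates with tau. Blue scatters more than
#' red, red more than NIR. The surrogate is not a substitute atmosphere --
#' it exists so the retrieval can be tested against scenes forward-modelled
#' through the *same* table, which is the consistency the method assumes.
#'
#' @param tau AOD axis (strictly increasing, non-negative).
#' @param theta_s,theta_v,phi angular axes in degrees.
#' @param bands subset of `c("red", "blue", "nir")`.
#' @return `aod_lut`.
#' @export
synthetic_lut <- function(tau = c(0.0001, 0.05, 0.1, 0.2, 0.3, 0.4, 0.6, 0.8,
                                  1.0, 1.2, 1.4, 1.7, 2.0),
                          theta_s = seq(0, 70, by = 5),
                          theta_v = seq(0, 40, by = 5),
                          phi = seq(0, 180, by = 12),
                          bands = c("red", "blue", "nir")) {
  if (is.unsorted(tau, strictly = TRUE) || any(tau < 0))
    stop("`tau` must be strictly increasing and non-negative", call. = FALSE)
  par <- list(red  = c(p = 0.18, e = 0.28, s0 = 0.05, s1 = 0.14),
              blue = c(p = 0.28, e = 0.38, s0 = 0.06, s1 = 0.20),
              nir  = c(p = 0.10, e = 0.18, s0 = 0.04, s1 = 0.10))
  bands <- match.arg(bands, names(par), several.ok = TRUE)
  g <- expand.grid(theta_s = theta_s, theta_v = theta_v, phi = phi, tau = tau,
                   KEEP.OUT.ATTRS = FALSE)
  m <- 0.5 * (1 / cos(g$theta_s * pi / 180) + 1 / cos(g$theta_v * pi / 180))
  rows <- lapply(bands, function(b) {
    pb <- par[[b]]
    data.frame(
      rho_a = pb["p"] * (1 - exp(-0.8 * g$tau * m)) *
        (1 + 0.05 * cos(g$phi * pi / 180)),
      T = exp(-pb["e"] * g$tau * m),
      S = pb["s0"] + pb["s1"] * (1 - exp(-g$tau)),
      theta_s = g$theta_s, theta_v = g$theta_v, phi = g$phi, tau = g$tau,
      band = b, row.names = NULL)
  })
  as_aod_lut(do.call(rbind, rows))
}

#' Collapse a LUT excerpt to a one-dimensional tau table
#'
#' Printed LUT excerpts often tabulate several geometries per tau. For
#' fixed-geometry experiments this helper keeps the first row of each tau
#' and returns an `aod_lut` whose angular axes are single nodes, usable by
#' [lut_interpolate()] and the retrieval at any nominal geometry.
#'
#' @param df long-format LUT table (see [as_aod_lut()]).
#' @param bands band names the collapsed coefficients are replicated to.
#' @return `aod_lut` with singleton angular axes.
#' @export
collapse_lut_tau <- function(df, bands = c("red", "blue")) {
  df <- as.data.frame(df)
  first <- df[!duplicated(df$tau), , drop = FALSE]
  first <- first[order(first$tau), ]
  rows <- lapply(bands, function(b)
    data.frame(rho_a = first$rho_a, T = first$T, S = first$S,
               theta_s = 0, theta_v = 0, phi = 0, tau = first$tau, band = b))
  as_aod_lut(do.call(rbind, rows))
}

#' Reference aerosol lookup-table excerpt
#'
#' The published excerpt of the HJ1-CCD aerosol lookup table distributed
#' with the package (16 rows spanning four AOD levels), as printed in the
#' original coastal-reserve survey this workflow reimplements.
#'
#' @return data.frame in the long LUT format (no band column).
#' @export
reference_aod_lut <- function() {
  utils::read.csv(system.file("extdata", "reference_aod_lut.csv",
                              package = "rseikit"))
}
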