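# Shared fixtures, built once per test run.

# small noiseless scene for structural checks
small_scene <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_scene(
      scene_config(rows = 48, cols = 48, noise_sd = 0), seed = 11)
    val
  }
})

# independent brute-force multilinear interpolation: nested loops over all
# corner nodes with tensor-product weights
brute_interp <- function(lut, band, theta_s, theta_v, phi, tau) {
  ax <- lut$axes
  q <- c(theta_s = theta_s, theta_v = theta_v, phi = phi, tau = tau)
  pieces <- lapply(1:4, function(d) {
    a <- ax[[d]]
    if (length(a) == 1) return(list(i = 1, w = 1))
    i <- max(1, min(findInterval(q[d], a), length(a) - 1))
    w1 <- (q[d] - a[i]) / (a[i + 1] - a[i])
    list(i = c(i, i + 1), w = c(1 - w1, w1))
  })
  out <- c(rho_a = 0, T = 0, S = 0)
  v <- lut$bands[[band]]
  for (i1 in seq_along(pieces[[1]]$i))
    for (i2 in seq_along(pieces[[2]]$i))
      for (i3 in seq_along(pieces[[3]]$i))
        for (i4 in seq_along(pieces[[4]]$i)) {
          w <- pieces[[1]]$w[i1] * pieces[[2]]$w[i2] *
            pieces[[3]]$w[i3] * pieces[[4]]$w[i4]
          id <- rbind(c(pieces[[1]]$i[i1], pieces[[2]]$i[i2],
                        pieces[[3]]$i[i3], pieces[[4]]$i[i4]))
          out <- out + w * c(v$rho_a[id], v$T[id], v$S[id])
        }
  out
}

# synthetic soil samples drawn from a known linear model
linear_soil_samples <- function(n = 30, coefs = c(B2 = 23.25, B6 = -119.43,
                                                  B7 = 375.46, B8 = -123.36,
                                                  B8A = -237.96),
                                intercept = 31.20, noise_sd = 0, seed = 5) {
  set.seed(seed)
  X <- as.data.frame(matrix(runif(n * length(coefs), 0.02, 0.4), n,
                            dimnames = list(NULL, names(coefs))))
  X$salt_gkg <- as.vector(as.matrix(X[names(coefs)]) %*% coefs) + intercept +
    rnorm(n, sd = noise_sd)
  X$id <- seq_len(n)
  X
}

const_raster <- function(value, n = 8, pixel_size = 10) {
  raster_grid(matrix(value, n, n), pixel_size)
}
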