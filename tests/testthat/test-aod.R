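test_that("surface reflectance inversion handles identity and path-only cases", {
  expect_equal(invert_surface_reflectance(0.21, 0.21, 0.7, 0.1), 0)
  expect_equal(invert_surface_reflectance(0.37, 0, 1, 0), 0.37)
  expect_true(is.na(invert_surface_reflectance(0.1, 0.5, 0.2, 0.6)))  # den < 0
})

test_that("LUT interpolation is exact at every tabulated node", {
  # the excerpt is not a complete 4-D grid, so use the per-tau collapsed form
  lut1 <- collapse_lut_tau(reference_aod_lut())
  ref <- reference_aod_lut()
  first <- ref[!duplicated(ref$tau), ]
  for (i in seq_len(nrow(first))) {
    got <- lut_interpolate(lut1, "red", 0, 0, 0, first$tau[i])
    expect_equal(got$rho_a, first$rho_a[i])
    expect_equal(got$T, first$T[i])
    expect_equal(got$S, first$S[i])
  }
  expect_equal(unlist(lut_interpolate(lut1, "red", 0, 0, 0, 0.0001),
                      use.names = FALSE),
               c(0.13766, 0.83489, 0.06554))
})

test_that("LUT interpolation is linear between nodes and matches a brute-force oracle", {
  lut <- synthetic_lut(tau = c(0.1, 0.5, 1.0),
                       theta_s = c(0, 30, 60), theta_v = c(0, 20, 40),
                       phi = c(0, 90, 180))
  # midpoint in phi only -> arithmetic mean of the two nodes
  a <- lut_interpolate(lut, "red", 30, 20, 0, 0.5)
  b <- lut_interpolate(lut, "red", 30, 20, 90, 0.5)
  m <- lut_interpolate(lut, "red", 30, 20, 45, 0.5)
  expect_equal(m$rho_a, (a$rho_a + b$rho_a) / 2, tolerance = 1e-12)
  expect_equal(m$S, (a$S + b$S) / 2, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:200) {
    q <- c(runif(1, 0, 60), runif(1, 0, 40), runif(1, 0, 180),
           runif(1, 0.1, 1.0))
    got <- lut_interpolate(lut, "blue", q[1], q[2], q[3], q[4])
    want <- brute_interp(lut, "blue", q[1], q[2], q[3], q[4])
    expect_equal(unlist(got, use.names = FALSE), unname(want),
                 tolerance = 1e-12)
  }
  expect_error(lut_interpolate(lut, "red", 75, 0, 0, 0.5), "hull")
})

test_that("dark-pixel detection uses a strict NDVI threshold and ignores nodata", {
  m <- raster_grid(matrix(c(0.31, 0.30, -0.2, NA), 2, 2), 10)
  mask <- detect_dark(m, 0.3)
  expect_identical(mask, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  water <- raster_grid(matrix(runif(16, -0.9, -0.1), 4, 4), 10)
  expect_equal(sum(detect_dark(water, 0.3)), 0)
})

test_that("single-pixel retrieval recovers the forward-modelled AOD", {
  lut <- collapse_lut_tau(reference_aod_lut())
  cfg <- ddv_config(tau_candidates = lut$axes$tau)
  geom <- c(theta_s = 0, theta_v = 0, phi = 0)
  co <- lut_interpolate(lut, "red", 0, 0, 0, 0.25)
  blue_s <- 0.025
  red_s <- cfg$k_ratio * blue_s
  r <- retrieve_aod_pixel(forward_toa(red_s, co$rho_a, co$T, co$S),
                          forward_toa(blue_s, co$rho_a, co$T, co$S),
                          geom, lut, cfg)
  expect_equal(r$tau, 0.25)
  expect_equal(r$discrepancy, 0, tolerance = 1e-10)
})

test_that("retrieval argmin equals an exhaustive candidate scan", {
  lut <- synthetic_lut(tau = seq(0.1, 1.5, by = 0.2))
  cfg <- ddv_config()
  geom <- c(theta_s = 24, theta_v = 30, phi = 96)
  set.seed(17)
  for (i in 1:100) {
    red_star <- runif(1, 0.05, 0.4)
    blue_star <- runif(1, 0.05, 0.4)
    got <- retrieve_aod_pixel(red_star, blue_star, geom, lut, cfg)
    disc <- vapply(lut$axes$tau, function(tv) {
      cr <- lut_interpolate(lut, "red", geom[1], geom[2], geom[3], tv)
      cb <- lut_interpolate(lut, "blue", geom[1], geom[2], geom[3], tv)
      sr <- invert_surface_reflectance(red_star, cr$rho_a, cr$T, cr$S)
      sb <- invert_surface_reflectance(blue_star, cb$rho_a, cb$T, cb$S)
      d <- abs(sr / sb - cfg$k_ratio)
      if (!is.finite(d) || is.na(sb) || sb <= 0) Inf else d
    }, numeric(1))
    if (all(!is.finite(disc))) {
      expect_true(is.na(got$tau))
    } else {
      expect_equal(got$tau, lut$axes$tau[which.min(disc)])
      expect_equal(got$discrepancy, min(disc), tolerance = 1e-12)
    }
  }
})

test_that("scene-wide retrieval recovers on-grid truth exactly at dark pixels", {
  lut <- synthetic_lut()
  sc <- make_scene(scene_config(rows = 48, cols = 48, noise_sd = 0),
                   seed = 3, lut = lut, tau_snap = lut$axes$tau)
  dark <- detect_dark(ndvi(sc$reflectance$red, sc$reflectance$nir), 0.3)
  expect_gt(sum(dark), 100)
  ret <- retrieve_aod(sc$reflectance$red, sc$reflectance$blue, dark,
                      sc$geometry, lut)
  expect_equal(ret$tau$values[dark], sc$truth_aod$values[dark])
  expect_false(any(ret$unretrieved))
})

test_that("off-grid truth is recovered to within the candidate spacing", {
  lut <- synthetic_lut()
  sc <- make_scene(scene_config(rows = 32, cols = 32, noise_sd = 0,
                                aod_field = c(0.9, 0.35)), seed = 8,
                   lut = lut)
  dark <- detect_dark(ndvi(sc$reflectance$red, sc$reflectance$nir), 0.3)
  ret <- retrieve_aod(sc$reflectance$red, sc$reflectance$blue, dark,
                      sc$geometry, lut)
  spacing <- max(diff(lut$axes$tau))
  err <- abs(ret$tau$values[dark] - sc$truth_aod$values[dark])
  expect_lte(max(err), spacing / 2 + 1e-9)
})

test_that("AOD fill preserves constant fields and stays within retrieved bounds", {
  v <- matrix(NA_real_, 16, 16)
  v[seq(1, 256, by = 7)] <- 0.8
  filled <- fill_aod(raster_grid(v, 10))
  expect_true(all(abs(filled$tau$values - 0.8) < 1e-12))

  single <- matrix(NA_real_, 12, 12); single[5, 7] <- 0.5
  expect_true(all(abs(fill_aod(raster_grid(single, 10))$tau$values - 0.5) < 1e-12))

  set.seed(6)
  r <- matrix(NA_real_, 20, 20)
  keep <- sample(400, 60)
  r[keep] <- runif(60, 0.3, 1.2)
  out <- fill_aod(raster_grid(r, 10))$tau$values
  expect_gte(min(out), min(r, na.rm = TRUE) - 1e-12)
  expect_lte(max(out), max(r, na.rm = TRUE) + 1e-12)
})

test_that("AOD fill without any retrieval errors", {
  expect_error(fill_aod(raster_grid(matrix(NA_real_, 8, 8), 10)),
               "no retrieved")
})

test_that("fill is deterministic given the sparse field", {
  set.seed(2)
  r <- matrix(NA_real_, 15, 15)
  r[sample(225, 40)] <- runif(40, 0.4, 1.0)
  g <- raster_grid(r, 10)
  expect_identical(fill_aod(g)$tau$values, fill_aod(g)$tau$values)
})

test_that("dark-target reflectance relations halve and quarter the 2.1um band", {
  k <- kaufman_dark_reflectance(0.2)
  expect_equal(k$red, 0.1)
  expect_equal(k$blue, 0.05)
})
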