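test_that("band diagnostics follow the definition and a brute-force oracle", {
  # direct arithmetic: sigma 0.5 and r 0.4 give a diagnosis index of 20
  s <- data.frame(salt_gkg = c(1, 2, 3))
  expect_equal(100 * 0.5 * 0.4, 20)

  # reflectance equal to the salt values correlates perfectly
  s$B2 <- s$salt_gkg
  d <- band_diagnostics(s, "B2")
  expect_equal(d$r, 1)

  set.seed(12)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    df <- data.frame(salt_gkg = runif(n, 0, 10), B2 = runif(n), B6 = runif(n))
    got <- band_diagnostics(df, c("B2", "B6"))
    for (b in c("B2", "B6")) {
      x <- df[[b]]
      sigma <- sqrt(mean((x - mean(x))^2))
      r <- sum((x - mean(x)) * (df$salt_gkg - mean(df$salt_gkg))) /
        (n * sigma * sqrt(mean((df$salt_gkg - mean(df$salt_gkg))^2)))
      expect_equal(got$di[got$band == b], 100 * sigma * r, tolerance = 1e-12)
    }
  }
})

test_that("constant bands are flagged with undefined correlation", {
  df <- data.frame(salt_gkg = 1:5, B2 = rep(0.2, 5), B3 = runif(5))
  d <- band_diagnostics(df)
  expect_true(d$flagged[d$band == "B2"])
  expect_true(is.na(d$di[d$band == "B2"]))
  expect_false(d$flagged[d$band == "B3"])
})

test_that("band selection ranks by |Di| and is invariant to input order", {
  d <- data.frame(band = c("B2", "B3", "B6", "B7", "B8", "B8A"),
                  di = c(0.20, 0.06, 0.20, 0.18, 0.19, -0.17),
                  flagged = FALSE)
  expect_equal(select_bands(d, 5), c("B2", "B6", "B8", "B7", "B8A"))
  expect_equal(sort(select_bands(d, 6)), sort(d$band))
  perm <- d[c(4, 1, 6, 2, 5, 3), ]
  expect_setequal(select_bands(perm, 5), select_bands(d, 5))
  expect_error(select_bands(d, 7), "exceeds")
})

test_that("OLS recovers generating coefficients from noiseless samples", {
  s <- linear_soil_samples(n = 40, noise_sd = 0)
  fit <- fit_linear(s, c("B2", "B6", "B7", "B8", "B8A"))
  expect_equal(unname(fit$coefficients),
               c(23.25, -119.43, 375.46, -123.36, -237.96),
               tolerance = 1e-8)
  expect_equal(fit$intercept, 31.20, tolerance = 1e-8)
})

test_that("OLS residuals are orthogonal to every regressor", {
  s <- linear_soil_samples(n = 25, noise_sd = 2, seed = 8)
  bands <- c("B2", "B6", "B7")
  fit <- fit_linear(s, bands)
  res <- s$salt_gkg - predict(fit, s)
  expect_lt(abs(sum(res)), 1e-8)
  for (b in bands) expect_lt(abs(sum(res * s[[b]])), 1e-8)
})

test_that("constant response yields zero slopes and the constant intercept", {
  set.seed(3)
  s <- data.frame(salt_gkg = rep(4.2, 12), B2 = runif(12), B6 = runif(12))
  fit <- fit_linear(s, c("B2", "B6"))
  expect_equal(unname(fit$coefficients), c(0, 0), tolerance = 1e-10)
  expect_equal(fit$intercept, 4.2, tolerance = 1e-10)
})

test_that("rank-deficient designs are refused", {
  set.seed(4)
  s <- data.frame(salt_gkg = runif(10), B2 = runif(10))
  s$B6 <- 2 * s$B2
  expect_error(fit_linear(s, c("B2", "B6")), "rank deficient")
  expect_error(fit_linear(s[1:2, ], c("B2", "B6")), "more samples")
})

test_that("the published regression evaluates as printed", {
  m <- salinity_model_published()
  zero <- data.frame(B2 = 0, B6 = 0, B7 = 0, B8 = 0, B8A = 0)
  expect_equal(predict(m, zero), 31.20)
  b7 <- zero; b7$B7 <- 0.01
  expect_equal(predict(m, b7), 31.20 + 3.7546)
  expect_error(predict(m, zero[c("B2", "B6")]), "missing band")
})

test_that("linear prediction on rasters equals the per-sample arithmetic", {
  sc <- small_scene()
  m <- salinity_model_published()
  r <- predict(m, sc$reflectance)
  s <- sample_soil(sc, 12, seed = 5)
  at <- r$values[cbind(s$row, s$col)]
  expect_equal(at, unname(predict(m, s)), tolerance = 1e-12)
})

test_that("training prediction satisfies the fitted identity", {
  s <- linear_soil_samples(n = 20, noise_sd = 1, seed = 9)
  bands <- c("B2", "B6", "B7", "B8", "B8A")
  fit <- fit_linear(s, bands)
  X <- cbind(1, as.matrix(s[bands]))
  beta <- c(fit$intercept, fit$coefficients)
  expect_equal(unname(predict(fit, s)), unname(drop(X %*% beta)),
               tolerance = 1e-12)
})

test_that("BP network trains to target on noiseless linear data", {
  s <- linear_soil_samples(n = 30, noise_sd = 0, seed = 2)
  cfg <- bpnn_config(max_hidden = 10, seed = 7)
  fit <- fit_bpnn(s, cfg)
  expect_true(fit$converged)
  expect_lte(fit$training_error, cfg$target_error)
  expect_gte(fit$hidden_nodes, 2)
})

test_that("BP training and prediction are deterministic for a fixed seed", {
  s <- linear_soil_samples(n = 20, noise_sd = 0.5, seed = 3)
  cfg <- bpnn_config(max_hidden = 6, seed = 11)
  a <- fit_bpnn(s, cfg)
  b <- fit_bpnn(s, cfg)
  expect_identical(predict(a, s), predict(b, s))
  expect_identical(a$hidden_nodes, b$hidden_nodes)
})

test_that("BP network beats the linear model on nonlinear synthetic salt", {
  set.seed(21)
  n <- 40
  s <- data.frame(B2 = runif(n, 0.05, 0.35), B6 = runif(n, 0.05, 0.35),
                  B7 = runif(n, 0.05, 0.35), B8 = runif(n, 0.05, 0.35),
                  B8A = runif(n, 0.05, 0.35))
  s$salt_gkg <- 3 + 40 * (s$B7 - 0.2)^2 + 15 * s$B2 * s$B8 + 5 * sin(8 * s$B6)
  lin <- fit_linear(s, names(s)[1:5])
  bp <- fit_bpnn(s, bpnn_config(max_hidden = 20, seed = 5))
  err_lin <- mean(abs(predict(lin, s) - s$salt_gkg))
  err_bp <- mean(abs(predict(bp, s) - s$salt_gkg))
  expect_lt(err_bp, err_lin)
})

test_that("validation arithmetic matches the printed convention", {
  v <- validate_inversion(8.18, 14.70)
  expect_equal(v$error, 6.52)
  expect_equal(v$relative_error, 100 * 6.52 / 14.70, tolerance = 1e-12)
  v2 <- validate_inversion(1.53, 10.96)
  expect_equal(v2$error, 9.43)
  expect_equal(round(v2$relative_error, 2), 86.04)
  same <- validate_inversion(c(2, 3), c(2, 3))
  expect_equal(same$error, c(0, 0))
  expect_equal(same$relative_error, c(0, 0))
  z <- validate_inversion(1, 0)
  expect_true(z$flagged && is.na(z$relative_error))
  expect_error(validate_inversion(1:3, 1:2), "equal length")
})
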