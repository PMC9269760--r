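test_that("percentile normalization clips tails then rescales to [0, 1]", {
  ramp <- raster_grid(matrix(seq(0, 100, length.out = 100), 10), 10)
  out <- percentile_normalize(ramp)$values
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)

  expect_true(all(percentile_normalize(const_raster(3))$values == 0.5))

  set.seed(1)
  v <- matrix(rnorm(400), 20)
  v[1, 1] <- 10 * quantile(v, 0.98)       # extreme outlier
  out2 <- percentile_normalize(raster_grid(v, 10))$values
  expect_equal(out2[1, 1], 1)             # clipped to the upper bound
  expect_true(all(out2 >= 0 & out2 <= 1))
  expect_error(percentile_normalize(raster_grid(matrix(NA_real_, 3, 3), 10)),
               "no valid pixels")
})

test_that("stack construction enforces normalization and propagates nodata", {
  a <- const_raster(0.5); b <- const_raster(0.7)
  expect_error(index_stack(greenness = a, heat = const_raster(2)),
               "normalize")
  bb <- b; bb$values[1, 1] <- NA
  st <- index_stack(greenness = a, wetness = bb)
  expect_false(st$valid[1, 1])
  expect_equal(sum(st$valid), 63)
})

test_that("SPCA satisfies the algebraic identities", {
  set.seed(14)
  n <- 12
  mk <- function() raster_grid(matrix(runif(n * n), n), 10)
  st <- index_stack(greenness = mk(), wetness = mk(), dryness = mk(),
                    heat = mk())
  p <- run_spca(st)
  L <- p$loadings
  expect_equal(t(L) %*% L, diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(p$contribution_rate), 100, tolerance = 1e-9)
  expect_equal(p$cumulative_rate[4], 100, tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_true(all(diff(p$cumulative_rate) >= -1e-12))
  # reconstruction from all components is exact
  X <- vapply(st$layers, function(l) l$values[st$valid], numeric(sum(st$valid)))
  Xc <- sweep(X, 2, p$center)
  expect_equal(Xc %*% L %*% t(L), Xc, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("two perfectly correlated layers put 100% on PC1", {
  set.seed(15)
  base <- matrix(runif(64), 8)
  st <- index_stack(greenness = raster_grid(base, 10),
                    wetness = raster_grid(base, 10))
  p <- run_spca(st)
  expect_equal(p$contribution_rate[1], 100, tolerance = 1e-9)
})

test_that("cumulative contribution of printed component rates totals 89.60", {
  rates <- reference_pca_rates()
  expect_equal(sum(rates$contribution_pct[1:3]), 89.60, tolerance = 1e-12)
})

test_that("RSEI is greenness-oriented, rank-preserving and spans [0, 1]", {
  sc <- small_scene()
  b <- run_rsei_pipeline(sc, layers = c("greenness", "wetness", "dryness",
                                        "heat"))
  v <- b$rsei$values[b$normalized$valid]
  expect_equal(min(v), 0)
  expect_equal(max(v), 1)
  g <- b$normalized$layers$greenness$values[b$normalized$valid]
  expect_gt(cor(v, g), 0)
  # rank invariance of the monotone rescale: recompute raw scores
  X <- vapply(b$normalized$layers, function(l) l$values[b$normalized$valid],
              numeric(sum(b$normalized$valid)))
  w <- b$pca$loadings[, 1]
  if (w["greenness"] < 0) w <- -w
  scores <- as.vector(sweep(X, 2, b$pca$center) %*% w)
  expect_equal(rank(scores), rank(v))
})

test_that("grading partitions [0, 1] with the declared bin closure", {
  vals <- matrix(c(0, 0.19, 0.2, 0.41, 0.61, 0.79, 0.8, 1.0, 0.5), 3)
  g <- grade_rsei(raster_grid(vals, 1000))   # 1 km pixels
  expect_equal(g$table$grade,
               c("Worst", "Worse", "Medium", "Good", "Excellent"))
  cls <- g$class_raster$values
  expect_equal(cls[vals == 0.2], 2)     # left-closed
  expect_equal(cls[vals == 0.8], 5)
  expect_equal(cls[vals == 1.0], 5)     # top bin closed
  expect_equal(cls[vals == 0.61], 4)    # mean RSEI 0.61 grades Good
  expect_equal(sum(g$table$area_km2), g$total_area_km2)
  expect_equal(sum(g$table$ratio_pct), 100)

  all_mid <- grade_rsei(const_raster(0.5))
  expect_equal(all_mid$table$ratio_pct[all_mid$table$grade == "Medium"], 100)
  expect_error(grade_rsei(const_raster(1.2)), "outside")
})

test_that("combined grade rates aggregate printed ratios", {
  tabs <- reference_grade_ratios()
  t2000 <- tabs[tabs$year == 2000, ]
  expect_equal(combined_rate(t2000, c("Good", "Excellent")), 4.05)
  t2014 <- tabs[tabs$year == 2014, ]
  expect_equal(combined_rate(t2014, c("Good", "Excellent")), 49.42)
  expect_equal(combined_rate(t2000, character(0)), 0)
  expect_error(combined_rate(t2000, "Pristine"), "unknown grade")
})

test_that("change detection classifies differences symmetrically", {
  a <- const_raster(0.4, n = 10, pixel_size = 1000)
  same <- change_detect(a, a)
  expect_equal(same$table$ratio_pct[same$table$class == "Unchanged"], 100)

  up <- change_detect(a, const_raster(0.55, n = 10, pixel_size = 1000))
  expect_equal(up$table$ratio_pct[up$table$class == "Better"], 100)
  down <- change_detect(a, const_raster(0.25, n = 10, pixel_size = 1000))
  expect_equal(down$table$ratio_pct[down$table$class == "Worse"], 100)
  # boundary: |delta| equal to the threshold is Unchanged (closed interval)
  edge <- change_detect(a, const_raster(0.5, n = 10, pixel_size = 1000))
  expect_equal(edge$table$ratio_pct[edge$table$class == "Unchanged"], 100)
  expect_equal(sum(up$table$area_km2), 100 * 1)   # conservation
  expect_error(change_detect(a, const_raster(0.4, n = 9)), "shapes differ")
})

test_that("correlation report matches an explicit loop oracle", {
  set.seed(18)
  n <- 10
  mk <- function() raster_grid(matrix(runif(n * n), n), 10)
  st <- index_stack(greenness = mk(), wetness = mk(), dryness = mk())
  rsei <- mk()
  rep_ <- correlation_report(st, rsei)
  expect_equal(diag(rep_$correlation), rep(1, 4), ignore_attr = TRUE)
  for (i in seq_len(4)) {
    others <- setdiff(seq_len(4), i)
    want <- mean(abs(rep_$correlation[i, others]))
    expect_equal(unname(rep_$mean_abs_corr[i]), want, tolerance = 1e-12)
  }
})

test_that("independent noise layers are nearly uncorrelated at n = 1e4", {
  set.seed(19)
  mk <- function() raster_grid(matrix(runif(1e4), 100), 10)
  st <- index_stack(greenness = mk(), wetness = mk())
  rep_ <- correlation_report(st, mk())
  off <- rep_$correlation[upper.tri(rep_$correlation)]
  expect_true(all(abs(off) < 0.05))
})

test_that("summary statistics are masked two-pass moments", {
  set.seed(20)
  v <- matrix(runif(81), 9)
  st <- list(greenness = raster_grid(v, 10))
  rsei <- const_raster(0.3, 9)
  s <- rsei_summary(st, rsei)
  expect_equal(s$mean[s$layer == "greenness"], mean(v))
  expect_equal(s$sd[s$layer == "greenness"], sd(as.vector(v)))
  expect_equal(s$sd[s$layer == "RSEI"], 0)
  # adding nodata pixels to another layer changes nothing about valid stats
  v2 <- v; v2[1, ] <- NA
  st2 <- list(greenness = raster_grid(v, 10), extra = raster_grid(v2, 10))
  s2 <- rsei_summary(st2, rsei)
  expect_equal(s2$mean[s2$layer == "greenness"], mean(v[-1, ]))
})
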