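#' Run the end-to-end RSEI evaluation on a scene
#'
#' Executes the full chain on an [make_scene()] scene (or any object with
#' the same fields): indicator computation (greenness NDVI, tasseled cap
#' wetness, bare-soil dryness, single-channel LST heat, regression
#' salinity, dark-target AOD), percentile normalization, spatial PCA,
#' RSEI composition, five-grade classification and the correlation /
#' summary reports. Negative-sense indicators are deliberately *not*
#' inverted before the PCA: the orientation rule in [compose_rsei()]
#' handles the sign of the composite.
#'
#' The run is fully deterministic: every stage is a pure function of the
#' scene and parameters.
#'
#' @param scene `rsei_scene`.
#' @param layers indicator subset to compose (any of `"greenness"`,
#'   `"wetness"`, `"dryness"`, `"heat"`, `"salinity"`, `"aod"`).
#' @param salinity_model fitted salinity model with a `predict` method
#'   (default: [salinity_model_published()]).
#' @param ddv [ddv_config()] for the AOD stage.
#' @param percentiles length-2 clip percentiles for normalization.
#' @param grade_breaks break vector for [grade_rsei()].
#' @param mask_water mask water pixels (MNDWI > 0 from B3/B11) to nodata
#'   before normalization and PCA. Water is extreme in wetness, dryness and
#'   heat, and with it left in, the leading component degenerates to a
#'   water-versus-land axis; masking is the standard practice for this
#'   composite.
#' @param out_dir optional directory; when given, indicator and RSEI
#'   rasters are written as ESRI ASCII grids and the tables as CSV.
#' @param verbose log each stage via `message()`.
#' @return `rsei_bundle` list: `indices` (raw rasters), `normalized`
#'   ([index_stack()]), `pca`, `rsei`, `grade`, `correlation`, `summary`.
#' @export
run_rsei_pipeline <- function(scene,
                              layers = c("greenness", "wetness", "dryness",
                                         "heat", "salinity", "aod"),
                              salinity_model = salinity_model_published(),
                              ddv = ddv_config(),
                              percentiles = c(2, 98),
                              grade_breaks = seq(0, 1, 0.2),
                              mask_water = TRUE,
                              out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(scene, "rsei_scene"))
  layers <- match.arg(layers, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  refl <- scene$reflectance
  idx <- list()

  if ("greenness" %in% layers) {
    say("greenness: NDVI from B4/B8")
    idx$greenness <- ndvi(refl$B4, refl$B8)
  }
  if ("wetness" %in% layers) {
    say("wetness: tasseled cap")
    idx$wetness <- tc_wetness(refl)
  }
  if ("dryness" %in% layers) {
    say("dryness: bare soil index")
    idx$dryness <- bare_soil_index(refl)
  }
  if ("heat" %in% layers) {
    say("heat: single-channel LST")
    heat <- lst(scene$thermal_radiance, scene$lst_params)
    if (!isTRUE(all.equal(heat$pixel_size, refl$B4$pixel_size)))
      heat <- resample(heat, refl$B4$pixel_size, "nearest")
    idx$heat <- heat
  }
  if ("salinity" %in% layers) {
    say("salinity: model inversion over %d bands",
        length(salinity_model$bands))
    idx$salinity <- stats::predict(salinity_model, refl)
  }
  if ("aod" %in% layers) {
    say("aod: dark-target retrieval (k = %.2f)", ddv$k_ratio)
    toa_ndvi <- ndvi(refl$red, refl$nir)
    dark <- detect_dark(toa_ndvi, ddv$ndvi_threshold)
    ret <- retrieve_aod(refl$red, refl$blue, dark, scene$geometry,
                        scene$lut, ddv)
    idx$aod <- fill_aod(ret$tau, ddv, dark)$tau
  }

  if (mask_water) {
    wm <- detect_water(mndwi(refl$B3, refl$B11))
    say("water mask: %.1f%% of pixels excluded", 100 * mean(wm))
    idx <- lapply(idx, function(r) { r$values[wm] <- NA_real_; r })
  }

  say("normalization: %g/%g percentile clip", percentiles[1], percentiles[2])
  normalized <- index_stack(lapply(idx, percentile_normalize,
                                   lower = percentiles[1],
                                   upper = percentiles[2]))
  say("spatial PCA over %d layers", length(idx))
  pca <- run_spca(normalized)
  rsei <- compose_rsei(normalized, pca)
  grade <- grade_rsei(rsei, breaks = grade_breaks)
  corr <- correlation_report(normalized, rsei)
  summ <- rsei_summary(idx, rsei)

  bundle <- structure(list(indices = idx, normalized = normalized,
                           pca = pca, rsei = rsei, grade = grade,
                           correlation = corr, summary = summ),
                      class = "rsei_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.rsei_bundle <- function(x, ...) {
  v <- x$rsei$values
  cat(sprintf("<rsei_bundle> layers: %s\n",
              paste(names(x$indices), collapse = ", ")))
  cat(sprintf("  mean RSEI %.3f; PC1 contribution %.2f%%\n",
              mean(v, na.rm = TRUE), x$pca$contribution_rate[1]))
  invisible(x)
}

#' Write a pipeline bundle to disk
#'
#' Rasters go out as ESRI ASCII grids, tables as CSV with a fixed column
#' order and 4-decimal floats so diffs stay stable.
#'
#' @param bundle `rsei_bundle`.
#' @param out_dir output directory (created if needed).
#' @return invisibly the vector of files written.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(obj, name) {
    p <- file.path(out_dir, name)
    write_raster(obj, p)
    files <<- c(files, p)
  }
  for (nm in names(bundle$indices)) wr(bundle$indices[[nm]],
                                       paste0("index_", nm, ".asc"))
  wr(bundle$rsei, "rsei.asc")
  wr(bundle$grade$class_raster, "rsei_grade_class.asc")
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, digits = 4)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wt(bundle$grade$table, "grade_table.csv")
  wt(bundle$summary, "summary_table.csv")
  extra <- rbind(bundle$pca$eigenvalues, bundle$pca$contribution_rate,
                 bundle$pca$cumulative_rate)
  rownames(extra) <- c("Eigenvalue", "ContributionPct", "CumulativePct")
  block <- rbind(bundle$pca$loadings, extra)
  pca_tab <- data.frame(index = rownames(block), block, row.names = NULL,
                        check.names = FALSE)
  wt(pca_tab, "pca_table.csv")
  cm <- as.data.frame(bundle$correlation$correlation)
  cm <- cbind(index = rownames(cm), cm,
              mean_abs = bundle$correlation$mean_abs_corr)
  wt(cm, "correlation_table.csv")
  invisible(files)
}

#' Reference grade and change tables
#'
#' Per-grade area/ratio tables for the four evaluation dates of the
#' original reserve survey (2000, 2007, 2014, 2019) and the per-period
#' change-class tables, as printed; shipped so aggregation arithmetic can
#' be reproduced without the satellite scenes.
#'
#' @return `reference_grade_ratios`: data.frame `year`, `grade`,
#'   `area_km2`, `ratio_pct`. `reference_change_areas`: data.frame
#'   `period`, `class`, `area_km2`, `ratio_pct`. `reference_pca_rates`:
#'   data.frame `component`, `contribution_pct` for the six-indicator
#'   evaluation.
#' @export
reference_grade_ratios <- function() {
  utils::read.csv(system.file("extdata", "reference_grade_ratios.csv",
                              package = "rseikit"))
}

#' @rdname reference_grade_ratios
#' @export
reference_change_areas <- function() {
  utils::read.csv(system.file("extdata", "reference_change_areas.csv",
                              package = "rseikit"))
}

#' @rdname reference_grade_ratios
#' @export
reference_pca_rates <- function() {
  utils::read.csv(system.file("extdata", "reference_pca_rates.csv",
                              package = "rseikit"))
}
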