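#!/usr/bin/env Rscript
# Dark-target AOD retrieval on the restored scene: dark-pixel detection at
# NDVI > 0.3, lookup-table inversion with k = 1.60 ratio matching, and
# inverse-distance-weighted fill with 3x3 smoothing. The scene generator's
# truth field gives exact error statistics.

suppressPackageStartupMessages(library(rseikit))
dir.create("results", showWarnings = FALSE)

lut <- synthetic_lut()
sc <- make_scene(scene_config(rows = 128, cols = 128, veg_fraction = 0.65),
                 seed = 2019, lut = lut, tau_snap = lut$axes$tau)

dark <- detect_dark(ndvi(sc$reflectance$red, sc$reflectance$nir), 0.3)
ret <- retrieve_aod(sc$reflectance$red, sc$reflectance$blue, dark,
                    sc$geometry, lut)
aod <- fill_aod(ret$tau, ddv_config(), dark)

err_dark <- ret$tau$values[dark] - sc$truth_aod$values[dark]
fill_err <- aod$tau$values - sc$truth_aod$values

tab <- data.frame(
  quantity = c("dark_pixels", "dark_fraction_pct", "unretrieved",
               "dark_rmse", "dark_exact_pct", "filled_rmse",
               "filled_min", "filled_max"),
  value = c(sum(dark), 100 * mean(dark), sum(ret$unretrieved),
            sqrt(mean(err_dark^2)), 100 * mean(err_dark == 0),
            sqrt(mean(fill_err^2, na.rm = TRUE)),
            min(aod$tau$values), max(aod$tau$values)))
write.csv(tab, "results/02_aod_retrieval.csv", row.names = FALSE)
write_raster(aod$tau, "scratch/scenes/restored_aod_retrieved.asc")

cat("AOD retrieval over", sum(dark), "dark pixels;",
    sprintf("%.0f%% exact on the candidate grid, filled-field RMSE %.3f.\n",
            100 * mean(err_dark == 0), sqrt(mean(fill_err^2, na.rm = TRUE))))
print(tab, digits = 4)
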