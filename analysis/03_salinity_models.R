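#!/usr/bin/env Rscript
# Soil salinity inversion: band screening by the diagnosis index
# Di = 100 * sigma_i * r_i, a five-band multiple linear regression, a
# single-hidden-layer BP network, and hold-out validation in the
# error / relative-error convention of the reference survey.

suppressPackageStartupMessages(library(rseikit))
dir.create("results", showWarnings = FALSE)

samples <- read.csv("results/01_soil_samples.csv")
train <- samples[1:10, ]
holdout <- samples[11:20, ]

diag <- band_diagnostics(train)
write.csv(diag, "results/03_band_diagnostics.csv", row.names = FALSE)
bands <- select_bands(diag, 5)
cat("Diagnosis index selects bands:", paste(bands, collapse = ", "), "\n")

lin <- fit_linear(train, bands)
print(lin)
bp <- fit_bpnn(train, bpnn_config(bands = bands, seed = 3))
cat(sprintf("BP network: %d hidden nodes, training MSE %.2g (converged: %s)\n",
            bp$hidden_nodes, bp$training_error, bp$converged))

val_lin <- validate_inversion(holdout$salt_gkg, predict(lin, holdout))
val_bp <- validate_inversion(holdout$salt_gkg, predict(bp, holdout))
val <- cbind(no = seq_len(nrow(holdout)),
             val_lin[c("measured", "inverted", "error", "relative_error")],
             setNames(val_bp[c("inverted", "error", "relative_error")],
                      c("bp_inverted", "bp_error", "bp_relative_error")))
write.csv(val, "results/03_validation.csv", row.names = FALSE)

cat(sprintf("Hold-out mean |error|: regression %.2f g/kg, BP network %.2f g/kg\n",
            mean(abs(val$error)), mean(abs(val$bp_error))))
print(val, digits = 3)

# reference verification arithmetic reproduced from the shipped table
ref <- reference_validation_table()
chk <- validate_inversion(ref$measured, ref$mlr_inverted)
cat(sprintf("Reference table arithmetic: max |recomputed - printed| relative error %.3f pp\n",
            max(abs(chk$relative_error - ref$mlr_relative_error))))
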