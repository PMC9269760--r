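#' Band diagnostics for salinity inversion
#'
#' Screens spectral bands for sensitivity to soil soluble salt: per band,
#' the dispersion `sigma` (population standard deviation of reflectance
#' across the samples), the Pearson correlation `r` with the measured salt,
#' and the diagnosis index `di = 100 * sigma * r`. Bands whose reflectance
#' is constant across samples have an undefined correlation and are
#' flagged.
#'
#' @param samples `soil_samples` data.frame ([sample_soil()] or any frame
#'   with `salt_gkg` and band columns).
#' @param bands band column names (default: every `B*` column present).
#' @return data.frame `band`, `sigma`, `r`, `di`, `flagged`.
#' @export
band_diagnostics <- function(samples, bands = NULL) {
  if (is.null(bands)) bands <- grep("^B", names(samples), value = TRUE)
  if (nrow(samples) < 3) stop("need at least 3 samples", call. = FALSE)
  n <- nrow(samples)
  out <- lapply(bands, function(b) {
    x <- samples[[b]]
    sigma <- stats::sd(x) * sqrt((n - 1) / n)
    if (sigma == 0) {
      data.frame(band = b, sigma = 0, r = NA_real_, di = NA_real_,
                 flagged = TRUE)
    } else {
      r <- stats::cor(x, samples$salt_gkg)
      data.frame(band = b, sigma = sigma, r = r, di = 100 * sigma * r,
                 flagged = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Select the most diagnostic bands
#'
#' Orders bands by decreasing |diagnosis index| (ties and flagged bands
#' keep their input order, flagged last) and returns the top `top_n`.
#'
#' @param diag output of [band_diagnostics()].
#' @param top_n number of bands to keep.
#' @return character vector of band names.
#' @export
select_bands <- function(diag, top_n) {
  if (top_n > nrow(diag)) stop("top_n exceeds band count", call. = FALSE)
  key <- abs(diag$di)
  key[is.na(key)] <- -Inf
  diag$band[order(-key, seq_len(nrow(diag)))][seq_len(top_n)]
}

#' Fit / evaluate the multiple linear salinity regression
#'
#' Ordinary least squares of soluble salt (g/kg) on the selected band
#' reflectances. `fit_linear` errors on a rank-deficient design;
#' `predict` accepts either a samples data.frame or a named list of
#' co-registered reflectance rasters and then maps salinity per pixel.
#'
#' @param samples `soil_samples` data.frame.
#' @param bands band columns to regress on.
#' @return `linear_salinity_model`: list with `bands`, named
#'   `coefficients` and `intercept`.
#' @export
fit_linear <- function(samples, bands) {
  if (nrow(samples) < length(bands) + 1)
    stop("need more samples than coefficients", call. = FALSE)
  X <- as.matrix(samples[, bands, drop = FALSE])
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), samples$salt_gkg)
  if (fit$rank < length(bands) + 1)
    stop("design matrix is rank deficient", call. = FALSE)
  co <- fit$coefficients
  structure(list(bands = bands, coefficients = co[bands],
                 intercept = unname(co["(Intercept)"])),
            class = "linear_salinity_model")
}

#' @export
print.linear_salinity_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g*%s", x$coefficients, x$bands),
                 collapse = " ")
  cat("<linear_salinity_model> salt_gkg =", sprintf("%.4g", x$intercept),
      terms, "\n")
  invisible(x)
}

#' @rdname fit_linear
#' @param object fitted model.
#' @param newdata data.frame with the model's band columns, or a named
#'   list of raster_grids keyed by band.
#' @param ... unused.
#' @export
predict.linear_salinity_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    miss <- setdiff(object$bands, names(newdata))
    if (length(miss)) stop("missing band(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    X <- as.matrix(newdata[, object$bands, drop = FALSE])
    drop(X %*% object$coefficients + object$intercept)
  } else if (is.list(newdata) && all(vapply(newdata, is_raster_grid, TRUE))) {
    miss <- setdiff(object$bands, names(newdata))
    if (length(miss)) stop("missing band(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    do.call(raster_map, c(list(function(...) {
      vals <- list(...)
      out <- vals[[1]] * 0 + object$intercept
      for (i in seq_along(object$bands))
        out <- out + object$coefficients[i] * vals[[i]]
      out
    }), newdata[object$bands]))
  } else stop("`newdata` must be a data.frame or a named list of rasters",
              call. = FALSE)
}

#' Published five-band salinity regression
#'
#' The reference multiple linear regression for Sentinel-2A surface
#' reflectance fitted on the original ten synchronous soil samples of the
#' coastal-reserve survey:
#' `salt = 23.25 B2 - 119.43 B6 + 375.46 B7 - 123.36 B8 - 237.96 B8A + 31.20`
#' (g/kg). Shipped as a constant so salinity maps can be produced without
#' refitting.
#'
#' @return `linear_salinity_model`.
#' @export
salinity_model_published <- function() {
  structure(list(bands = c("B2", "B6", "B7", "B8", "B8A"),
                 coefficients = c(B2 = 23.25, B6 = -119.43, B7 = 375.46,
                                  B8 = -123.36, B8A = -237.96),
                 intercept = 31.20),
            class = "linear_salinity_model")
}

#' Back-propagation network configuration
#'
#' Single-hidden-layer feed-forward network settings for nonlinear salt
#' inversion: inputs and the output are min-max normalized to [0, 1] before
#' training, the hidden-layer size is found by the stepwise search (start
#' at 2 nodes, grow until the training mean squared error on the normalized
#' output meets `target_error` or `max_hidden` is reached).
#'
#' @param bands input band columns (defaults to the regression's five).
#' @param max_hidden search cap on hidden nodes.
#' @param target_error training MSE goal on the normalized output.
#' @param seed integer; training is deterministic given the seed.
#' @param maxit optimizer iteration cap per candidate size.
#' @return object of class `bpnn_config`.
#' @export
bpnn_config <- function(bands = c("B2", "B6", "B7", "B8", "B8A"),
                        max_hidden = 20, target_error = 0.001, seed = 1,
                        maxit = 2000) {
  if (max_hidden < 2) stop("max_hidden must be >= 2", call. = FALSE)
  if (target_error <= 0) stop("target_error must be positive", call. = FALSE)
  structure(list(bands = bands, max_hidden = as.integer(max_hidden),
                 target_error = target_error, seed = as.integer(seed),
                 maxit = as.integer(maxit)),
            class = "bpnn_config")
}

#' Fit the back-propagation salinity network
#'
#' Trains `nnet::nnet` single-hidden-layer networks of growing size until
#' the normalized training MSE reaches the target. If no size converges the
#' best network found is returned with `converged = FALSE` and a warning.
#'
#' @param samples `soil_samples` data.frame.
#' @param cfg [bpnn_config()].
#' @return `bpnn_salinity_model`: the trained net plus the normalization
#'   ranges, chosen hidden size, final training error and convergence flag.
#' @export
fit_bpnn <- function(samples, cfg = bpnn_config()) {
  if (nrow(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  X <- as.matrix(samples[, cfg$bands, drop = FALSE])
  y <- samples$salt_gkg
  x_min <- apply(X, 2, min); x_rng <- pmax(apply(X, 2, max) - x_min, 1e-12)
  y_min <- min(y); y_rng <- max(max(y) - y_min, 1e-12)
  Xn <- sweep(sweep(X, 2, x_min), 2, x_rng, "/")
  yn <- (y - y_min) / y_rng
  best <- NULL; best_mse <- Inf; best_h <- NA_integer_
  for (h in 2:cfg$max_hidden) {
    set.seed(cfg$seed + h)
    net <- nnet::nnet(Xn, yn, size = h, linout = TRUE, trace = FALSE,
                      maxit = cfg$maxit, decay = 0,
                      MaxNWts = 10000, abstol = 1e-10, reltol = 1e-12)
    mse <- mean((stats::predict(net, Xn) - yn)^2)
    if (mse < best_mse) { best <- net; best_mse <- mse; best_h <- h }
    if (mse <= cfg$target_error) break
  }
  converged <- best_mse <= cfg$target_error
  if (!converged)
    warning("BP network did not reach target error ", cfg$target_error,
            " within ", cfg$max_hidden, " hidden nodes (best MSE ",
            signif(best_mse, 3), ")", call. = FALSE)
  structure(list(net = best, bands = cfg$bands, x_min = x_min,
                 x_rng = x_rng, y_min = y_min, y_rng = y_rng,
                 hidden_nodes = best_h, training_error = best_mse,
                 converged = converged, config = cfg),
            class = "bpnn_salinity_model")
}

#' @rdname fit_bpnn
#' @param object fitted network.
#' @param newdata data.frame with band columns, or named list of rasters.
#' @param ... unused.
#' @export
predict.bpnn_salinity_model <- function(object, newdata, ...) {
  denorm <- function(v) v * object$y_rng + object$y_min
  if (is.data.frame(newdata)) {
    X <- as.matrix(newdata[, object$bands, drop = FALSE])
    Xn <- sweep(sweep(X, 2, object$x_min), 2, object$x_rng, "/")
    denorm(drop(stats::predict(object$net, Xn)))
  } else if (is.list(newdata) && all(vapply(newdata, is_raster_grid, TRUE))) {
    ref <- newdata[[object$bands[1]]]
    X <- vapply(object$bands, function(b) as.vector(newdata[[b]]$values),
                numeric(length(ref$values)))
    Xn <- sweep(sweep(X, 2, object$x_min), 2, object$x_rng, "/")
    pred <- rep(NA_real_, nrow(Xn))
    ok <- stats::complete.cases(Xn)
    if (any(ok)) pred[ok] <- denorm(drop(stats::predict(object$net,
                                                        Xn[ok, , drop = FALSE])))
    raster_grid(matrix(pred, nrow(ref$values), ncol(ref$values)),
                ref$pixel_size, ref$origin, ref$crs)
  } else stop("`newdata` must be a data.frame or a named list of rasters",
              call. = FALSE)
}

#' Validation arithmetic for salinity inversion
#'
#' Pairs measured and inverted salt contents:
#' `error = inverted - measured` (g/kg) and
#' `relative_error = 100 * error / inverted` (%) -- the denominator is the
#' *inverted* value, the convention under which the reference validation
#' table is internally consistent. Rows with `inverted == 0` get an `NA`
#' relative error and are flagged.
#'
#' @param measured,inverted equal-length numeric vectors, g/kg.
#' @return data.frame `measured`, `inverted`, `error`, `relative_error`,
#'   `flagged`.
#' @export
validate_inversion <- function(measured, inverted) {
  if (length(measured) != length(inverted))
    stop("measured and inverted must have equal length", call. = FALSE)
  err <- inverted - measured
  rel <- ifelse(inverted == 0, NA_real_, 100 * err / inverted)
  data.frame(measured = measured, inverted = inverted, error = err,
             relative_error = rel, flagged = inverted == 0)
}

#' Reference salinity validation table
#'
#' The printed verification table of the original survey: measured soluble
#' salt at ten hold-out points with the regression and network inversions
#' and their (relative) errors.
#'
#' @return data.frame with columns `no`, `measured`, `mlr_inverted`,
#'   `mlr_error`, `mlr_relative_error`, `bp_inverted`, `bp_error`,
#'   `bp_relative_error`.
#' @export
reference_validation_table <- function() {
  utils::read.csv(system.file("extdata", "reference_salinity_validation.csv",
                              package = "rseikit"))
}
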