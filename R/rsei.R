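#' Percentile-clip min-max normalization
#'
#' Robust [0, 1] scaling used before composing indicators: values are
#' clipped to the `lower`/`upper` percentiles of the valid-pixel histogram
#' (2% tails by default, absorbing sensor noise outliers) and min-max
#' scaled. A constant raster maps to 0.5 everywhere (declared degenerate
#' rule).
#'
#' @param raster raster_grid with at least one valid pixel.
#' @param lower,upper clip percentiles in [0, 100].
#' @return raster_grid in [0, 1], nodata preserved.
#' @export
percentile_normalize <- function(raster, lower = 2, upper = 98) {
  stopifnot(is_raster_grid(raster))
  v <- raster$values
  ok <- !is.na(v)
  if (!any(ok)) stop("raster has no valid pixels", call. = FALSE)
  q <- stats::quantile(v[ok], c(lower, upper) / 100, names = FALSE)
  out <- v
  if (q[2] == q[1]) {
    out[ok] <- 0.5
  } else {
    out[ok] <- (pmin(pmax(v[ok], q[1]), q[2]) - q[1]) / (q[2] - q[1])
  }
  raster_grid(out, raster$pixel_size, raster$origin, raster$crs)
}

#' Bundle normalized indicator layers
#'
#' Collects co-registered indicator rasters into a named stack with the
#' union nodata mask (a pixel is valid only where every layer is). Layers
#' are expected in [0, 1] (see [percentile_normalize()]).
#'
#' @param ... named raster_grid layers, or a single named list.
#' @return object of class `index_stack`.
#' @export
index_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !is_raster_grid(layers[[1]]))
    layers <- layers[[1]]
  rng <- range(unlist(lapply(layers, function(l) range(l$values, na.rm = TRUE))))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("stack layers must lie in [0, 1]; normalize first", call. = FALSE)
  .raw_stack(layers)
}

# stack assembly without the [0, 1] requirement (raw summaries)
.raw_stack <- function(layers) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named", call. = FALSE)
  do.call(stopifnot_same_grid, unname(layers))
  valid <- Reduce(`&`, lapply(layers, function(l) !is.na(l$values)))
  structure(list(layers = layers, valid = valid), class = "index_stack")
}

#' @export
print.index_stack <- function(x, ...) {
  cat(sprintf("<index_stack> %s; %d/%d valid pixels\n",
              paste(names(x$layers), collapse = ", "), sum(x$valid),
              length(x$valid)))
  invisible(x)
}

stack_matrix <- function(stack) {
  vapply(stack$layers, function(l) l$values[stack$valid],
         numeric(sum(stack$valid)))
}

#' Spatial principal component analysis of an indicator stack
#'
#' Treats every valid pixel as an observation of the layer vector and
#' eigendecomposes the covariance matrix (covariance, not correlation: the
#' layers are already on a common [0, 1] scale and their variances carry
#' information). Eigenvalues are reported in descending order with each
#' component's contribution rate `100 * lambda_i / sum(lambda)` and the
#' cumulative rate; loadings columns are orthonormal with the sign fixed so
#' the first non-zero loading of each component is positive.
#'
#' @param stack [index_stack()] with >= 2 layers.
#' @return `spca_result`: `loadings` (layers x components), `eigenvalues`,
#'   `contribution_rate`, `cumulative_rate`, `center` (layer means).
#' @export
run_spca <- function(stack) {
  stopifnot(inherits(stack, "index_stack"))
  if (length(stack$layers) < 2) stop("need at least two layers", call. = FALSE)
  X <- stack_matrix(stack)
  if (nrow(X) < ncol(X)) stop("fewer valid pixels than layers", call. = FALSE)
  S <- stats::cov(X)
  eg <- eigen(S, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)           # clip numerically negative zeros
  L <- eg$vectors
  for (j in seq_len(ncol(L))) {
    nz <- which(abs(L[, j]) > 1e-12)[1]
    if (!is.na(nz) && L[nz, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(names(stack$layers),
                      paste0("PC", seq_len(ncol(L))))
  contrib <- 100 * lambda / sum(lambda)
  structure(list(loadings = L, eigenvalues = lambda,
                 contribution_rate = contrib,
                 cumulative_rate = cumsum(contrib),
                 center = colMeans(X)),
            class = "spca_result")
}

#' @export
print.spca_result <- function(x, ...) {
  cat("<spca_result>\n")
  print(round(rbind(x$loadings,
                    Eigenvalue = x$eigenvalues,
                    `Contribution %` = x$contribution_rate,
                    `Cumulative %` = x$cumulative_rate), 4))
  invisible(x)
}

#' Compose the RSEI from the first principal component
#'
#' Projects the stack onto PC1, orients the axis so that greenness loads
#' positively (a higher score then means a better eco-environment), and
#' min-max rescales the scores to [0, 1]. Rescaling is monotone, so pixel
#' ranking is exactly the PC1 ranking.
#'
#' @param stack the [index_stack()] the PCA was run on.
#' @param pca [run_spca()] result for that stack.
#' @param green_layer name of the greenness layer used for orientation.
#' @return RSEI raster_grid in [0, 1].
#' @export
compose_rsei <- function(stack, pca, green_layer = "greenness") {
  stopifnot(inherits(stack, "index_stack"), inherits(pca, "spca_result"))
  if (!green_layer %in% rownames(pca$loadings))
    stop("no '", green_layer, "' layer to orient by", call. = FALSE)
  X <- stack_matrix(stack)
  w <- pca$loadings[, 1]
  if (w[green_layer] < 0) w <- -w
  scores <- as.vector(sweep(X, 2, pca$center) %*% w)
  rng <- range(scores)
  scaled <- if (rng[2] > rng[1]) (scores - rng[1]) / (rng[2] - rng[1])
  else rep(0.5, length(scores))
  ref <- stack$layers[[1]]
  out <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  out[stack$valid] <- scaled
  raster_grid(out, ref$pixel_size, ref$origin, ref$crs)
}

.grade_labels <- c("Worst", "Worse", "Medium", "Good", "Excellent")

#' Grade an RSEI raster into five ecological classes
#'
#' Partitions [0, 1] at 0.2 intervals into Worst, Worse, Medium, Good,
#' Excellent (bins left-closed right-open, top bin closed at 1) and
#' reports per-class area and ratio.
#'
#' @param rsei RSEI raster_grid in [0, 1].
#' @param pixel_area_km2 area of one pixel; default derived from the pixel
#'   size.
#' @param breaks increasing break vector spanning [0, 1].
#' @return list: `table` (grade, area_km2, ratio_pct), `class_raster`
#'   (integer class codes 1..5), `total_area_km2`.
#' @export
grade_rsei <- function(rsei, pixel_area_km2 = NULL, breaks = seq(0, 1, 0.2)) {
  stopifnot(is_raster_grid(rsei))
  v <- rsei$values
  ok <- !is.na(v)
  if (any(v[ok] < breaks[1] | v[ok] > breaks[length(breaks)]))
    stop("RSEI values outside [", breaks[1], ", ", breaks[length(breaks)],
         "]", call. = FALSE)
  if (is.null(pixel_area_km2))
    pixel_area_km2 <- (rsei$pixel_size / 1000)^2
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  cls[ok] <- findInterval(v[ok], breaks, rightmost.closed = TRUE)
  labels <- if (length(breaks) == 6) .grade_labels
  else paste0("G", seq_len(length(breaks) - 1))
  counts <- tabulate(cls[ok], nbins = length(breaks) - 1)
  area <- counts * pixel_area_km2
  tab <- data.frame(grade = labels, area_km2 = area,
                    ratio_pct = 100 * counts / sum(counts))
  list(table = tab,
       class_raster = raster_grid(cls + 0, rsei$pixel_size, rsei$origin,
                                  rsei$crs),
       total_area_km2 = sum(area))
}

#' Combined ratio of selected grades
#'
#' Sums the `ratio_pct` entries of the requested grades (e.g. the
#' "excellent and good rate"). Accepts any data.frame with `grade` and
#' `ratio_pct` columns, so printed grade tables can be aggregated directly.
#'
#' @param table grade table ([grade_rsei()]'s `$table` or equivalent).
#' @param grades character subset of the table's grades.
#' @return numeric percentage.
#' @export
combined_rate <- function(table, grades) {
  unknown <- setdiff(grades, table$grade)
  if (length(unknown))
    stop("unknown grade(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  sum(table$ratio_pct[table$grade %in% grades])
}

#' Change detection between two RSEI dates
#'
#' Image differencing `delta = rsei_b - rsei_a` classified with a
#' symmetric threshold: Better where `delta > threshold`, Worse where
#' `delta < -threshold`, Unchanged on the closed interval between.
#'
#' @param rsei_a,rsei_b co-registered RSEI rasters (earlier, later).
#' @param threshold class half-width (default 0.1).
#' @param pixel_area_km2 area of one pixel; default from pixel size.
#' @return list: `table` (class, area_km2, ratio_pct), `class_raster`
#'   (-1 Worse, 0 Unchanged, 1 Better), `delta` raster, `threshold`.
#' @export
change_detect <- function(rsei_a, rsei_b, threshold = 0.1,
                          pixel_area_km2 = NULL) {
  stopifnot_same_grid(rsei_a, rsei_b)
  if (is.null(pixel_area_km2))
    pixel_area_km2 <- (rsei_a$pixel_size / 1000)^2
  d <- rsei_b$values - rsei_a$values
  cls <- matrix(NA_real_, nrow(d), ncol(d))
  ok <- !is.na(d)
  cls[ok] <- ifelse(d[ok] > threshold, 1, ifelse(d[ok] < -threshold, -1, 0))
  counts <- c(Worse = sum(cls[ok] == -1), Unchanged = sum(cls[ok] == 0),
              Better = sum(cls[ok] == 1))
  area <- counts * pixel_area_km2
  tab <- data.frame(class = names(counts), area_km2 = as.numeric(area),
                    ratio_pct = 100 * as.numeric(counts) / sum(counts))
  list(table = tab,
       class_raster = raster_grid(cls, rsei_a$pixel_size, rsei_a$origin,
                                  rsei_a$crs),
       delta = raster_grid(d, rsei_a$pixel_size, rsei_a$origin, rsei_a$crs),
       threshold = threshold)
}

#' Correlation report for indicators and RSEI
#'
#' Pearson correlations over the common valid pixels between every
#' indicator layer and the RSEI, plus each variable's mean absolute
#' correlation with the other variables (self excluded) -- the measure of
#' how well the composite integrates the individual indicators. Constant
#' layers have undefined correlations and are flagged.
#'
#' @param stack [index_stack()].
#' @param rsei RSEI raster on the same grid.
#' @return list: `correlation` matrix, `mean_abs_corr` named vector,
#'   `flagged` names of constant layers.
#' @export
correlation_report <- function(stack, rsei) {
  stopifnot(inherits(stack, "index_stack"), is_raster_grid(rsei))
  stopifnot_same_grid(stack$layers[[1]], rsei)
  X <- cbind(stack_matrix(stack), RSEI = rsei$values[stack$valid])
  sds <- apply(X, 2, stats::sd)
  flagged <- colnames(X)[sds == 0]
  cm <- suppressWarnings(stats::cor(X))
  mean_abs <- vapply(seq_len(ncol(cm)), function(i)
    mean(abs(cm[i, -i])), numeric(1))
  names(mean_abs) <- colnames(cm)
  list(correlation = cm, mean_abs_corr = mean_abs, flagged = flagged)
}

#' Mean and standard deviation per layer and for RSEI
#'
#' Masked statistics over the stack's valid pixels, mirroring the summary
#' table that accompanies an RSEI evaluation.
#'
#' @param stack [index_stack()] (layers need not be normalized here).
#' @param rsei RSEI raster on the same grid.
#' @return data.frame `layer`, `mean`, `sd`.
#' @export
rsei_summary <- function(stack, rsei) {
  if (!inherits(stack, "index_stack")) stack <- .raw_stack(stack)
  stopifnot(is_raster_grid(rsei))
  X <- cbind(stack_matrix(stack), RSEI = rsei$values[stack$valid])
  data.frame(layer = colnames(X),
             mean = colMeans(X),
             sd = apply(X, 2, stats::sd),
             row.names = NULL)
}
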