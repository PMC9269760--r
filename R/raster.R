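#' Create a raster grid
#'
#' `raster_grid` is the raster currency used throughout the package: a plain
#' numeric matrix with square pixels, a top-left origin and an `NA`-encoded
#' nodata mask. Row 1 is the northernmost row, column 1 the westernmost
#' column; indexing is 0-based nowhere -- all functions use R's 1-based
#' row/column convention internally and the standard north-up affine
#' convention on disk.
#'
#' @param values numeric matrix; `NA` marks nodata.
#' @param pixel_size positive pixel edge length in metres (square pixels).
#' @param origin numeric length-2, x/y map coordinates of the top-left
#'   corner of the top-left pixel.
#' @param crs free-form coordinate reference identifier carried as metadata.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, pixel_size = 10, origin = c(0, 0), crs = "local") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || !is.finite(pixel_size) ||
      pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 2 || !all(is.finite(origin)))
    stop("`origin` must be two finite coordinates", call. = FALSE)
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin), crs = as.character(crs)[1]),
    class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
as.matrix.raster_grid <- function(x, ...) x$values

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid> %d x %d, pixel %g m, origin (%g, %g), crs '%s'\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              x$origin[1], x$origin[2], x$crs))
  if (length(v))
    cat(sprintf("  valid %d/%d, range [%.6g, %.6g]\n", length(v),
                length(x$values), min(v), max(v)))
  else cat("  no valid pixels\n")
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Check that rasters share grid geometry
#'
#' Stops unless all rasters have identical shape, pixel size and origin
#' (co-registration requirement for any per-pixel algebra).
#'
#' @param ... raster_grid objects.
#' @return invisibly `TRUE`.
#' @export
stopifnot_same_grid <- function(...) {
  rs <- list(...)
  ref <- rs[[1]]
  for (r in rs[-1]) {
    if (!identical(dim(r$values), dim(ref$values)))
      stop("rasters are not co-registered: shapes differ", call. = FALSE)
    if (!isTRUE(all.equal(r$pixel_size, ref$pixel_size)) ||
        !isTRUE(all.equal(r$origin, ref$origin)))
      stop("rasters are not co-registered: georeference differs", call. = FALSE)
  }
  invisible(TRUE)
}

#' Elementwise map over co-registered rasters
#'
#' @param f function applied to the value matrices.
#' @param ... raster_grid inputs (first supplies geometry).
#' @return raster_grid with `f`'s result.
#' @keywords internal
raster_map <- function(f, ...) {
  rs <- list(...)
  stopifnot_same_grid(...)
  out <- do.call(f, lapply(rs, function(r) r$values))
  raster_grid(out, rs[[1]]$pixel_size, rs[[1]]$origin, rs[[1]]$crs)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Rasters are stored in the plain-text ESRI ASCII grid format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed
#' by north-to-south rows) with values printed at full double precision, so
#' a write/read round trip is exact. The CRS identifier travels in a JSON
#' sidecar (`<path>.aux.json`).
#'
#' @param path file path (conventionally `.asc`).
#' @param grid raster_grid to write.
#' @return `read_raster` returns a raster_grid; `write_raster` returns
#'   `path` invisibly.
#' @export
write_raster <- function(grid, path) {
  if (!is_raster_grid(grid)) stop("`grid` must be a raster_grid", call. = FALSE)
  v <- grid$values
  nodata <- -9999
  if (any(v[!is.na(v)] == nodata)) nodata <- -3.402823e38
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10f", grid$origin[1]),
    sprintf("yllcorner %.10f", grid$origin[2] - nrow(v) * grid$pixel_size),
    sprintf("cellsize %.10f", grid$pixel_size),
    sprintf("NODATA_value %s", format(nodata, digits = 17)))
  body <- apply(v, 1, function(row) {
    row[is.na(row)] <- nodata
    paste(format(row, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  jsonlite::write_json(list(crs = grid$crs), paste0(path, ".aux.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  crs <- "local"
  aux <- paste0(path, ".aux.json")
  if (file.exists(aux)) {
    meta <- jsonlite::read_json(aux)
    if (!is.null(meta$crs)) crs <- meta$crs
  }
  raster_grid(m, hdr$cellsize,
              origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
              crs = crs)
}

#' Resample a raster to a new pixel size
#'
#' Nearest-neighbour resampling preserves the source value set (used when
#' pairing 30 m thermal output with a 10 m optical grid); bilinear
#' interpolates between source pixel centres, clamping at the edges.
#'
#' @param raster raster_grid.
#' @param target_pixel_size new pixel edge in metres.
#' @param method `"nearest"` or `"bilinear"`.
#' @return raster_grid on the new grid covering the same extent.
#' @export
resample <- function(raster, target_pixel_size, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (!is.numeric(target_pixel_size) || target_pixel_size <= 0 ||
      !is.finite(target_pixel_size))
    stop("`target_pixel_size` must be positive", call. = FALSE)
  src <- raster$values
  ratio <- raster$pixel_size / target_pixel_size
  nr <- max(1L, as.integer(round(nrow(src) * ratio)))
  nc <- max(1L, as.integer(round(ncol(src) * ratio)))
  # centre coordinates of target pixels measured in source pixel units
  ri <- ((seq_len(nr) - 0.5) / ratio)
  ci <- ((seq_len(nc) - 0.5) / ratio)
  if (method == "nearest") {
    rsrc <- pmin(nrow(src), pmax(1L, ceiling(ri)))
    csrc <- pmin(ncol(src), pmax(1L, ceiling(ci)))
    out <- src[rsrc, csrc, drop = FALSE]
  } else {
    f <- function(x, n) pmin(pmax(x + 0.5, 1), n)  # fractional source index
    rf <- f(ri, nrow(src)); cf <- f(ci, ncol(src))
    r0 <- pmin(floor(rf), nrow(src) - 1L); r0[nrow(src) == 1] <- 1
    c0 <- pmin(floor(cf), ncol(src) - 1L); c0[ncol(src) == 1] <- 1
    wr <- rf - r0; wc <- cf - c0
    r1 <- pmin(r0 + 1, nrow(src)); c1 <- pmin(c0 + 1, ncol(src))
    out <- matrix(NA_real_, nr, nc)
    for (j in seq_len(nc)) {
      a <- src[r0, c0[j]] * (1 - wr) + src[r1, c0[j]] * wr
      b <- src[r0, c1[j]] * (1 - wr) + src[r1, c1[j]] * wr
      out[, j] <- a * (1 - wc[j]) + b * wc[j]
    }
  }
  raster_grid(out, target_pixel_size, raster$origin, raster$crs)
}
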