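#' Define a regular longitude/latitude grid
#'
#' All rasters in the package live on a `grid_spec`: a regular grid of square
#' cells (in degrees) whose lower-left corner is at
#' (`origin_lon`, `origin_lat`). Rows are stored north-to-south (row 1 is the
#' northernmost row), matching the ESRI ASCII grid convention.
#'
#' @param n_rows,n_cols Grid dimensions (each at least 8).
#' @param origin_lon,origin_lat Lower-left corner of the grid, decimal degrees.
#' @param cell_size Cell edge length in degrees; must be positive.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, origin_lon = 0, origin_lat = 40,
                      cell_size = 0.05) {
  if (n_rows < 8 || n_cols < 8)
    stop("grid must be at least 8 x 8 cells")
  if (cell_size <= 0)
    stop("cell_size must be positive")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size),
    class = "grid_spec")
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @param cells Optional vector of cell indices (column-major over the
#'   `n_rows x n_cols` value matrix); default all cells.
#' @return A data frame with columns `cell`, `row`, `col`, `lon`, `lat`.
#' @export
cell_centers <- function(grid, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(grid$n_rows * grid$n_cols)
  row <- ((cells - 1L) %% grid$n_rows) + 1L
  col <- ((cells - 1L) %/% grid$n_rows) + 1L
  data.frame(
    cell = cells, row = row, col = col,
    lon = grid$origin_lon + (col - 0.5) * grid$cell_size,
    lat = grid$origin_lat + (grid$n_rows - row + 0.5) * grid$cell_size)
}

#' Map coordinates to the cell index containing them
#'
#' Points outside the grid return `NA`.
#' @param grid A [grid_spec()].
#' @param lon,lat Coordinate vectors in degrees.
#' @return Integer vector of column-major cell indices.
#' @export
cell_at <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1
  row <- grid$n_rows - floor((lat - grid$origin_lat) / grid$cell_size)
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(lon) | !is.finite(lat)
  idx <- (col - 1) * grid$n_rows + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Construct a single-layer raster
#'
#' @param values Numeric matrix `n_rows x n_cols` (row 1 = north). `NA` marks
#'   nodata cells.
#' @param grid A [grid_spec()] with matching dimensions.
#' @return An object of class `rf_raster`.
#' @export
rf_raster <- function(values, grid) {
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("raster values do not match grid dimensions")
  structure(list(values = values, grid = grid), class = "rf_raster")
}

#' Construct a multi-layer raster stack
#'
#' @param layers Named list of value matrices sharing one grid.
#' @param grid A [grid_spec()].
#' @param scenario Scenario tag, e.g. `"current"` or `"lgm"`.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(layers, grid, scenario = "current") {
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be named")
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop("layer '", nm, "' does not match grid dimensions")
  }
  structure(list(layers = layers, grid = grid, scenario = scenario),
            class = "raster_stack")
}

#' Extract layer values at cells
#'
#' @param stack A [raster_stack()].
#' @param cells Cell indices (column-major); default all.
#' @param vars Layer names; default all.
#' @return Numeric matrix, one row per cell, one column per layer.
#' @export
layer_values <- function(stack, cells = NULL, vars = NULL) {
  if (is.null(vars)) vars <- names(stack$layers)
  if (is.null(cells)) cells <- seq_len(stack$grid$n_rows * stack$grid$n_cols)
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss))
    stop("missing layer(s): ", paste(miss, collapse = ", "))
  out <- vapply(vars, function(v) stack$layers[[v]][cells], numeric(length(cells)))
  out <- matrix(out, nrow = length(cells),
                dimnames = list(NULL, vars))
  out
}

#' @export
print.rf_raster <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<rf_raster> %d x %d cells, %.4g deg, origin (%.4g, %.4g)\n",
              g$n_rows, g$n_cols, g$cell_size, g$origin_lon, g$origin_lat))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], %d nodata\n", min(v), max(v),
                sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> scenario '%s', %d layer(s): %s\n", x$scenario,
              length(x$layers), paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster An [rf_raster()].
#' @param path Output file path.
#' @param nodata Value used to encode `NA` cells.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  v <- raster$values
  v[is.na(v)] <- nodata
  hdr <- c(
    paste("ncols", g$n_cols),
    paste("nrows", g$n_rows),
    paste("xllcorner", format(g$origin_lon, digits = 15)),
    paste("yllcorner", format(g$origin_lat, digits = 15)),
    paste("cellsize", format(g$cell_size, digits = 15)),
    paste("NODATA_value", nodata))
  body <- apply(v, 1, function(r) paste(format(r, digits = 15, trim = TRUE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return An [rf_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  g <- grid_spec(hdr$nrows, hdr$ncols, hdr$xllcorner, hdr$yllcorner,
                 hdr$cellsize)
  rf_raster(m, g)
}

# Gaussian smoothing by separable band-matrix convolution; edge effects are
# handled by renormalising truncated kernels (weights always sum to 1).
gaussian_smooth <- function(mat, sigma) {
  smooth_1d <- function(n) {
    h <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-h:h, sd = sigma)
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, i - h):pmin(n, i + h)
      B[i, j] <- k[j - i + h + 1L]
    }
    B / rowSums(B)
  }
  Br <- smooth_1d(nrow(mat))
  Bc <- smooth_1d(ncol(mat))
  Br %*% mat %*% t(Bc)
}
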