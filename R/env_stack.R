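#' Gridded environmental stack
#'
#' `env_stack` is the package's container for a set of named, co-registered
#' environmental layers on a regular geographic (lon/lat, WGS84) grid. All
#' layers share one shape and one validity mask; georeferencing is
#' cell-centre with the origin at the lower-left corner of the grid.
#'
#' Matrices are stored image-style: row 1 is the northernmost row of cells,
#' column 1 the westernmost. Cell membership for points uses half-open
#' intervals closed at the lower/left edge, so every in-extent point belongs
#' to exactly one cell.
#'
#' @param layers named list of numeric matrices, all of identical dimension.
#' @param xmin,ymin longitude/latitude of the grid's lower-left corner
#'   (decimal degrees).
#' @param xres,yres cell size in decimal degrees (both > 0). `yres` defaults
#'   to `xres`.
#' @param mask optional logical matrix of valid cells; `NA` cells in any
#'   layer are always masked in addition.
#'
#' @return An object of class `env_stack`: a list with elements `layers`,
#'   `mask`, `xmin`, `ymin`, `xres`, `yres`, `nrow`, `ncol`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4)
#' env <- env_stack(list(bio1 = m), xmin = 100, ymin = 30, xres = 0.5)
#' env
env_stack <- function(layers, xmin, ymin, xres, yres = xres, mask = NULL) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a non-empty named list of matrices")
  nms <- names(layers)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    stop("all layers must have unique non-empty names")
  if (!all(vapply(layers, is.matrix, logical(1))))
    stop("all layers must be matrices")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share the same dimensions")
  nr <- unname(dims[1, 1]); nc <- unname(dims[2, 1])
  if (nr < 1L || nc < 1L) stop("grid must have at least one cell")
  if (!is.numeric(xres) || !is.numeric(yres) || xres <= 0 || yres <= 0)
    stop("cell sizes must be positive")
  layers <- lapply(layers, function(m) { storage.mode(m) <- "double"; m })
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (!is.logical(mask) || !identical(dim(mask), c(nr, nc)))
    stop("`mask` must be a logical matrix matching the layer dimensions")
  mask[is.na(mask)] <- FALSE
  for (m in layers) mask <- mask & !is.na(m)
  # invalid cells are flagged identically across layers
  layers <- lapply(layers, function(m) { m[!mask] <- NA_real_; m })
  structure(
    list(layers = layers, mask = mask,
         xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         xres = as.numeric(xres), yres = as.numeric(yres),
         nrow = nr, ncol = nc),
    class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d x %d cells, %d layer(s): %s\n",
              x$nrow, x$ncol, length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  extent: lon [%g, %g), lat [%g, %g); cell %g x %g deg\n",
              x$xmin, x$xmin + x$ncol * x$xres,
              x$ymin, x$ymin + x$nrow * x$yres,
              x$xres, x$yres))
  cat(sprintf("  valid cells: %d / %d\n", sum(x$mask), x$nrow * x$ncol))
  invisible(x)
}

#' @export
#' @rdname env_stack
is_env_stack <- function(x) inherits(x, "env_stack")

#' @export
#' @rdname env_stack
#' @param x an `env_stack`.
layer_names <- function(x) names(x$layers)

stack_ymax <- function(x) x$ymin + x$nrow * x$yres
stack_xmax <- function(x) x$xmin + x$ncol * x$xres

#' Grid identity check
#'
#' Two stacks are co-registered when shape and transform agree within `tol`
#' degrees.
#' @param a,b `env_stack` objects.
#' @param tol absolute tolerance on the transform, in degrees.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xmin - b$xmin) <= tol && abs(a$ymin - b$ymin) <= tol &&
    abs(a$xres - b$xres) <= tol && abs(a$yres - b$yres) <= tol
}

stop_unless_coregistered <- function(a, b, what = "stacks") {
  if (!same_grid(a, b))
    stop("co-registration error: ", what,
         " differ in shape or transform", call. = FALSE)
  invisible(TRUE)
}

#' Cell-centre coordinates
#'
#' @param env an `env_stack`.
#' @param row,col cell indices (row 1 = northernmost).
#' @return numeric vector of longitudes / latitudes.
#' @export
cell_lon <- function(env, col) env$xmin + (col - 0.5) * env$xres

#' @rdname cell_lon
#' @export
cell_lat <- function(env, row) stack_ymax(env) - (row - 0.5) * env$yres

#' Locate points on the grid
#'
#' Maps lon/lat points to cell indices using the half-open convention
#' (closed at the lower/left cell edge); points on the extreme top/right
#' grid edge are out of extent.
#'
#' @param env an `env_stack`.
#' @param lon,lat point coordinates in decimal degrees.
#' @return data.frame with columns `row`, `col` (NA when out of extent),
#'   `in_extent`, and `valid` (in extent and on an unmasked cell).
#' @export
cell_index <- function(env, lon, lat) {
  col <- floor((lon - env$xmin) / env$xres) + 1
  krow <- floor((lat - env$ymin) / env$yres) + 1  # 1 = southernmost band
  row <- env$nrow - krow + 1
  inx <- is.finite(lon) & is.finite(lat) &
    col >= 1 & col <= env$ncol & krow >= 1 & krow <= env$nrow
  row[!inx] <- NA_integer_; col[!inx] <- NA_integer_
  valid <- inx
  valid[inx] <- env$mask[cbind(row[inx], col[inx])]
  data.frame(row = as.integer(row), col = as.integer(col),
             in_extent = inx, valid = valid)
}

#' Per-cell values of all layers
#'
#' @param env an `env_stack`.
#' @param valid_only drop masked cells.
#' @return data.frame with `row`, `col`, `lon`, `lat` and one column per
#'   layer; one row per grid cell (column-major over the grid).
#' @export
stack_values <- function(env, valid_only = TRUE) {
  idx <- which(env$mask | !valid_only, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1], col = idx[, 2],
                    lon = cell_lon(env, idx[, 2]),
                    lat = cell_lat(env, idx[, 1]))
  for (nm in names(env$layers)) out[[nm]] <- env$layers[[nm]][idx]
  out
}

#' Spherical cell areas by latitude band
#'
#' Area of one grid cell in each row of the grid, on the authalic sphere
#' (R = 6371.0088 km): R^2 * dlon * (sin(lat_top) - sin(lat_bottom)).
#'
#' @param env an `env_stack` (geographic grid).
#' @return numeric vector of length `env$nrow`, km^2 per cell.
#' @export
cell_area_km2 <- function(env) {
  R <- 6371.0088
  top <- stack_ymax(env) - (seq_len(env$nrow) - 1) * env$yres
  bot <- top - env$yres
  R^2 * (env$xres * pi / 180) * (sinpi(top / 180) - sinpi(bot / 180))
}
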