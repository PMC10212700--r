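#' Occurrence sets
#'
#' A species-labelled set of presence coordinates (WGS84 decimal degrees).
#'
#' @param species single species label.
#' @param lon,lat numeric coordinate vectors of equal length.
#' @param provenance free-text source tag.
#' @return An object of class `occurrence_set` with fields `species`,
#'   `points` (data.frame `lon`, `lat`) and `provenance`.
#' @export
occurrence_set <- function(species, lon, lat, provenance = "") {
  stopifnot(length(species) == 1L, length(lon) == length(lat))
  if (length(lon) && any(!is.finite(lon) | !is.finite(lat)))
    stop("occurrence coordinates must be finite")
  structure(list(species = as.character(species),
                 points = data.frame(lon = as.numeric(lon),
                                     lat = as.numeric(lat)),
                 provenance = provenance),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d record(s)\n",
              x$species, nrow(x$points)))
  invisible(x)
}

#' Read occurrence records from CSV
#'
#' Expects a UTF-8 CSV with header columns `species`, `lon`, `lat`
#' (optionally `source`). Rows with missing or non-numeric coordinates are
#' dropped and counted; exact duplicate rows are collapsed to one record.
#'
#' @param path CSV file path.
#' @return Named list with one `occurrence_set` per species label, carrying
#'   attributes `n_dropped` (unparseable coordinates) and `n_duplicates`
#'   (collapsed exact duplicates).
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("species", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  ndup <- sum(duplicated(df))
  df <- df[!duplicated(df), , drop = FALSE]
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  ok <- is.finite(lon) & is.finite(lat) & nzchar(df$species)
  ndrop <- sum(!ok)
  df <- df[ok, , drop = FALSE]; lon <- lon[ok]; lat <- lat[ok]
  out <- lapply(split(seq_along(lon), df$species), function(i)
    occurrence_set(df$species[i[1]], lon[i], lat[i], provenance = path))
  attr(out, "n_dropped") <- ndrop
  attr(out, "n_duplicates") <- ndup
  out
}

#' Write occurrence sets to CSV
#'
#' @param occs an `occurrence_set` or list of them.
#' @param path output CSV path (columns `species,lon,lat`).
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occs, path) {
  if (inherits(occs, "occurrence_set")) occs <- list(occs)
  df <- do.call(rbind, lapply(occs, function(o)
    data.frame(species = o$species, lon = o$points$lon, lat = o$points$lat)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------

#' Read a raster layer
#'
#' Reads one ESRI ASCII grid (`.asc`) layer. The `NODATA_value` header is
#' honoured and, together with `NaN` cells, becomes the validity mask.
#' Non-square cells written with the `DX`/`DY` header extension are
#' supported. GeoTIFF input is not supported by this package; convert to
#' ESRI ASCII first.
#'
#' @param path file path.
#' @param expected_grid optional `env_stack`; the layer must then match its
#'   shape and transform within 1e-9 degrees or a co-registration error is
#'   raised.
#' @param name layer name; defaults to the file base name.
#' @return A single-layer `env_stack`.
#' @export
read_raster <- function(path, expected_grid = NULL, name = NULL) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF input is not supported; supply an ESRI ASCII grid (.asc)")
  lines <- readLines(path, n = 7L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- toupper(tok[1])
    if (key %in% c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "XLLCENTER",
                   "YLLCENTER", "CELLSIZE", "DX", "DY", "NODATA_VALUE")) {
      hdr[[key]] <- as.numeric(tok[2]); nhdr <- nhdr + 1L
    } else break
  }
  if (is.null(hdr$NCOLS) || is.null(hdr$NROWS))
    stop("I/O error: not an ESRI ASCII grid: ", path)
  nc <- as.integer(hdr$NCOLS); nr <- as.integer(hdr$NROWS)
  xres <- if (!is.null(hdr$DX)) hdr$DX else hdr$CELLSIZE
  yres <- if (!is.null(hdr$DY)) hdr$DY else hdr$CELLSIZE
  if (is.null(xres) || is.null(yres))
    stop("I/O error: missing CELLSIZE (or DX/DY) in ", path)
  xmin <- if (!is.null(hdr$XLLCORNER)) hdr$XLLCORNER
          else hdr$XLLCENTER - xres / 2
  ymin <- if (!is.null(hdr$YLLCORNER)) hdr$YLLCORNER
          else hdr$YLLCENTER - yres / 2
  vals <- scan(path, skip = nhdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("I/O error: expected ", nr * nc, " values, got ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # row 1 = north
  if (!is.null(hdr$NODATA_VALUE)) m[m == hdr$NODATA_VALUE] <- NA_real_
  m[is.nan(m)] <- NA_real_
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  out <- env_stack(stats::setNames(list(m), name),
                   xmin = xmin, ymin = ymin, xres = xres, yres = yres)
  if (!is.null(expected_grid)) stop_unless_coregistered(out, expected_grid,
                                                        paste0("'", path, "' and expected grid"))
  out
}

#' Write a raster layer as ESRI ASCII
#'
#' Masked cells are written as the `NODATA_value`. Non-square cells are
#' written with `DX`/`DY` headers.
#'
#' @param env an `env_stack`.
#' @param layer layer name to write (default: first layer).
#' @param path output path.
#' @param nodata nodata sentinel value.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(env, path, layer = layer_names(env)[1],
                             nodata = -9999) {
  m <- env$layers[[layer]]
  if (is.null(m)) stop("unknown layer: ", layer)
  m[!env$mask] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("NCOLS %d", env$ncol),
               sprintf("NROWS %d", env$nrow),
               sprintf("XLLCORNER %.10g", env$xmin),
               sprintf("YLLCORNER %.10g", env$ymin)), con)
  if (isTRUE(all.equal(env$xres, env$yres, tolerance = 1e-12))) {
    writeLines(sprintf("CELLSIZE %.10g", env$xres), con)
  } else {
    writeLines(c(sprintf("DX %.10g", env$xres),
                 sprintf("DY %.10g", env$yres)), con)
  }
  writeLines(sprintf("NODATA_value %.10g", nodata), con)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.9g", r),
                                           collapse = " ")), con)
  invisible(path)
}

#' Write every layer of a stack to a directory
#'
#' @param env an `env_stack`.
#' @param dir output directory (created if needed); one `<layer>.asc` per
#'   layer.
#' @return character vector of paths, invisibly.
#' @export
write_env_stack <- function(env, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(layer_names(env), function(nm)
    write_ascii_grid(env, file.path(dir, paste0(nm, ".asc")), layer = nm),
    character(1))
  invisible(paths)
}

#' Read several co-registered layers into one stack
#'
#' @param paths named character vector of `.asc` paths; names become layer
#'   names (file base names when unnamed).
#' @return An `env_stack` with the union mask (a cell is valid only where
#'   every layer has data).
#' @export
read_env_stack <- function(paths) {
  first <- read_raster(paths[1])
  layers <- list(first$layers[[1]])
  for (p in paths[-1]) {
    r <- read_raster(p, expected_grid = first)
    layers <- c(layers, r$layers)
  }
  nms <- if (!is.null(names(paths)) && all(nzchar(names(paths))))
    names(paths) else sub("\\.[^.]*$", "", basename(paths))
  env_stack(stats::setNames(layers, nms), xmin = first$xmin,
            ymin = first$ymin, xres = first$xres, yres = first$yres)
}

# ---- spatial preparation ----------------------------------------------------

#' Clip a stack to a lon/lat window
#'
#' Keeps exactly the cells whose centres fall in the half-open window
#' `[lon_min, lon_max) x [lat_min, lat_max)` and updates the transform.
#'
#' @param env an `env_stack`.
#' @param lon_min,lon_max,lat_min,lat_max window bounds, decimal degrees.
#' @return The clipped `env_stack`.
#' @export
clip_window <- function(env, lon_min, lon_max, lat_min, lat_max) {
  lons <- cell_lon(env, seq_len(env$ncol))
  lats <- cell_lat(env, seq_len(env$nrow))
  jkeep <- which(lons >= lon_min & lons < lon_max)
  ikeep <- which(lats >= lat_min & lats < lat_max)
  if (!length(jkeep) || !length(ikeep))
    stop("clip window does not intersect the stack extent")
  layers <- lapply(env$layers, function(m) m[ikeep, jkeep, drop = FALSE])
  env_stack(layers,
            xmin = env$xmin + (min(jkeep) - 1) * env$xres,
            ymin = stack_ymax(env) - max(ikeep) * env$yres,
            xres = env$xres, yres = env$yres,
            mask = env$mask[ikeep, jkeep, drop = FALSE])
}

#' Thin occurrences to one record per grid cell
#'
#' Applies the standard one-record-per-cell rule: of several records in a
#' cell the first in input order is kept; records falling outside the grid
#' extent or on masked cells are removed.
#'
#' @param occ an `occurrence_set`.
#' @param grid an `env_stack` defining cells and mask.
#' @return The thinned `occurrence_set`, with attribute `n_removed`.
#' @export
thin_to_grid <- function(occ, grid) {
  ci <- cell_index(grid, occ$points$lon, occ$points$lat)
  keep <- ci$valid
  # one record per cell, first in input order among valid records
  keep[keep] <- !duplicated(cbind(ci$row, ci$col)[keep, , drop = FALSE])
  out <- occurrence_set(occ$species, occ$points$lon[keep],
                        occ$points$lat[keep], occ$provenance)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Extract layer values at occurrence points
#'
#' Looks up, for each point, all layer values at the containing cell
#' (half-open cell membership). Points outside the extent or on masked
#' cells are excluded from the result and reported.
#'
#' @param env an `env_stack`.
#' @param occ an `occurrence_set`, or a data.frame with `lon`, `lat`.
#' @return data.frame with `species`, `lon`, `lat` and one column per
#'   layer; attribute `excluded` holds the dropped points with a `reason`
#'   column (`"out_of_extent"` or `"masked"`).
#' @export
extract_at_points <- function(env, occ) {
  if (inherits(occ, "occurrence_set")) {
    pts <- occ$points; species <- occ$species
  } else {
    pts <- as.data.frame(occ); species <- pts$species %||% NA_character_
  }
  ci <- cell_index(env, pts$lon, pts$lat)
  excl <- data.frame(lon = pts$lon, lat = pts$lat,
                     reason = ifelse(!ci$in_extent, "out_of_extent",
                                     ifelse(!ci$valid, "masked", "")))
  excl <- excl[excl$reason != "", , drop = FALSE]
  keep <- ci$valid
  if (!any(keep)) stop("all points fall outside the extent or on masked cells")
  out <- data.frame(species = if (length(species) == 1L)
    rep(species, sum(keep)) else species[keep],
    lon = pts$lon[keep], lat = pts$lat[keep])
  idx <- cbind(ci$row[keep], ci$col[keep])
  for (nm in names(env$layers)) out[[nm]] <- env$layers[[nm]][idx]
  attr(out, "excluded") <- excl
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

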