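#' Specification of a virtual landscape
#'
#' Describes a synthetic study region: a regular lon/lat grid carrying
#' several spatially autocorrelated, optionally inter-correlated
#' environmental layers. The defaults mirror a coarse mountain-region
#' setup: a 200 x 200 grid over 91-125 E / 20-47 N with six layers named
#' after the bioclimatic variables commonly retained after collinearity
#' screening (bio1, bio3, bio7, bio12, bio15, srad12).
#'
#' @param n_rows,n_cols grid dimensions (>= 2).
#' @param extent numeric `c(lon_min, lon_max, lat_min, lat_max)` in decimal
#'   degrees.
#' @param layer_names layer identifiers.
#' @param spatial_range autocorrelation length of the random fields, in
#'   cells (Gaussian smoothing kernel standard deviation).
#' @param inter_layer_corr target correlation matrix among layers
#'   (symmetric, unit diagonal, positive semidefinite). Default: identity.
#' @param seed integer seed; field generation is a pure function of it.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(n_rows = 200, n_cols = 200,
                           extent = c(91, 125, 20, 47),
                           layer_names = c("bio1", "bio3", "bio7",
                                           "bio12", "bio15", "srad12"),
                           spatial_range = 8,
                           inter_layer_corr = NULL,
                           seed = 1L) {
  if (n_rows < 2 || n_cols < 2) stop("grid must be at least 2 x 2")
  stopifnot(length(extent) == 4)
  if (extent[1] < -180 || extent[2] > 180 || extent[1] >= extent[2])
    stop("longitude extent must be increasing within [-180, 180]")
  if (extent[3] < -90 || extent[4] > 90 || extent[3] >= extent[4])
    stop("latitude extent must be increasing within [-90, 90]")
  k <- length(layer_names)
  if (is.null(inter_layer_corr)) inter_layer_corr <- diag(k)
  C <- as.matrix(inter_layer_corr)
  if (!identical(dim(C), c(k, k)))
    stop("inter_layer_corr must be ", k, " x ", k)
  if (max(abs(C - t(C))) > 1e-8 || max(abs(diag(C) - 1)) > 1e-8)
    stop("inter_layer_corr must be symmetric with unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("inter_layer_corr is not positive semidefinite")
  if (spatial_range <= 0) stop("spatial_range must be positive")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 extent = as.numeric(extent),
                 layer_names = as.character(layer_names),
                 spatial_range = spatial_range,
                 inter_layer_corr = C, seed = as.integer(seed)),
            class = "landscape_spec")
}

# plausible per-layer units so synthetic layers look like the real
# variables they stand in for (affine rescaling of a unit-variance field;
# correlations are unaffected)
layer_unit_table <- function(names) {
  defaults <- list(bio1  = c(mean = 8,    sd = 6),     # deg C
                   bio3  = c(mean = 35,   sd = 8),     # percent
                   bio7  = c(mean = 30,   sd = 6),     # deg C
                   bio12 = c(mean = 800,  sd = 300),   # mm
                   bio15 = c(mean = 70,   sd = 20),    # percent
                   srad12 = c(mean = 9000, sd = 2500)) # kJ m-2 day-1
  lapply(stats::setNames(names, names), function(nm)
    defaults[[nm]] %||% c(mean = 0, sd = 1))
}

# smooth a white-noise matrix with a truncated, row-normalized Gaussian
# kernel of sd `range` cells (separable: rows then columns)
smooth_field <- function(m, range) {
  wmat <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    w <- exp(-0.5 * (d / range)^2)
    w[abs(d) > 4 * range] <- 0
    sweep(w, 1, rowSums(w), "/")
  }
  wmat(nrow(m)) %*% m %*% t(wmat(ncol(m)))
}

#' Generate a synthetic environmental stack
#'
#' Each layer is a spatially smooth Gaussian random field: white noise is
#' smoothed with a Gaussian kernel of width `spatial_range` cells,
#' standardized, and the independent fields are then linearly mixed through
#' a factor decomposition of `inter_layer_corr`, so empirical inter-layer
#' correlations approach the target as the grid grows. Finally each layer
#' is rescaled to plausible units for its name (e.g. degrees Celsius for
#' bio1, millimetres for bio12).
#'
#' @param spec a `landscape_spec`.
#' @return An `env_stack` with one layer per `spec$layer_names`.
#' @export
#' @examples
#' env <- gen_env_stack(landscape_spec(n_rows = 40, n_cols = 40, seed = 7))
#' env
gen_env_stack <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  k <- length(spec$layer_names)
  nr <- spec$n_rows; nc <- spec$n_cols
  F <- with_seed(spec$seed, {
    vapply(seq_len(k), function(i) {
      z <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                        spec$spatial_range)
      as.vector((z - mean(z)) / stats::sd(z))
    }, numeric(nr * nc))
  })
  # Empirically whiten the smoothed fields (spatial autocorrelation
  # inflates sample correlations between independent fields), then apply
  # the factor transform of the target: the sample correlation matrix of
  # the layers then equals the target exactly, the mvrnorm
  # `empirical = TRUE` convention.
  if (k > 1) F <- F %*% backsolve(chol(stats::cov(F)), diag(k))
  L <- tryCatch(t(chol(spec$inter_layer_corr)), error = function(e) {
    eg <- eigen(spec$inter_layer_corr, symmetric = TRUE)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), k)
  })
  X <- F %*% t(L)
  X <- scale(X)  # unit variance per mixed layer before unit rescaling
  units <- layer_unit_table(spec$layer_names)
  layers <- stats::setNames(lapply(seq_len(k), function(i) {
    u <- units[[i]]
    matrix(X[, i] * u[["sd"]] + u[["mean"]], nr, nc)
  }), spec$layer_names)
  env_stack(layers,
            xmin = spec$extent[1], ymin = spec$extent[3],
            xres = (spec$extent[2] - spec$extent[1]) / nc,
            yres = (spec$extent[4] - spec$extent[3]) / nr)
}

#' Define a virtual species
#'
#' A Gaussian-bell niche response: suitability declines with the
#' breadth-scaled squared environmental distance from the niche centre,
#' the standard virtual-species convention.
#'
#' @param name species label.
#' @param niche_center named numeric vector: optimum per layer, in layer
#'   units.
#' @param niche_breadth named numeric vector: positive niche width per
#'   layer, same units.
#' @param max_suitability suitability at the optimum, in (0, 1].
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(name, niche_center, niche_breadth,
                            max_suitability = 1) {
  if (is.null(names(niche_center)) || is.null(names(niche_breadth)))
    stop("niche_center and niche_breadth must be named by layer")
  if (!setequal(names(niche_center), names(niche_breadth)))
    stop("niche_center and niche_breadth must name the same layers")
  niche_breadth <- niche_breadth[names(niche_center)]
  if (any(niche_breadth <= 0)) stop("niche breadths must be positive")
  if (max_suitability <= 0 || max_suitability > 1)
    stop("max_suitability must be in (0, 1]")
  structure(list(name = as.character(name),
                 niche_center = niche_center,
                 niche_breadth = niche_breadth,
                 max_suitability = max_suitability),
            class = "virtual_species")
}

#' True habitat suitability of a virtual species
#'
#' Per-cell suitability
#' `max_suitability * exp(-0.5 * sum_l ((x_l - center_l) / breadth_l)^2)`,
#' a Gaussian bell in breadth-scaled environmental space: 1 at the niche
#' centre (for `max_suitability = 1`), symmetric in scaled distance, and
#' non-decreasing everywhere when breadths grow. Masked cells are `NA`.
#'
#' @param env an `env_stack`.
#' @param sp a `virtual_species` referencing only layers present in `env`.
#' @return A single-layer `env_stack` (layer `"suitability"`) on the same
#'   grid and mask.
#' @export
true_suitability <- function(env, sp) {
  stopifnot(inherits(sp, "virtual_species"))
  unknown <- setdiff(names(sp$niche_center), layer_names(env))
  if (length(unknown))
    stop("virtual species references unknown layer(s): ",
         paste(unknown, collapse = ", "))
  d2 <- 0
  for (nm in names(sp$niche_center)) {
    d2 <- d2 + ((env$layers[[nm]] - sp$niche_center[[nm]]) /
                  sp$niche_breadth[[nm]])^2
  }
  suit <- sp$max_suitability * exp(-0.5 * d2)
  env_stack(list(suitability = suit), xmin = env$xmin, ymin = env$ymin,
            xres = env$xres, yres = env$yres, mask = env$mask)
}

#' Sample presence records from a suitability surface
#'
#' Draws `n` presence points (with replacement) with probability
#' proportional to cell suitability; points are placed at cell centres so
#' grid thinning behaves exactly.
#'
#' @param suit a single-layer `env_stack` of nonnegative suitabilities
#'   (e.g. from [true_suitability()]).
#' @param n number of records (>= 1).
#' @param seed integer seed; the draw is a pure function of it.
#' @param species species label for the returned set.
#' @return An `occurrence_set`.
#' @export
sample_occurrences <- function(suit, n, seed, species = "virtual") {
  stopifnot(n >= 1)
  w <- suit$layers[[1]]
  idx <- which(suit$mask & is.finite(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("suitability is zero everywhere on the mask")
  p <- w[idx]
  draw <- with_seed(seed,
                    sample.int(nrow(idx), size = n, replace = TRUE, prob = p))
  occurrence_set(species,
                 lon = cell_lon(suit, idx[draw, 2]),
                 lat = cell_lat(suit, idx[draw, 1]),
                 provenance = "synthetic")
}

#' Define a climate scenario as layer shifts
#'
#' A scenario stack is derived from the baseline by the cellwise affine
#' map `x * factor + offset` per named layer — an abstract stand-in for
#' past (LGM/Mid-Holocene-like) or future (SSP-like) layer sets.
#'
#' @param name scenario label.
#' @param additive_offsets named numeric vector of per-layer offsets
#'   (layer units); unnamed layers are unshifted.
#' @param multiplicative_factors named numeric vector of positive
#'   per-layer factors.
#' @return An object of class `scenario_shift`.
#' @export
scenario_shift <- function(name, additive_offsets = numeric(0),
                           multiplicative_factors = numeric(0)) {
  if (length(additive_offsets) && is.null(names(additive_offsets)))
    stop("additive_offsets must be named by layer")
  if (length(multiplicative_factors)) {
    if (is.null(names(multiplicative_factors)))
      stop("multiplicative_factors must be named by layer")
    if (any(multiplicative_factors <= 0))
      stop("multiplicative factors must be positive")
  }
  structure(list(name = as.character(name),
                 additive_offsets = additive_offsets,
                 multiplicative_factors = multiplicative_factors),
            class = "scenario_shift")
}

#' Apply a scenario shift to a stack
#'
#' @param env baseline `env_stack`.
#' @param shift a `scenario_shift`; all its layer names must exist in
#'   `env`. Untouched layers are copied; georeferencing and mask are
#'   preserved.
#' @return The shifted `env_stack`.
#' @export
apply_scenario <- function(env, shift) {
  stopifnot(inherits(shift, "scenario_shift"))
  touched <- union(names(shift$additive_offsets),
                   names(shift$multiplicative_factors))
  unknown <- setdiff(touched, layer_names(env))
  if (length(unknown))
    stop("scenario shifts unknown layer(s): ", paste(unknown, collapse = ", "))
  layers <- env$layers
  for (nm in touched) {
    f <- shift$multiplicative_factors[nm]
    a <- shift$additive_offsets[nm]
    f <- if (is.na(f)) 1 else unname(f)
    a <- if (is.na(a)) 0 else unname(a)
    layers[[nm]] <- layers[[nm]] * f + a
  }
  env_stack(layers, xmin = env$xmin, ymin = env$ymin,
            xres = env$xres, yres = env$yres, mask = env$mask)
}
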