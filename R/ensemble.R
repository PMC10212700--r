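#' TSS-gated ensemble of SDM replicates
#'
#' Admits every evaluated replicate whose maximized TSS meets `tss_min`
#' and averages their suitability surfaces with weights proportional to
#' member TSS. The ensemble's binarization cutoff is the TSS-weighted
#' mean of the members' TSS-maximizing thresholds.
#'
#' @param fits list of evaluated `sdm_fit` objects (see
#'   [evaluate_sdm()]).
#' @param env the `env_stack` to predict on (the calibration grid).
#' @param tss_min admission threshold on member TSS (default 0.8, the
#'   usual "excellent model" bar).
#' @param rule `"weighted_mean"` (default): TSS-weighted mean of member
#'   suitabilities, cutoff = TSS-weighted mean of member thresholds;
#'   `"committee"`: TSS-weighted vote of member ranges each binarized at
#'   its own threshold, cutoff 0.5 (majority).
#' @return An object of class `ensemble_suitability`: `suitability`
#'   (single-layer `env_stack`), `members` (admitted fits),
#'   `member_weights` (sum to 1), `n_members`, `cutoff`, `rule`,
#'   `tss_min`, and `scenario` label (`"current"`).
#' @export
ensemble_sdm <- function(fits, env, tss_min = 0.8,
                         rule = c("weighted_mean", "committee")) {
  rule <- match.arg(rule)
  if (!length(fits)) stop("no fits supplied")
  if (any(vapply(fits, function(f) is.null(f$eval), logical(1))))
    stop("all fits must be evaluated before ensembling")
  tss <- vapply(fits, function(f) f$eval$tss_max, numeric(1))
  admit <- which(tss >= tss_min)
  if (!length(admit))
    stop("no admissible members: every TSS below ", tss_min)
  members <- fits[admit]
  w <- tss[admit] / sum(tss[admit])
  agg <- combine_members(members, w, rule, env)
  structure(list(
    suitability = agg$suitability, members = members,
    member_weights = w, n_members = length(members),
    cutoff = agg$cutoff, rule = rule, tss_min = tss_min,
    scenario = "current"),
    class = "ensemble_suitability")
}

combine_members <- function(members, w, rule, env) {
  preds <- lapply(members, predict_stack, env = env)
  if (rule == "weighted_mean") {
    s <- Reduce(`+`, Map(function(p, wi) p$layers[[1]] * wi, preds, w))
    cutoff <- sum(w * vapply(members, function(f) f$eval$tss_threshold,
                             numeric(1)))
  } else {
    votes <- Map(function(p, f, wi)
      (p$layers[[1]] >= f$eval$tss_threshold) * wi, preds, members, w)
    s <- Reduce(`+`, votes)
    cutoff <- 0.5
  }
  list(suitability = env_stack(list(suitability = s), xmin = env$xmin,
                               ymin = env$ymin, xres = env$xres,
                               yres = env$yres, mask = env$mask),
       cutoff = cutoff)
}

#' @export
print.ensemble_suitability <- function(x, ...) {
  cat(sprintf(
    "<ensemble_suitability> %s: %d member(s), cutoff %.4f (TSS >= %g)\n",
    x$scenario, x$n_members, x$cutoff, x$tss_min))
  invisible(x)
}

#' Project an ensemble onto a scenario stack
#'
#' Each admitted member predicts on the scenario layers; the weights and
#' binarization cutoff frozen at current-climate calibration are reused,
#' so the projection measures pure environmental transfer.
#'
#' @param ens an `ensemble_suitability`.
#' @param scenario an `env_stack` providing every layer used in training.
#' @param label scenario label for downstream tables.
#' @return A new `ensemble_suitability` on the scenario grid.
#' @export
project_ensemble <- function(ens, scenario, label = "scenario") {
  agg <- combine_members(ens$members, ens$member_weights,
                         ens$rule %||% "weighted_mean", scenario)
  out <- ens
  out$suitability <- agg$suitability
  out$scenario <- label
  out
}

#' Binarize an ensemble surface into a range map
#'
#' A cell is suitable when its ensemble suitability reaches the cutoff
#' and the cell is valid.
#'
#' @param ens an `ensemble_suitability`, or a single-layer `env_stack` of
#'   suitabilities (then `cutoff` is required).
#' @param cutoff optional override of the stored cutoff, in (0, 1).
#' @param scenario label carried on the result.
#' @return An object of class `binary_range`: logical `presence` matrix
#'   plus grid georeferencing and the `scenario` label.
#' @export
binarize <- function(ens, cutoff = NULL,
                     scenario = if (inherits(ens, "ensemble_suitability"))
                       ens$scenario else "current") {
  if (inherits(ens, "ensemble_suitability")) {
    suit <- ens$suitability
    if (is.null(cutoff)) cutoff <- ens$cutoff
  } else {
    suit <- ens
    if (is.null(cutoff)) stop("cutoff required when binarizing a raw surface")
  }
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  m <- suit$layers[[1]]
  pres <- suit$mask & !is.na(m) & m >= cutoff
  structure(list(presence = pres, xmin = suit$xmin, ymin = suit$ymin,
                 xres = suit$xres, yres = suit$yres,
                 nrow = suit$nrow, ncol = suit$ncol,
                 cutoff = cutoff, scenario = scenario),
            class = "binary_range")
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf("<binary_range> %s: %d suitable cell(s), %.4g x 10^5 km^2\n",
              x$scenario, sum(x$presence), area_km2(x) / 1e5))
  invisible(x)
}

#' Range area on the sphere
#'
#' Sums spherical quadrilateral cell areas
#' `R^2 * dlon * (sin lat_top - sin lat_bottom)` (authalic radius
#' R = 6371.0088 km) over all suitable cells.
#'
#' @param range a `binary_range`.
#' @return area in km^2.
#' @export
area_km2 <- function(range) {
  grid <- list(nrow = range$nrow, ncol = range$ncol, xres = range$xres,
               yres = range$yres, ymin = range$ymin)
  per_row <- cell_area_km2(structure(grid, class = "env_stack"))
  sum(per_row * rowSums(range$presence))
}

#' Cellwise mean of co-registered scenario stacks
#'
#' Abstract stand-in for assembling several general-circulation-model
#' layer sets into one scenario: the per-layer cellwise mean.
#'
#' @param stacks list of co-registered `env_stack`s with identical layer
#'   names.
#' @return An `env_stack`; the mask is the intersection of member masks.
#' @export
average_scenarios <- function(stacks) {
  if (!length(stacks)) stop("no stacks supplied")
  first <- stacks[[1]]
  for (s in stacks[-1]) {
    stop_unless_coregistered(first, s, "scenario stacks")
    if (!identical(layer_names(first), layer_names(s)))
      stop("co-registration error: scenario stacks have different layers")
  }
  mask <- Reduce(`&`, lapply(stacks, `[[`, "mask"))
  layers <- lapply(stats::setNames(layer_names(first), layer_names(first)),
                   function(nm)
                     Reduce(`+`, lapply(stacks, function(s)
                       s$layers[[nm]])) / length(stacks))
  env_stack(layers, xmin = first$xmin, ymin = first$ymin,
            xres = first$xres, yres = first$yres, mask = mask)
}
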