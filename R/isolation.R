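#' Pairwise ecogeographic isolation
#'
#' For two binarized ranges, `RI = 1 - S / (S + U)` where `S` is the
#' number of cells where both species are predicted to occur and `U` the
#' focal species' unshared suitable cells. The index is asymmetric: each
#' species has its own `U`, so isolation of A from B differs from that of
#' B from A whenever range sizes differ. 0 means the focal range is
#' entirely shared, 1 complete separation. An empty focal range has
#' undefined isolation, reported as `NA` with a flag.
#'
#' @param rangeA,rangeB co-registered `binary_range`s.
#' @param area_weighted count spherical km^2 instead of cells (default
#'   `FALSE`: the index is defined on cell counts).
#' @return list with `ri_A`, `ri_B`, `S`, `U_A`, `U_B` (cell counts, or
#'   km^2 when `area_weighted`), `empty_A`, `empty_B`.
#' @export
ri_ecogeo <- function(rangeA, rangeB, area_weighted = FALSE) {
  if (rangeA$nrow != rangeB$nrow || rangeA$ncol != rangeB$ncol ||
      abs(rangeA$xmin - rangeB$xmin) > 1e-9 ||
      abs(rangeA$ymin - rangeB$ymin) > 1e-9 ||
      abs(rangeA$xres - rangeB$xres) > 1e-9 ||
      abs(rangeA$yres - rangeB$yres) > 1e-9)
    stop("co-registration error: ranges are on different grids")
  A <- rangeA$presence; B <- rangeB$presence
  if (area_weighted) {
    grid <- structure(list(nrow = rangeA$nrow, ncol = rangeA$ncol,
                           xres = rangeA$xres, yres = rangeA$yres,
                           ymin = rangeA$ymin), class = "env_stack")
    cw <- cell_area_km2(grid)
    S <- sum(cw * rowSums(A & B))
    U_A <- sum(cw * rowSums(A & !B))
    U_B <- sum(cw * rowSums(B & !A))
  } else {
    S <- sum(A & B)
    U_A <- sum(A & !B)
    U_B <- sum(B & !A)
  }
  list(ri_A = if (S + U_A > 0) 1 - S / (S + U_A) else NA_real_,
       ri_B = if (S + U_B > 0) 1 - S / (S + U_B) else NA_real_,
       S = S, U_A = U_A, U_B = U_B,
       empty_A = S + U_A == 0, empty_B = S + U_B == 0)
}

#' Isolation matrix over all species pairs
#'
#' Fills all ordered pairs with [ri_ecogeo()]: entry `(i, j)` is the
#' isolation of species `i` from species `j`. The diagonal is `NA`
#' (not applicable).
#'
#' @param ranges named list of co-registered `binary_range`s (>= 2,
#'   unique names).
#' @param scenario label carried on the result.
#' @param area_weighted passed to [ri_ecogeo()].
#' @return An object of class `isolation_matrix`: `scenario`, `species`,
#'   `ri` (square matrix), `S` and `U` (cell counts; `U[i, j]` is species
#'   i's unshared cells against j).
#' @export
isolation_matrix <- function(ranges, scenario = "current",
                             area_weighted = FALSE) {
  if (length(ranges) < 2) stop("need at least 2 species")
  sp <- names(ranges)
  if (is.null(sp) || anyDuplicated(sp) || any(!nzchar(sp)))
    stop("ranges must carry unique species names")
  k <- length(sp)
  ri <- S <- U <- matrix(NA_real_, k, k, dimnames = list(sp, sp))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- ri_ecogeo(ranges[[i]], ranges[[j]], area_weighted = area_weighted)
    ri[i, j] <- r$ri_A; ri[j, i] <- r$ri_B
    S[i, j] <- S[j, i] <- r$S
    U[i, j] <- r$U_A; U[j, i] <- r$U_B
  }
  structure(list(scenario = scenario, species = sp, ri = ri, S = S, U = U),
            class = "isolation_matrix")
}

#' @export
print.isolation_matrix <- function(x, ...) {
  cat(sprintf("<isolation_matrix> %s (%d species)\n", x$scenario,
              length(x$species)))
  print(round(x$ri, 4))
  invisible(x)
}

#' Habitat-area dynamics across scenarios
#'
#' Tabulates per-species range areas per scenario in units of 1e5 km^2
#' with the signed change against the baseline scenario, formatted like
#' `"9.05 [+2.33]"`.
#'
#' @param areas numeric matrix of areas in km^2, species in rows,
#'   scenarios in columns (dimnames required).
#' @param current name of the baseline scenario column.
#' @param scale area unit divisor (default 1e5, i.e. 10^5 km^2).
#' @return data.frame with `species`, `scenario`, `area` (scaled),
#'   `delta` (exact `area - area_current`), and `formatted`.
#' @export
area_dynamics <- function(areas, current = "current", scale = 1e5) {
  areas <- as.matrix(areas)
  if (!current %in% colnames(areas))
    stop("baseline scenario '", current, "' not present")
  a <- areas / scale
  out <- expand.grid(species = rownames(a), scenario = colnames(a),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$area <- as.vector(a)
  out$delta <- as.vector(a - a[, current])
  out$formatted <- ifelse(out$scenario == current,
                          sprintf("%.2f", out$area),
                          sprintf("%.2f [%+.2f]", out$area, out$delta))
  out
}

#' Isolation change between two scenarios
#'
#' Per ordered species pair, the difference in RI between a scenario and
#' the baseline, classified against the identity line (the Figure-4-style
#' comparison: above = increased isolation, below = decreased), plus the
#' mean shift over all ordered pairs.
#'
#' @param current,scenario `isolation_matrix` objects over the same
#'   species set.
#' @return list with `pairs` (data.frame `from`, `to`, `ri_current`,
#'   `ri_scenario`, `delta`, `class`) and `mean_shift` (mean delta over
#'   ordered pairs, `NA`s removed).
#' @export
isolation_shift_summary <- function(current, scenario) {
  if (!identical(current$species, scenario$species))
    stop("isolation matrices cover different species sets")
  sp <- current$species
  pairs <- expand.grid(from = sp, to = sp, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  idx <- cbind(match(pairs$from, sp), match(pairs$to, sp))
  pairs$ri_current <- current$ri[idx]
  pairs$ri_scenario <- scenario$ri[idx]
  pairs$delta <- pairs$ri_scenario - pairs$ri_current
  pairs$class <- ifelse(is.na(pairs$delta), NA_character_,
                        ifelse(pairs$delta > 0, "above",
                               ifelse(pairs$delta < 0, "below", "on")))
  rownames(pairs) <- NULL
  list(pairs = pairs, mean_shift = mean(pairs$delta, na.rm = TRUE))
}
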