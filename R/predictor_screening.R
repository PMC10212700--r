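#' Flag collinear variable pairs by Pearson correlation
#'
#' Computes Pearson correlations on complete cases and flags every
#' unordered pair at or above the threshold. Zero-variance variables have
#' undefined correlations and are flagged for removal separately.
#'
#' @param values data.frame or matrix of numeric variables (samples in
#'   rows).
#' @param r_threshold absolute correlation at or above which a pair is
#'   flagged (default 0.75, the usual screening convention).
#' @return list with `flagged` (data.frame `var1`, `var2`, `r`),
#'   `zero_variance` (variable names), and `corr` (the full correlation
#'   matrix).
#' @export
pearson_screen <- function(values, r_threshold = 0.75) {
  x <- as.matrix(as.data.frame(values))
  if (ncol(x) < 2) stop("need at least 2 variables")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete samples")
  sds <- apply(x, 2, stats::sd)
  zv <- colnames(x)[sds == 0]
  ok <- sds > 0
  corr <- matrix(NA_real_, ncol(x), ncol(x),
                 dimnames = list(colnames(x), colnames(x)))
  corr[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
  flagged <- data.frame(var1 = character(0), var2 = character(0),
                        r = numeric(0))
  nm <- colnames(x)
  for (i in seq_len(ncol(x) - 1)) for (j in (i + 1):ncol(x)) {
    r <- corr[i, j]
    if (!is.na(r) && abs(r) >= r_threshold)
      flagged <- rbind(flagged,
                       data.frame(var1 = nm[i], var2 = nm[j], r = r))
  }
  list(flagged = flagged, zero_variance = zv, corr = corr)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` with `R2_j` from the least-squares regression
#' of variable `j` on all the others. Exact linear dependence yields
#' `Inf`.
#'
#' @param values data.frame or matrix of numeric variables.
#' @return named numeric vector of VIFs.
#' @export
vif_all <- function(values) {
  x <- as.matrix(as.data.frame(values))
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 variables")
  if (nrow(x) <= ncol(x)) stop("need more samples than variables")
  vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss == 0) return(NA_real_)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(x))
}

#' Screen predictors for collinearity
#'
#' Two-stage screening: (1) while any retained pair has `|r| >=
#' r_threshold`, take the worst pair and drop the member with the larger
#' mean absolute correlation to all other retained variables; (2) while
#' any retained VIF exceeds `vif_threshold`, drop the variable with the
#' largest VIF. Zero-variance variables are dropped first. All ties break
#' by input order, so the result is deterministic.
#'
#' @param values data.frame or matrix of numeric variables.
#' @param r_threshold pairwise absolute-correlation ceiling (default
#'   0.75).
#' @param vif_threshold VIF ceiling (default 10).
#' @return An object of class `screening_result`: list with `retained`
#'   (ordered names), `dropped` (data.frame `variable`, `reason`),
#'   `corr_matrix` (input correlations), `vif` (VIF per retained
#'   variable; `NA` when fewer than 2 retained).
#' @export
screen_predictors <- function(values, r_threshold = 0.75,
                              vif_threshold = 10) {
  x <- as.data.frame(values)
  input <- names(x)
  dropped <- data.frame(variable = character(0), reason = character(0))
  if (length(input) < 2) {
    warning("fewer than 2 variables supplied; nothing to screen")
    return(structure(list(retained = input, dropped = dropped,
                          corr_matrix = NULL,
                          vif = stats::setNames(rep(NA_real_,
                                                    length(input)), input)),
                     class = "screening_result"))
  }
  scr <- pearson_screen(x, r_threshold)
  for (v in scr$zero_variance) {
    dropped <- rbind(dropped,
                     data.frame(variable = v, reason = "zero variance"))
  }
  keep <- setdiff(input, scr$zero_variance)
  corr0 <- scr$corr
  # stage 1: pairwise correlation rule
  repeat {
    if (length(keep) < 2) break
    cc <- abs(stats::cor(x[stats::complete.cases(x), keep, drop = FALSE]))
    diag(cc) <- 0
    if (max(cc) < r_threshold) break
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    pair <- keep[sort(worst)]
    meanabs <- rowMeans(cc)[pair]
    drop <- if (meanabs[2] > meanabs[1]) pair[2] else
      if (meanabs[1] > meanabs[2]) pair[1] else pair[2]  # tie: later in order
    dropped <- rbind(dropped, data.frame(
      variable = drop,
      reason = sprintf("|r| = %.3f with %s", max(cc),
                       setdiff(pair, drop))))
    keep <- setdiff(keep, drop)
  }
  # stage 2: VIF rule
  repeat {
    if (length(keep) < 2) break
    v <- vif_all(x[, keep, drop = FALSE])
    if (max(v) <= vif_threshold) break
    drop <- keep[which.max(v)]
    dropped <- rbind(dropped, data.frame(
      variable = drop, reason = sprintf("VIF = %.2f", max(v))))
    keep <- setdiff(keep, drop)
  }
  if (length(keep) < 2)
    warning("fewer than 2 variables survive screening")
  vif <- if (length(keep) >= 2) vif_all(x[, keep, drop = FALSE])
         else stats::setNames(rep(NA_real_, length(keep)), keep)
  structure(list(retained = keep, dropped = dropped,
                 corr_matrix = corr0, vif = vif),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> retained %d: %s\n", length(x$retained),
              paste(x$retained, collapse = ", ")))
  if (nrow(x$dropped))
    cat(paste0("  dropped ", x$dropped$variable, " (", x$dropped$reason,
               ")\n"), sep = "")
  invisible(x)
}

#' Principal component analysis of habitat variables
#'
#' Variables are standardized to zero mean and unit variance and the
#' correlation matrix is eigen-decomposed, so axis k explains
#' `lambda_k / sum(lambda)` of the variance and the shares sum to one.
#'
#' @param values per-occurrence variable table (>= 3 samples).
#' @return An object of class `ordination_result` with `axis_loadings`
#'   (orthonormal columns), `variance_explained`, and `scores`.
#' @export
pca_habitat <- function(values) {
  x <- as.matrix(as.data.frame(values))
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  load <- eg$vectors
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(x))))
  structure(list(method = "PCA",
                 axis_loadings = load,
                 variance_explained = eg$values / sum(eg$values),
                 scores = z %*% load,
                 group_labels = NULL, confusion = NULL),
            class = "ordination_result")
}

#' Discriminant function analysis of habitat variables
#'
#' Linear discriminant axes maximizing the between- to within-group
#' variance ratio, with priors proportional to group sizes; the
#' training-set classification table is reported.
#'
#' @param values per-occurrence variable table.
#' @param species_labels group label per sample (>= 2 groups, each larger
#'   than the number of variables).
#' @return An `ordination_result` with `scores` on the discriminant axes,
#'   `variance_explained` (proportion of between-group variance per
#'   axis), `group_labels`, and `confusion` (true x predicted table).
#' @export
dfa_habitat <- function(values, species_labels) {
  x <- as.data.frame(values)
  g <- factor(species_labels)
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) <= ncol(x)))
    stop("every group needs more samples than variables")
  fit <- tryCatch(MASS::lda(x, grouping = g),
                  error = function(e)
                    stop("singular within-group covariance: ",
                         conditionMessage(e), call. = FALSE))
  pred <- stats::predict(fit, x)
  prop <- fit$svd^2 / sum(fit$svd^2)
  structure(list(method = "DFA",
                 axis_loadings = fit$scaling,
                 variance_explained = prop,
                 scores = pred$x,
                 group_labels = g,
                 confusion = table(truth = g, predicted = pred$class)),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %s, %d axes; variance explained: %s\n",
              x$method, length(x$variance_explained),
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  invisible(x)
}
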