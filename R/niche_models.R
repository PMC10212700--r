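#' Sample background (pseudo-absence) points
#'
#' Draws `n` cell-centre points uniformly from the valid mask; sampling is
#' without replacement while `n` does not exceed the number of valid cells
#' and with replacement otherwise.
#'
#' @param env an `env_stack`.
#' @param n number of background points (>= 1).
#' @param seed integer seed.
#' @return data.frame with `lon`, `lat` and one column per layer.
#' @export
sample_background <- function(env, n, seed) {
  stopifnot(n >= 1)
  idx <- which(env$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no valid cells")
  draw <- with_seed(seed,
                    sample.int(nrow(idx), size = n,
                               replace = n > nrow(idx)))
  out <- data.frame(lon = cell_lon(env, idx[draw, 2]),
                    lat = cell_lat(env, idx[draw, 1]))
  ij <- idx[draw, , drop = FALSE]
  for (nm in names(env$layers)) out[[nm]] <- env$layers[[nm]][ij]
  out
}

#' Split presences and background into training and testing sets
#'
#' Presences and background points are split independently at
#' `train_frac` (rounded to nearest, at least one record per side), the
#' standard subsampling scheme for SDM replicate evaluation.
#'
#' @param presence,background data.frames of extracted covariates.
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `test`, each a list of `presence` and
#'   `background` data.frames; the two partitions are disjoint and their
#'   union is the input.
#' @export
split_data <- function(presence, background, train_frac = 0.7, seed) {
  if (nrow(presence) < 2) stop("need at least 2 presence records")
  split1 <- function(df, s) {
    n <- nrow(df)
    ntr <- min(max(round(n * train_frac), 1L), n - 1L)
    tr <- with_seed(s, sample.int(n, ntr))
    list(train = df[tr, , drop = FALSE],
         test = df[-tr, , drop = FALSE])
  }
  p <- split1(presence, derive_seed(seed, 1))
  b <- split1(background, derive_seed(seed, 2))
  list(train = list(presence = p$train, background = b$train),
       test = list(presence = p$test, background = b$test))
}

# ---- feature construction ---------------------------------------------------

hinge_knots <- function(x, n_knots) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_knots + 2L),
                        names = FALSE, type = 7)
  unique(qs[-c(1, n_knots + 2L)])
}

# design matrix for a family given raw covariates
build_features <- function(df, spec) {
  x <- as.matrix(df[, spec$vars, drop = FALSE])
  out <- list()
  for (v in spec$vars) {
    xc <- (x[, v] - spec$center[v]) / spec$scale[v]
    out[[v]] <- xc
    if (spec$quadratic) out[[paste0(v, "^2")]] <- xc^2
    for (t in spec$knots[[v]]) {
      tc <- (t - spec$center[v]) / spec$scale[v]
      out[[sprintf("h(%s-%.4g)", v, t)]] <- pmax(xc - tc, 0)
      out[[sprintf("h(%.4g-%s)", t, v)]] <- pmax(tc - xc, 0)
    }
  }
  do.call(cbind, out)
}

make_feature_spec <- function(train, vars, quadratic, n_knots) {
  x <- as.matrix(train[, vars, drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  knots <- if (n_knots > 0)
    lapply(stats::setNames(vars, vars), function(v)
      hinge_knots(x[, v], n_knots))
  else stats::setNames(rep(list(numeric(0)), length(vars)), vars)
  list(vars = vars, center = ctr, scale = scl,
       quadratic = quadratic, knots = knots)
}

# ---- model families ---------------------------------------------------------

fit_glm_family <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial()))
  separated <- !fit$converged ||
    (min(fit$fitted.values[y == 1]) > 1 - 1e-8 &&
       max(fit$fitted.values[y == 0]) < 1e-8)
  if (separated || anyNA(fit$coefficients) ||
      any(!is.finite(fit$coefficients), na.rm = TRUE)) {
    # complete separation: fall back to a ridge-penalized fit
    g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = c(1, 0.1, 0.01))
    beta <- as.numeric(stats::coef(g, s = 0.01))
    list(coef = stats::setNames(beta, c("(Intercept)", colnames(X))),
         fallback = "ridge-penalized (separation)")
  } else {
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    list(coef = cf, fallback = NULL)
  }
}

fit_maxent_family <- function(X, y, regularization) {
  lam <- sort(unique(c(regularization * c(100, 10, 1))), decreasing = TRUE)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 1, lambda = lam,
                      standardize = TRUE)
  beta <- as.numeric(stats::coef(g, s = min(lam)))
  list(coef = stats::setNames(beta, c("(Intercept)", colnames(X))),
       fallback = NULL)
}

# forward/backward hinge-basis least squares pruned by GCV (additive,
# degree 1) on the 0/1 response
fit_mars_family <- function(X, y, max_terms = 15, penalty = 2) {
  n <- length(y)
  sel <- integer(0)
  rss_path <- list()
  Xc <- cbind(`(Intercept)` = rep(1, n))
  current_rss <- sum((y - mean(y))^2)
  candidates <- seq_len(ncol(X))
  while (length(sel) < max_terms && length(candidates)) {
    best <- NULL; best_rss <- current_rss
    for (j in candidates) {
      f <- stats::.lm.fit(cbind(Xc, X[, j]), y)
      rss <- sum(f$residuals^2)
      if (rss < best_rss - 1e-12) { best <- j; best_rss <- rss }
    }
    if (is.null(best)) break
    sel <- c(sel, best)
    candidates <- setdiff(candidates, best)
    Xc <- cbind(Xc, X[, best])
    current_rss <- best_rss
  }
  # backward pruning by generalized cross-validation
  gcv <- function(rss, m) {
    c_m <- (m + 1) + penalty * m  # effective parameters for m basis terms
    if (c_m >= n) return(Inf)
    (rss / n) / (1 - c_m / n)^2
  }
  best_set <- sel
  fit_rss <- function(s) {
    f <- stats::.lm.fit(cbind(1, X[, s, drop = FALSE]), y)
    sum(f$residuals^2)
  }
  best_gcv <- gcv(fit_rss(best_set), length(best_set))
  cur <- sel
  while (length(cur) > 0) {
    step_best <- NULL; step_gcv <- Inf
    for (drop in seq_along(cur)) {
      s <- cur[-drop]
      g <- gcv(fit_rss(s), length(s))
      if (g < step_gcv) { step_gcv <- g; step_best <- s }
    }
    cur <- step_best
    if (step_gcv < best_gcv) { best_gcv <- step_gcv; best_set <- cur }
  }
  f <- stats::.lm.fit(cbind(`(Intercept)` = 1,
                            X[, best_set, drop = FALSE]), y)
  cf <- stats::setNames(numeric(ncol(X) + 1),
                        c("(Intercept)", colnames(X)))
  cf[c("(Intercept)", colnames(X)[best_set])] <- f$coefficients
  list(coef = cf, fallback = NULL, n_terms = length(best_set))
}

#' Fit one SDM replicate
#'
#' Fits a single presence/background model of one of three families:
#' \describe{
#'   \item{GLM}{binomial regression with linear and quadratic terms per
#'     variable.}
#'   \item{MAXENT}{penalized (lasso) binomial background-contrast
#'     regression with linear, quadratic and two-sided hinge features —
#'     the core of the Maxent approach; suitability is the fitted
#'     occurrence probability rescaled to [0, 1].}
#'   \item{MARS}{forward/backward hinge-basis least-squares regression
#'     pruned by generalized cross-validation.}
#' }
#' Complete separation in the GLM triggers a ridge-penalized fallback,
#' recorded in `metadata$fallback`.
#'
#' @param family `"GLM"`, `"MAXENT"`, or `"MARS"`.
#' @param presence,background training data.frames holding the covariate
#'   columns.
#' @param vars covariate column names to use; default: all shared numeric
#'   columns except coordinates.
#' @param regularization penalty strength for the MAXENT family.
#' @param n_knots interior hinge knots per variable (MAXENT / MARS).
#' @param max_terms forward-pass cap for MARS.
#' @return An object of class `sdm_fit`; use [predict_sdm()] /
#'   [predict_stack()] for predictions and [evaluate_sdm()] for test
#'   metrics.
#' @export
fit_replicate <- function(family = c("GLM", "MAXENT", "MARS"),
                          presence, background, vars = NULL,
                          regularization = 0.001, n_knots = 4,
                          max_terms = 15) {
  family <- match.arg(family)
  if (is.null(vars)) {
    shared <- intersect(names(presence), names(background))
    vars <- setdiff(shared[vapply(presence[shared], is.numeric, logical(1))],
                    c("lon", "lat", "row", "col"))
  }
  if (!length(vars)) stop("no covariates to fit")
  train <- rbind(presence[, vars, drop = FALSE],
                 background[, vars, drop = FALSE])
  if (any(!stats::complete.cases(train)))
    stop("training covariates contain missing values")
  y <- c(rep(1, nrow(presence)), rep(0, nrow(background)))
  if (stats::var(y) == 0) stop("training data are degenerate (one class)")
  fspec <- make_feature_spec(train, vars, quadratic = TRUE,
                             n_knots = if (family == "GLM") 0 else n_knots)
  X <- build_features(train, fspec)
  fit <- switch(family,
                GLM = fit_glm_family(X, y),
                MAXENT = fit_maxent_family(X, y, regularization),
                MARS = fit_mars_family(X, y, max_terms = max_terms))
  out <- structure(list(family = family, vars = vars,
                        feature_spec = fspec,
                        coefficients = fit$coef,
                        metadata = list(fallback = fit$fallback,
                                        n_presence = nrow(presence),
                                        n_background = nrow(background)),
                        eval = NULL, rescale = 1),
                   class = "sdm_fit")
  if (family == "MAXENT") {
    # rescale so the maximum fitted training probability maps to 1
    p <- predict_sdm(out, train)
    out$rescale <- max(p, 1e-12)
  }
  out
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> %s on %s (%d presences / %d background)\n",
              x$family, paste(x$vars, collapse = ", "),
              x$metadata$n_presence, x$metadata$n_background))
  if (!is.null(x$eval))
    cat(sprintf("  AUC %.3f, TSSmax %.3f @ %.3f\n", x$eval$auc,
                x$eval$tss_max, x$eval$tss_threshold))
  invisible(x)
}

#' Predict suitability for new records
#'
#' @param fit an `sdm_fit`.
#' @param newdata data.frame with the fit's covariate columns.
#' @return numeric suitability in [0, 1].
#' @export
predict_sdm <- function(fit, newdata) {
  X <- build_features(newdata, fit$feature_spec)
  eta <- drop(cbind(1, X) %*% fit$coefficients)
  p <- if (fit$family == "MARS") pmin(pmax(eta, 0), 1)
       else stats::plogis(eta)
  if (fit$family == "MAXENT") p <- pmin(p / fit$rescale, 1)
  unname(p)
}

#' Predict suitability over a stack
#'
#' @param fit an `sdm_fit`.
#' @param env an `env_stack` providing every covariate layer used in
#'   training.
#' @return single-layer `env_stack` (`"suitability"`).
#' @export
predict_stack <- function(fit, env) {
  missing <- setdiff(fit$vars, layer_names(env))
  if (length(missing))
    stop("stack is missing layer(s) used in training: ",
         paste(missing, collapse = ", "))
  vals <- stack_values(env, valid_only = TRUE)
  p <- predict_sdm(fit, vals)
  m <- matrix(NA_real_, env$nrow, env$ncol)
  m[cbind(vals$row, vals$col)] <- p
  env_stack(list(suitability = m), xmin = env$xmin, ymin = env$ymin,
            xres = env$xres, yres = env$yres, mask = env$mask)
}

# ---- evaluation -------------------------------------------------------------

#' Rank-based AUC
#'
#' Area under the ROC curve by rank comparison of presence versus
#' background scores; ties count one half.
#'
#' @param pres,bg numeric score vectors.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(pres, bg) {
  np <- length(pres); nb <- length(bg)
  if (np == 0 || nb == 0) stop("need scores from both classes")
  r <- rank(c(pres, bg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Maximized True Skill Statistic
#'
#' Scans all distinct scores as candidate thresholds (classification rule:
#' score >= threshold is presence) and returns the maximum of
#' sensitivity + specificity - 1 with the smallest maximizing threshold.
#'
#' @param pres,bg numeric score vectors.
#' @return list with `tss_max` and `tss_threshold`.
#' @export
tss_scan <- function(pres, bg) {
  if (!length(pres) || !length(bg)) stop("need scores from both classes")
  thr <- sort(unique(c(pres, bg)))
  tss <- vapply(thr, function(t)
    mean(pres >= t) + mean(bg < t) - 1, numeric(1))
  best <- max(tss)
  list(tss_max = best, tss_threshold = thr[which(tss == best)[1]])
}

#' Evaluate an SDM replicate on held-out data
#'
#' @param fit an `sdm_fit`.
#' @param test_presence,test_background held-out data.frames (each
#'   non-empty).
#' @return The fit with an `eval` element (class `eval_metrics`: `auc`,
#'   `tss_max`, `tss_threshold`).
#' @export
evaluate_sdm <- function(fit, test_presence, test_background) {
  if (!nrow(test_presence) || !nrow(test_background))
    stop("test set needs at least one presence and one background record")
  sp <- predict_sdm(fit, test_presence)
  sb <- predict_sdm(fit, test_background)
  ts <- tss_scan(sp, sb)
  fit$eval <- structure(list(auc = auc_rank(sp, sb),
                             tss_max = ts$tss_max,
                             tss_threshold = ts$tss_threshold),
                        class = "eval_metrics")
  fit
}
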