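#' Normalize a suitability surface into a niche distribution
#'
#' Divides nonnegative cell suitabilities by their sum over the valid
#' mask, giving the probability surface that Schoener's D, Warren's I and
#' Levins' B operate on.
#'
#' @param suit a single-layer `env_stack`, a numeric matrix, or a numeric
#'   vector of nonnegative weights.
#' @return An object of class `niche_distribution`: `p` (weights summing
#'   to 1 over valid cells), `mask` (or `NULL` for plain vectors), and
#'   `n` (number of cells carrying the distribution).
#' @export
niche_distribution <- function(suit) {
  if (is_env_stack(suit)) {
    w <- suit$layers[[1]][suit$mask]
    mask <- suit$mask
  } else if (is.matrix(suit)) {
    mask <- !is.na(suit)
    w <- suit[mask]
  } else {
    w <- as.numeric(suit)
    mask <- NULL
  }
  if (any(!is.finite(w)) || any(w < 0))
    stop("suitabilities must be finite and nonnegative")
  s <- sum(w)
  if (s <= 0) stop("suitability is zero everywhere")
  structure(list(p = w / s, mask = mask, n = length(w)),
            class = "niche_distribution")
}

as_niche_distribution <- function(x) {
  if (inherits(x, "niche_distribution")) x else niche_distribution(x)
}

check_shared_mask <- function(p, q) {
  if (!is.null(p$mask) || !is.null(q$mask)) {
    if (is.null(p$mask) || is.null(q$mask) || !identical(p$mask, q$mask))
      stop("distributions must share one validity mask")
  } else if (p$n != q$n) {
    stop("distributions must have the same number of cells")
  }
  invisible(TRUE)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum |p_i - q_i|`, from 0 (no overlap) to 1 (identical
#' surfaces).
#'
#' @param p,q `niche_distribution`s (or inputs coercible by
#'   [niche_distribution()]) on a shared mask.
#' @return D in [0, 1].
#' @export
schoener_D <- function(p, q) {
  p <- as_niche_distribution(p); q <- as_niche_distribution(q)
  check_shared_mask(p, q)
  max(0, min(1, 1 - 0.5 * sum(abs(p$p - q$p))))
}

#' Warren's I niche overlap
#'
#' Hellinger-based overlap `I = 1 - 0.5 * sum (sqrt(p_i) - sqrt(q_i))^2`,
#' equal to the Bhattacharyya coefficient `sum sqrt(p_i q_i)`; from 0 (no
#' overlap) to 1 (identical). Always `I >= D`.
#'
#' @inheritParams schoener_D
#' @return I in [0, 1].
#' @export
warren_I <- function(p, q) {
  p <- as_niche_distribution(p); q <- as_niche_distribution(q)
  check_shared_mask(p, q)
  max(0, min(1, 1 - 0.5 * sum((sqrt(p$p) - sqrt(q$p))^2)))
}

#' Levins' niche breadth
#'
#' `B_raw = 1 / sum p_i^2` (inverse Simpson concentration, from 1 for a
#' point niche to the cell count for a uniform one) and the standardized
#' `B_std = (B_raw - 1) / (n - 1)` in [0, 1].
#'
#' @param p a `niche_distribution` (or coercible input).
#' @return An object of class `niche_breadth`: `B_raw`, `B_std` (`NA`
#'   with a note when n = 1), `n_cells`, and an empty `bootstrap_samples`
#'   slot.
#' @export
levins_B <- function(p) {
  p <- as_niche_distribution(p)
  B_raw <- 1 / sum(p$p^2)
  B_std <- if (p$n > 1) (B_raw - 1) / (p$n - 1) else NA_real_
  structure(list(B_raw = B_raw, B_std = B_std, n_cells = p$n,
                 bootstrap_samples = numeric(0),
                 note = if (p$n == 1) "B_std undefined for a single cell"),
            class = "niche_breadth")
}

#' @export
print.niche_breadth <- function(x, ...) {
  cat(sprintf("<niche_breadth> B_raw = %.4g, B_std = %.4g over %d cells\n",
              x$B_raw, x$B_std, x$n_cells))
  if (length(x$bootstrap_samples))
    cat(sprintf("  %d bootstrap replicate(s), median B_std %.4g\n",
                length(x$bootstrap_samples),
                stats::median(x$bootstrap_samples)))
  invisible(x)
}

# fit one single-family suitability surface and return its normalized
# distribution (shared helper of the identity test and breadth bootstrap)
fit_niche_surface <- function(coords, env, background, model_family) {
  ext <- extract_at_points(env, coords)
  fit <- fit_replicate(model_family, presence = ext,
                       background = background,
                       vars = layer_names(env))
  niche_distribution(predict_stack(fit, env))
}

#' Monte Carlo niche identity test
#'
#' Tests whether two species' modelled niches are identical. Observed D
#' and I come from single-family (default GLM) suitability surfaces
#' fitted to each species against one shared background sample. The null
#' distribution pools both species' occurrences, randomly repartitions
#' them into groups of the original sizes, refits both surfaces and
#' recomputes D and I per pseudoreplicate. The one-tailed p-value
#' `p = (1 + #\{null <= observed\}) / (n_reps + 1)` is small when the
#' observed overlap falls below the null, i.e. when niches diverge.
#'
#' @param occA,occB `occurrence_set`s (non-empty).
#' @param env an `env_stack` of the model covariates.
#' @param background background data.frame (held fixed across
#'   pseudoreplicates).
#' @param n_reps number of pseudoreplicates (default 100).
#' @param model_family model family for all surfaces (default `"GLM"`).
#' @param seed integer seed.
#' @param alpha significance level for the reported flags (default 0.05).
#' @return An object of class `niche_overlap`: `D_obs`, `I_obs`,
#'   `null_D`, `null_I`, `p_D`, `p_I`, `significant_D`, `significant_I`,
#'   `n_reps`.
#' @export
identity_test <- function(occA, occB, env, background, n_reps = 100,
                          model_family = "GLM", seed = 1L, alpha = 0.05) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  if (!nrow(occA$points) || !nrow(occB$points))
    stop("both occurrence sets must be non-empty")
  pA <- fit_niche_surface(occA$points, env, background, model_family)
  pB <- fit_niche_surface(occB$points, env, background, model_family)
  D_obs <- schoener_D(pA, pB)
  I_obs <- warren_I(pA, pB)
  pool <- rbind(occA$points, occB$points)
  nA <- nrow(occA$points)
  null_D <- null_I <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- with_seed(derive_seed(seed, r),
                     sample.int(nrow(pool), nA))
    qA <- fit_niche_surface(pool[idx, , drop = FALSE], env, background,
                            model_family)
    qB <- fit_niche_surface(pool[-idx, , drop = FALSE], env, background,
                            model_family)
    null_D[r] <- schoener_D(qA, qB)
    null_I[r] <- warren_I(qA, qB)
  }
  p_D <- (1 + sum(null_D <= D_obs)) / (n_reps + 1)
  p_I <- (1 + sum(null_I <= I_obs)) / (n_reps + 1)
  structure(list(D_obs = D_obs, I_obs = I_obs,
                 null_D = null_D, null_I = null_I,
                 p_D = p_D, p_I = p_I,
                 significant_D = p_D < alpha, significant_I = p_I < alpha,
                 n_reps = n_reps),
            class = "niche_overlap")
}

#' @export
print.niche_overlap <- function(x, ...) {
  cat(sprintf("<niche_overlap> D = %.4f (p = %.4f%s), I = %.4f (p = %.4f%s), %d pseudoreplicates\n",
              x$D_obs, x$p_D, if (x$significant_D) " *" else "",
              x$I_obs, x$p_I, if (x$significant_I) " *" else "",
              x$n_reps))
  invisible(x)
}

#' Bootstrap Levins' niche breadth
#'
#' Resamples a species' occurrences with replacement, refits the
#' single-family suitability surface and recomputes standardized Levins'
#' B per replicate. Replicates whose model fit fails are skipped and
#' counted.
#'
#' @param occ an `occurrence_set`.
#' @param env an `env_stack`.
#' @param background background data.frame (fixed across replicates).
#' @param model_family model family (default `"GLM"`).
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return A `niche_breadth` for the full sample whose
#'   `bootstrap_samples` holds the replicate `B_std` values; attribute
#'   `n_failed` counts skipped replicates.
#' @export
bootstrap_breadth <- function(occ, env, background, model_family = "GLM",
                              n_boot = 100, seed = 1L) {
  stopifnot(n_boot >= 1)
  full <- levins_B(fit_niche_surface(occ$points, env, background,
                                     model_family))
  n <- nrow(occ$points)
  samples <- numeric(0); failed <- 0L
  for (r in seq_len(n_boot)) {
    idx <- with_seed(derive_seed(seed, r),
                     sample.int(n, n, replace = TRUE))
    b <- tryCatch(
      levins_B(fit_niche_surface(occ$points[idx, , drop = FALSE], env,
                                 background, model_family))$B_std,
      error = function(e) NA_real_)
    if (is.na(b)) failed <- failed + 1L else samples <- c(samples, b)
  }
  full$bootstrap_samples <- samples
  attr(full, "n_failed") <- failed
  full
}

#' Mann-Whitney U comparison of niche breadths
#'
#' Two-sided Mann-Whitney U test between two samples of standardized
#' breadths (e.g. bootstrap replicates). Uses exhaustive enumeration of
#' all label assignments (exact even with ties) when that is feasible,
#' otherwise the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param samplesA,samplesB numeric vectors (non-empty).
#' @param max_enumeration largest `choose(nA + nB, nA)` for which the
#'   exact null distribution is enumerated.
#' @return list with `U` (statistic for sample A), `p_value`, and
#'   `method`.
#' @export
breadth_difference <- function(samplesA, samplesB,
                               max_enumeration = 2e5) {
  a <- as.numeric(samplesA); b <- as.numeric(samplesB)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (choose(n, n1) <= max_enumeration) {
    combs <- utils::combn(n, n1)
    rs <- colSums(matrix(r[combs], nrow = n1))
    Us <- rs - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p_value = p, method = method)
}
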