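test_that("background sampling respects the mask and the seed", {
  mask <- matrix(TRUE, 6, 6); mask[1:3, 1:3] <- FALSE
  env <- tiny_env(nr = 6, nc = 6, mask = mask)
  bg <- sample_background(env, 500, seed = 1)
  ci <- cell_index(env, bg$lon, bg$lat)
  expect_true(all(ci$valid))
  expect_identical(sample_background(env, 500, seed = 1), bg)
  expect_false(identical(sample_background(env, 500, seed = 2), bg))
  # empty mask contract
  none <- tiny_env(mask = matrix(FALSE, 4, 5))
  expect_error(sample_background(none, 1, seed = 1), "no valid cells")
})

test_that("oversampled background is uniform over valid cells", {
  env <- tiny_env(nr = 5, nc = 5, xres = 1, yres = 1)
  n_cells <- 25
  bg <- sample_background(env, 4 * n_cells, seed = 7)
  counts <- table(factor(paste(round(bg$lon, 6), round(bg$lat, 6)),
                         levels = unique(paste(round(bg$lon, 6),
                                               round(bg$lat, 6)))))
  expect_equal(sum(counts), 4 * n_cells)
  p <- suppressWarnings(chisq.test(as.vector(counts))$p.value)
  expect_gt(p, 0.01)
})

test_that("70/30 splitting partitions presences and background", {
  pres <- data.frame(bio1 = rnorm(10), id = 1:10)
  bg <- data.frame(bio1 = rnorm(40), id = 101:140)
  sp <- split_data(pres, bg, 0.7, seed = 1)
  expect_equal(nrow(sp$train$presence), 7)
  expect_equal(nrow(sp$test$presence), 3)
  expect_setequal(c(sp$train$presence$id, sp$test$presence$id), pres$id)
  expect_length(intersect(sp$train$background$id, sp$test$background$id), 0)
  expect_setequal(c(sp$train$background$id, sp$test$background$id), bg$id)
  # different seeds: same sizes, different membership
  sp2 <- split_data(pres, bg, 0.7, seed = 2)
  expect_equal(nrow(sp2$train$presence), 7)
  expect_false(setequal(sp$train$presence$id, sp2$train$presence$id) &&
                 setequal(sp$train$background$id, sp2$train$background$id))
  expect_error(split_data(pres[1, , drop = FALSE], bg, 0.7, 1),
               "at least 2")
})

test_that("GLM replicates recover a known Gaussian niche on one variable", {
  env <- model_landscape(seed = 21, nr = 100, nc = 100)
  sp <- virtual_species("g", c(bio1 = 9), c(bio1 = 2))
  dat <- species_data(env, sp, n_occ = 100, n_bg = 5000, seed = 4)
  fit <- fit_replicate("GLM", dat$presence, dat$background, vars = "bio1")
  b <- fit$coefficients
  quad <- b[["bio1^2"]]
  expect_lt(quad, 0)  # concave response
  # optimum of a + b1 x + b2 x^2 (standardized scale) mapped back
  opt <- -b[["bio1"]] / (2 * quad) * fit$feature_spec$scale[["bio1"]] +
    fit$feature_spec$center[["bio1"]]
  expect_lt(abs(opt - 9), 0.5 * 2)
  # determinism: identical call, identical coefficients
  fit2 <- fit_replicate("GLM", dat$presence, dat$background, vars = "bio1")
  expect_identical(fit2$coefficients, fit$coefficients)
})

test_that("shuffled labels give chance-level AUC", {
  env <- model_landscape(seed = 22, nr = 40, nc = 40)
  sp <- niche_species("s")
  dat <- species_data(env, sp, n_occ = 40, n_bg = 400, seed = 5)
  all_rows <- rbind(dat$presence[, c("bio1", "bio12")],
                    dat$background[, c("bio1", "bio12")])
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    idx <- sample(nrow(all_rows), nrow(dat$presence))
    spl <- split_data(all_rows[idx, ], all_rows[-idx, ], 0.7, seed = s)
    f <- fit_replicate("GLM", spl$train$presence, spl$train$background)
    evaluate_sdm(f, spl$test$presence, spl$test$background)$eval$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("every family predicts in [0, 1] and discriminates a clear niche", {
  env <- model_landscape(seed = 23, nr = 60, nc = 60)
  sp <- niche_species("s")
  dat <- species_data(env, sp, n_occ = 80, n_bg = 1500, seed = 6)
  split <- split_data(dat$presence, dat$background, 0.7, seed = 1)
  for (fam in c("GLM", "MAXENT", "MARS")) {
    f <- fit_replicate(fam, split$train$presence, split$train$background)
    f <- evaluate_sdm(f, split$test$presence, split$test$background)
    grid <- predict_stack(f, env)
    vals <- grid$layers$suitability[grid$mask]
    expect_true(all(vals >= 0 & vals <= 1), info = fam)
    expect_gt(f$eval$auc, 0.75)
  }
})

test_that("rank AUC and scanned TSS match exhaustive oracles", {
  # worked example
  pres <- c(0.9, 0.8, 0.4); bg <- c(0.7, 0.3, 0.2)
  expect_equal(auc_rank(pres, bg), 8 / 9)
  ts <- tss_scan(pres, bg)
  expect_equal(ts$tss_max, 2 / 3)
  # perfect and uninformative classifiers
  expect_equal(auc_rank(c(2, 3), c(0, 1)), 1)
  expect_equal(tss_scan(c(2, 3), c(0, 1))$tss_max, 1)
  expect_equal(auc_rank(rep(1, 4), rep(1, 6)), 0.5)
  expect_equal(tss_scan(rep(1, 4), rep(1, 6))$tss_max, 0)
  # 200 random instances (<= 50 points, with ties): AUC equals exhaustive
  # pair counting, TSS equals exhaustive threshold scan
  pair_auc <- function(p, b) {
    s <- 0
    for (x in p) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
    s / (length(p) * length(b))
  }
  brute_tss <- function(p, b) {
    max(vapply(sort(unique(c(p, b))), function(t)
      mean(p >= t) + mean(b < t) - 1, numeric(1)))
  }
  set.seed(10)
  for (i in 1:200) {
    np <- sample(1:25, 1); nb <- sample(1:25, 1)
    p <- sample(seq(0, 1, 0.05), np, replace = TRUE)
    b <- sample(seq(0, 1, 0.05), nb, replace = TRUE)
    expect_lt(abs(auc_rank(p, b) - pair_auc(p, b)), 1e-10)
    expect_lt(abs(tss_scan(p, b)$tss_max - brute_tss(p, b)), 1e-10)
  }
})

test_that("rank AUC equals trapezoidal ROC integration", {
  trap_auc <- function(p, b) {
    thr <- c(Inf, sort(unique(c(p, b)), decreasing = TRUE), -Inf)
    sens <- vapply(thr, function(t) mean(p >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(b >= t), numeric(1))
    sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  }
  set.seed(11)
  for (i in 1:200) {
    p <- round(runif(sample(2:30, 1)), 2)
    b <- round(runif(sample(2:30, 1)), 2)
    expect_lt(abs(auc_rank(p, b) - trap_auc(p, b)), 1e-10)
  }
})

test_that("smaller training sets never improve median test AUC", {
  env <- model_landscape(seed = 24, nr = 50, nc = 50)
  sp <- niche_species("s")
  med_auc <- vapply(c(100, 10), function(n_occ) {
    aucs <- vapply(1:20, function(s) {
      dat <- species_data(env, sp, n_occ = n_occ, n_bg = 600, seed = s)
      spl <- split_data(dat$presence, dat$background, 0.7, seed = s)
      f <- fit_replicate("GLM", spl$train$presence, spl$train$background)
      evaluate_sdm(f, spl$test$presence, spl$test$background)$eval$auc
    }, numeric(1))
    median(aucs)
  }, numeric(1))
  expect_gte(med_auc[1], med_auc[2])
})
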