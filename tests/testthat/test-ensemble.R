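# shared fixture: one species, several evaluated replicates
fit_batch <- function(env, dat, fams = c("GLM", "GLM", "MARS"),
                      seeds = seq_along(fams)) {
  Map(function(fam, s) {
    spl <- split_data(dat$presence, dat$background, 0.7, seed = s)
    f <- fit_replicate(fam, spl$train$presence, spl$train$background)
    evaluate_sdm(f, spl$test$presence, spl$test$background)
  }, fams, seeds)
}

test_that("TSS gating and weighting follow the weighted-mean oracle", {
  env <- model_landscape(seed = 31, nr = 40, nc = 40)
  dat <- species_data(env, niche_species("s", b1 = 1.5, b12 = 60),
                      n_occ = 70, n_bg = 1200, seed = 2)
  fits <- fit_batch(env, dat)
  tss <- vapply(fits, function(f) f$eval$tss_max, numeric(1))
  tss_min <- min(tss) - 0.01  # admit all
  ens <- ensemble_sdm(fits, env, tss_min = tss_min)
  expect_equal(sum(ens$member_weights), 1)
  # weighted-mean oracle, cellwise
  preds <- lapply(fits, predict_stack, env = env)
  w <- tss / sum(tss)
  oracle <- Reduce(`+`, Map(function(p, wi) p$layers[[1]] * wi, preds, w))
  expect_equal(ens$suitability$layers$suitability, oracle)
  expect_equal(ens$cutoff,
               sum(w * vapply(fits, function(f) f$eval$tss_threshold,
                              numeric(1))))
  # ensemble bounded by members cellwise
  lo <- Reduce(pmin, lapply(preds, function(p) p$layers[[1]]))
  hi <- Reduce(pmax, lapply(preds, function(p) p$layers[[1]]))
  s <- ens$suitability$layers$suitability
  expect_true(all(s >= lo - 1e-12 & s <= hi + 1e-12, na.rm = TRUE))
  # identical members: ensemble equals any member
  same <- ensemble_sdm(fits[c(1, 1)], env, tss_min = tss_min)
  expect_equal(same$suitability$layers$suitability, preds[[1]]$layers[[1]])
  # gating contract
  expect_error(ensemble_sdm(fits, env, tss_min = max(tss) + 0.01),
               "no admissible members")
  # committee rule: weighted vote of member binaries, majority cutoff
  com <- ensemble_sdm(fits, env, tss_min = tss_min, rule = "committee")
  votes <- Reduce(`+`, Map(function(p, f, wi)
    (p$layers[[1]] >= f$eval$tss_threshold) * wi, preds, fits, w))
  expect_equal(com$suitability$layers$suitability, votes)
  expect_equal(com$cutoff, 0.5)
})

test_that("binarization respects cutoff bounds and the stored value", {
  env <- model_landscape(seed = 32, nr = 40, nc = 40)
  sp <- niche_species("s", b1 = 1.5, b12 = 60)
  dat <- species_data(env, sp, n_occ = 70, n_bg = 1200, seed = 3)
  fits <- fit_batch(env, dat, fams = c("GLM", "GLM"))
  ens <- ensemble_sdm(fits, env, tss_min = 0)
  s <- ens$suitability$layers$suitability
  # cutoff just above zero: presence = all cells with suitability > 0
  eps <- 1e-9
  all_on <- binarize(ens, cutoff = eps)
  expect_equal(sum(all_on$presence), sum(s >= eps, na.rm = TRUE))
  # cutoff above the maximum: empty range
  expect_equal(sum(binarize(ens, cutoff = 0.999999)$presence), 0)
  # at the stored cutoff the range contains the niche-centre cell
  rng <- binarize(ens)
  ctr <- stack_values(env)
  d <- ((ctr$bio1 - 8) / 1.5)^2 + ((ctr$bio12 - 800) / 60)^2
  best <- ctr[which.min(d), ]
  expect_true(rng$presence[best$row, best$col])
  expect_error(binarize(ens, cutoff = 1.5), "in \\(0, 1\\)")
})

test_that("projection transfers members, weights and cutoff unchanged", {
  env <- model_landscape(seed = 33, nr = 40, nc = 40)
  sp <- virtual_species("s", c(bio1 = 8), c(bio1 = 1.5))
  dat <- species_data(env, sp, n_occ = 70, n_bg = 1200, seed = 4)
  fits <- fit_batch(env, dat, fams = c("GLM", "GLM"))
  ens <- ensemble_sdm(fits, env, tss_min = 0)
  # projecting onto the training stack reproduces the ensemble cellwise
  same <- project_ensemble(ens, env, label = "again")
  expect_equal(same$suitability$layers$suitability,
               ens$suitability$layers$suitability)
  expect_equal(same$cutoff, ens$cutoff)
  # a uniform +4 shift on the only used variable translates the response:
  # the cell at the old optimum is no longer maximal
  shifted_env <- apply_scenario(env, scenario_shift("warm",
    additive_offsets = c(bio1 = 4)))
  proj <- project_ensemble(ens, shifted_env, label = "warm")
  s0 <- ens$suitability$layers$suitability
  s1 <- proj$suitability$layers$suitability
  old_opt <- which(s0 == max(s0, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_lt(s1[old_opt[1], old_opt[2]], max(s1, na.rm = TRUE))
  # cells whose shifted bio1 equals the old optimum now score like it
  expect_gt(cor(as.vector(s1), as.vector(true_suitability(shifted_env,
    sp)$layers$suitability)), 0.8)
  # missing-layer contract names the layer
  no12 <- env_stack(env$layers["bio3"], env$xmin, env$ymin, env$xres,
                    env$yres)
  expect_error(project_ensemble(ens, no12), "bio1")
})

test_that("scenario averaging is an exact cellwise mean", {
  env <- model_landscape(seed = 34, nr = 20, nc = 20)
  # average with itself: identity
  expect_equal(average_scenarios(list(env, env)), env)
  # average of x and x + 2 is x + 1
  warm <- apply_scenario(env, scenario_shift("w",
    additive_offsets = c(bio1 = 2)))
  avg <- average_scenarios(list(env, warm))
  expect_equal(avg$layers$bio1, env$layers$bio1 + 1)
  # three stacks against a brute-force loop
  s3 <- apply_scenario(env, scenario_shift("m",
    multiplicative_factors = c(bio12 = 1.2)))
  got <- average_scenarios(list(env, warm, s3))
  for (nm in layer_names(env)) {
    brute <- (env$layers[[nm]] + warm$layers[[nm]] + s3$layers[[nm]]) / 3
    expect_equal(got$layers[[nm]], brute)
  }
  # co-registration contract
  small <- model_landscape(seed = 34, nr = 10, nc = 20)
  expect_error(average_scenarios(list(env, small)), "co-registration")
})
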