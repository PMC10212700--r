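test_that("landscape spec validates its geometry and correlation target", {
  expect_error(landscape_spec(n_rows = 1), "at least 2 x 2")
  expect_error(landscape_spec(extent = c(91, 200, 20, 47)), "longitude")
  bad <- diag(6); bad[1, 2] <- bad[2, 1] <- 1.5  # not PSD
  expect_error(landscape_spec(inter_layer_corr = bad),
               "positive semidefinite")
  nonsym <- diag(6); nonsym[1, 2] <- 0.5
  expect_error(landscape_spec(inter_layer_corr = nonsym), "symmetric")
})

test_that("generated stacks are deterministic and hit the correlation target", {
  spec <- landscape_spec(seed = 1)  # 200x200, 6 layers, identity target
  env <- gen_env_stack(spec)
  expect_identical(gen_env_stack(spec), env)  # bit-identical on same seed
  vals <- as.matrix(stack_values(env)[, layer_names(env)])
  C <- cor(vals)
  expect_lt(max(abs(C[upper.tri(C)])), 0.15)
  # correlated target
  tgt <- diag(6); tgt[1, 2] <- tgt[2, 1] <- 0.9
  env2 <- gen_env_stack(landscape_spec(inter_layer_corr = tgt, seed = 2))
  v2 <- as.matrix(stack_values(env2)[, layer_names(env2)])
  expect_equal(cor(v2[, 1], v2[, 2]), 0.9, tolerance = 0.1)
  # fields are spatially smooth: lag-1 autocorrelation is strong
  l <- env$layers$bio1
  expect_gt(cor(as.vector(l[-1, ]), as.vector(l[-nrow(l), ])), 0.8)
})

test_that("suitability is maximal at the niche centre and symmetric", {
  env <- tiny_env(nr = 6, nc = 6)
  env$layers$bio1[] <- seq(-5, 5, length.out = 36)
  env$layers$bio12[] <- 800  # flat: distance driven by bio1 only
  env$layers$bio1[3, 3] <- 0 # exact centre cell
  sp <- niche_species("s", bio1 = 0, bio12 = 800, b1 = 2, b12 = 100)
  suit <- true_suitability(env, sp)
  s <- suit$layers$suitability
  expect_equal(s[3, 3], max(s))
  expect_equal(s[3, 3], 1)  # max_suitability at the centre
  # equal breadth-scaled distance implies equal suitability
  env$layers$bio1[1, 1] <- 3; env$layers$bio1[6, 6] <- -3
  s2 <- true_suitability(env, sp)$layers$suitability
  expect_equal(s2[1, 1], s2[6, 6])
  # doubling breadths never decreases suitability anywhere
  wide <- niche_species("w", bio1 = 0, bio12 = 800, b1 = 4, b12 = 200)
  s3 <- true_suitability(env, wide)$layers$suitability
  expect_true(all(s3 >= s2 - 1e-12))
  # unknown layer contract
  bad <- virtual_species("b", c(bio99 = 0), c(bio99 = 1))
  expect_error(true_suitability(env, bad), "bio99")
})

test_that("occurrence sampling follows the suitability surface", {
  env <- tiny_env(nr = 2, nc = 1, xres = 1, yres = 1)
  one <- matrix(c(0, 1), 2, 1)
  suit1 <- env_stack(list(suitability = one), env$xmin, env$ymin, 1)
  # degenerate support: every draw in the one nonzero cell
  occ <- sample_occurrences(suit1, 5, seed = 3)
  expect_equal(nrow(occ$points), 5)
  expect_equal(unique(occ$points$lat), cell_lat(suit1, 2))
  # determinism
  expect_identical(sample_occurrences(suit1, 5, seed = 3), occ)
  # binomial share on a 2-cell grid with weights (0.75, 0.25)
  suit2 <- env_stack(list(suitability = matrix(c(0.75, 0.25), 2, 1)),
                     env$xmin, env$ymin, 1)
  occ2 <- sample_occurrences(suit2, 10000, seed = 11)
  share <- mean(occ2$points$lat == cell_lat(suit2, 1))
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(share - 0.75), 3 * se)
  # all-zero suitability contract
  zero <- env_stack(list(suitability = matrix(0, 2, 1)), 0, 0, 1)
  expect_error(sample_occurrences(zero, 1, seed = 1), "zero everywhere")
})

test_that("sampling frequencies converge to normalized suitability", {
  # chi-square goodness of fit at n = 10,000 across 100 seeds: at least
  # 95% of draws consistent with the surface at alpha = 0.01
  set.seed(42)
  w <- matrix(rgamma(25, 2), 5, 5)
  suit <- env_stack(list(suitability = w), 0, 0, 1)
  p <- as.vector(w) / sum(w)
  reject <- vapply(1:100, function(s) {
    occ <- sample_occurrences(suit, 10000, seed = s)
    ci <- cell_index(suit, occ$points$lon, occ$points$lat)
    counts <- table(factor(paste(ci$row, ci$col),
                           levels = paste(as.vector(row(w)),
                                          as.vector(col(w)))))
    suppressWarnings(chisq.test(as.vector(counts), p = p)$p.value) < 0.01
  }, logical(1))
  expect_lte(sum(reject), 5)
})

test_that("scenario shifts are exact cellwise affine maps", {
  env <- model_landscape(seed = 5, nr = 20, nc = 20)
  # identity shift
  ident <- scenario_shift("same")
  expect_equal(apply_scenario(env, ident), env)
  # offset +2 on bio1 moves the mean by exactly 2
  warm <- scenario_shift("warm", additive_offsets = c(bio1 = 2))
  shifted <- apply_scenario(env, warm)
  expect_equal(mean(shifted$layers$bio1), mean(env$layers$bio1) + 2)
  expect_equal(shifted$layers$bio12, env$layers$bio12)
  # factor 1.1 on bio12: per-cell ratio 1.1 everywhere on the mask
  wet <- scenario_shift("wet", multiplicative_factors = c(bio12 = 1.1))
  r <- apply_scenario(env, wet)$layers$bio12 / env$layers$bio12
  expect_equal(range(r[env$mask]), c(1.1, 1.1))
  # unknown layer contract, positive factor contract
  expect_error(apply_scenario(env, scenario_shift("x",
    additive_offsets = c(bioX = 1))), "bioX")
  expect_error(scenario_shift("x", multiplicative_factors = c(bio1 = 0)),
               "positive")
})

test_that("pulling niche centres apart never lowers downstream isolation", {
  # three increasing niche-centre separations; ranges from binarizing the
  # true suitabilities at a fixed 0.9 quantile cutoff
  env <- model_landscape(seed = 9, nr = 80, nc = 80)
  base <- niche_species("a", bio1 = 8, bio12 = 800)
  ri_at <- vapply(c(0, 2, 6), function(sep) {
    other <- niche_species("b", bio1 = 8 + sep * 2, bio12 = 800 + sep * 100)
    ra <- true_suitability(env, base)
    rb <- true_suitability(env, other)
    cut_a <- quantile(ra$layers$suitability, 0.9, na.rm = TRUE)
    cut_b <- quantile(rb$layers$suitability, 0.9, na.rm = TRUE)
    r <- ri_ecogeo(binarize(ra, cutoff = min(cut_a, 0.999)),
                   binarize(rb, cutoff = min(cut_b, 0.999)))
    (r$ri_A + r$ri_B) / 2
  }, numeric(1))
  expect_true(all(diff(ri_at) >= 0))
  expect_lt(ri_at[1], 0.05)  # coincident niches share their range
})
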