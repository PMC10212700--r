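# fixture builders shared across the test files; everything is generated
# in code so tests carry no data files

# deterministic small stack with hand-set layer values
tiny_env <- function(nr = 4, nc = 5, xmin = 100, ymin = 30, xres = 0.5,
                     yres = 0.5, mask = NULL) {
  bio1 <- matrix(seq_len(nr * nc), nr, nc)         # distinct values per cell
  bio12 <- matrix(100 + 2 * seq_len(nr * nc), nr, nc)
  env_stack(list(bio1 = bio1, bio12 = bio12), xmin = xmin, ymin = ymin,
            xres = xres, yres = yres, mask = mask)
}

# binary_range directly from a logical matrix (unit-degree grid at the
# equator unless stated otherwise)
make_range <- function(presence, xmin = 0, ymin = 0, xres = 1, yres = 1,
                       scenario = "current") {
  structure(list(presence = presence, xmin = xmin, ymin = ymin,
                 xres = xres, yres = yres,
                 nrow = nrow(presence), ncol = ncol(presence),
                 cutoff = 0.5, scenario = scenario),
            class = "binary_range")
}

# a small random landscape for model-fitting tests
model_landscape <- function(seed, nr = 60, nc = 60, range = 4) {
  gen_env_stack(landscape_spec(n_rows = nr, n_cols = nc,
                               spatial_range = range, seed = seed))
}

# Gaussian-niche virtual species on bio1/bio12 at a given centre shift
# (in bio1-degC / bio12-mm units)
niche_species <- function(name, bio1 = 8, bio12 = 800, b1 = 2, b12 = 100) {
  virtual_species(name, niche_center = c(bio1 = bio1, bio12 = bio12),
                  niche_breadth = c(bio1 = b1, bio12 = b12))
}

# presence/background feature tables for one species on one landscape
species_data <- function(env, sp, n_occ = 80, n_bg = 1500, seed = 1) {
  suit <- true_suitability(env, sp)
  occ <- sample_occurrences(suit, n_occ, seed = seed, species = sp$name)
  list(occ = occ,
       presence = extract_at_points(env, occ),
       background = sample_background(env, n_bg,
                                      seed = derive_seed_t(seed)))
}

derive_seed_t <- function(seed) (seed * 33 + 7) %% 2147483647

# exact sample-correlation construction: two unit-variance columns with
# empirical correlation exactly r (for VIF / PCA closed-form checks)
exact_corr_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  z <- scale(matrix(rnorm(2 * n), n, 2))
  q <- qr.Q(qr(z)) * sqrt(n - 1)          # exactly orthonormal, unit var
  cbind(x1 = q[, 1], x2 = r * q[, 1] + sqrt(1 - r^2) * q[, 2])
}
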