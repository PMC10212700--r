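#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()],
#' optionally overridden field-by-field. Model defaults are desk-scale
#' (10 replicates per family, 10,000 background points); classic
#' full-scale studies use 100 replicates and 200,000 background points,
#' both reachable through overrides.
#'
#' @param ... named overrides merged (recursively) into the defaults.
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    landscape = list(n_rows = 200, n_cols = 200,
                     extent = c(91, 125, 20, 47),
                     layer_names = c("bio1", "bio3", "bio7", "bio12",
                                     "bio15", "srad12"),
                     spatial_range = 8),
    species = list(),     # list of virtual-species definitions
    n_occurrences = 100,  # presence records sampled per species
    scenarios = list(),   # list of scenario_shift definitions
    screening = list(r_threshold = 0.75, vif_threshold = 10),
    models = list(families = c("GLM", "MAXENT", "MARS"),
                  replicates = 10, background_n = 10000,
                  train_frac = 0.7, tss_min = 0.8,
                  ensemble_rule = "weighted_mean"),
    isolation = list(area_weighted = FALSE),
    overlap = list(enabled = TRUE, identity_test = FALSE, n_reps = 100,
                   bootstrap_n = 0))
  merge_config(cfg, list(...))
}

# recursive merge of named sub-lists; `species` and `scenarios` are
# sequences and are replaced wholesale
merge_config <- function(base, override) {
  for (nm in names(override)) {
    recurse <- is.list(base[[nm]]) && is.list(override[[nm]]) &&
      !is.null(names(override[[nm]])) &&
      all(nzchar(names(override[[nm]]))) &&
      !nm %in% c("species", "scenarios")
    base[[nm]] <- if (recurse) merge_config(base[[nm]], override[[nm]])
                  else override[[nm]]
  }
  base
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  do.call(default_config, config)
}

# order-independent 32-bit FNV-1a hash of the deparsed config, for the
# run manifest
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 216613626
  for (b in utf8ToInt(s)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", h)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

as_virtual_species <- function(x) {
  if (inherits(x, "virtual_species")) return(x)
  virtual_species(x$name, unlist(x$niche_center), unlist(x$niche_breadth),
                  x$max_suitability %||% 1)
}

as_scenario_shift <- function(x) {
  if (inherits(x, "scenario_shift")) return(x)
  scenario_shift(x$name, unlist(x$additive_offsets) %||% numeric(0),
                 unlist(x$multiplicative_factors) %||% numeric(0))
}

#' Run the full ecogeographic-isolation pipeline
#'
#' Executes the end-to-end analysis on a synthetic landscape: generate
#' the environmental stack, sample and thin virtual-species occurrences,
#' screen predictors for collinearity, fit replicate SDMs of each family
#' on 70/30 subsampling splits, evaluate by AUC/TSS, build the TSS-gated
#' ensemble, binarize, compute per-species areas and the pairwise RI
#' matrix, then project onto every scenario and summarize isolation
#' shifts. Every random step is seeded from the one master seed, so the
#' whole report is a pure function of the configuration.
#'
#' @param config a configuration list (see [default_config()]) or the
#'   path of a YAML file holding one.
#' @param outdir optional directory; when given, occurrence/screening/
#'   evaluation/RI/area tables are written as CSV, ensemble surfaces and
#'   ranges as ESRI ASCII grids, and a JSON manifest records seed and
#'   config hash.
#' @return An object of class `scenario_report`; see the elements
#'   `screening`, `evaluation`, `ensembles`, `ranges`, `areas`,
#'   `ri`, `area_table`, `shifts`, `overlap`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  cfg <- read_pipeline_config(config)
  if (length(cfg$species) < 2)
    stop("pipeline stage 'config' failed: need at least 2 species")
  seed <- as.integer(cfg$seed)

  env <- run_stage("landscape", {
    ls_cfg <- cfg$landscape
    ls_cfg$seed <- ls_cfg$seed %||% derive_seed(seed, 11)
    gen_env_stack(do.call(landscape_spec, ls_cfg))
  })

  species <- lapply(cfg$species, as_virtual_species)
  names(species) <- vapply(species, `[[`, character(1), "name")

  occs <- run_stage("occurrences", {
    out <- lapply(seq_along(species), function(i) {
      suit <- true_suitability(env, species[[i]])
      occ <- sample_occurrences(suit, cfg$n_occurrences,
                                seed = derive_seed(seed, 100 + i),
                                species = names(species)[i])
      thin_to_grid(occ, env)
    })
    stats::setNames(out, names(species))
  })

  background <- run_stage("background",
    sample_background(env, cfg$models$background_n,
                      seed = derive_seed(seed, 12)))

  screening <- run_stage("screening", {
    vals <- background[, layer_names(env), drop = FALSE]
    screen_predictors(vals, cfg$screening$r_threshold,
                      cfg$screening$vif_threshold)
  })
  vars <- screening$retained

  fits <- run_stage("fit", {
    lapply(names(species), function(spn) {
      ext <- extract_at_points(env, occs[[spn]])
      reps <- list()
      for (fam in cfg$models$families) {
        for (r in seq_len(cfg$models$replicates)) {
          s <- derive_seed(seed, 1000 + 100 * match(fam, cfg$models$families) +
                             r + 17 * match(spn, names(species)))
          sp_l <- split_data(ext, background, cfg$models$train_frac, s)
          fit <- fit_replicate(fam, sp_l$train$presence,
                               sp_l$train$background, vars = vars)
          fit <- evaluate_sdm(fit, sp_l$test$presence, sp_l$test$background)
          reps[[length(reps) + 1L]] <- fit
        }
      }
      reps
    }) |> stats::setNames(names(species))
  })

  evaluation <- do.call(rbind, lapply(names(fits), function(spn)
    do.call(rbind, lapply(fits[[spn]], function(f)
      data.frame(species = spn, family = f$family, auc = f$eval$auc,
                 tss = f$eval$tss_max, threshold = f$eval$tss_threshold)))))

  ensembles <- run_stage("ensemble",
    lapply(fits, ensemble_sdm, env = env, tss_min = cfg$models$tss_min,
           rule = cfg$models$ensemble_rule))

  scenarios <- lapply(cfg$scenarios, as_scenario_shift)
  names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  scen_envs <- run_stage("scenario",
    lapply(scenarios, apply_scenario, env = env))

  ranges <- run_stage("binarize", {
    out <- list(current = lapply(ensembles, binarize))
    for (sc in names(scen_envs)) {
      out[[sc]] <- lapply(ensembles, function(e)
        binarize(project_ensemble(e, scen_envs[[sc]], label = sc)))
    }
    out
  })

  areas <- sapply(ranges, function(rs) vapply(rs, area_km2, numeric(1)))
  ri <- lapply(names(ranges), function(sc)
    isolation_matrix(ranges[[sc]], scenario = sc,
                     area_weighted = isTRUE(cfg$isolation$area_weighted))) |>
    stats::setNames(names(ranges))
  area_table <- area_dynamics(areas, current = "current")
  shifts <- lapply(setdiff(names(ri), "current"), function(sc)
    isolation_shift_summary(ri$current, ri[[sc]])) |>
    stats::setNames(setdiff(names(ri), "current"))

  overlap <- NULL
  if (isTRUE(cfg$overlap$enabled)) {
    overlap <- run_stage("overlap", {
      dists <- lapply(ensembles, function(e) niche_distribution(e$suitability))
      sp <- names(dists)
      prs <- t(utils::combn(sp, 2))
      ov <- data.frame(speciesA = prs[, 1], speciesB = prs[, 2],
                       D = NA_real_, I = NA_real_,
                       p_D = NA_real_, p_I = NA_real_)
      for (i in seq_len(nrow(ov))) {
        ov$D[i] <- schoener_D(dists[[ov$speciesA[i]]], dists[[ov$speciesB[i]]])
        ov$I[i] <- warren_I(dists[[ov$speciesA[i]]], dists[[ov$speciesB[i]]])
        if (isTRUE(cfg$overlap$identity_test)) {
          it <- identity_test(occs[[ov$speciesA[i]]], occs[[ov$speciesB[i]]],
                              env, background, n_reps = cfg$overlap$n_reps,
                              seed = derive_seed(seed, 5000 + i))
          ov$p_D[i] <- it$p_D; ov$p_I[i] <- it$p_I
        }
      }
      breadth <- lapply(dists, levins_B)
      list(pairs = ov, breadth = breadth)
    })
  }

  manifest <- list(package = "ecogeoiso",
                   version = as.character(utils::packageVersion("ecogeoiso")),
                   seed = seed, config_hash = config_hash(cfg),
                   species = names(species),
                   scenarios = names(scenarios),
                   retained_vars = vars,
                   timestamp = NULL)  # kept NULL: reports must be seed-pure

  report <- structure(list(config = cfg, env = env, occurrences = occs,
                           screening = screening, evaluation = evaluation,
                           ensembles = ensembles, ranges = ranges,
                           areas = areas, ri = ri, area_table = area_table,
                           shifts = shifts, overlap = overlap,
                           manifest = manifest),
                      class = "scenario_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %d species, %d scenario(s) + current\n",
              length(x$occurrences), length(x$shifts)))
  cat("current RI matrix:\n")
  print(round(x$ri$current$ri, 4))
  invisible(x)
}

#' Write pipeline artifacts to disk
#'
#' @param report a `scenario_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_occurrences(report$occurrences, file.path(outdir, "occurrences.csv"))
  utils::write.csv(report$screening$dropped,
                   file.path(outdir, "screening_dropped.csv"),
                   row.names = FALSE)
  utils::write.csv(report$evaluation, file.path(outdir, "evaluation.csv"),
                   row.names = FALSE)
  utils::write.csv(report$area_table, file.path(outdir, "area_dynamics.csv"),
                   row.names = FALSE)
  for (sc in names(report$ri))
    utils::write.csv(report$ri[[sc]]$ri,
                     file.path(outdir, paste0("ri_", sc, ".csv")))
  for (spn in names(report$ensembles))
    write_ascii_grid(report$ensembles[[spn]]$suitability,
                     file.path(outdir, paste0("suitability_", spn, ".asc")))
  jsonlite::write_json(report$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(outdir)
}
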