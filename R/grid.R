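# --- deterministic seed derivation -----------------------------------------

# 31-ary rolling hash of a string, modulo the Mersenne prime 2^31 - 1.
# Intermediate products stay far below 2^53, so double arithmetic is exact.
stable_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible sub-seed from a base seed and a label
#'
#' Combines an integer base seed with a stable string hash of `label` so
#' that a single master seed deterministically reproduces every dataset and
#' model in an experiment. The result is always in [0, 2^31 - 2].
#'
#' @param base_seed integer master seed.
#' @param label character label (e.g. a configuration id plus replicate
#'   number).
#' @return a non-negative integer seed.
#' @export
derive_seed <- function(base_seed, label) {
  as.integer((as.numeric(base_seed) + stable_hash(label)) %% 2147483647)
}

# --- the study's simulation grid -------------------------------------------

#' The simulation study configuration grid
#'
#' Returns the full grid of 70 dataset configurations of the simulation
#' study as a data frame, one row per configuration: clean XOR epistasis
#' (orders 2-5 at 20/40/60/80/100 features), the noisy 2-way "core" grid
#' (easy/hard architectures x four heritabilities x four sample sizes), the
#' 2-way feature sweep (100 to 100,000 features), two-subgroup heterogeneous
#' 2-way epistasis (50:50 and 75:25), noisy 3-way epistasis, and the
#' non-epistatic main-effect and additive families. With 30 replicates per
#' configuration the grid expands to 2,100 datasets.
#'
#' @param families optional character vector restricting the grid to a
#'   subset of `xor`, `core_2way`, `feature_sweep_2way`, `het_2way`,
#'   `noisy_3way`, `main_1`, `additive_2`, `additive_4`.
#' @return a data.frame with columns `config_id`, `family`, `order`,
#'   `n_predictive`, `n_features`, `n_instances`, `heritability`,
#'   `difficulty`, `variation`.
#' @export
benchmark_grid <- function(families = NULL) {
  rows <- list()
  add <- function(family, order, n_predictive, n_features, n_instances,
                  heritability, difficulty, variation, config_id) {
    rows[[length(rows) + 1L]] <<- data.frame(
      config_id = config_id, family = family, order = order,
      n_predictive = n_predictive, n_features = n_features,
      n_instances = n_instances, heritability = heritability,
      difficulty = difficulty, variation = variation,
      stringsAsFactors = FALSE)
  }
  for (k in 2:5) for (f in c(20L, 40L, 60L, 80L, 100L))
    add("xor", k, k, f, 1600L, 1, NA_character_, NA_character_,
        sprintf("xor_k%d_f%d", k, f))
  for (dif in c("E", "H")) for (h2 in c(0.05, 0.1, 0.2, 0.4))
    for (n in c(200L, 400L, 800L, 1600L))
      add("core_2way", 2L, 2L, 100L, n, h2, dif, NA_character_,
          sprintf("core2_%s_h%g_n%d", dif, h2, n))
  for (f in c(100L, 1000L, 10000L, 100000L))
    add("feature_sweep_2way", 2L, 2L, f, 1600L, 0.4, "E", NA_character_,
        sprintf("sweep2_f%d", f))
  for (r in c("50:50", "75:25"))
    add("het_2way", 2L, 4L, 100L, 1600L, 0.4, "E", r,
        sprintf("het2_%s", gsub(":", "-", r)))
  add("noisy_3way", 3L, 3L, 100L, 1600L, 0.2, "E", NA_character_,
      "noisy3")
  for (dif in c("E", "H")) for (h2 in c(0.05, 0.1, 0.2, 0.4))
    add("main_1", 1L, 1L, 100L, 1600L, h2, dif, NA_character_,
        sprintf("main1_%s_h%g", dif, h2))
  for (s in c("50:50", "75:25"))
    add("additive_2", 1L, 2L, 100L, 1600L, 0.4, "E", s,
        sprintf("add2_%s", gsub(":", "-", s)))
  add("additive_4", 1L, 4L, 100L, 1600L, 0.4, "E", NA_character_, "add4")
  grid <- do.call(rbind, rows)
  if (!is.null(families)) {
    bad <- setdiff(families, unique(grid$family))
    if (length(bad)) stop("unknown families: ", paste(bad, collapse = ", "))
    grid <- grid[grid$family %in% families, , drop = FALSE]
    rownames(grid) <- NULL
  }
  grid
}

#' Expand a configuration grid into replicate-level jobs
#'
#' Each configuration row is expanded into `n_replicates` jobs with a
#' deterministic per-job seed derived from the base seed and a stable hash
#' of (config_id, replicate). The job list is sorted by configuration id and
#' replicate, so the same grid and base seed always yield the same jobs.
#'
#' @param grid a data.frame as returned by [benchmark_grid()].
#' @param n_replicates replicates per configuration (default 30).
#' @param base_seed integer master seed.
#' @return the grid with added `replicate` and `seed` columns, one row per
#'   job.
#' @export
expand_grid_jobs <- function(grid, n_replicates = 30L, base_seed = 1L) {
  if (nrow(grid) == 0L || n_replicates == 0L) {
    out <- grid[integer(0), , drop = FALSE]
    out$replicate <- integer(0)
    out$seed <- integer(0)
    return(out)
  }
  jobs <- grid[rep(seq_len(nrow(grid)), each = n_replicates), , drop = FALSE]
  jobs$replicate <- rep(seq_len(n_replicates), times = nrow(grid))
  jobs$seed <- mapply(function(id, r)
    derive_seed(base_seed, paste0(id, "#", r)),
    jobs$config_id, jobs$replicate, USE.NAMES = FALSE)
  jobs <- jobs[order(jobs$config_id, jobs$replicate), , drop = FALSE]
  rownames(jobs) <- NULL
  jobs
}

# --- configuration -> dataset dispatch -------------------------------------

#' Build the penetrance model a configuration calls for
#'
#' For model-based families (`core_2way`, `feature_sweep_2way`,
#' `noisy_3way`) returns the pure/strict penetrance model shared by all
#' replicates of the configuration; the model seed is derived from the base
#' seed and the configuration id, mirroring how GAMETES fixes one model per
#' configuration and samples replicate datasets from it. Other families
#' build their models inside their generators and return `NULL` here.
#'
#' @param config one row of [benchmark_grid()].
#' @param base_seed integer master seed.
#' @param maf predictive-locus minor allele frequency (default 0.2).
#' @param n_candidates model-search candidate budget.
#' @return a `penetrance_model` or `NULL`.
#' @export
config_model <- function(config, base_seed = 1L, maf = 0.2,
                         n_candidates = 100L) {
  if (!config$family %in% c("core_2way", "feature_sweep_2way", "noisy_3way"))
    return(NULL)
  build_penetrance_model(
    k = config$order, maf = maf, heritability = config$heritability,
    difficulty = if (is.na(config$difficulty)) "E" else config$difficulty,
    seed = derive_seed(base_seed, paste0(config$config_id, "/model")),
    n_candidates = n_candidates)
}

#' Generate the dataset for one (configuration, seed) job
#'
#' Dispatches on the configuration family to the matching simulator.
#' Identical (configuration, seed, model) inputs reproduce the dataset
#' bit-identically.
#'
#' @param config one row of [benchmark_grid()].
#' @param seed integer RNG seed for this replicate.
#' @param model optional prebuilt `penetrance_model` (see [config_model()]);
#'   built on the fly when `NULL`.
#' @param n_candidates model-search budget when models are built here.
#' @return a `snp_dataset`.
#' @export
generate_dataset <- function(config, seed, model = NULL,
                             n_candidates = 100L) {
  fam <- config$family
  if (fam == "xor") {
    simulate_xor(config$order, config$n_features, config$n_instances, seed,
                 config_id = config$config_id)
  } else if (fam %in% c("core_2way", "feature_sweep_2way", "noisy_3way")) {
    if (is.null(model))
      model <- config_model(config, base_seed = seed,
                            n_candidates = n_candidates)
    sample_from_model(model, config$n_features, config$n_instances, seed,
                      config_id = config$config_id)
  } else if (fam == "het_2way") {
    ratio <- parse_ratio(config$variation)
    simulate_heterogeneous(ratio, config$n_features, config$n_instances,
                           config$heritability, seed,
                           difficulty = ifelse(is.na(config$difficulty), "E",
                                               config$difficulty),
                           n_candidates = n_candidates,
                           config_id = config$config_id)
  } else if (fam %in% c("main_1", "additive_2", "additive_4")) {
    m <- config$n_predictive
    shares <- if (fam == "additive_2" && !is.na(config$variation))
      parse_ratio(config$variation) else rep(1 / m, m)
    simulate_main_or_additive(
      m, config$n_features, config$heritability,
      difficulty = ifelse(is.na(config$difficulty), "E", config$difficulty),
      seed = seed, n_instances = config$n_instances, shares = shares,
      n_candidates = n_candidates, config_id = config$config_id)
  } else {
    stop("unknown family: ", fam)
  }
}

parse_ratio <- function(s) {
  parts <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
  parts / sum(parts)
}
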