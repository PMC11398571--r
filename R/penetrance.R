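# --- Hardy-Weinberg helpers -------------------------------------------------

#' Hardy-Weinberg genotype frequencies
#'
#' Genotypes are coded as the count of minor alleles (0, 1, 2), so the
#' frequencies are ((1-q)^2, 2q(1-q), q^2) for minor allele frequency q.
#'
#' @param maf minor allele frequency in (0, 0.5].
#' @return numeric vector of length 3 summing to 1.
#' @export
hwe_freqs <- function(maf) {
  stopifnot(maf > 0, maf <= 0.5)
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

# all 3^k genotype combinations; locus 1 varies fastest
genotype_combos <- function(k) {
  as.matrix(expand.grid(rep(list(0:2), k), KEEP.OUT.ATTRS = FALSE))
}

# joint Hardy-Weinberg frequency of each row of genotype_combos(k)
joint_freqs <- function(mafs) {
  per_locus <- lapply(mafs, hwe_freqs)
  combos <- genotype_combos(length(mafs))
  f <- rep(1, nrow(combos))
  for (l in seq_along(mafs)) f <- f * per_locus[[l]][combos[, l] + 1L]
  f
}

# --- Penetrance model container --------------------------------------------

#' Construct and validate a k-locus penetrance model
#'
#' A penetrance model assigns P(case) to each of the 3^k multilocus genotype
#' combinations of k biallelic loci. Under Hardy-Weinberg genotype
#' frequencies the table determines the population prevalence
#' K = sum_i f_i p_i and the broad-sense heritability
#' h2 = sum_i f_i (p_i - K)^2 / (K (1 - K)). Models emitted by
#' [build_penetrance_model()] are additionally *pure and strict*: the
#' frequency-weighted marginal penetrance of every proper subset of the loci
#' is flat at K, so no lower-order effect carries signal.
#'
#' @param mafs minor allele frequencies of the k loci, each in (0, 0.5].
#' @param table numeric vector of 3^k penetrances in [0,1], ordered as
#'   `genotype_combos(k)` (locus 1 fastest).
#' @param prevalence target prevalence K in (0,1).
#' @param heritability target heritability in (0,1].
#' @param check validate the purity/prevalence/heritability identities
#'   (default `TRUE`). Disable for intentionally non-pure tables.
#' @return an object of class `penetrance_model`.
#' @export
penetrance_model <- function(mafs, table, prevalence, heritability,
                             check = TRUE) {
  k <- length(mafs)
  stopifnot(length(table) == 3^k, all(table >= 0), all(table <= 1),
            prevalence > 0, prevalence < 1)
  m <- structure(
    list(k = k, mafs = mafs, table = table,
         prevalence = prevalence, heritability = heritability),
    class = "penetrance_model")
  if (check) {
    if (max(abs(marginal_penetrance_deviation(m))) > 1e-9)
      stop("model is not pure/strict to tolerance 1e-9")
    if (abs(model_heritability(m) - heritability) > 1e-6)
      stop("model heritability does not match the target to 1e-6")
  }
  m
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("penetrance_model: %d loci, MAF %s, K = %g, h2 = %g\n",
              x$k, paste(signif(x$mafs, 3), collapse = "/"),
              x$prevalence, x$heritability))
  invisible(x)
}

#' Heritability implied by a penetrance table
#'
#' Evaluates sum_i f_i (p_i - K)^2 / (K (1 - K)) with f_i the joint
#' Hardy-Weinberg frequencies, using the realized prevalence
#' K = sum_i f_i p_i.
#'
#' @param model a `penetrance_model`.
#' @return the heritability as a number.
#' @export
model_heritability <- function(model) {
  f <- joint_freqs(model$mafs)
  K <- sum(f * model$table)
  sum(f * (model$table - K)^2) / (K * (1 - K))
}

#' Prevalence implied by a penetrance table
#' @param model a `penetrance_model`.
#' @return sum_i f_i p_i.
#' @export
model_prevalence <- function(model) {
  sum(joint_freqs(model$mafs) * model$table)
}

# Deviations of all proper-subset marginal penetrances from the target K.
# Returns a vector of (marginal - K) values across every non-empty proper
# subset of loci and every genotype combination of that subset.
marginal_penetrance_deviation <- function(model, K = model$prevalence) {
  k <- model$k
  f <- joint_freqs(model$mafs)
  combos <- genotype_combos(k)
  devs <- numeric(0)
  subsets <- proper_subsets(k)
  for (S in subsets) {
    idx <- combo_index(combos, S)
    marg <- rowsum(f * model$table, idx) / rowsum(f, idx)
    devs <- c(devs, marg - K)
  }
  devs
}

# non-empty proper subsets of 1..k (for k = 1: the single locus itself)
proper_subsets <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (size in 1:(k - 1)) out <- c(out, utils::combn(k, size, simplify = FALSE))
  out
}

# base-3 code of each combo restricted to loci S (1-based group index)
combo_index <- function(combos, S) {
  idx <- rep(0L, nrow(combos))
  for (l in S) idx <- idx * 3L + combos[, l]
  idx + 1L
}

# --- Pure/strict model search ----------------------------------------------

# Cyclic projection: repeatedly flatten the frequency-weighted marginal
# penetrance of every (k-1)-subset of loci at K. Flat (k-1)-marginals imply
# flat marginals for all smaller subsets. For k = 2 this is single-locus
# purity.
flatten_marginals <- function(p, f, combos, K, tol = 1e-13, max_sweeps = 200L) {
  k <- ncol(combos)
  S_list <- if (k == 1L) list(1L) else utils::combn(k, k - 1L, simplify = FALSE)
  idx_list <- lapply(S_list, function(S) combo_index(combos, S))
  fw_list <- lapply(idx_list, function(idx) rowsum(f, idx)[, 1L])
  for (sweep in seq_len(max_sweeps)) {
    dev_max <- 0
    for (j in seq_along(S_list)) {
      idx <- idx_list[[j]]
      marg <- rowsum(f * p, idx)[, 1L] / fw_list[[j]]
      dev <- marg - K
      dev_max <- max(dev_max, max(abs(dev)))
      p <- p - dev[idx]
    }
    if (dev_max < tol) break
  }
  p
}

# largest |marginal - K| over all (k-1)-subsets (implies all smaller subsets)
max_marginal_dev <- function(p, f, combos, K) {
  k <- ncol(combos)
  S_list <- if (k == 1L) list(1L) else utils::combn(k, k - 1L, simplify = FALSE)
  dev <- 0
  for (S in S_list) {
    idx <- combo_index(combos, S)
    marg <- rowsum(f * p, idx)[, 1L] / rowsum(f, idx)[, 1L]
    dev <- max(dev, max(abs(marg - K)))
  }
  dev
}

# Affine rescale of deviations from K so the heritability identity hits h2.
rescale_heritability <- function(p, f, K, h2) {
  v <- sum(f * (p - K)^2)
  if (v <= 0) return(NULL)
  K + sqrt(h2 * K * (1 - K) / v) * (p - K)
}

#' Search for a pure, strict penetrance model with target heritability
#'
#' Emulates the random model search of penetrance-table simulators such as
#' GAMETES. Candidate deviation tables are drawn at random, projected onto
#' the pure/strict constraint set (every proper-subset marginal penetrance
#' flat at the prevalence K, to within 1e-9), affinely rescaled so the
#' heritability identity hits the target exactly (to within 1e-6), and
#' driven into the probability simplex by alternating projections (clipping
#' to [0,1], re-flattening, re-rescaling); candidates that fail to converge
#' are rejected.
#'
#' When `prevalence` is `NULL` (default) the prevalence is treated as a free
#' model parameter, as in GAMETES when no prevalence is requested: a coarse
#' feasibility scan over K identifies the prevalence window within which the
#' target heritability is attainable, and each candidate draws its K from
#' that window. This matters because the attainable heritability of a pure
#' and strict table depends sharply on K (for two MAF-0.2 loci it peaks
#' around K = 0.3); fixing K = 0.5 makes h2 = 0.4 unattainable.
#'
#' Among valid candidates a difficulty proxy -- the unweighted variance of
#' the table entries -- selects the architecture: with the
#' frequency-weighted variance pinned by the heritability target, a large
#' unweighted variance means the signal sits in rare genotype combinations
#' (harder to detect). `difficulty = "E"` returns the minimum-variance
#' candidate, `"H"` the maximum.
#'
#' @param k interaction order (number of loci), k >= 2 for epistatic models.
#'   k = 1 is rejected: purity forces a flat table, which is incompatible
#'   with positive heritability (use [simulate_main_or_additive()] for main
#'   effects).
#' @param maf minor allele frequency shared by the k loci, in (0, 0.5].
#' @param heritability target heritability in (0, 1].
#' @param prevalence prevalence K in (0, 1), or `NULL` (default) to let the
#'   search choose a feasible K.
#' @param difficulty `"E"` (easy) or `"H"` (hard) architecture.
#' @param seed integer RNG seed.
#' @param n_candidates number of valid candidate models to collect before
#'   selecting (default 100).
#' @param max_attempts bound on raw candidate draws before declaring the
#'   (maf, heritability, prevalence) combination infeasible.
#' @return a `penetrance_model`.
#' @export
build_penetrance_model <- function(k, maf, heritability, prevalence = NULL,
                                   difficulty = c("E", "H"), seed = 1L,
                                   n_candidates = 100L,
                                   max_attempts = 50L * n_candidates) {
  difficulty <- match.arg(difficulty)
  stopifnot(heritability > 0, heritability <= 1, maf > 0, maf <= 0.5)
  if (!is.null(prevalence))
    stopifnot(prevalence > 0, prevalence < 1)
  if (k < 2)
    stop("k = 1 is infeasible: purity constraints force a flat table with ",
         "zero heritability; use simulate_main_or_additive() instead")
  mafs <- rep(maf, k)
  f <- joint_freqs(mafs)
  combos <- genotype_combos(k)
  best <- list(E = NULL, H = NULL)
  best_proxy <- c(E = Inf, H = -Inf)
  best_K <- c(E = NA_real_, H = NA_real_)
  n_valid <- 0L
  local_seed(seed, {
    K_pool <- if (is.null(prevalence))
      feasible_prevalences(f, combos, heritability) else prevalence
    if (length(K_pool) > 0L) {
      for (attempt in seq_len(max_attempts)) {
        K <- if (length(K_pool) == 1L) K_pool else sample(K_pool, 1L)
        p <- candidate_table(3^k, K)
        p <- settle_candidate(p, f, combos, K, heritability)
        if (is.null(p)) next
        n_valid <- n_valid + 1L
        proxy <- stats::var(p)
        if (proxy < best_proxy["E"]) {
          best_proxy["E"] <- proxy; best$E <- p; best_K["E"] <- K
        }
        if (proxy > best_proxy["H"]) {
          best_proxy["H"] <- proxy; best$H <- p; best_K["H"] <- K
        }
        if (n_valid >= n_candidates) break
      }
    }
  })
  if (n_valid == 0L)
    stop(sprintf(paste0(
      "infeasible constraint set: no pure/strict %d-locus table with ",
      "maf = %g, heritability = %g, prevalence = %s found in %d attempts"),
      k, maf, heritability,
      if (is.null(prevalence)) "free" else format(prevalence), max_attempts))
  penetrance_model(mafs, best[[difficulty]], best_K[[difficulty]],
                   heritability)
}

# raw candidate: mixture of uniform and U-shaped draws around K so that
# near-boundary (high-heritability) tables are reachable
candidate_table <- function(n, K) {
  if (stats::runif(1) < 0.5) stats::runif(n)
  else K + (stats::rbeta(n, 0.25, 0.25) - 0.5)
}

# alternating projections: flat margins + exact heritability + [0,1] box.
# Returns the settled table or NULL if the candidate fails to converge.
settle_candidate <- function(p, f, combos, K, h2, max_rounds = 120L) {
  for (round in seq_len(max_rounds)) {
    p <- flatten_marginals(p, f, combos, K)
    p <- rescale_heritability(p, f, K, h2)
    if (is.null(p)) return(NULL)
    if (min(p) >= 0 && max(p) <= 1) {
      if (max_marginal_dev(p, f, combos, K) < 1e-10) return(p)
    } else {
      p <- pmin(pmax(p, 0), 1)
    }
  }
  NULL
}

# coarse scan: prevalence values at which the target heritability is
# attainable for some table in the pure/strict deviation subspace, estimated
# by pushing random projected directions to the [−K, 1−K] box boundary
feasible_prevalences <- function(f, combos, h2,
                                 K_grid = seq(0.05, 0.5, by = 0.025),
                                 n_rays = 400L) {
  dirs <- lapply(seq_len(n_rays), function(j)
    flatten_marginals(stats::runif(length(f), -1, 1), f, combos, K = 0))
  ok <- vapply(K_grid, function(K) {
    for (d in dirs) {
      lim <- suppressWarnings(
        min(ifelse(d > 0, (1 - K) / d, ifelse(d < 0, -K / d, Inf))))
      if (!is.finite(lim)) next
      if (sum(f * (d * lim)^2) / (K * (1 - K)) >= h2) return(TRUE)
    }
    FALSE
  }, logical(1))
  K_grid[ok]
}

# --- Sampling from a model --------------------------------------------------

#' Sample a balanced case-control dataset from a penetrance model
#'
#' Draws exactly n/2 cases and n/2 controls. Predictive genotype
#' combinations are drawn from the class-conditional distributions implied
#' by the Hardy-Weinberg frequencies and the penetrance table
#' (P(combo | case) proportional to f_i p_i), which yields the same law as
#' rejection sampling of population draws at fixed class quotas.
#' Non-predictive features are drawn independently of class under
#' Hardy-Weinberg with per-feature MAF ~ Uniform(0.05, 0.5).
#'
#' @param model a `penetrance_model`.
#' @param n_features total feature count (>= model$k).
#' @param n_instances even number of instances.
#' @param seed integer RNG seed.
#' @param config_id provenance string stored in the dataset.
#' @return a `snp_dataset` with the k model loci named `M0P0..M0P<k-1>`
#'   (first columns) followed by noise features `N0..`.
#' @export
sample_from_model <- function(model, n_features, n_instances, seed,
                              config_id = "") {
  k <- model$k
  if (n_features < k) stop("n_features must be at least model$k")
  if (n_instances %% 2L != 0L)
    stop("n_instances must be even: exact class balance is impossible")
  f <- joint_freqs(model$mafs)
  combos <- genotype_combos(k)
  local_seed(seed, {
    g_pred <- sample_predictive_combos(f, model$table, combos, n_instances)
    noise <- sample_noise_features(n_instances, n_features - k)
  })
  geno <- cbind(g_pred, noise)
  pred_names <- paste0("M0P", seq_len(k) - 1L)
  feature_names <- c(pred_names,
                     if (n_features > k) paste0("N", seq_len(n_features - k) - 1L))
  ds <- snp_dataset(geno, rep(1:0, each = n_instances / 2L), feature_names,
                    pred_names, config_id = config_id, seed = seed)
  attr(ds, "model") <- model
  ds
}

# draw n/2 case rows then n/2 control rows of predictive genotypes
sample_predictive_combos <- function(f, table, combos, n_instances) {
  w_case <- f * table
  w_ctrl <- f * (1 - table)
  if (sum(w_case) <= 0 || sum(w_ctrl) <= 0)
    stop("model admits no cases or no controls")
  i_case <- sample.int(length(f), n_instances / 2L, TRUE, prob = w_case)
  i_ctrl <- sample.int(length(f), n_instances / 2L, TRUE, prob = w_ctrl)
  combos[c(i_case, i_ctrl), , drop = FALSE]
}

# class-independent Hardy-Weinberg noise features, MAF ~ U(0.05, 0.5)
sample_noise_features <- function(n_instances, n_noise) {
  if (n_noise == 0L) return(matrix(integer(0), n_instances, 0L))
  mafs <- stats::runif(n_noise, 0.05, 0.5)
  vapply(mafs, function(q)
    sample(0:2, n_instances, TRUE, prob = hwe_freqs(q)),
    integer(n_instances))
}

# --- local RNG scope --------------------------------------------------------

# evaluate `code` under set.seed(seed) without disturbing the caller's RNG
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}
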