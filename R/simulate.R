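#' Simulate clean k-way XOR epistasis
#'
#' Generates a balanced case-control SNP dataset whose class is a
#' deterministic parity function of `order` predictive loci: each predictive
#' genotype g (0/1/2, MAF 0.5 under Hardy-Weinberg) is binarized by parity
#' (g mod 2, heterozygote = 1) and the class is the XOR of the bits. The
#' resulting interaction is *clean* (full penetrance), *pure* and *strict*:
#' because each parity bit is Bernoulli(1/2) independent of the others, the
#' joint distribution of any proper subset of the predictive genotypes is
#' identical in cases and controls, so no lower-order effect carries any
#' signal. Non-predictive features are Hardy-Weinberg noise with per-feature
#' MAF ~ Uniform(0.05, 0.5), independent of class.
#'
#' @param order interaction order k, 2..5 in the study design (any k >= 1
#'   accepted).
#' @param n_features total feature count, >= `order`.
#' @param n_instances even instance count; exactly half are cases.
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   bit-identically.
#' @param config_id provenance string (default derived from the arguments).
#' @return a `snp_dataset` with predictive features `M0P0..M0P<k-1>`.
#' @export
simulate_xor <- function(order, n_features, n_instances, seed,
                         config_id = sprintf("xor_k%d_f%d", order, n_features)) {
  if (order > n_features)
    stop("order must not exceed n_features")
  if (n_instances %% 2L != 0L)
    stop("n_instances must be even: exact class balance is impossible")
  model <- xor_penetrance_model(order)
  sample_from_model(model, n_features, n_instances, seed,
                    config_id = config_id)
}

#' The clean k-way XOR interaction as a penetrance table
#'
#' P(case) is 1 for genotype combinations with odd parity-bit sum and 0
#' otherwise; all loci have MAF 0.5. Prevalence is exactly 0.5 and
#' heritability exactly 1 (clean). Exposed so that the penetrance-table
#' sampling route and [simulate_xor()] can be cross-checked against each
#' other.
#'
#' @param order interaction order k.
#' @return a `penetrance_model` with heritability 1.
#' @export
xor_penetrance_model <- function(order) {
  combos <- genotype_combos(order)
  parity <- as.numeric(rowSums(combos %% 2L) %% 2L)
  penetrance_model(rep(0.5, order), parity, prevalence = 0.5,
                   heritability = 1, check = FALSE)
}

#' Simulate two-subgroup heterogeneous 2-way epistasis
#'
#' Instances are split into two subgroups by `ratio`. Each subgroup's class
#' is driven by its own pure/strict 2-locus penetrance model (independently
#' searched), while the other subgroup's predictive pair is drawn
#' class-independently from Hardy-Weinberg in that subgroup. Both subgroups
#' are internally balanced, so the dataset keeps the exact n/2 case quota.
#'
#' @param ratio length-2 positive vector summing to 1, e.g. `c(0.5, 0.5)` or
#'   `c(0.75, 0.25)`. A zero second component degenerates to a plain 2-way
#'   dataset in which the second "predictive" pair carries no signal.
#' @param n_features total feature count (>= 4).
#' @param n_instances even instance count.
#' @param heritability per-subgroup model heritability (default 0.4).
#' @param seed integer RNG seed.
#' @param maf minor allele frequency of the predictive loci (default 0.2).
#' @param difficulty model architecture difficulty passed to the model
#'   search.
#' @param n_candidates model-search budget per subgroup.
#' @param config_id provenance string.
#' @return a `snp_dataset` with four predictive features `M0P0, M0P1`
#'   (subgroup 1) and `M1P0, M1P1` (subgroup 2).
#' @export
simulate_heterogeneous <- function(ratio = c(0.5, 0.5), n_features = 100L,
                                   n_instances = 1600L, heritability = 0.4,
                                   seed = 1L, maf = 0.2, difficulty = "E",
                                   n_candidates = 100L,
                                   config_id = sprintf("het2_%g:%g",
                                                       100 * ratio[1],
                                                       100 * ratio[2])) {
  if (length(ratio) != 2L || any(ratio < 0))
    stop("ratio must be two non-negative proportions")
  if (abs(sum(ratio) - 1) > 1e-9)
    stop("ratio components must sum to 1")
  if (n_features < 4L) stop("n_features must be at least 4")
  if (n_instances %% 2L != 0L)
    stop("n_instances must be even: exact class balance is impossible")
  # even subgroup sizes preserving the total
  n1 <- 2L * round(ratio[1] * n_instances / 2)
  n1 <- min(max(n1, 0L), n_instances)
  n2 <- n_instances - n1
  m1 <- build_penetrance_model(2L, maf, heritability,
                               difficulty = difficulty,
                               seed = derive_seed(seed, "het-model-1"),
                               n_candidates = n_candidates)
  m2 <- build_penetrance_model(2L, maf, heritability,
                               difficulty = difficulty,
                               seed = derive_seed(seed, "het-model-2"),
                               n_candidates = n_candidates)
  f2 <- joint_freqs(m1$mafs)
  combos2 <- genotype_combos(2L)
  local_seed(seed, {
    sub1 <- heterogeneous_subgroup(m1, f2, combos2, n1, active_first = TRUE)
    sub2 <- heterogeneous_subgroup(m2, f2, combos2, n2, active_first = FALSE)
    noise <- sample_noise_features(n_instances, n_features - 4L)
  })
  geno <- cbind(rbind(sub1$geno, sub2$geno), noise)
  labels <- c(sub1$labels, sub2$labels)
  pred <- c("M0P0", "M0P1", "M1P0", "M1P1")
  feature_names <- c(pred, if (n_features > 4L)
    paste0("N", seq_len(n_features - 4L) - 1L))
  ds <- snp_dataset(geno, labels, feature_names, pred,
                    config_id = config_id, seed = seed)
  attr(ds, "models") <- list(m1, m2)
  ds
}

# one balanced subgroup: the active pair drawn from the model conditional on
# class, the inactive pair from Hardy-Weinberg independent of class
heterogeneous_subgroup <- function(model, f, combos, n_sub, active_first) {
  if (n_sub == 0L)
    return(list(geno = matrix(integer(0), 0L, 4L), labels = integer(0)))
  if (n_sub %% 2L != 0L) stop("subgroup sizes must be even")
  active <- sample_predictive_combos(f, model$table, combos, n_sub)
  inert <- cbind(
    sample(0:2, n_sub, TRUE, prob = hwe_freqs(model$mafs[1])),
    sample(0:2, n_sub, TRUE, prob = hwe_freqs(model$mafs[2])))
  geno <- if (active_first) cbind(active, inert) else cbind(inert, active)
  list(geno = geno, labels = rep(1:0, each = n_sub / 2L))
}

#' Simulate main-effect or additive (non-epistatic) architectures
#'
#' Each of `n_predictive` loci receives a centered random liability effect
#' whose variance is proportional to its share of the heritability; the
#' penetrance table is the logistic link of the summed liabilities, with the
#' intercept solved for exact prevalence and the slope for the exact total
#' penetrance-scale heritability. Every locus is therefore individually
#' informative (in contrast with pure epistasis), which is the defining
#' property of these non-epistatic controls. Among candidate architectures
#' the difficulty proxy (unweighted variance of the penetrance entries)
#' selects the easiest (`"E"` = minimum) or hardest (`"H"` = maximum).
#'
#' @param n_predictive number of predictive loci (1, 2 or 4 in the study
#'   design).
#' @param n_features total feature count.
#' @param heritability total heritability in (0, 1).
#' @param difficulty `"E"` or `"H"`.
#' @param seed integer RNG seed.
#' @param n_instances even instance count (default 1600).
#' @param maf minor allele frequency of the predictive loci (default 0.2).
#' @param shares positive per-locus liability-variance shares summing to 1;
#'   default equal shares. `c(0.75, 0.25)` reproduces the unequal 2-locus
#'   additive variant.
#' @param prevalence prevalence K (default 0.5; the logistic link keeps the
#'   table inside (0,1) for any prevalence).
#' @param n_candidates candidate budget for the architecture search.
#' @param config_id provenance string.
#' @return a `snp_dataset` with predictive features `M0P0, M1P0, ...` (one
#'   per locus).
#' @export
simulate_main_or_additive <- function(n_predictive, n_features, heritability,
                                      difficulty = c("E", "H"), seed = 1L,
                                      n_instances = 1600L, maf = 0.2,
                                      shares = rep(1 / n_predictive,
                                                   n_predictive),
                                      prevalence = NULL,
                                      n_candidates = 100L,
                                      config_id = sprintf("add%d", n_predictive)) {
  difficulty <- match.arg(difficulty)
  if (n_predictive > n_features)
    stop("n_predictive must not exceed n_features")
  stopifnot(length(shares) == n_predictive, all(shares > 0),
            abs(sum(shares) - 1) < 1e-9,
            heritability > 0, heritability < 1)
  model <- build_additive_model(n_predictive, maf, heritability, shares,
                                prevalence, difficulty,
                                seed = derive_seed(seed, "add-model"),
                                n_candidates = n_candidates)
  ds <- sample_from_model(model, n_features, n_instances, seed,
                          config_id = config_id)
  # per-locus naming convention: each main-effect locus is its own model
  pred <- paste0("M", seq_len(n_predictive) - 1L, "P0")
  idx <- match(ds$predictive_ids, ds$feature_names)
  ds$feature_names[idx] <- pred
  colnames(ds$genotypes) <- ds$feature_names
  ds$predictive_ids <- pred
  ds
}

# Additive-on-the-liability-scale model: each locus contributes a centered
# random effect delta_l(g_l) with liability variance proportional to its
# heritability share; the penetrance is the logistic link
# p(g1..gm) = plogis(theta + beta * sum_l delta_l(g_l)), with theta solved
# so the prevalence is exactly K and beta so the penetrance-scale
# heritability identity sum f (p - K)^2 / (K(1-K)) hits the target exactly.
# Strict penetrance-scale additivity cannot represent several loci sharing
# a large heritability (the per-locus deviation ranges add and overflow
# [0,1]); the liability link is the standard construction and keeps p in
# (0,1) for any heritability below 1.
build_additive_model <- function(m, maf, h2, shares, K = NULL, difficulty,
                                 seed, n_candidates = 100L,
                                 max_attempts = 10L * n_candidates) {
  if (is.null(K)) K <- 0.5
  f1 <- hwe_freqs(maf)
  combos <- genotype_combos(m)
  fj <- joint_freqs(rep(maf, m))
  best <- NULL
  best_proxy <- if (difficulty == "E") Inf else -Inf
  n_valid <- 0L
  local_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      deltas <- lapply(shares, function(sh) {
        d <- stats::runif(3)
        d <- d - sum(f1 * d)
        s <- sum(f1 * d^2)
        if (s <= 1e-12) return(NULL)
        d * sqrt(sh / s)
      })
      if (any(vapply(deltas, is.null, logical(1)))) next
      L <- rep(0, nrow(combos))
      for (l in seq_len(m)) L <- L + deltas[[l]][combos[, l] + 1L]
      p <- solve_liability_table(L, fj, K, h2)
      if (is.null(p)) next
      n_valid <- n_valid + 1L
      proxy <- stats::var(p)
      better <- if (difficulty == "E") proxy < best_proxy else proxy > best_proxy
      if (better) { best_proxy <- proxy; best <- p }
      if (n_valid >= n_candidates) break
    }
  })
  if (n_valid == 0L)
    stop(sprintf(paste0(
      "infeasible constraint set: no additive %d-locus table with maf = %g, ",
      "heritability = %g, prevalence = %g found in %d attempts"),
      m, maf, h2, K, max_attempts))
  penetrance_model(rep(maf, m), best, K, h2, check = FALSE)
}

# penetrance table p = plogis(theta + beta * L) with exact prevalence and
# penetrance-scale heritability; NULL if the target is out of reach
solve_liability_table <- function(L, fj, K, h2, beta_max = 5000) {
  theta_for <- function(beta) {
    stats::uniroot(function(th) sum(fj * stats::plogis(th + beta * L)) - K,
                   interval = c(-50, 50), tol = 1e-13)$root
  }
  h2_gap <- function(beta) {
    p <- stats::plogis(theta_for(beta) + beta * L)
    sum(fj * (p - K)^2) / (K * (1 - K)) - h2
  }
  hi <- 1
  while (h2_gap(hi) < 0) {
    hi <- hi * 4
    if (hi > beta_max) return(NULL)
  }
  beta <- stats::uniroot(h2_gap, c(0, hi), tol = 1e-12)$root
  stats::plogis(theta_for(beta) + beta * L)
}
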