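#' Plug-in mutual information between two discrete vectors
#'
#' Maximum-likelihood (plug-in) estimate from the empirical contingency
#' table: sum over cells of p_xy * log(p_xy / (p_x p_y)). Non-negative by
#' construction and invariant to relabeling of either variable's
#' categories.
#'
#' @param x,y equal-length vectors coerced to factors.
#' @param base logarithm base: `exp(1)` for nats (default), 2 for bits.
#' @return mutual information as a number.
#' @export
plugin_mi <- function(x, y, base = exp(1)) {
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz])) / log(base)
}

#' Joint mutual information of a feature subset with the class
#'
#' Collapses the selected genotype columns into a single joint variable and
#' evaluates [plugin_mi()] against the class labels. Used to verify the
#' pure/strict property of simulated interactions: for a clean k-way XOR,
#' every proper subset of the predictive loci has (asymptotically) zero
#' joint information about the class.
#'
#' @param ds a `snp_dataset`.
#' @param features character names or integer indices of the columns.
#' @param base logarithm base (2 for bits).
#' @return mutual information as a number.
#' @export
joint_mi <- function(ds, features, base = exp(1)) {
  x <- ds$genotypes[, features, drop = FALSE]
  joint <- x[, 1L]
  for (j in seq_len(ncol(x))[-1L]) joint <- joint * 3L + x[, j]
  plugin_mi(joint, ds$labels, base = base)
}

#' Mutual-information feature scores (univariate control)
#'
#' The non-RBA positive control of the evaluation: each feature is scored
#' by the plug-in mutual information (in nats) between its three genotype
#' levels and the binary class. Sensitive to univariate effects only -- a
#' pure epistatic interaction leaves every single-locus MI at its noise
#' floor, which is why this control fails on XOR data.
#'
#' @param ds a `snp_dataset`.
#' @return a `feature_scores` object (method `MI`); scores are >= 0.
#' @export
mutual_information_scores <- function(ds) {
  validate_snp_dataset(ds)
  s <- apply(ds$genotypes, 2L, plugin_mi, y = ds$labels)
  feature_scores("MI", s, ds$feature_names)
}

#' Random-shuffle ranking (negative control)
#'
#' Ranks the features by a seeded uniformly random permutation, bypassing
#' scoring entirely (`scheme = "native"`). Its weakest-link distribution is
#' the analytic null against which real methods are compared.
#'
#' @param ds a `snp_dataset`.
#' @param seed integer RNG seed.
#' @return a `ranking_result` with method `Shuffle`.
#' @export
shuffle_ranking <- function(ds, seed) {
  validate_snp_dataset(ds)
  ord <- local_seed(seed, sample(ds$feature_names))
  structure(list(method = "Shuffle", scheme = "native", order = ord),
            class = "ranking_result")
}
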