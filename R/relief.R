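# --- distances --------------------------------------------------------------

#' Genotype difference used by the Relief metric
#'
#' Discrete 0/1 mismatch indicator: two genotypes differ (1) unless they are
#' identical (0). This is the conventional discrete-attribute metric of
#' Relief implementations for SNP data; summing it over features gives the
#' Hamming distance between instances.
#'
#' @param a,b genotype vectors with values in \{0,1,2\} (recycled).
#' @return numeric vector of 0/1 mismatch indicators.
#' @export
genotype_diff <- function(a, b) {
  if (!all(a %in% 0:2) || !all(b %in% 0:2))
    stop("genotypes must be 0, 1 or 2")
  as.numeric(a != b)
}

#' Instance-by-instance Hamming distance matrix
#'
#' Computes the pairwise Hamming distance over all features (predictive and
#' non-predictive alike) via indicator cross-products, so the entries are
#' exact integer-valued doubles. Symmetric with a zero diagonal.
#'
#' @param ds a `snp_dataset` or a 0/1/2 integer matrix (rows = instances).
#' @return an n x n numeric matrix of integer-valued distances.
#' @export
pairwise_distances <- function(ds) {
  x <- if (inherits(ds, "snp_dataset")) ds$genotypes else ds
  matches <- matrix(0, nrow(x), nrow(x))
  for (g in 0:2) {
    a <- matrix(as.numeric(x == g), nrow(x), ncol(x))
    matches <- matches + tcrossprod(a)
  }
  d <- ncol(x) - matches
  diag(d) <- 0
  d
}

# --- ReliefF ----------------------------------------------------------------

#' ReliefF feature scores
#'
#' Deterministic full-pass ReliefF for discrete genotypes and a binary
#' class: every instance serves once as the target; its `nn` nearest hits
#' (same class) and `nn` nearest misses (opposite class) are found by
#' Hamming distance with ties broken by ascending instance index, and each
#' feature's weight accumulates mismatches with misses (positive) and hits
#' (negative). The final score is the accumulated mismatch-count difference
#' divided by `n_instances * nn`, which bounds every score in [-1, 1].
#'
#' @param ds a `snp_dataset`.
#' @param nn number of nearest hits and misses per target (the classic
#'   ReliefF run parameter; the benchmark grid uses 10 and 100). Capped,
#'   with a warning, at the available number of same/opposite-class
#'   instances.
#' @param distances optional precomputed [pairwise_distances()] matrix.
#' @return a `feature_scores` object (method `ReliefF-<nn>NN`).
#' @export
relieff_scores <- function(ds, nn, distances = NULL) {
  validate_snp_dataset(ds)
  x <- ds$genotypes
  y <- ds$labels
  n <- nrow(x)
  f <- ncol(x)
  stopifnot(nn >= 1L)
  if (min(tabulate(y + 1L, 2L)) < 2L)
    stop("each class needs at least 2 instances")
  D <- if (is.null(distances)) pairwise_distances(x) else distances
  idx0 <- which(y == 0L)
  idx1 <- which(y == 1L)
  avail <- min(length(idx0), length(idx1) - 1L,
               length(idx1), length(idx0) - 1L)
  nn_use <- as.integer(min(nn, avail))
  if (nn_use < nn)
    warning(sprintf("nn = %d exceeds available neighbors; capped at %d",
                    nn, nn_use))
  acc <- numeric(f)   # integer-valued mismatch-count accumulator
  for (i in seq_len(n)) {
    same <- if (y[i] == 0L) idx0 else idx1
    opp <- if (y[i] == 0L) idx1 else idx0
    same <- same[same != i]
    nh <- min(nn_use, length(same))
    nm <- min(nn_use, length(opp))
    sel_h <- same[order(D[same, i], same)[seq_len(nh)]]
    sel_m <- opp[order(D[opp, i], opp)[seq_len(nm)]]
    ri <- x[i, ]
    ch <- .colSums(x[sel_h, , drop = FALSE] != rep(ri, each = nh), nh, f)
    cm <- .colSums(x[sel_m, , drop = FALSE] != rep(ri, each = nm), nm, f)
    acc <- acc + (cm - ch)
  }
  feature_scores(sprintf("ReliefF-%dNN", nn), acc / (n * nn_use),
                 ds$feature_names)
}

# --- MultiSURF / MultiSURF* -------------------------------------------------

#' MultiSURF feature scores
#'
#' Parameter-free Relief scoring: for each target instance the neighborhood
#' is defined adaptively by the distance distribution rather than a fixed
#' neighbor count. With T the mean and s the standard deviation of the
#' target's distances to all other instances, instances closer than
#' T - s/2 are "near" (the s/2 dead-band excludes ambiguous neighbors).
#' Near-miss mismatches raise a feature's weight and near-hit mismatches
#' lower it; each side is normalized by its realized neighbor count, a
#' target with an empty side contributes nothing for that side, and the
#' result is averaged over targets, keeping all scores in [-1, 1].
#'
#' @inheritParams relieff_scores
#' @return a `feature_scores` object (method `MultiSURF`).
#' @export
multisurf_scores <- function(ds, distances = NULL) {
  surf_scores(ds, distances, far = FALSE, method = "MultiSURF")
}

#' MultiSURF* feature scores
#'
#' MultiSURF extended with inverse "far" scoring: instances beyond T + s/2
#' form the far set, where the update direction flips (far-hit mismatches
#' raise the weight, far-miss mismatches lower it), which is what gives the
#' algorithm its power on pure pairwise interactions. Near and far zones are
#' each normalized by their realized counts and contribute with equal
#' weight; the per-target contribution is their mean, so scores stay in
#' [-1, 1].
#'
#' @inheritParams relieff_scores
#' @return a `feature_scores` object (method `MultiSURF*`).
#' @export
multisurf_star_scores <- function(ds, distances = NULL) {
  surf_scores(ds, distances, far = TRUE, method = "MultiSURF*")
}

# shared MultiSURF / MultiSURF* pass
surf_scores <- function(ds, distances, far, method) {
  validate_snp_dataset(ds)
  x <- ds$genotypes
  y <- ds$labels
  n <- nrow(x)
  f <- ncol(x)
  if (min(tabulate(y + 1L, 2L)) < 2L)
    stop("each class needs at least 2 instances")
  D <- if (is.null(distances)) pairwise_distances(x) else distances
  W <- numeric(f)
  m <- n - 1
  for (i in seq_len(n)) {
    d <- D[, i]
    s <- sum(d)              # distances are integers: sums are exact
    ssq <- sum(d * d)
    Ti <- s / m
    v <- (ssq - s * s / m) / (m - 1)
    if (v < 0) v <- 0
    dead <- sqrt(v) / 2
    ri <- x[i, ]
    near <- which(d < Ti - dead)
    near <- near[near != i]
    hit <- near[y[near] == y[i]]
    mis <- near[y[near] != y[i]]
    contrib <- zone_contrib(x, ri, mis, hit, f)
    if (far) {
      fa <- which(d > Ti + dead)
      fhit <- fa[y[fa] == y[i]]
      fmis <- fa[y[fa] != y[i]]
      # inverse scoring: far-hit mismatch is positive, far-miss negative
      contrib <- (contrib + zone_contrib(x, ri, fhit, fmis, f)) / 2
    }
    W <- W + contrib
  }
  feature_scores(method, W / n, ds$feature_names)
}

# per-zone contribution: positive-set mismatch rate minus negative-set
# mismatch rate, each normalized by its realized count; empty sides drop out
zone_contrib <- function(x, ri, pos, neg, f) {
  contrib <- numeric(f)
  np <- length(pos)
  nn <- length(neg)
  if (np > 0L)
    contrib <- .colSums(x[pos, , drop = FALSE] != rep(ri, each = np),
                        np, f) / np
  if (nn > 0L)
    contrib <- contrib - .colSums(x[neg, , drop = FALSE] != rep(ri, each = nn),
                                  nn, f) / nn
  contrib
}
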