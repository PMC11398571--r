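#' Construct a feature-scores object
#'
#' One real-valued importance score per feature from one scoring method.
#'
#' @param method scoring-method identifier (e.g. `"ReliefF-10NN"`,
#'   `"MultiSURF"`, `"MI"`).
#' @param scores numeric vector, one finite value per feature.
#' @param feature_names character vector aligned with `scores`.
#' @return an object of class `feature_scores`.
#' @export
feature_scores <- function(method, scores, feature_names) {
  if (length(scores) != length(feature_names))
    stop("scores and feature_names must have the same length")
  if (any(!is.finite(scores)))
    stop("scores must be finite with no missing values")
  structure(list(method = method,
                 scores = stats::setNames(as.numeric(scores), feature_names)),
            class = "feature_scores")
}

#' @export
print.feature_scores <- function(x, ...) {
  cat(sprintf("feature_scores: %s, %d features, range [%.4g, %.4g]\n",
              x$method, length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Rank features under the standard or absolute-value scheme
#'
#' Standard ranking sorts feature scores in descending order from most
#' positive to most negative; absolute-value ranking first takes the
#' absolute value of every score and then sorts descending, so strongly
#' negative scores rank alongside strongly positive ones. Ties are broken
#' by ascending feature index (the input order), making the ordering
#' deterministic.
#'
#' @param scores a `feature_scores` object.
#' @param scheme `"standard"` or `"absolute"`.
#' @return a `ranking_result`: list with `method`, `scheme`, and `order`, a
#'   permutation of the feature names with rank 1 first.
#' @export
rank_features <- function(scores, scheme = c("standard", "absolute")) {
  scheme <- match.arg(scheme)
  if (!inherits(scores, "feature_scores"))
    stop("scores must be a feature_scores object")
  s <- scores$scores
  key <- if (scheme == "absolute") abs(s) else s
  ord <- order(-key, seq_along(key))
  structure(list(method = scores$method, scheme = scheme,
                 order = names(s)[ord]),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  top <- utils::head(x$order, 5L)
  cat(sprintf("ranking_result: %s (%s), %d features; top: %s%s\n",
              x$method, x$scheme, length(x$order),
              paste(top, collapse = ", "),
              if (length(x$order) > 5L) ", ..." else ""))
  invisible(x)
}

#' Weakest-link position of the predictive features
#'
#' The 1-based rank of the lowest-ranked (worst) known predictive feature
#' in a ranking: if the predictive features sit at ranks 1 and 5, the
#' weakest link is 5. This is the unit of the power analysis, since missing
#' even one predictive feature defeats interaction detection.
#'
#' @param ranking a `ranking_result`.
#' @param predictive_ids character vector of predictive feature names; all
#'   must appear in the ranking.
#' @return integer position in 1..n_features (>= the number of predictive
#'   features).
#' @export
weakest_link <- function(ranking, predictive_ids) {
  pos <- match(predictive_ids, ranking$order)
  if (anyNA(pos))
    stop("unknown predictive feature(s): ",
         paste(predictive_ids[is.na(pos)], collapse = ", "))
  max(pos)
}
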