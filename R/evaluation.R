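#' Per-rank-position detection power of a method
#'
#' Converts the weakest-link positions of a configuration's replicates into
#' a power curve: the percentage of replicates whose weakest link is at or
#' above (i.e. numerically less than or equal to) each rank position. The
#' curve is non-decreasing and reaches 100 at the last position. The strict
#' reading (`strict = TRUE`) counts only weakest links strictly better than
#' the position; it differs by exactly one position shift.
#'
#' @param weakest_links integer vector of weakest-link positions, one per
#'   replicate, each in 1..n_features.
#' @param n_features number of rank positions.
#' @param strict use the strict (<) comparison instead of inclusive (<=).
#' @return numeric vector of length `n_features` with values in [0, 100].
#' @export
power_curve <- function(weakest_links, n_features, strict = FALSE) {
  wl <- as.integer(weakest_links)
  if (length(wl) == 0L) return(rep(NA_real_, n_features))
  if (any(wl < 1L | wl > n_features))
    stop("weakest-link positions must lie in 1..n_features")
  counts <- tabulate(wl, nbins = n_features)
  cum <- cumsum(counts)
  if (strict) cum <- c(0L, cum[-n_features])
  100 * cum / length(wl)
}

#' Default method set of the evaluation
#'
#' The ten rows of each heatmap: the four RBAs under both ranking schemes,
#' plus the mutual-information and random-shuffle controls.
#'
#' @return character vector of row labels in display order.
#' @export
method_rows <- function() {
  rba <- c("ReliefF-10NN", "ReliefF-100NN", "MultiSURF", "MultiSURF*")
  c(rba, paste0(rba, "_ABS"), "MI", "Shuffle")
}

#' Run the scoring / ranking / weakest-link experiment over a grid
#'
#' For every configuration: builds the configuration's penetrance model
#' (where applicable), generates `n_replicates` seeded datasets, scores each
#' with the requested methods (sharing one distance matrix across the RBAs),
#' ranks RBA scores under both the standard and absolute-value schemes (MI
#' under standard only, shuffle natively), and records the weakest-link
#' position of the known predictive features.
#'
#' @param grid a data.frame of configurations ([benchmark_grid()] rows).
#' @param n_replicates replicates per configuration (default 30).
#' @param base_seed master seed; per-replicate seeds are derived exactly as
#'   in [expand_grid_jobs()], so results are reproducible end to end.
#' @param rows subset of [method_rows()] to compute (default all ten).
#' @param n_candidates model-search budget for model-based families.
#' @param keep_scores also return the raw per-dataset feature scores
#'   (memory proportional to datasets x features).
#' @param verbose print per-configuration progress.
#' @return a list with `results` (data.frame: config_id, replicate, row,
#'   method, scheme, weakest_link, n_features) and `heatmaps` (named list,
#'   one rows-by-positions percentage matrix per configuration); when
#'   `keep_scores = TRUE`, also `scores` (data.frame: config_id, replicate,
#'   method, feature, predictive, score).
#' @export
run_experiment <- function(grid, n_replicates = 30L, base_seed = 1L,
                           rows = method_rows(), n_candidates = 100L,
                           keep_scores = FALSE, verbose = FALSE) {
  stopifnot(all(rows %in% method_rows()))
  res <- list()
  score_rows <- list()
  heatmaps <- list()
  for (ci in seq_len(nrow(grid))) {
    config <- grid[ci, , drop = FALSE]
    if (verbose)
      message(sprintf("[%d/%d] %s", ci, nrow(grid), config$config_id))
    model <- config_model(config, base_seed, n_candidates = n_candidates)
    cfg_res <- list()
    for (r in seq_len(n_replicates)) {
      seed <- derive_seed(base_seed, paste0(config$config_id, "#", r))
      ds <- generate_dataset(config, seed, model, n_candidates = n_candidates)
      wl <- replicate_weakest_links(ds, rows,
                                    shuffle_seed = derive_seed(
                                      base_seed,
                                      paste0(config$config_id, "#", r,
                                             "/shuffle")),
                                    keep_scores = keep_scores)
      cfg_res[[r]] <- data.frame(
        config_id = config$config_id, replicate = r,
        row = names(wl$links), method = wl$method, scheme = wl$scheme,
        weakest_link = unname(wl$links),
        n_features = config$n_features, stringsAsFactors = FALSE)
      if (keep_scores && length(wl$scores))
        score_rows[[length(score_rows) + 1L]] <-
          data.frame(config_id = config$config_id, replicate = r, wl$scores,
                     stringsAsFactors = FALSE)
    }
    cfg_res <- do.call(rbind, cfg_res)
    res[[ci]] <- cfg_res
    if (n_replicates > 0L)
      heatmaps[[config$config_id]] <-
        heatmap_matrix(cfg_res, config$n_features, rows = rows)
  }
  out <- list(results = if (length(res)) do.call(rbind, res) else
                data.frame(), heatmaps = heatmaps)
  if (keep_scores)
    out$scores <- if (length(score_rows)) do.call(rbind, score_rows) else
      data.frame()
  out
}

# score and rank one dataset under the requested heatmap rows
replicate_weakest_links <- function(ds, rows, shuffle_seed,
                                    keep_scores = FALSE) {
  rba_specs <- list(
    "ReliefF-10NN" = function(D) relieff_scores(ds, 10L, D),
    "ReliefF-100NN" = function(D) relieff_scores(ds, 100L, D),
    "MultiSURF" = function(D) multisurf_scores(ds, D),
    "MultiSURF*" = function(D) multisurf_star_scores(ds, D))
  need_rba <- names(rba_specs)[vapply(names(rba_specs), function(m)
    any(rows %in% c(m, paste0(m, "_ABS"))), logical(1))]
  D <- if (length(need_rba)) pairwise_distances(ds) else NULL
  links <- numeric(0)
  method <- character(0)
  scheme <- character(0)
  scores_df <- NULL
  keep <- function(fs) {
    if (!keep_scores) return()
    scores_df <<- rbind(scores_df, data.frame(
      method = fs$method, feature = names(fs$scores),
      predictive = names(fs$scores) %in% ds$predictive_ids,
      score = unname(fs$scores), stringsAsFactors = FALSE))
  }
  for (m in need_rba) {
    fs <- rba_specs[[m]](D)
    keep(fs)
    if (m %in% rows) {
      links[m] <- weakest_link(rank_features(fs, "standard"),
                               ds$predictive_ids)
      method <- c(method, m); scheme <- c(scheme, "standard")
    }
    ma <- paste0(m, "_ABS")
    if (ma %in% rows) {
      links[ma] <- weakest_link(rank_features(fs, "absolute"),
                                ds$predictive_ids)
      method <- c(method, m); scheme <- c(scheme, "absolute")
    }
  }
  if ("MI" %in% rows) {
    fs <- mutual_information_scores(ds)
    keep(fs)
    links["MI"] <- weakest_link(rank_features(fs, "standard"),
                                ds$predictive_ids)
    method <- c(method, "MI"); scheme <- c(scheme, "standard")
  }
  if ("Shuffle" %in% rows) {
    links["Shuffle"] <- weakest_link(shuffle_ranking(ds, shuffle_seed),
                                     ds$predictive_ids)
    method <- c(method, "Shuffle"); scheme <- c(scheme, "native")
  }
  list(links = links, method = method, scheme = scheme, scores = scores_df)
}

#' Assemble one configuration's power heatmap matrix
#'
#' Rows are method/scheme identifiers in [method_rows()] order, columns are
#' rank positions 1..n_features, cells are the power percentages of
#' [power_curve()].
#'
#' @param results the rows of a `run_experiment()` results data.frame
#'   belonging to one configuration.
#' @param n_features number of rank positions.
#' @param rows row labels to include, in order.
#' @param strict passed to [power_curve()].
#' @return a numeric matrix, `length(rows)` x `n_features`.
#' @export
heatmap_matrix <- function(results, n_features, rows = method_rows(),
                           strict = FALSE) {
  mat <- t(vapply(rows, function(m)
    power_curve(results$weakest_link[results$row == m], n_features,
                strict = strict),
    numeric(n_features)))
  dimnames(mat) <- list(rows, seq_len(n_features))
  mat
}

#' Write experiment outputs as TSV files
#'
#' Writes the tidy results table (`results.tsv`: config_id, replicate,
#' method, scheme, weakest_link) and one heatmap matrix per configuration
#' (`heatmap_<config_id>.tsv`).
#'
#' @param experiment the list returned by [run_experiment()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(experiment$results, file.path(dir, "results.tsv"),
                     sep = "\t", quote = FALSE)
  for (id in names(experiment$heatmaps)) {
    m <- experiment$heatmaps[[id]]
    dt <- data.table::data.table(row = rownames(m))
    dt <- cbind(dt, data.table::as.data.table(m))
    data.table::fwrite(dt, file.path(dir, paste0("heatmap_", id, ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  invisible(dir)
}

#' Plot a power heatmap
#'
#' Renders a [heatmap_matrix()] in the orientation of the study figures:
#' one row per method, rank positions along the x axis, low power in
#' orange/white and high power in blue. Rendering is cosmetic; the matrix
#' is the tested artifact. Requires ggplot2.
#'
#' @param mat a matrix from [heatmap_matrix()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_power_heatmap <- function(mat, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(
    row = factor(rep(rownames(mat), ncol(mat)), levels = rev(rownames(mat))),
    position = rep(seq_len(ncol(mat)), each = nrow(mat)),
    power = as.vector(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = position, y = row, fill = power)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkorange", mid = "white",
                                  high = "royalblue4", midpoint = 50,
                                  limits = c(0, 100), name = "Power (%)") +
    ggplot2::labs(x = "Rank position", y = NULL, title = title) +
    ggplot2::theme_minimal()
}
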