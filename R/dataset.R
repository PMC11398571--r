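#' Construct a simulated SNP dataset
#'
#' A `snp_dataset` bundles a genotype matrix (additively coded 0/1/2), a
#' binary class label per instance, and the ground-truth identity of the
#' predictive features, together with provenance (configuration id and seed).
#' All simulators in the package return this container and all scoring
#' functions consume it.
#'
#' @param genotypes integer matrix, rows = instances, columns = features,
#'   values in \{0,1,2\}. Column names, if present, must match
#'   `feature_names`.
#' @param labels integer vector of 0/1 class labels, one per row.
#' @param feature_names character vector of unique feature names.
#' @param predictive_ids non-empty subset of `feature_names` carrying the
#'   simulated signal.
#' @param config_id string identifying the generating configuration.
#' @param seed integer seed the dataset was generated from.
#' @return An object of class `snp_dataset`: a list with the fields above.
#' @export
snp_dataset <- function(genotypes, labels, feature_names,
                        predictive_ids, config_id = "", seed = NA_integer_) {
  storage.mode(genotypes) <- "integer"
  labels <- as.integer(labels)
  dimnames(genotypes) <- list(NULL, feature_names)
  ds <- structure(
    list(genotypes = genotypes, labels = labels,
         feature_names = feature_names, predictive_ids = predictive_ids,
         config_id = config_id, seed = as.integer(seed)),
    class = "snp_dataset")
  validate_snp_dataset(ds)
  ds
}

#' Validate a snp_dataset
#'
#' Checks the structural invariants: genotype values in \{0,1,2\}, labels in
#' \{0,1\}, unique feature names aligned with the matrix, and a non-empty
#' predictive set contained in the feature names.
#'
#' @param ds a `snp_dataset`.
#' @return `ds`, invisibly; errors on violation.
#' @export
validate_snp_dataset <- function(ds) {
  g <- ds$genotypes
  if (!is.matrix(g)) stop("genotypes must be a matrix")
  if (!all(g %in% 0:2)) stop("genotype values must be 0, 1 or 2")
  if (!all(ds$labels %in% 0:1)) stop("labels must be 0 or 1")
  if (length(ds$labels) != nrow(g))
    stop("labels length must equal the number of instances")
  if (anyDuplicated(ds$feature_names))
    stop("feature names must be unique")
  if (length(ds$feature_names) != ncol(g))
    stop("feature_names length must equal the number of features")
  if (length(ds$predictive_ids) == 0L)
    stop("predictive_ids must be non-empty")
  if (!all(ds$predictive_ids %in% ds$feature_names))
    stop("predictive_ids must be a subset of feature_names")
  invisible(ds)
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat(sprintf("snp_dataset: %d instances x %d features (%d cases / %d controls)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  cat(sprintf("  predictive: %s\n", paste(x$predictive_ids, collapse = ", ")))
  if (nzchar(x$config_id))
    cat(sprintf("  config: %s (seed %d)\n", x$config_id, x$seed))
  invisible(x)
}

#' Number of instances and features of a dataset
#' @param ds a `snp_dataset`.
#' @return integer vector `c(instances, features)`.
#' @export
dim.snp_dataset <- function(ds) dim(ds$genotypes)

#' Write a dataset in GAMETES-dialect tab-delimited text
#'
#' The file has a header row of feature names plus a final `Class` column,
#' genotype cells 0/1/2 and class cells 0/1, matching the output dialect of
#' the GAMETES simulator. A sidecar JSON manifest (`<path>.manifest.json`)
#' records the predictive feature ids, configuration id and seed so that the
#' ground truth survives the round trip.
#'
#' @param ds a `snp_dataset`.
#' @param path output file path.
#' @param manifest write the sidecar manifest (default `TRUE`).
#' @param extra named list merged into the manifest (e.g. a penetrance
#'   table).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, manifest = TRUE, extra = list()) {
  dt <- data.table::as.data.table(ds$genotypes)
  data.table::setnames(dt, ds$feature_names)
  dt[["Class"]] <- ds$labels
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  if (manifest) {
    man <- c(list(predictive_ids = ds$predictive_ids,
                  config_id = ds$config_id, seed = ds$seed),
             extra)
    jsonlite::write_json(man, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a GAMETES-dialect dataset file
#'
#' Accepts files written by [write_dataset()] as well as real GAMETES v2.2
#' output. Predictive features are taken from, in order of precedence: the
#' `predictive_ids` argument, a sidecar `<path>.manifest.json`, or the
#' GAMETES naming convention (`M0P0`, `M1P1`, ... i.e. names matching
#' `^M[0-9]+P[0-9]+$`).
#'
#' @param path dataset file (tab-delimited, final column `Class`).
#' @param predictive_ids optional explicit predictive feature names.
#' @return a `snp_dataset`.
#' @export
read_dataset <- function(path, predictive_ids = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "integer")
  cls <- names(dt)[ncol(dt)]
  if (!identical(cls, "Class"))
    stop("expected the final column to be named 'Class'")
  labels <- dt[["Class"]]
  dt[["Class"]] <- NULL
  feature_names <- names(dt)
  config_id <- ""
  seed <- NA_integer_
  man_path <- paste0(path, ".manifest.json")
  if (is.null(predictive_ids) && file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    predictive_ids <- man$predictive_ids
    config_id <- man$config_id %||% ""
    seed <- man$seed %||% NA_integer_
  }
  if (is.null(predictive_ids)) {
    predictive_ids <- grep("^M[0-9]+P[0-9]+$", feature_names, value = TRUE)
    if (length(predictive_ids) == 0L)
      stop("no manifest found and no features match the M*P* convention; ",
           "supply predictive_ids explicitly")
  }
  snp_dataset(as.matrix(dt), labels, feature_names, predictive_ids,
              config_id = config_id, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
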