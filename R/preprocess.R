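## Metabolite QC chain: missingness filter -> per-batch median scaling ->
## minimum-value imputation -> rank-based inverse normal transform.
## The order is fixed; each stage records itself in the object's stage tag.

#' Construct a metabolite matrix with batch labels and a processing stage
#'
#' @param values samples x metabolites numeric matrix (`NA` = missing);
#'   row names are sample ids, column names metabolite names.
#' @param batch batch identifier per sample (length = sample count).
#' @param stage one of `"raw"`, `"scaled"`, `"imputed"`, `"normalized"`.
#' @return an object of class `"metabolite_matrix"`: a list with elements
#'   `values`, `batch`, `stage`.
#' @export
metabolite_matrix <- function(values, batch, stage = "raw") {
  if (!is.matrix(values)) values <- as.matrix(values)
  stage <- match.arg(stage, c("raw", "scaled", "imputed", "normalized"))
  batch <- as.character(batch)
  if (length(batch) != nrow(values)) {
    stop("`batch` must have one label per sample (row)", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("met_%03d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%05d", seq_len(nrow(values)))
  }
  structure(list(values = values, batch = batch, stage = stage),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("metabolite_matrix: %d samples x %d metabolites, %d batch(es), stage '%s'\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch)), x$stage))
  cat(sprintf("  missing: %.1f%% of entries\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

stage_index <- function(stage) {
  match(stage, c("raw", "scaled", "imputed", "normalized"))
}

#' Drop metabolites with excess missingness
#'
#' Metabolites missing in strictly more than `threshold` of samples are
#' excluded (a metabolite missing in exactly the threshold fraction is kept).
#'
#' @param m a [metabolite_matrix()] at stage `"raw"`.
#' @param threshold maximum tolerated missing fraction (default 0.20).
#' @return the filtered matrix; dropped names and their missing fractions are
#'   attached as attribute `"dropped"`. Warns (does not fail) if everything
#'   is dropped.
#' @export
filter_missingness <- function(m, threshold = 0.20) {
  stopifnot(inherits(m, "metabolite_matrix"))
  check_fraction(threshold, "threshold")
  if (m$stage != "raw") stop("missingness filter applies to raw data", call. = FALSE)
  frac <- colMeans(is.na(m$values))
  drop <- frac > threshold
  if (all(drop) && ncol(m$values) > 0) {
    warning("all metabolites exceed the missingness threshold; output has zero columns")
  }
  out <- metabolite_matrix(m$values[, !drop, drop = FALSE], m$batch, stage = "raw")
  attr(out, "dropped") <- frac[drop]
  out
}

#' Scale each metabolite to a within-batch median of one
#'
#' For every (metabolite, batch) cell, observed values are divided by the
#' median of the observed values of that metabolite in that batch, so each
#' batch — and hence the metabolite — gets a median of one. Missing entries
#' stay missing. Idempotent.
#'
#' @param m a [metabolite_matrix()] at stage `"raw"` (possibly filtered).
#' @return the matrix at stage `"scaled"`.
#' @export
batch_median_scale <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  if (stage_index(m$stage) > stage_index("scaled")) {
    stop("matrix is already past the scaling stage", call. = FALSE)
  }
  v <- m$values
  for (b in unique(m$batch)) {
    rows <- m$batch == b
    for (j in seq_len(ncol(v))) {
      obs <- v[rows, j]
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0) {
        stop(sprintf("metabolite '%s' has no observed values in batch '%s'",
                     colnames(v)[j], b), call. = FALSE)
      }
      med <- median(obs)
      if (med == 0) {
        stop(sprintf("within-batch median of metabolite '%s' in batch '%s' is zero",
                     colnames(v)[j], b), call. = FALSE)
      }
      v[rows, j] <- v[rows, j] / med
    }
  }
  metabolite_matrix(v, m$batch, stage = "scaled")
}

#' Impute missing entries with the metabolite's global observed minimum
#'
#' Each missing entry is replaced by the minimum observed value of that
#' metabolite across all samples and batches of the scaled data — the repair
#' implied by detection-limit (left-censored) missingness.
#'
#' @param m a [metabolite_matrix()] at stage `"scaled"`.
#' @return the matrix at stage `"imputed"`, with no missing entries.
#' @export
impute_minimum <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  if (m$stage != "scaled") {
    stop("minimum imputation applies to batch-scaled data", call. = FALSE)
  }
  v <- m$values
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (all(miss)) {
      stop(sprintf("metabolite '%s' has no observed values", colnames(v)[j]),
           call. = FALSE)
    }
    if (any(miss)) v[miss, j] <- min(v[!miss, j])
  }
  metabolite_matrix(v, m$batch, stage = "imputed")
}

#' Rank-based inverse normal transform
#'
#' Maps a vector onto Gaussian quantiles through its ranks:
#' `qnorm((rank - offset) / (n + 1 - 2*offset))`, with average ranks for
#' ties. The default `offset = 3/8` is the Blom variant. For a
#' [metabolite_matrix()] the transform is applied column-wise.
#'
#' @param x numeric vector with no missing values (length >= 2), or a
#'   [metabolite_matrix()] at stage `"imputed"`.
#' @param offset rank offset in `[0, 0.5]`; 3/8 (Blom) by default.
#' @return transformed vector, or the matrix at stage `"normalized"`.
#' @export
inverse_normal_transform <- function(x, offset = 3/8) {
  check_fraction(offset, "offset", hi = 0.5)
  if (inherits(x, "metabolite_matrix")) {
    if (x$stage != "imputed") {
      stop("inverse normal transform applies to imputed (complete) data",
           call. = FALSE)
    }
    v <- apply(x$values, 2, inverse_normal_transform, offset = offset)
    dimnames(v) <- dimnames(x$values)
    return(metabolite_matrix(v, x$batch, stage = "normalized"))
  }
  if (anyNA(x)) stop("input must have no missing values", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  r <- avg_rank(x)
  qnorm((r - offset) / (n + 1 - 2 * offset))
}

#' Run the full metabolite QC chain
#'
#' filter (missingness > `max_missing` dropped) -> per-batch median scaling ->
#' global-minimum imputation -> column-wise inverse normal transform.
#'
#' @param m a [metabolite_matrix()] at stage `"raw"`.
#' @param max_missing missingness threshold (default 0.20).
#' @param offset inverse-normal rank offset (default Blom, 3/8).
#' @return a [metabolite_matrix()] at stage `"normalized"`; the names dropped
#'   by the missingness filter are carried over in attribute `"dropped"`.
#' @export
preprocess_metabolites <- function(m, max_missing = 0.20, offset = 3/8) {
  filt <- filter_missingness(m, max_missing)
  out <- inverse_normal_transform(impute_minimum(batch_median_scale(filt)),
                                  offset = offset)
  attr(out, "dropped") <- attr(filt, "dropped")
  out
}
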