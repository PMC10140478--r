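## Random-forest prediction of metabolites from species relative abundances,
## under twin-aware k-fold cross-validation: whenever an individual is in a
## test fold, their co-family members are removed from that fold's training
## set, so family-shared variance cannot leak into the performance estimate.
## Forests are grown with ranger (single-threaded, seeded) with the
## conventional defaults ntree = 1000, mtry = p/3 (regression) or sqrt(p)
## (classification).

#' Drop near-zero-variance predictors
#'
#' A species is removed if its variance is exactly zero, or if the frequency
#' ratio of its most common to second most common value exceeds `freq_ratio`
#' while its fraction of distinct values is below `unique_cut` — the
#' conventional near-zero-variance screen.
#'
#' @param profile samples x species numeric matrix (>= 2 samples).
#' @param freq_ratio ratio threshold (default 19, i.e. 95/5).
#' @param unique_cut distinct-value fraction threshold (default 0.10).
#' @return the filtered matrix with dropped species names in attribute
#'   `"dropped"`.
#' @export
filter_near_zero_variance <- function(profile, freq_ratio = 19, unique_cut = 0.10) {
  stopifnot(is.matrix(profile), nrow(profile) >= 2)
  n <- nrow(profile)
  drop <- vapply(seq_len(ncol(profile)), function(j) {
    x <- profile[, j]
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) == 1) return(TRUE)  # zero variance
    ratio <- tab[1] / tab[2]
    distinct_frac <- length(tab) / n
    ratio > freq_ratio && distinct_frac < unique_cut
  }, logical(1))
  out <- profile[, !drop, drop = FALSE]
  attr(out, "dropped") <- colnames(profile)[drop]
  out
}

#' Build twin-aware cross-validation folds
#'
#' Samples are randomly partitioned into `k` test folds at the individual
#' level; each fold's training set is then the complement of the test fold
#' minus any co-family member of a test sample, preventing family-level
#' leakage.
#'
#' @param meta data.frame with `sample_id` and `family_id` columns.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param twin_aware set `FALSE` for naive folds (complement training sets),
#'   e.g. to quantify leakage.
#' @return object of class `"fold_assignment"`: list with `fold` (named
#'   integer vector), `test` and `train` (lists of sample-id vectors per
#'   fold), `twin_aware`.
#' @export
make_twin_aware_folds <- function(meta, k = 5, seed = 1, twin_aware = TRUE) {
  stopifnot(all(c("sample_id", "family_id") %in% names(meta)))
  n <- nrow(meta)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("more folds than samples", call. = FALSE)
  set.seed(substream(seed, "folds"))
  fold <- sample(rep_len(seq_len(k), n))
  names(fold) <- meta$sample_id
  test <- split(meta$sample_id, fold)
  train <- lapply(seq_len(k), function(f) {
    out_ids <- meta$sample_id[fold != f]
    if (twin_aware) {
      test_fams <- meta$family_id[fold == f]
      out_ids <- out_ids[!(meta$family_id[fold != f] %in% test_fams)]
    }
    out_ids
  })
  structure(list(fold = fold, test = unname(test), train = train,
                 k = k, twin_aware = twin_aware),
            class = "fold_assignment")
}

## internal: one ranger fit + prediction per fold
rf_fold <- function(X, y, train_ids, test_ids, ntree, mtry, seed,
                    probability = FALSE) {
  tr <- match(train_ids, rownames(X)); te <- match(test_ids, rownames(X))
  fit <- ranger::ranger(x = X[tr, , drop = FALSE], y = y[tr],
                        num.trees = ntree, mtry = mtry,
                        probability = probability,
                        num.threads = 1, seed = seed)
  pred <- predict(fit, data = X[te, , drop = FALSE], num.threads = 1)$predictions
  if (probability) pred <- pred[, "1"]
  pred
}

#' Cross-validated random-forest regression of a metabolite on the microbiome
#'
#' Per fold, a forest is trained on the (twin-aware) training set and the
#' Spearman correlation between observed and predicted values on the test
#' fold is recorded.
#'
#' @param profile samples x species matrix with sample ids as row names.
#' @param target numeric vector named by sample id (or aligned to rows).
#' @param folds a [make_twin_aware_folds()] result.
#' @param ntree trees per forest (default 1000).
#' @param mtry predictors per split; default `max(1, floor(p/3))`.
#' @param seed integer seed (per-fold forests get derived sub-seeds).
#' @return numeric vector of per-fold Spearman rho (NA, with a warning, for a
#'   fold whose training target is constant).
#' @export
run_rf_regressor <- function(profile, target, folds, ntree = 1000,
                             mtry = NULL, seed = 1) {
  stopifnot(inherits(folds, "fold_assignment"))
  if (is.null(names(target))) names(target) <- rownames(profile)
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(profile) / 3))
  vapply(seq_len(folds$k), function(f) {
    tr <- folds$train[[f]]; te <- folds$test[[f]]
    y_tr <- target[tr]
    if (var(y_tr) == 0) {
      warning(sprintf("fold %d: constant training target; rho undefined", f))
      return(NA_real_)
    }
    pred <- rf_fold(profile, target, tr, te, ntree, mtry,
                    seed = substream(seed, paste0("rf_reg_fold", f)))
    cor(target[te], pred, method = "spearman")
  }, numeric(1))
}

#' Dichotomise a continuous response into its outer quartiles
#'
#' Samples at or below the 25th percentile become class 0, at or above the
#' 75th percentile class 1; the middle half is excluded from the
#' classification task. With heavy ties at a quartile boundary, all tied
#' samples go to the corresponding outer class.
#'
#' @param target numeric vector (`n >= 8`, not all values identical).
#' @return list with `labels` (factor `0`/`1` for kept samples, named) and
#'   `keep` (logical mask over the input).
#' @export
dichotomize_quartiles <- function(target) {
  if (length(target) < 8) stop("need at least 8 samples", call. = FALSE)
  if (length(unique(target)) == 1) {
    stop("all values identical: quartile classes undefined", call. = FALSE)
  }
  q <- quantile(target, c(0.25, 0.75), names = FALSE)
  lab <- ifelse(target <= q[1], 0L, ifelse(target >= q[2], 1L, NA_integer_))
  keep <- !is.na(lab)
  labels <- factor(lab[keep], levels = c(0, 1))
  names(labels) <- names(target)[keep]
  list(labels = labels, keep = keep)
}

#' AUC by the Mann-Whitney rank formula
#'
#' Area under the ROC curve for scores against binary labels, computed as
#' the rescaled rank-sum statistic; tied scores receive midrank credit.
#'
#' @param scores numeric predicted scores (higher = more class 1).
#' @param labels binary labels (0/1 or a 2-level factor).
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_rank <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels == levels(labels)[2]) else
    as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated random-forest classification of quartile-extreme samples
#'
#' Per fold, a probability forest is trained on the training set and the AUC
#' of the out-of-fold class-1 probabilities against the test labels is
#' recorded via the rank formula.
#'
#' @param profile samples x species matrix restricted to the kept
#'   (outer-quartile) samples.
#' @param labels factor from [dichotomize_quartiles()], aligned to `profile`.
#' @param folds folds built on the kept subset.
#' @param ntree trees per forest (default 1000).
#' @param mtry default `max(1, floor(sqrt(p)))`.
#' @param seed integer seed.
#' @return numeric vector of per-fold AUCs (NA, with a warning, for a fold
#'   whose test set has a single class).
#' @export
run_rf_classifier <- function(profile, labels, folds, ntree = 1000,
                              mtry = NULL, seed = 1) {
  stopifnot(inherits(folds, "fold_assignment"))
  if (is.null(names(labels))) names(labels) <- rownames(profile)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(profile))))
  vapply(seq_len(folds$k), function(f) {
    tr <- folds$train[[f]]; te <- folds$test[[f]]
    if (length(unique(labels[te])) < 2) {
      warning(sprintf("fold %d: single-class test set; AUC undefined", f))
      return(NA_real_)
    }
    prob <- rf_fold(profile, labels, tr, te, ntree, mtry,
                    seed = substream(seed, paste0("rf_cls_fold", f)),
                    probability = TRUE)
    auc_rank(prob, labels[te])
  }, numeric(1))
}

#' Summarise per-fold performance values
#'
#' Mean and t-based 95% confidence interval over the defined fold values
#' (`mean +- t[0.975, m-1] * sd / sqrt(m)`).
#'
#' @param values per-fold metric values (NA = undefined fold).
#' @param level CI coverage (default 0.95).
#' @return list with `mean`, `ci` (`c(lower, upper)`, `NA` if fewer than two
#'   defined folds), `per_fold`, `n_folds`.
#' @export
summarize_performance <- function(values, level = 0.95) {
  v <- values[!is.na(values)]
  m <- length(v)
  if (m == 0) return(list(mean = NA_real_, ci = c(NA_real_, NA_real_),
                          per_fold = values, n_folds = 0L))
  mu <- mean(v)
  ci <- if (m >= 2) {
    half <- qt(1 - (1 - level) / 2, m - 1) * sd(v) / sqrt(m)
    c(mu - half, mu + half)
  } else c(NA_real_, NA_real_)
  list(mean = mu, ci = ci, per_fold = values, n_folds = m)
}

#' Full twin-aware prediction of one metabolite from the microbiome
#'
#' Runs the near-zero-variance screen, the cross-validated regressor on all
#' samples, and the cross-validated classifier on the outer-quartile subset
#' (folds are rebuilt on that subset), then summarises per-fold Spearman rho
#' and AUC.
#'
#' @param profile samples x species relative-abundance matrix.
#' @param target metabolite vector named by sample id.
#' @param meta data.frame with `sample_id`, `family_id` covering the samples.
#' @param k folds (default 5).
#' @param ntree trees per forest (default 1000).
#' @param seed integer seed.
#' @param twin_aware remove co-family members from training sets (default
#'   `TRUE`).
#' @return object of class `"prediction_performance"`: list with `rho` and
#'   `auc` summaries (see [summarize_performance()]) plus bookkeeping fields.
#' @export
predict_from_microbiome <- function(profile, target, meta, k = 5,
                                    ntree = 1000, seed = 1, twin_aware = TRUE) {
  stopifnot(identical(rownames(profile), meta$sample_id))
  if (is.null(names(target))) names(target) <- rownames(profile)
  X <- filter_near_zero_variance(profile)
  folds_reg <- make_twin_aware_folds(meta, k, seed = substream(seed, "reg"),
                                     twin_aware = twin_aware)
  rho <- run_rf_regressor(X, target, folds_reg, ntree = ntree,
                          seed = substream(seed, "reg_rf"))
  dic <- dichotomize_quartiles(target)
  meta_cls <- meta[dic$keep, , drop = FALSE]
  folds_cls <- make_twin_aware_folds(meta_cls, k, seed = substream(seed, "cls"),
                                     twin_aware = twin_aware)
  auc <- run_rf_classifier(X[dic$keep, , drop = FALSE], dic$labels, folds_cls,
                           ntree = ntree, seed = substream(seed, "cls_rf"))
  structure(list(rho = summarize_performance(rho),
                 auc = summarize_performance(auc),
                 n_samples = nrow(profile), n_species = ncol(X),
                 k = k, ntree = ntree, twin_aware = twin_aware),
            class = "prediction_performance")
}

#' @export
print.prediction_performance <- function(x, ...) {
  cat(sprintf("random-forest prediction (%d samples, %d species, %d-fold%s)\n",
              x$n_samples, x$n_species, x$k,
              if (x$twin_aware) ", twin-aware" else ""))
  cat(sprintf("  Spearman rho: mean %.3f [%.3f, %.3f]\n",
              x$rho$mean, x$rho$ci[1], x$rho$ci[2]))
  cat(sprintf("  AUC:          mean %.3f [%.3f, %.3f]\n",
              x$auc$mean, x$auc$ci[1], x$auc$ci[2]))
  invisible(x)
}

#' Prediction-performance table over a metabolite panel
#'
#' @param profile samples x species matrix.
#' @param traits samples x metabolites matrix (normalised), sample ids as
#'   row names matching `profile`.
#' @param meta metadata with `sample_id`, `family_id`.
#' @param ... passed to [predict_from_microbiome()]; per-metabolite sub-seeds
#'   are derived from `seed`.
#' @param seed integer seed.
#' @return data.frame: metabolite, mean_rho, rho_lo, rho_hi, mean_auc,
#'   auc_lo, auc_hi.
#' @export
prediction_table <- function(profile, traits, meta, seed = 1, ...) {
  rows <- lapply(colnames(traits), function(met) {
    perf <- predict_from_microbiome(profile, traits[, met], meta,
                                    seed = substream(seed, met), ...)
    data.frame(metabolite = met,
               mean_rho = perf$rho$mean, rho_lo = perf$rho$ci[1],
               rho_hi = perf$rho$ci[2],
               mean_auc = perf$auc$mean, auc_lo = perf$auc$ci[1],
               auc_hi = perf$auc$ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
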