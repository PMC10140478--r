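## Association statistics: prevalence filtering, covariate-adjusted partial
## Spearman screens with Benjamini-Hochberg control, two-cohort concordance,
## post-prandial peak/delta summaries and linear models, DerSimonian-Laird
## random-effects meta-analysis, paired t-tests, and complete-linkage
## clustering for species heatmaps.

#' Keep species above a prevalence threshold
#'
#' Prevalence is the fraction of samples with nonzero abundance; species are
#' kept when strictly above the threshold.
#'
#' @param profile samples x species matrix.
#' @param threshold prevalence cut (default 0.20).
#' @return the filtered matrix (attribute `"dropped"` lists removed species).
#' @export
prevalence_filter <- function(profile, threshold = 0.20) {
  stopifnot(is.matrix(profile))
  check_fraction(threshold, "threshold")
  prev <- colMeans(profile > 0)
  keep <- prev > threshold
  out <- profile[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(profile)[!keep]
  out
}

#' Partial Spearman correlation adjusted for covariates
#'
#' Both variables are rank-transformed (average ranks), each is residualised
#' on an intercept plus the covariates by least squares, and the Pearson
#' correlation of the residuals is returned. The p-value uses the t
#' transform with `df = n - 2 - ncov`. With no covariates this reduces to
#' the plain Spearman correlation.
#'
#' @param x,y numeric vectors (complete cases, aligned).
#' @param covariates data.frame/matrix of adjustment variables or `NULL`.
#' @return list with `rho`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (anyNA(x) || anyNA(y)) stop("x and y must be complete", call. = FALSE)
  n <- length(x)
  stopifnot(length(y) == n)
  ncov <- 0L
  rx <- avg_rank(x); ry <- avg_rank(y)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    Z <- as.matrix(covariates)
    stopifnot(nrow(Z) == n)
    ncov <- ncol(Z)
    D <- cbind(1, Z)
    rx <- lm.fit(D, rx)$residuals
    ry <- lm.fit(D, ry)$residuals
  }
  if (n <= ncov + 2) stop("need n > number of covariates + 2", call. = FALSE)
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop("zero residual variance: correlation undefined", call. = FALSE)
  }
  rho <- cor(rx, ry)
  df <- n - 2 - ncov
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * pt(-abs(tstat), df), n = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; monotone in p-rank and capped at 1.
#'
#' @param pvals p-values in `(0, 1]`.
#' @return adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Covariate-adjusted partial Spearman screen of species against a metabolite
#'
#' Applies the prevalence filter, then computes the partial Spearman
#' correlation of every retained species with the outcome, adjusting for the
#' covariates, with Benjamini-Hochberg correction across the screen.
#' A constant covariate (e.g. sex in a single-sex cohort) is dropped with a
#' message.
#'
#' @param profile samples x species matrix.
#' @param y outcome vector aligned to rows.
#' @param covariates data.frame of adjustment covariates (or `NULL`).
#' @param prevalence prevalence threshold (default 0.20).
#' @return data.frame: `feature`, `rho`, `p`, `q`, `direction`, `n` — one
#'   row per retained species, input column order preserved.
#' @export
species_screen <- function(profile, y, covariates = NULL, prevalence = 0.20) {
  X <- prevalence_filter(profile, prevalence)
  n <- nrow(X)
  D <- NULL
  ncov <- 0L
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    Z <- as.matrix(covariates)
    const <- apply(Z, 2, function(z) var(z) == 0)
    if (any(const)) {
      message("dropping constant covariate(s): ",
              paste(colnames(Z)[const], collapse = ", "))
      Z <- Z[, !const, drop = FALSE]
    }
    if (ncol(Z) > 0) { D <- cbind(1, Z); ncov <- ncol(Z) }
  }
  ry <- avg_rank(y)
  RX <- apply(X, 2, avg_rank)
  if (!is.null(D)) {
    qr_d <- qr(D)
    ry <- qr.resid(qr_d, ry)
    RX <- qr.resid(qr_d, RX)
  }
  rho <- drop(cor(RX, ry))
  df <- n - 2 - ncov
  tstat <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  data.frame(feature = colnames(X), rho = rho, p = p, q = bh_fdr(p),
             direction = sign(rho), n = n, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Two-cohort concordance gate
#'
#' A feature replicates when it passes FDR in the discovery screen
#' (`q < q_disc`), is nominally significant in the validation screen
#' (`p < p_val`), and has the same effect direction in both.
#'
#' @param discovery,validation screen data.frames with `feature`, `rho`,
#'   `p`, `q` columns (as from [species_screen()]).
#' @param q_disc discovery FDR gate (default 0.05).
#' @param p_val validation nominal-p gate (default 0.05).
#' @return data.frame of concordant features with both cohorts' estimates;
#'   discovery features absent from the validation screen are excluded and
#'   listed in attribute `"unmatched"`.
#' @export
replicate_concordance <- function(discovery, validation,
                                  q_disc = 0.05, p_val = 0.05) {
  unmatched <- setdiff(discovery$feature, validation$feature)
  merged <- merge(discovery, validation, by = "feature",
                  suffixes = c("_disc", "_val"))
  hit <- merged$q_disc < q_disc & merged$p_val < p_val &
    sign(merged$rho_disc) == sign(merged$rho_val) & merged$rho_disc != 0
  out <- merged[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' Summarise post-prandial trajectories into baseline, peak and delta
#'
#' Baseline is the analyte value at time 0; the peak is the maximum over the
#' post-meal window `(0, window_hours]` — the fasting sample is excluded from
#' the peak, so delta (`peak - baseline`) may be negative for a declining
#' trajectory.
#'
#' @param timeseries long data.frame with `sample_id`, `analyte`,
#'   `timepoint_min`, `value`.
#' @param analyte which analyte to summarise.
#' @param window_hours post-meal window length in hours (e.g. 6 for
#'   triglycerides, 2 for glucose and insulin).
#' @return data.frame: `sample_id`, `analyte`, `baseline`, `peak`, `delta`,
#'   `window_hours`.
#' @export
summarize_meal <- function(timeseries, analyte, window_hours) {
  stopifnot(all(c("sample_id", "analyte", "timepoint_min", "value") %in%
                  names(timeseries)))
  ts <- timeseries[timeseries$analyte == analyte, , drop = FALSE]
  if (nrow(ts) == 0) stop("no records for analyte '", analyte, "'", call. = FALSE)
  rows <- lapply(split(ts, ts$sample_id), function(d) {
    base <- d$value[d$timepoint_min == 0]
    if (length(base) == 0) {
      stop("sample '", d$sample_id[1], "' lacks a time-0 record", call. = FALSE)
    }
    inwin <- d$timepoint_min > 0 & d$timepoint_min <= window_hours * 60
    if (!any(inwin)) {
      stop("sample '", d$sample_id[1], "' has no in-window record", call. = FALSE)
    }
    peak <- max(d$value[inwin])
    data.frame(sample_id = d$sample_id[1], analyte = analyte,
               baseline = base[1], peak = peak, delta = peak - base[1],
               window_hours = window_hours, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[match(unique(ts$sample_id), out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted linear association of an outcome with an exposure
#'
#' Ordinary least squares of `outcome` on an intercept, the exposure and the
#' covariates; returns the exposure coefficient with t-based confidence
#' interval and p-value, plus the model R-squared and overall F statistic.
#'
#' @param outcome,exposure aligned numeric vectors (complete cases).
#' @param covariates data.frame of adjustment variables or `NULL`.
#' @param level CI coverage (default 0.95).
#' @return one-row data.frame: `beta`, `se`, `ci_lo`, `ci_hi`, `p`, `n`,
#'   `r_squared`, `f_stat`.
#' @export
linear_association <- function(outcome, exposure, covariates = NULL,
                               level = 0.95) {
  n <- length(outcome)
  stopifnot(length(exposure) == n)
  dat <- data.frame(.outcome = outcome, .exposure = exposure)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    stopifnot(nrow(covariates) == n)
    dat <- cbind(dat, covariates)
  }
  if (anyNA(dat)) stop("complete cases required", call. = FALSE)
  if (n <= ncol(dat) + 1) stop("need n > number of parameters + 1", call. = FALSE)
  fit <- lm(.outcome ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  co <- sm$coefficients[".exposure", ]
  dfres <- fit$df.residual
  half <- qt(1 - (1 - level) / 2, dfres) * co["Std. Error"]
  fs <- sm$fstatistic
  data.frame(beta = unname(co["Estimate"]), se = unname(co["Std. Error"]),
             ci_lo = unname(co["Estimate"] - half),
             ci_hi = unname(co["Estimate"] + half),
             p = unname(co["Pr(>|t|)"]), n = n,
             r_squared = sm$r.squared,
             f_stat = if (!is.null(fs)) unname(fs["value"]) else NA_real_)
}

#' Code a continuous variable into sample tertiles
#'
#' Returns integer codes 1/2/3 by the empirical tertile boundaries
#' (`quantile` type 7, midrank handling of ties via `<=` cuts). Useful as a
#' tertile-contrast exposure in [linear_association()], e.g. for
#' first-vs-third-tertile change analyses.
#'
#' @param x numeric vector (`n >= 3`, not all values identical).
#' @return integer vector of tertile codes aligned to `x`.
#' @export
tertile_code <- function(x) {
  if (length(x) < 3) stop("need at least 3 values", call. = FALSE)
  if (length(unique(x)) == 1) stop("all values identical", call. = FALSE)
  q <- quantile(x, c(1/3, 2/3), names = FALSE)
  ifelse(x <= q[1], 1L, ifelse(x <= q[2], 2L, 3L))
}

#' DerSimonian-Laird random-effects inverse-variance meta-analysis
#'
#' Between-study variance `tau2 = max(0, (Q - (k-1)) / (sum(w) -
#' sum(w^2)/sum(w)))` with fixed-effect weights `w = 1/se^2` and Cochran's
#' `Q`; the pooled estimate uses weights `1/(se^2 + tau2)` with a Wald
#' confidence interval and p-value. When `tau2 = 0` this reduces exactly to
#' fixed-effect inverse-variance pooling.
#'
#' @param betas per-study effect estimates (>= 2 studies).
#' @param ses per-study standard errors (> 0).
#' @param level CI coverage (default 0.95).
#' @return list with `beta` (pooled), `se`, `ci`, `p`, `tau2`, `Q`, `k`,
#'   `study_betas`, `study_ses`.
#' @export
meta_random_effects <- function(betas, ses, level = 0.95) {
  k <- length(betas)
  if (k < 2) stop("meta-analysis needs at least 2 studies", call. = FALSE)
  stopifnot(length(ses) == k, all(ses > 0))
  w <- 1 / ses^2
  beta_fixed <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - beta_fixed)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (ses^2 + tau2)
  pooled <- sum(w_star * betas) / sum(w_star)
  se <- sqrt(1 / sum(w_star))
  z <- qnorm(1 - (1 - level) / 2)
  list(beta = pooled, se = se, ci = c(pooled - z * se, pooled + z * se),
       p = 2 * pnorm(-abs(pooled / se)), tau2 = tau2, Q = Q, k = k,
       study_betas = betas, study_ses = ses)
}

#' Paired t-test for intervention change
#'
#' Mean of within-pair differences (`after - before`) with t-based
#' confidence interval and two-sided p-value on `n - 1` degrees of freedom.
#'
#' @param before,after aligned measurement vectors (`n >= 2`).
#' @param level CI coverage (default 0.95).
#' @return list with `mean_diff`, `ci`, `p`, `n`.
#' @export
paired_ttest <- function(before, after, level = 0.95) {
  n <- length(before)
  stopifnot(length(after) == n, n >= 2)
  d <- after - before
  if (sd(d) <= 10 * .Machine$double.eps * max(abs(mean(d)), abs(d))) {
    stop("zero variance of paired differences: t statistic undefined",
         call. = FALSE)
  }
  tt <- t.test(after, before, paired = TRUE, conf.level = level)
  list(mean_diff = unname(tt$estimate), ci = unname(tt$conf.int),
       p = tt$p.value, n = n)
}

#' Complete-linkage clustering of a species association matrix
#'
#' Agglomerative hierarchical clustering of the rows (species) on Euclidean
#' distance with complete linkage, as used for association heatmaps. Leaf
#' order is the deterministic order produced by the standard agglomeration
#' with ties resolved by first-merge (input) order.
#'
#' @param assoc_matrix complete numeric matrix, species as rows.
#' @return list with `order` (row indices in leaf order), `labels`, and the
#'   `hclust` object in `tree`.
#' @export
cluster_species <- function(assoc_matrix) {
  if (!is.matrix(assoc_matrix)) assoc_matrix <- as.matrix(assoc_matrix)
  if (anyNA(assoc_matrix)) stop("association matrix has missing entries",
                                call. = FALSE)
  tree <- hclust(dist(assoc_matrix, method = "euclidean"), method = "complete")
  list(order = tree$order,
       labels = if (!is.null(rownames(assoc_matrix))) rownames(assoc_matrix)
       else as.character(seq_len(nrow(assoc_matrix))),
       tree = tree)
}
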