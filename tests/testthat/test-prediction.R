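test_that("near-zero-variance screen applies the ratio and distinct-fraction rules", {
  set.seed(201)
  n <- 100
  X <- cbind(allzero = rep(0, n),
             rare = c(0.3, rep(0, n - 1)),       # ratio 99 > 19, 2% distinct
             cont = runif(n),                     # continuous: retained
             common = rep(c(0, 1), each = n / 2)) # ratio 1: retained
  rownames(X) <- sprintf("S%d", 1:n)
  out <- filter_near_zero_variance(X)
  expect_identical(colnames(out), c("cont", "common"))
  expect_identical(attr(out, "dropped"), c("allzero", "rare"))
})

test_that("near-zero-variance screen agrees with the caret reference", {
  skip_if_not_installed("caret")
  set.seed(202)
  X <- cbind(matrix(runif(300), 100, 3),
             rep(0, 100),
             c(rep(0, 97), 0.1, 0.2, 0.3),
             sample(c(0, 0.5), 100, replace = TRUE, prob = c(0.97, 0.03)))
  colnames(X) <- sprintf("sp%d", 1:6)
  rownames(X) <- sprintf("S%d", 1:100)
  ours <- attr(filter_near_zero_variance(X), "dropped")
  ref <- colnames(X)[caret::nearZeroVar(as.data.frame(X))]
  expect_setequal(ours, ref)
})

test_that("twin-aware folds purge exactly the co-family members of test samples", {
  meta <- pair_meta(100)
  f <- make_twin_aware_folds(meta, k = 5, seed = 203)
  expect_setequal(unlist(f$test), meta$sample_id)
  expect_equal(sum(lengths(f$test)), nrow(meta))
  for (i in 1:5) {
    test_fams <- meta$family_id[match(f$test[[i]], meta$sample_id)]
    train_fams <- meta$family_id[match(f$train[[i]], meta$sample_id)]
    # no family straddles the train/test divide
    expect_length(intersect(test_fams, train_fams), 0)
    # removed samples are exactly co-family members of test samples
    naive <- setdiff(meta$sample_id, f$test[[i]])
    removed <- setdiff(naive, f$train[[i]])
    removed_fams <- meta$family_id[match(removed, meta$sample_id)]
    expect_true(all(removed_fams %in% test_fams))
    expect_true(all(f$train[[i]] %in% naive))
  }
  # unrelated singletons: training sets are exact complements
  ms <- singleton_meta(50)
  fs <- make_twin_aware_folds(ms, k = 5, seed = 204)
  for (i in 1:5) {
    expect_setequal(fs$train[[i]], setdiff(ms$sample_id, fs$test[[i]]))
  }
  expect_error(make_twin_aware_folds(singleton_meta(3), k = 5), "folds")
  expect_identical(make_twin_aware_folds(meta, 5, seed = 7),
                   make_twin_aware_folds(meta, 5, seed = 7))
})

test_that("quartile dichotomisation keeps the outer quartiles only", {
  d <- dichotomize_quartiles(setNames(1:100, sprintf("S%d", 1:100)))
  expect_equal(sum(d$keep), 50)
  expect_equal(sum(d$labels == "0"), 25)
  expect_true(all(names(d$labels)[d$labels == "0"] %in% sprintf("S%d", 1:25)))
  expect_true(all(names(d$labels)[d$labels == "1"] %in% sprintf("S%d", 76:100)))
  # n = 8 distinct values: two per class
  d8 <- dichotomize_quartiles(setNames(1:8, letters[1:8]))
  expect_equal(as.vector(table(d8$labels)), c(2, 2))
  # heavy ties at the lower quartile all land in class 0
  v <- c(rep(1, 40), 2:61)
  dt <- dichotomize_quartiles(v)
  expect_true(all(dt$keep[v == 1]))
  expect_true(all(dt$labels[v[dt$keep] == 1] == "0"))
  expect_error(dichotomize_quartiles(rep(3, 20)), "identical")
  expect_error(dichotomize_quartiles(1:5), "at least 8")
})

test_that("rank-formula AUC matches trapezoidal ROC integration and pROC", {
  set.seed(211)
  scores <- c(rnorm(40), rnorm(40, 1))
  labels <- rep(c(0, 1), each = 40)
  a <- auc_rank(scores, labels)
  # trapezoidal integration over all thresholds (independent construction)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(c(Inf, th), function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(c(Inf, th), function(t) mean(scores[labels == 0] >= t), 0)
  trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_equal(a, trap, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
  # midrank credit for tied scores
  expect_equal(auc_rank(c(1, 1, 1, 1), c(0, 0, 1, 1)), 0.5)
  expect_true(is.na(auc_rank(1:4, c(1, 1, 1, 1))))
})

test_that("per-fold summaries use the t-based interval", {
  s <- summarize_performance(rep(0.5, 5))
  expect_equal(s$mean, 0.5)
  expect_equal(s$ci, c(0.5, 0.5))
  s2 <- summarize_performance(c(0.4, 0.6))
  half <- qt(0.975, 1) * sd(c(0.4, 0.6)) / sqrt(2)
  expect_equal(s2$ci, c(0.5 - half, 0.5 + half))
  # shift equivariance
  s3 <- summarize_performance(c(0.4, 0.6) + 0.2)
  expect_equal(s3$mean, s2$mean + 0.2)
  expect_equal(s3$ci, s2$ci + 0.2)
  # undefined folds are dropped; <2 defined -> no interval
  s4 <- summarize_performance(c(0.3, NA, NA, NA, NA))
  expect_equal(s4$mean, 0.3)
  expect_true(all(is.na(s4$ci)))
})

test_that("forests recover a self-predictable signal and stay null on noise", {
  set.seed(221)
  mb <- simulate_microbiome(300, 20, 1, seed = 222)
  meta <- singleton_meta(300)
  rownames(mb) <- meta$sample_id
  folds <- make_twin_aware_folds(meta, 5, seed = 223)
  # target identical to one species' abundance: near-perfect rank recovery
  y <- setNames(mb[, 7], meta$sample_id)
  rho <- run_rf_regressor(mb, y, folds, ntree = 500, seed = 224)
  expect_gt(mean(rho), 0.9)
  # pure-noise target: mean rho near zero
  y0 <- setNames(rnorm(300), meta$sample_id)
  rho0 <- run_rf_regressor(mb, y0, folds, ntree = 300, seed = 225)
  expect_lt(abs(mean(rho0)), 0.15)
})

test_that("classifier separates a thresholded species and is null otherwise", {
  set.seed(231)
  mb <- simulate_microbiome(400, 15, 1, seed = 232)
  meta <- singleton_meta(400)
  rownames(mb) <- meta$sample_id
  # labels fully determined by one species' abundance
  y <- setNames(mb[, 4], meta$sample_id)
  d <- dichotomize_quartiles(y)
  meta_k <- meta[d$keep, ]
  folds <- make_twin_aware_folds(meta_k, 5, seed = 233)
  auc <- run_rf_classifier(mb[d$keep, ], d$labels, folds, ntree = 300, seed = 234)
  expect_gt(mean(auc), 0.95)
  # labels independent of the profile: AUC ~ 0.5
  y0 <- setNames(rnorm(400), meta$sample_id)
  d0 <- dichotomize_quartiles(y0)
  folds0 <- make_twin_aware_folds(meta[d0$keep, ], 5, seed = 235)
  auc0 <- run_rf_classifier(mb[d0$keep, ], d0$labels, folds0, ntree = 300,
                            seed = 236)
  expect_lt(abs(mean(auc0) - 0.5), 0.1)
})

test_that("regressor and classifier rank metabolites by planted signal concordantly", {
  mb <- simulate_microbiome(240, 40, 0.8, seed = 251)
  meta <- singleton_meta(240)
  rownames(mb) <- meta$sample_id
  # ten metabolites spanning planted R2 from ~0 to ~0.8
  noise_levels <- seq(2.5, 0.35, length.out = 10)
  r2 <- rho <- auc <- numeric(10)
  for (i in 1:10) {
    cm <- couple_metabolite(mb, 1:3, c(0.8, -0.7, 0.7),
                            noise_sd = noise_levels[i], seed = 252 + i)
    p <- predict_from_microbiome(mb, cm$trait, meta, ntree = 100,
                                 seed = 262 + i)
    r2[i] <- cm$r2; rho[i] <- p$rho$mean; auc[i] <- p$auc$mean
  }
  expect_gt(cor(r2, rho, method = "spearman"), 0.8)
  expect_gt(cor(r2, auc, method = "spearman"), 0.8)
  expect_gt(cor(rho, auc, method = "spearman"), 0.8)
})

test_that("family leakage inflates the naive classifier AUC as well", {
  # family-shared trait, family-correlated microbiome, no causal coupling
  diffs <- vapply(1:15, function(r) {
    s <- 27000 + 10 * r
    co <- simulate_twin_cohort(cohort_design(100, 0, 0),
                               list(y = ace_spec(0, 1)), seed = s)
    mb <- simulate_microbiome(200, 80, 0.5, seed = s + 1,
                              family = co$family_id, family_icc = 0.6)
    rownames(mb) <- co$sample_id
    meta <- co[c("sample_id", "family_id")]
    d <- dichotomize_quartiles(setNames(co$y, co$sample_id))
    mk <- meta[d$keep, ]
    fa <- make_twin_aware_folds(mk, 5, seed = s + 2, twin_aware = TRUE)
    fn <- make_twin_aware_folds(mk, 5, seed = s + 2, twin_aware = FALSE)
    Xk <- mb[d$keep, ]
    mean(run_rf_classifier(Xk, d$labels, fa, ntree = 150, seed = s + 3),
         na.rm = TRUE) -
      mean(run_rf_classifier(Xk, d$labels, fn, ntree = 150, seed = s + 3),
           na.rm = TRUE)
  }, numeric(1))
  # twin-aware minus naive AUC is negative in expectation under this null
  expect_lt(binom.test(sum(diffs < 0), length(diffs),
                       alternative = "greater")$p.value, 0.05)
})

test_that("prediction is reproducible under the seed and ranks planted signals", {
  mb <- simulate_microbiome(240, 30, 0.8, seed = 241)
  meta <- singleton_meta(240)
  rownames(mb) <- meta$sample_id
  cm <- couple_metabolite(mb, 1:3, c(0.8, -0.7, 0.7), noise_sd = 0.6, seed = 242)
  p1 <- predict_from_microbiome(mb, cm$trait, meta, ntree = 150, seed = 243)
  p2 <- predict_from_microbiome(mb, cm$trait, meta, ntree = 150, seed = 243)
  expect_identical(p1$rho$per_fold, p2$rho$per_fold)
  expect_identical(p1$auc$per_fold, p2$auc$per_fold)
  # strong planted coupling outperforms a null metabolite on both metrics
  cm0 <- couple_metabolite(mb, integer(0), numeric(0), noise_sd = 1, seed = 244)
  p0 <- predict_from_microbiome(mb, cm0$trait, meta, ntree = 150, seed = 245)
  expect_gt(p1$rho$mean, p0$rho$mean)
  expect_gt(p1$auc$mean, p0$auc$mean)
})
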