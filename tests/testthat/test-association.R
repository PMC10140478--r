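test_that("prevalence filter keeps species strictly above the threshold", {
  X <- cbind(p21 = c(rep(0.1, 21), rep(0, 79)),
             p20 = c(rep(0.1, 20), rep(0, 80)),
             full = rep(0.2, 100))
  rownames(X) <- sprintf("S%d", 1:100)
  out <- prevalence_filter(X, 0.20)
  expect_identical(colnames(out), c("p21", "full"))
  expect_identical(attr(out, "dropped"), "p20")
  allfull <- X[, c("full"), drop = FALSE]
  expect_equal(prevalence_filter(allfull), allfull, ignore_attr = TRUE)
})

test_that("partial Spearman reduces to plain Spearman and removes confounding", {
  set.seed(301)
  x <- rnorm(100); y <- 0.4 * x + rnorm(100)
  ps <- partial_spearman(x, y)
  expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(ps$p, cor.test(x, y, method = "spearman", exact = FALSE)$p.value,
               tolerance = 1e-6)
  # perfect monotone dependence survives irrelevant covariates
  z <- rnorm(100)
  expect_equal(partial_spearman(x, x, data.frame(z))$rho, 1, tolerance = 1e-9)
  # classic confounder: x = z + noise, y = z + noise, x ⊥ y | z
  set.seed(302)
  z <- rnorm(1000)
  x2 <- z + rnorm(1000); y2 <- z + rnorm(1000)
  expect_gt(cor(x2, y2, method = "spearman"), 0.4)
  expect_lt(abs(partial_spearman(x2, y2, data.frame(z))$rho), 0.05)
})

test_that("partial Spearman is invariant to monotone transforms", {
  set.seed(303)
  x <- rlnorm(200); y <- x + rnorm(200)
  z <- data.frame(z = rnorm(200))
  base <- partial_spearman(x, y, z)
  expect_equal(partial_spearman(exp(x / 5), y, z)$rho, base$rho, tolerance = 1e-12)
  expect_equal(partial_spearman(x, y^3, z)$rho, base$rho, tolerance = 1e-12)
  expect_error(partial_spearman(rep(1, 50), rnorm(50)), "zero residual")
})

test_that("bh_fdr matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  set.seed(311)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
  # order-equivariance
  p <- runif(10)
  perm <- sample(10)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("species screen controls the FDR and flags planted signals", {
  set.seed(321)
  mb <- simulate_microbiome(400, 50, 0.9, seed = 322)
  cm <- couple_metabolite(mb, 1:3, c(0.9, -0.8, 0.8), noise_sd = 0.8, seed = 323)
  covars <- data.frame(age = runif(400, 30, 70), bmi = rnorm(400, 26, 4),
                       sex = rbinom(400, 1, 0.5))
  scr <- species_screen(mb, cm$trait, covars)
  expect_true(all(scr$q >= scr$p))
  expect_true(all(c("sp_001", "sp_002", "sp_003") %in%
                    scr$feature[scr$q < 0.05]))
  expect_equal(sign(scr$rho[scr$feature == "sp_002"]), -1)
  # constant covariate dropped with a message, not an error
  covars$sex <- 1
  expect_message(species_screen(mb, cm$trait, covars), "constant")
})

test_that("concordance gate requires discovery FDR, validation p and same sign", {
  disc <- data.frame(feature = c("a", "b", "c", "d"),
                     rho = c(0.3, 0.3, 0.3, 0.3),
                     p = c(1e-4, 1e-4, 1e-4, 1e-4),
                     q = c(0.01, 0.01, 0.06, 0.01))
  val <- data.frame(feature = c("a", "b", "c"),
                    rho = c(0.2, -0.2, 0.3),
                    p = c(0.04, 0.04, 0.001),
                    q = c(0.2, 0.2, 0.01))
  out <- replicate_concordance(disc, val)
  expect_identical(out$feature, "a")          # b: sign flip; c: discovery gate
  expect_identical(attr(out, "unmatched"), "d")
})

test_that("meal summaries take the post-meal peak and signed delta", {
  ts <- data.frame(sample_id = rep(c("A", "B"), each = 4),
                   analyte = "tg",
                   timepoint_min = rep(c(0, 120, 240, 360), 2),
                   value = c(1.0, 2.5, 2.0, 1.5,   # rises then falls
                             3.0, 2.5, 2.0, 1.5))  # monotone decreasing
  ms <- summarize_meal(ts, "tg", 6)
  expect_equal(ms$baseline, c(1.0, 3.0))
  expect_equal(ms$peak, c(2.5, 2.5))
  expect_equal(ms$delta, c(1.5, -0.5))        # declining trajectory: delta < 0
  # a 2-hour window restricts the peak search
  ms2 <- summarize_meal(ts, "tg", 2)
  expect_equal(ms2$peak[1], 2.5)
  expect_error(summarize_meal(ts[ts$timepoint_min > 0, ], "tg", 6), "time-0")
  expect_error(summarize_meal(ts, "nope", 6), "no records")
})

test_that("linear associations recover exact and planted coefficients", {
  x <- rnorm(50)
  la <- suppressWarnings(linear_association(2 * x, x))  # exact fit warns in lm
  expect_equal(la$beta, 2, tolerance = 1e-10)
  expect_lt(la$p, 1e-12)
  # CI coverage under the null: ~95% of intervals cover zero
  set.seed(331)
  cover <- vapply(1:200, function(i) {
    e <- rnorm(60); o <- rnorm(60)
    ci <- linear_association(o, e)
    ci$ci_lo <= 0 && 0 <= ci$ci_hi
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
  # collinear design rejected with the column named
  z <- data.frame(dup = x)
  expect_error(linear_association(rnorm(50), x, z), "collinear")
})

test_that("tertile coding splits samples evenly and supports contrasts", {
  tc <- tertile_code(1:9)
  expect_equal(tc, rep(1:3, each = 3))
  # a monotone dose across tertiles is recovered as a positive contrast
  set.seed(361)
  x <- rnorm(300)
  y <- 0.5 * tertile_code(x) + rnorm(300)
  la <- linear_association(y, tertile_code(x))
  expect_lt(abs(la$beta - 0.5), 2 * la$se)
  expect_error(tertile_code(rep(2, 10)), "identical")
})

test_that("DerSimonian-Laird pooling matches hand arithmetic and metafor", {
  # equal effects: homogeneous, fixed-effect reduction
  m0 <- meta_random_effects(c(0.5, 0.5), c(0.2, 0.2))
  expect_equal(m0$beta, 0.5)
  expect_equal(m0$tau2, 0)
  expect_equal(m0$se, sqrt(1 / sum(1 / c(0.2, 0.2)^2)))
  # hand-derived: w = 100 each, Q = 2, tau2 = 1/100, w* = 50 each
  m <- meta_random_effects(c(0.4, 0.6), c(0.1, 0.1))
  expect_equal(m$beta, 0.5, tolerance = 1e-12)
  expect_equal(m$Q, 2, tolerance = 1e-12)
  expect_equal(m$tau2, 0.01, tolerance = 1e-12)
  expect_equal(m$se, sqrt(1 / 100), tolerance = 1e-12)
  # pooled estimate always inside the study range
  set.seed(341)
  for (i in 1:20) {
    b <- rnorm(4); s <- runif(4, 0.05, 0.5)
    mm <- meta_random_effects(b, s)
    expect_gte(mm$beta, min(b)); expect_lte(mm$beta, max(b))
  }
  expect_error(meta_random_effects(0.4, 0.1), "2 studies")
  skip_if_not_installed("metafor")
  rf <- metafor::rma(yi = c(0.4, 0.6, 0.1), sei = c(0.1, 0.1, 0.3),
                     method = "DL")
  mm <- meta_random_effects(c(0.4, 0.6, 0.1), c(0.1, 0.1, 0.3))
  expect_equal(mm$beta, as.numeric(rf$beta), tolerance = 1e-10)
  expect_equal(mm$tau2, rf$tau2, tolerance = 1e-10)
  expect_equal(mm$se, rf$se, tolerance = 1e-10)
})

test_that("paired t-tests report the mean change with its interval", {
  d <- c(-1, 0, 1, -2, 2)
  pt <- paired_ttest(rep(0, 5), d)
  expect_equal(pt$mean_diff, 0)
  expect_equal(pt$p, 1)
  # cross-check against the closed form
  set.seed(351)
  before <- rnorm(30); after <- before + rnorm(30, -0.5)
  pt2 <- paired_ttest(before, after)
  dd <- after - before
  expect_equal(pt2$mean_diff, mean(dd))
  expect_equal(pt2$p, t.test(dd)$p.value)
  # constant shift: zero difference variance is an error
  expect_error(paired_ttest(before, before + 1), "zero variance")
})

test_that("complete-linkage clustering merges by maximum distance", {
  m <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  cl <- cluster_species(m)
  expect_equal(sort(cl$tree$height), c(1, 10))  # final merge at max distance
  expect_equal(cl$tree$merge[1, ], c(-1, -2))   # {0, 1} merge first
  # identical rows merge first at height zero
  m2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  cl2 <- cluster_species(m2)
  expect_equal(min(cl2$tree$height), 0)
  # invariant to row permutation up to relabeling
  perm <- c(3, 1, 2)
  cl3 <- cluster_species(m[perm, , drop = FALSE])
  expect_equal(sort(cl3$tree$height), sort(cl$tree$height))
  expect_error(cluster_species(matrix(c(1, NA), 1, 2)), "missing")
})
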