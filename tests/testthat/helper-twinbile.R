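# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# small metabolite matrix with controlled batches / missingness
toy_metabolites <- function() {
  v <- matrix(c(2, 4, 8, 1, 2, 3,
                10, 20, 30, 5, 5, 5), nrow = 6,
              dimnames = list(sprintf("S%d", 1:6), c("metA", "metB")))
  metabolite_matrix(v, batch = rep(c("B1", "B2"), each = 3))
}

# unrelated-singleton metadata for fold tests
singleton_meta <- function(n) {
  data.frame(sample_id = sprintf("S%05d", seq_len(n)),
             family_id = sprintf("F%05d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# metadata of n_pairs twin pairs (no singletons)
pair_meta <- function(n_pairs) {
  data.frame(sample_id = sprintf("S%05d", seq_len(2 * n_pairs)),
             family_id = rep(sprintf("F%05d", seq_len(n_pairs)), each = 2),
             stringsAsFactors = FALSE)
}

# empirical within-pair correlations of a simulated cohort trait
pair_correlations <- function(cohort, trait) {
  ord <- order(cohort$family_id)
  fam <- cohort$family_id[ord]
  y <- cohort[[trait]][ord]
  z <- cohort$zygosity[ord]
  paired <- fam %in% names(which(table(fam) == 2))
  y <- y[paired]; z <- z[paired]
  x1 <- y[c(TRUE, FALSE)]; x2 <- y[c(FALSE, TRUE)]
  zz <- z[c(TRUE, FALSE)]
  c(rmz = if (any(zz == "MZ")) cor(x1[zz == "MZ"], x2[zz == "MZ"]) else NA,
    rdz = if (any(zz == "DZ")) cor(x1[zz == "DZ"], x2[zz == "DZ"]) else NA)
}

# hand-coded bivariate normal log-density (independent likelihood oracle)
dbvnorm_log <- function(x1, x2, mu, v, cv) {
  det <- v^2 - cv^2
  q <- (v * (x1 - mu)^2 - 2 * cv * (x1 - mu) * (x2 - mu) + v * (x2 - mu)^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# brute-force Benjamini-Hochberg step-up adjustment (definition-level oracle)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  pmin(q_sorted, 1)[order(o)]
}
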