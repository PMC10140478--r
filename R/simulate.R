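## Synthetic twin-cohort, microbiome, batch and meal-response generators.
## Every generator is a pure function of (parameters, seed) and returns its
## ground-truth parameters alongside the data so downstream stages can be
## scored for recovery.

#' Specify an ACE variance decomposition for one simulated trait
#'
#' The classical twin model splits phenotypic variance into additive genetic
#' (A), common/shared environmental (C) and unique environmental (E) parts.
#' Here `a2`, `c2`, `e2` are the variance *shares*, which must sum to one.
#'
#' @param a2,c2,e2 variance shares in `[0, 1]`, summing to 1.
#' @param trait_mean,trait_sd mean and standard deviation of the trait on its
#'   measurement scale (`trait_sd > 0`).
#' @return an object of class `"ace_spec"`.
#' @export
ace_spec <- function(a2, c2 = 0, e2 = 1 - a2 - c2, trait_mean = 0, trait_sd = 1) {
  vals <- c(a2 = a2, c2 = c2, e2 = e2)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("ACE variance shares must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(vals) - 1) > 1e-12) {
    stop("a2 + c2 + e2 must equal 1 (tolerance 1e-12), got ",
         format(sum(vals), digits = 15), call. = FALSE)
  }
  stopifnot(is.numeric(trait_sd), trait_sd > 0)
  structure(list(a2 = a2, c2 = c2, e2 = e2,
                 trait_mean = trait_mean, trait_sd = trait_sd),
            class = "ace_spec")
}

#' Specify the composition of a simulated twin cohort
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons non-negative counts of
#'   monozygotic pairs, dizygotic pairs, and unpaired individuals.
#' @param covariate_specs list controlling simulated covariates:
#'   `age = c(min, max)` (uniform, years), `bmi = c(mean, sd)` (normal,
#'   kg/m^2), `sex = p` (probability of female, coded 1). Twins share age
#'   and sex within a pair.
#' @return an object of class `"cohort_design"`.
#' @export
cohort_design <- function(n_mz_pairs, n_dz_pairs, n_singletons = 0,
                          covariate_specs = list(age = c(30, 75),
                                                 bmi = c(26, 4),
                                                 sex = 0.85)) {
  counts <- c(n_mz_pairs, n_dz_pairs, n_singletons)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("pair and singleton counts must be non-negative integers", call. = FALSE)
  }
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_singletons = as.integer(n_singletons),
                 n_individuals = 2L * as.integer(n_mz_pairs) +
                   2L * as.integer(n_dz_pairs) + as.integer(n_singletons),
                 covariate_specs = covariate_specs),
            class = "cohort_design")
}

#' Simulate a twin cohort with known ACE trait architecture
#'
#' Each individual's trait value is
#' `trait_mean + trait_sd * (a*G + c*C + e*U)` with `a = sqrt(a2)` etc.
#' The additive-genetic factor `G` is identical within MZ pairs and
#' correlated 0.5 within DZ pairs (standard additive model); the common
#' environment `C` is identical within any pair; `U` is independent across
#' individuals. Expected intraclass correlations are therefore
#' `rMZ = a2 + c2` and `rDZ = 0.5*a2 + c2`.
#'
#' @param design a [cohort_design()].
#' @param traits named list of [ace_spec()] objects, one per trait column.
#' @param seed integer seed; identical calls give identical output.
#' @return a `data.frame` with columns `sample_id`, `family_id`, `zygosity`
#'   (`MZ`/`DZ`/`SINGLETON`), `age`, `bmi`, `sex`, and one column per trait.
#'   The list of generating [ace_spec()]s is attached as attribute
#'   `"ground_truth"`.
#' @export
simulate_twin_cohort <- function(design, traits, seed) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(names(traits)) || any(!nzchar(names(traits)))) {
    stop("`traits` must be a named list of ace_spec objects", call. = FALSE)
  }
  lapply(traits, function(s) if (!inherits(s, "ace_spec"))
    stop("each trait must be an ace_spec", call. = FALSE))
  set.seed(substream(seed, "twin_cohort"))

  n_mz <- design$n_mz_pairs; n_dz <- design$n_dz_pairs; n_s <- design$n_singletons
  n_pairs <- n_mz + n_dz
  n <- design$n_individuals
  fam_pair <- if (n_pairs > 0) sprintf("F%05d", seq_len(n_pairs)) else character(0)
  fam_single <- if (n_s > 0) sprintf("F%05d", n_pairs + seq_len(n_s)) else character(0)

  family_id <- c(rep(fam_pair, each = 2), fam_single)
  zygosity <- c(rep(c("MZ", "DZ"), times = c(2 * n_mz, 2 * n_dz)),
                rep("SINGLETON", n_s))
  sample_id <- sprintf("S%05d", seq_len(n))

  cs <- design$covariate_specs
  # age and sex are shared within a pair; BMI is individual
  age_f <- runif(n_pairs + n_s, cs$age[1], cs$age[2])
  sex_f <- rbinom(n_pairs + n_s, 1, cs$sex)
  fam_index <- c(rep(seq_len(n_pairs), each = 2),
                 if (n_s > 0) n_pairs + seq_len(n_s))
  age <- age_f[fam_index]
  sex <- sex_f[fam_index]
  bmi <- rnorm(n, cs$bmi[1], cs$bmi[2])

  out <- data.frame(sample_id = sample_id, family_id = family_id,
                    zygosity = zygosity, age = age, bmi = bmi, sex = sex,
                    stringsAsFactors = FALSE)

  for (tr in names(traits)) {
    sp <- traits[[tr]]
    a <- sqrt(sp$a2); cc <- sqrt(sp$c2); e <- sqrt(sp$e2)
    # genetic factor: shared for MZ, correlated 0.5 for DZ
    g_mz <- rep(rnorm(n_mz), each = 2)
    g1_dz <- rnorm(n_dz)
    g2_dz <- 0.5 * g1_dz + sqrt(0.75) * rnorm(n_dz)
    g_dz <- as.vector(rbind(g1_dz, g2_dz))
    g_s <- rnorm(n_s)
    G <- c(g_mz, g_dz, g_s)
    # common environment: shared within any pair
    C <- c(rep(rnorm(n_pairs), each = 2), rnorm(n_s))
    U <- rnorm(n)
    out[[tr]] <- sp$trait_mean + sp$trait_sd * (a * G + cc * C + e * U)
  }
  attr(out, "ground_truth") <- traits
  out
}

#' Simulate compositional gut-microbiome relative-abundance profiles
#'
#' Species abundances are drawn from a zero-inflated log-normal: each species
#' is present in a sample with its prevalence probability, present values are
#' log-normal with species-specific location (drawn once per species, giving
#' the uneven abundance structure of real profiles), and rows are closed to
#' sum to one.
#'
#' @param n_samples,n_species positive counts.
#' @param prevalence_profile per-species presence probability in `[0, 1]`;
#'   a single value is recycled.
#' @param seed integer seed.
#' @param meanlog_sd spread of species-specific log-abundance locations.
#' @param sdlog within-species log-scale standard deviation.
#' @param family optional family id per sample; members of the same family
#'   get correlated profiles (twins share gut-microbiome composition).
#' @param family_icc intraclass correlation of the log-abundance (and the
#'   probability that a family shares one presence/absence draw) within a
#'   family; ignored when `family` is `NULL`.
#' @return a samples x species matrix of relative abundances with sample ids
#'   as row names and `sp_###` column names; each row sums to 1.
#' @export
simulate_microbiome <- function(n_samples, n_species, prevalence_profile = 0.5,
                                seed = 1, meanlog_sd = 1.5, sdlog = 1,
                                family = NULL, family_icc = 0.5) {
  stopifnot(n_samples >= 1)
  if (n_species < 1) stop("n_species must be >= 1", call. = FALSE)
  prevalence_profile <- rep_len(prevalence_profile, n_species)
  if (any(prevalence_profile < 0 | prevalence_profile > 1)) {
    stop("prevalence_profile entries must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(family)) {
    stopifnot(length(family) == n_samples)
    check_fraction(family_icc, "family_icc")
  }
  set.seed(substream(seed, "microbiome"))
  meanlog <- rnorm(n_species, 0, meanlog_sd)
  prev_m <- rep(prevalence_profile, each = n_samples)
  present <- matrix(rbinom(n_samples * n_species, 1, prev_m),
                    n_samples, n_species)
  noise <- matrix(rnorm(n_samples * n_species), n_samples, n_species)
  if (is.null(family)) {
    logab <- rep(meanlog, each = n_samples) + sdlog * noise
  } else {
    fam <- match(family, unique(family))
    nf <- length(unique(family))
    fam_noise <- matrix(rnorm(nf * n_species), nf, n_species)
    fam_present <- matrix(rbinom(nf * n_species, 1,
                                 rep(prevalence_profile, each = nf)),
                          nf, n_species)
    share <- matrix(rbinom(nf * n_species, 1, family_icc), nf, n_species)
    # presence: with probability family_icc the whole family shares one draw
    present <- share[fam, ] * fam_present[fam, ] + (1 - share[fam, ]) * present
    logab <- rep(meanlog, each = n_samples) +
      sdlog * (sqrt(family_icc) * fam_noise[fam, ] +
                 sqrt(1 - family_icc) * noise)
  }
  ab <- present * exp(logab)
  # a sample with no detected species at all gets its most prevalent species
  empty <- rowSums(ab) == 0
  if (any(empty)) ab[empty, which.max(prevalence_profile)] <- 1
  ab <- ab / rowSums(ab)
  dimnames(ab) <- list(sprintf("S%05d", seq_len(n_samples)),
                       sprintf("sp_%03d", seq_len(n_species)))
  ab
}

#' Plant a species-driven metabolite signal on a microbiome profile
#'
#' The trait is a linear combination of standardised `log1p` abundances of the
#' chosen causal species plus Gaussian noise; the generating signal variance
#' and implied R-squared are returned as ground truth.
#'
#' @param profile samples x species relative-abundance matrix.
#' @param causal_species column indices (or names) of causal species.
#' @param effect_sizes signed effects, one per causal species, in trait-SD
#'   units per SD of log1p abundance.
#' @param noise_sd residual standard deviation (`>= 0`).
#' @param seed integer seed.
#' @return list with `trait` (numeric vector named by sample), `r2`
#'   (ground-truth variance explained on this realisation), `signal_var`,
#'   `noise_sd`, `causal_species`, `effect_sizes`.
#' @export
couple_metabolite <- function(profile, causal_species, effect_sizes,
                              noise_sd, seed = 1) {
  if (!is.matrix(profile) || nrow(profile) == 0) {
    stop("`profile` must be a non-empty samples x species matrix", call. = FALSE)
  }
  if (length(causal_species) != length(effect_sizes)) {
    stop("effect_sizes must match causal_species in length", call. = FALSE)
  }
  if (is.character(causal_species)) {
    causal_species <- match(causal_species, colnames(profile))
  }
  if (any(is.na(causal_species)) || any(causal_species > ncol(profile))) {
    stop("causal species indices must address columns of the profile", call. = FALSE)
  }
  stopifnot(noise_sd >= 0)
  set.seed(substream(seed, "couple_metabolite"))
  signal <- rep(0, nrow(profile))
  if (length(causal_species) > 0) {
    Z <- log1p(profile[, causal_species, drop = FALSE])
    Z <- scale(Z)
    Z[, attr(Z, "scaled:scale") == 0] <- 0  # constant species carry no signal
    signal <- drop(Z %*% effect_sizes)
  }
  trait <- signal + rnorm(nrow(profile), 0, noise_sd)
  names(trait) <- rownames(profile)
  sv <- var(signal)
  list(trait = trait,
       r2 = if (sv + noise_sd^2 > 0) sv / (sv + noise_sd^2) else 0,
       signal_var = sv, noise_sd = noise_sd,
       causal_species = causal_species, effect_sizes = effect_sizes)
}

#' Impose instrument-batch scale effects and detection-limit censoring
#'
#' Samples are assigned to batches, values are multiplied by their batch's
#' scale factor (emulating inter-day instrument tuning differences), and the
#' lowest `censor_quantile` fraction of each metabolite's values is set to
#' missing — left-censoring, the mechanism under which minimum-value
#' imputation is the natural repair.
#'
#' @param values samples x metabolites numeric matrix.
#' @param n_batches number of instrument batches (`>= 1`).
#' @param batch_scales positive multiplicative scale per batch.
#' @param censor_quantile fraction in `[0, 1)` of each metabolite left-censored.
#' @param seed integer seed.
#' @return a [metabolite_matrix()] at stage `"raw"`, with the batch assignment
#'   in `$batch` and the pre-censoring values as attribute `"uncensored"`.
#' @export
apply_batch_structure <- function(values, n_batches, batch_scales,
                                  censor_quantile = 0, seed = 1) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(n_batches >= 1, length(batch_scales) == n_batches,
            all(batch_scales > 0))
  if (n_batches > nrow(values)) stop("more batches than samples", call. = FALSE)
  check_fraction(censor_quantile, "censor_quantile", strict_hi = TRUE)
  set.seed(substream(seed, "batch_structure"))
  n <- nrow(values)
  batch <- sample(rep_len(sprintf("B%02d", seq_len(n_batches)), n))
  scaled <- values * batch_scales[match(batch, sprintf("B%02d", seq_len(n_batches)))]
  censored <- scaled
  k <- floor(censor_quantile * n)
  if (k > 0) {
    for (j in seq_len(ncol(censored))) {
      censored[order(censored[, j])[seq_len(k)], j] <- NA_real_
    }
  }
  out <- metabolite_matrix(censored, batch = batch, stage = "raw")
  attr(out, "uncensored") <- scaled
  out
}

#' Simulate post-prandial analyte trajectories coupled to a metabolite
#'
#' Each sample gets an analyte time course starting at a fasting baseline and
#' rising to a post-meal peak whose excess over baseline is
#' `amplitude_base + beta*trait + covariate effects + noise`, truncated at
#' zero (a trajectory never dips below its own baseline by construction).
#' The trajectory shape is a gamma-like pulse peaking mid-window.
#'
#' @param trait numeric exposure vector (one value per sample).
#' @param beta planted slope of peak on trait.
#' @param covariates data.frame of per-sample covariates (may be `NULL`);
#'   numeric columns enter the amplitude additively with effects
#'   `covariate_effects`.
#' @param timepoints sampling times in minutes; must include 0 and have at
#'   least 2 points.
#' @param seed integer seed.
#' @param noise_sd amplitude noise SD.
#' @param amplitude_base baseline rise, keeping amplitudes almost surely
#'   positive.
#' @param covariate_effects named effects for covariate columns (default 0).
#' @param analyte analyte label in the output table.
#' @return long `data.frame` (`sample_id`, `analyte`, `timepoint_min`,
#'   `value`) with attribute `"ground_truth"` = list(beta, amplitude_base,
#'   noise_sd, covariate_effects).
#' @export
simulate_postprandial <- function(trait, beta, covariates = NULL,
                                  timepoints = c(0, 30, 120, 240, 360),
                                  seed = 1, noise_sd = 1, amplitude_base = 5,
                                  covariate_effects = NULL,
                                  analyte = "triglycerides") {
  if (length(timepoints) < 2) stop("need at least 2 timepoints", call. = FALSE)
  if (!0 %in% timepoints) stop("timepoints must include 0 (fasting)", call. = FALSE)
  n <- length(trait)
  if (!is.null(covariates) && nrow(covariates) != n) {
    stop("`covariates` must have one row per trait value", call. = FALSE)
  }
  set.seed(substream(seed, "postprandial"))
  baseline <- 1 + abs(rnorm(n, 0, 0.2))
  cov_part <- rep(0, n)
  if (!is.null(covariates) && !is.null(covariate_effects)) {
    for (nm in names(covariate_effects)) {
      cov_part <- cov_part + covariate_effects[[nm]] * covariates[[nm]]
    }
  }
  amplitude <- pmax(0, amplitude_base + beta * trait + cov_part + rnorm(n, 0, noise_sd))
  tp <- sort(unique(timepoints))
  t_peak <- tp[tp > 0][ceiling(sum(tp > 0) / 2)]  # mid-window peak time
  shape <- ifelse(tp == 0, 0, (tp / t_peak) * exp(1 - tp / t_peak))
  ids <- if (!is.null(names(trait))) names(trait) else sprintf("S%05d", seq_len(n))
  out <- data.frame(
    sample_id = rep(ids, each = length(tp)),
    analyte = analyte,
    timepoint_min = rep(tp, times = n),
    value = as.vector(vapply(seq_len(n),
                             function(i) baseline[i] + amplitude[i] * shape,
                             numeric(length(tp)))),
    stringsAsFactors = FALSE)
  attr(out, "ground_truth") <- list(beta = beta, amplitude_base = amplitude_base,
                                    noise_sd = noise_sd,
                                    covariate_effects = covariate_effects)
  out
}
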