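## Tabular I/O and the end-to-end pipeline driver.
## All tables are TSV (CSV accepted on read); an empty cell is a missing
## value; lines starting with '#' are header comments carrying the run seed
## and input checksums. Numeric values are written with 17 significant
## digits so write -> read round-trips exactly.

#' Read a samples x features matrix from TSV/CSV
#'
#' The first column holds sample (row) ids; empty cells are missing. Long
#' format expects three columns (sample, feature, value) and is pivoted to
#' the same wide matrix, with rows and columns in first-appearance order.
#'
#' @param path file path (`.tsv`/`.txt` tab-separated; `.csv` comma).
#' @param orientation `"wide"` (default) or `"long"`.
#' @return numeric matrix with sample ids as row names.
#' @export
read_matrix <- function(path, orientation = c("wide", "long")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cf <- count.fields(path, sep = sep, quote = "\"", comment.char = "#",
                     blank.lines.skip = TRUE)
  cf <- cf[!is.na(cf)]
  if (length(unique(cf)) > 1) {
    bad <- which(cf != cf[1])[1]
    stop(sprintf("ragged table: line %d has %d fields, expected %d",
                 bad, cf[bad], cf[1]), call. = FALSE)
  }
  df <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   comment.char = "#", na.strings = c("", "NA"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (orientation == "wide") {
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      stop("duplicated sample id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  } else {
    if (ncol(df) != 3) stop("long format needs exactly 3 columns", call. = FALSE)
    s <- as.character(df[[1]]); f <- as.character(df[[2]]); v <- as.numeric(df[[3]])
    if (anyDuplicated(paste(s, f, sep = "\r"))) {
      stop("duplicated (sample, feature) record(s)", call. = FALSE)
    }
    rows <- unique(s); cols <- unique(f)
    m <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
    m[cbind(match(s, rows), match(f, cols))] <- v
    m
  }
}

#' Write a samples x features matrix as TSV
#'
#' Missing entries become empty cells; optional comment lines (prefixed
#' `# `) are written above the header.
#'
#' @param x numeric matrix with row names.
#' @param path output path.
#' @param comments character vector of header-comment lines (without the
#'   leading `#`).
#' @param id_col name for the id column (default `"sample_id"`).
#' @export
write_matrix <- function(x, path, comments = NULL, id_col = "sample_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c(id_col, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(r) {
    paste(ifelse(is.na(r), "", sprintf("%.17g", r)), collapse = "\t")
  })
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

## internal: write a data.frame as commented TSV
write_table_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), "", sprintf("%.17g", v)))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' Build a pipeline configuration
#'
#' Defaults mirror the full twin-cohort study design: 654 MZ pairs, 380 DZ
#' pairs and 471 singletons; two purely heritable/environmental traits plus
#' one microbiome-coupled metabolite; 4 instrument batches with 10%
#' left-censoring; thresholds 0.20 (missingness and prevalence), q < 0.05,
#' 5-fold cross-validation, 1000 trees.
#'
#' @param seed integer master seed; every stage derives sub-seeds from it.
#' @param out_dir output directory for tables and the run report.
#' @param n_mz_pairs,n_dz_pairs,n_singletons cohort composition.
#' @param traits named list of [ace_spec()]s simulated on the cohort.
#' @param n_species,coupled_species,coupled_effects,coupling_noise_sd
#'   microbiome panel and the planted species -> metabolite coupling.
#' @param n_batches,batch_scales,censor_quantile instrument-batch structure.
#' @param max_missing,prevalence,q_threshold,p_threshold analysis thresholds.
#' @param k,ntree cross-validation folds and forest size.
#' @param stages character subset of
#'   `c("preprocess", "heritability", "predict", "associate")`.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("twinbile_run_"),
                            n_mz_pairs = 654, n_dz_pairs = 380,
                            n_singletons = 471,
                            traits = list(
                              ba_heritable = ace_spec(a2 = 0.6, c2 = 0.1),
                              ba_environmental = ace_spec(a2 = 0, c2 = 0)),
                            n_species = 150,
                            coupled_species = 1:5,
                            coupled_effects = c(0.6, -0.5, 0.5, -0.4, 0.4),
                            coupling_noise_sd = 1,
                            n_batches = 4,
                            batch_scales = c(1, 1.5, 0.8, 1.2),
                            censor_quantile = 0.10,
                            max_missing = 0.20, prevalence = 0.20,
                            q_threshold = 0.05, p_threshold = 0.05,
                            k = 5, ntree = 1000,
                            stages = c("preprocess", "heritability",
                                       "predict", "associate")) {
  stopifnot(k >= 2, ntree >= 1, seed == round(seed))
  lapply(list(max_missing, prevalence, q_threshold, p_threshold),
         check_fraction, name = "threshold", strict_hi = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates a twin cohort, microbiome and metabolite panel with known
#' ground truth, then runs the enabled stages in order: preprocessing
#' (filter, batch scaling, imputation, inverse-normal transform),
#' heritability (all twin models + AIC selection + CIs), twin-aware
#' random-forest prediction, and the association stage (species screen on
#' two split cohorts, concordance, post-prandial linear model,
#' meta-analysis, paired intervention t-test). Writes all result tables,
#' the simulated inputs, and a YAML run report into `config$out_dir`.
#' Identical configs produce byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory results and the report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  report <- list(package_version = as.character(packageVersion("twinbile")),
                 seed = seed, stages = cfg$stages, counts = list(),
                 sub_seeds = list())

  ## --- simulate -----------------------------------------------------------
  design <- cohort_design(cfg$n_mz_pairs, cfg$n_dz_pairs, cfg$n_singletons)
  cohort <- simulate_twin_cohort(design, cfg$traits,
                                 seed = substream(seed, "cohort"))
  profile <- simulate_microbiome(design$n_individuals, cfg$n_species,
                                 prevalence_profile = 0.6,
                                 seed = substream(seed, "microbiome"))
  rownames(profile) <- cohort$sample_id
  coupled <- couple_metabolite(profile, cfg$coupled_species,
                               cfg$coupled_effects, cfg$coupling_noise_sd,
                               seed = substream(seed, "coupling"))
  trait_mat <- cbind(as.matrix(cohort[names(cfg$traits)]),
                     ba_microbial = coupled$trait)
  rownames(trait_mat) <- cohort$sample_id
  raw <- apply_batch_structure(trait_mat + 10, cfg$n_batches, cfg$batch_scales,
                               cfg$censor_quantile,
                               seed = substream(seed, "batches"))
  report$sub_seeds <- lapply(c(cohort = "cohort", microbiome = "microbiome",
                               coupling = "coupling", batches = "batches"),
                             function(l) substream(seed, l))
  meta <- cohort[c("sample_id", "family_id", "zygosity", "age", "bmi", "sex")]
  hdr <- function(inputs = character(0)) {
    c(sprintf("twinbile pipeline, seed %d", seed),
      if (length(inputs))
        sprintf("input %s md5 %s", basename(inputs),
                unname(tools::md5sum(inputs))))
  }
  p_meta <- file.path(cfg$out_dir, "metadata.tsv")
  p_raw <- file.path(cfg$out_dir, "metabolites_raw.tsv")
  p_mb <- file.path(cfg$out_dir, "microbiome.tsv")
  write_table_tsv(meta, p_meta, comments = hdr())
  write_matrix(raw$values, p_raw,
               comments = c(hdr(), paste0("batch\t",
                                          paste(raw$batch, collapse = ","))))
  write_matrix(profile, p_mb, comments = hdr())
  report$counts$samples <- nrow(meta)
  report$counts$species <- ncol(profile)
  results <- list(cohort = cohort, profile = profile, coupled = coupled)

  ## --- preprocess ---------------------------------------------------------
  norm <- NULL
  if ("preprocess" %in% cfg$stages) {
    norm <- preprocess_metabolites(raw, cfg$max_missing)
    write_matrix(norm$values,
                 file.path(cfg$out_dir, "metabolites_normalized.tsv"),
                 comments = hdr(c(p_raw, p_meta)))
    report$counts$metabolites_dropped <- length(attr(norm, "dropped"))
    report$counts$metabolites_kept <- ncol(norm$values)
    results$normalized <- norm
  }

  ## --- heritability -------------------------------------------------------
  if ("heritability" %in% cfg$stages) {
    if (is.null(norm)) stop("heritability stage requires preprocessing",
                            call. = FALSE)
    cohort_h <- cbind(meta, as.data.frame(norm$values))
    htab <- heritability_table(cohort_h, colnames(norm$values))
    write_table_tsv(htab, file.path(cfg$out_dir, "heritability.tsv"),
                    comments = hdr(c(p_raw, p_meta)))
    results$heritability <- htab
  }

  ## --- predict ------------------------------------------------------------
  if ("predict" %in% cfg$stages) {
    if (is.null(norm)) stop("prediction stage requires preprocessing",
                            call. = FALSE)
    ptab <- prediction_table(profile, norm$values, meta, k = cfg$k,
                             ntree = cfg$ntree,
                             seed = substream(seed, "predict"))
    write_table_tsv(ptab, file.path(cfg$out_dir, "prediction.tsv"),
                    comments = hdr(c(p_mb, p_raw, p_meta)))
    results$prediction <- ptab
  }

  ## --- associate ----------------------------------------------------------
  if ("associate" %in% cfg$stages) {
    if (is.null(norm)) stop("association stage requires preprocessing",
                            call. = FALSE)
    y <- norm$values[, "ba_microbial"]
    covars <- meta[c("age", "bmi", "sex")]
    # split into two pseudo-cohorts at the family level for discovery /
    # validation and meta-analysis
    fams <- unique(meta$family_id)
    set.seed(substream(seed, "cohort_split"))
    disc_fams <- sample(fams, floor(length(fams) / 2))
    in_disc <- meta$family_id %in% disc_fams
    scr_d <- species_screen(profile[in_disc, , drop = FALSE], y[in_disc],
                            covars[in_disc, ], cfg$prevalence)
    scr_v <- species_screen(profile[!in_disc, , drop = FALSE], y[!in_disc],
                            covars[!in_disc, ], cfg$prevalence)
    conc <- replicate_concordance(scr_d, scr_v, cfg$q_threshold,
                                  cfg$p_threshold)
    write_table_tsv(scr_d, file.path(cfg$out_dir, "screen_discovery.tsv"),
                    comments = hdr(c(p_mb, p_meta)))
    write_table_tsv(scr_v, file.path(cfg$out_dir, "screen_validation.tsv"),
                    comments = hdr(c(p_mb, p_meta)))
    write_table_tsv(conc, file.path(cfg$out_dir, "concordant_species.tsv"),
                    comments = hdr(c(p_mb, p_meta)))
    # post-prandial arm: peak/delta linear model per pseudo-cohort + pooling
    meal <- simulate_postprandial(y, beta = 0.32, covariates = covars,
                                  seed = substream(seed, "meal"),
                                  covariate_effects = list(age = 0.01,
                                                           bmi = 0.02))
    ms <- summarize_meal(meal, "triglycerides", window_hours = 6)
    stopifnot(identical(ms$sample_id, meta$sample_id))
    la_d <- linear_association(ms$peak[in_disc], y[in_disc],
                               covars[in_disc, c("age", "bmi")])
    la_v <- linear_association(ms$peak[!in_disc], y[!in_disc],
                               covars[!in_disc, c("age", "bmi")])
    pooled <- meta_random_effects(c(la_d$beta, la_v$beta), c(la_d$se, la_v$se))
    meta_tab <- data.frame(cohort = c("discovery", "validation", "pooled"),
                           beta = c(la_d$beta, la_v$beta, pooled$beta),
                           se = c(la_d$se, la_v$se, pooled$se),
                           ci_lo = c(la_d$ci_lo, la_v$ci_lo, pooled$ci[1]),
                           ci_hi = c(la_d$ci_hi, la_v$ci_hi, pooled$ci[2]),
                           p = c(la_d$p, la_v$p, pooled$p),
                           tau2 = c(NA, NA, pooled$tau2))
    write_table_tsv(meta_tab, file.path(cfg$out_dir, "postprandial_meta.tsv"),
                    comments = hdr(c(p_raw, p_meta)))
    # intervention arm: planted change of -0.5 on a random subset
    set.seed(substream(seed, "intervention"))
    arm <- sort(sample(nrow(meta), min(71, nrow(meta))))
    before <- y[arm]
    after <- before - 0.5 + rnorm(length(arm), 0, 1)
    pt <- paired_ttest(before, after)
    itab <- data.frame(n = pt$n, mean_diff = pt$mean_diff,
                       ci_lo = pt$ci[1], ci_hi = pt$ci[2], p = pt$p)
    write_table_tsv(itab, file.path(cfg$out_dir, "intervention.tsv"),
                    comments = hdr(c(p_raw, p_meta)))
    results$screens <- list(discovery = scr_d, validation = scr_v,
                            concordant = conc)
    results$postprandial <- meta_tab
    results$intervention <- itab
    report$counts$concordant_species <- nrow(conc)
  }

  report$outputs <- sort(list.files(cfg$out_dir))
  yaml::write_yaml(report, file.path(cfg$out_dir, "run_report.yaml"))
  results$report <- report
  invisible(results)
}
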