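## Twin variance decomposition by maximum likelihood.
##
## Pairs contribute bivariate-normal likelihood terms with common mean and
## variance across zygosity groups and covariance a^2 + c^2 (MZ) or
## 0.5*a^2 + c^2 (DZ); singletons contribute univariate-normal terms and so
## inform the mean and total variance only. The likelihood depends on the
## data only through per-group sufficient statistics, so evaluation is O(1)
## after a single pass over the cohort — fits and profile intervals are cheap
## at any cohort size.

TWIN_MODELS <- c("saturated", "ACE", "AE", "CE", "E")

## internal: per-group sufficient statistics for one trait
twin_suffstats <- function(cohort, trait) {
  needed <- c("family_id", "zygosity", trait)
  miss <- setdiff(needed, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  y <- cohort[[trait]]
  if (anyNA(y)) stop("trait has missing values; preprocess first", call. = FALSE)
  fam <- as.character(cohort$family_id)
  sizes <- table(fam)
  if (any(sizes > 2)) {
    stop("family ids must map to at most 2 individuals", call. = FALSE)
  }
  ord <- order(fam)
  fam_o <- fam[ord]; y_o <- y[ord]; zyg_o <- as.character(cohort$zygosity)[ord]
  is_pair_fam <- fam_o %in% names(sizes)[sizes == 2]
  # paired individuals, ordered so consecutive entries are co-twins
  yp <- y_o[is_pair_fam]; zp <- zyg_o[is_pair_fam]
  x1 <- yp[c(TRUE, FALSE)]; x2 <- yp[c(FALSE, TRUE)]
  z <- zp[c(TRUE, FALSE)]
  if (any(zp[c(TRUE, FALSE)] != zp[c(FALSE, TRUE)])) {
    stop("members of a family disagree on zygosity", call. = FALSE)
  }
  grp <- function(keep, x1, x2) {
    list(n = sum(keep), s1 = sum(x1[keep] + x2[keep]),
         s2 = sum(x1[keep]^2 + x2[keep]^2), s12 = sum(x1[keep] * x2[keep]))
  }
  ys <- y_o[!is_pair_fam]
  list(mz = grp(z == "MZ", x1, x2),
       dz = grp(z == "DZ", x1, x2),
       single = list(n = length(ys), s1 = sum(ys), s2 = sum(ys^2)),
       mean = mean(y), var = var(y),
       rmz = if (sum(z == "MZ") > 1) cor(x1[z == "MZ"], x2[z == "MZ"]) else NA_real_,
       rdz = if (sum(z == "DZ") > 1) cor(x1[z == "DZ"], x2[z == "DZ"]) else NA_real_)
}

## internal: log-likelihood of one pair group from sufficient statistics,
## bivariate normal with common mean mu, variance v, covariance cv
ll_pair_group <- function(g, mu, v, cv) {
  if (g$n == 0) return(0)
  det <- v^2 - cv^2
  if (!is.finite(det) || det <= 0 || v <= 0) return(-Inf)
  A <- g$s2 - 2 * mu * g$s1 + 2 * g$n * mu^2     # sum of squared deviations
  B <- g$s12 - mu * g$s1 + g$n * mu^2            # sum of cross-products
  -g$n * log(2 * pi) - g$n / 2 * log(det) - (v * A - 2 * cv * B) / (2 * det)
}

ll_single_group <- function(g, mu, v) {
  if (g$n == 0) return(0)
  if (!is.finite(v) || v <= 0) return(-Inf)
  A <- g$s2 - 2 * mu * g$s1 + g$n * mu^2
  -g$n / 2 * log(2 * pi * v) - A / (2 * v)
}

## internal: loglik of an ACE-family model at path coefficients
ll_ace <- function(ss, mu, a, c, e) {
  v <- a^2 + c^2 + e^2
  ll_pair_group(ss$mz, mu, v, a^2 + c^2) +
    ll_pair_group(ss$dz, mu, v, 0.5 * a^2 + c^2) +
    ll_single_group(ss$single, mu, v)
}

## internal: loglik of the saturated model; par packs per-group
## (mu, log var, atanh r) for MZ and DZ and (mu, log var) for singletons
ll_saturated <- function(ss, par) {
  i <- 0; ll <- 0
  for (g in list(ss$mz, ss$dz)) {
    if (g$n > 0) {
      mu <- par[i + 1]; v <- exp(par[i + 2]); r <- tanh(par[i + 3])
      ll <- ll + ll_pair_group(g, mu, v, r * v)
      i <- i + 3
    }
  }
  if (ss$single$n > 0) {
    ll <- ll + ll_single_group(ss$single, par[i + 1], exp(par[i + 2]))
  }
  ll
}

## internal: parameter layout per model (mu first, then free path coefficients)
model_paths <- function(model) {
  switch(model,
         ACE = c("a", "c", "e"), AE = c("a", "e"), CE = c("c", "e"), E = "e",
         stop("unknown model id: ", model, call. = FALSE))
}

## internal: maximize one model's likelihood with deterministic restarts
fit_model_ml <- function(ss, model, n_restarts = 5) {
  if (model == "saturated") {
    par0 <- c()
    for (g in list(ss$mz, ss$dz)) {
      if (g$n > 0) {
        r0 <- (g$s12 / g$n - (g$s1 / (2 * g$n))^2) /
          max(g$s2 / (2 * g$n) - (g$s1 / (2 * g$n))^2, 1e-8)
        par0 <- c(par0, g$s1 / (2 * g$n),
                  log(max(g$s2 / (2 * g$n) - (g$s1 / (2 * g$n))^2, 1e-8)),
                  atanh(max(min(r0, 0.99), -0.99)))
      }
    }
    if (ss$single$n > 0) {
      mu0 <- ss$single$s1 / ss$single$n
      par0 <- c(par0, mu0, log(max(ss$single$s2 / ss$single$n - mu0^2, 1e-8)))
    }
    neg <- function(p) { v <- ll_saturated(ss, p); if (is.finite(v)) -v else 1e10 }
    opt <- optim(par0, neg, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    return(list(loglik = -opt$value, par = opt$par, n_params = length(par0),
                convergence = opt$convergence))
  }
  paths <- model_paths(model)
  v0 <- max(ss$var, 1e-8)
  rmz <- if (is.finite(ss$rmz)) ss$rmz else 0.4
  rdz <- if (is.finite(ss$rdz)) ss$rdz else 0.2
  a2_0 <- min(max(2 * (rmz - rdz), 0.05), 0.9)
  c2_0 <- min(max(2 * rdz - rmz, 0.05), 0.9 - a2_0 + 0.05)
  e2_0 <- max(1 - a2_0 - c2_0, 0.05)
  start_shares <- list(a = a2_0, c = c2_0, e = e2_0)
  # deterministic restart jitters (no RNG consumed inside the fitter)
  jit <- list(c(1, 1, 1), c(2, 0.5, 1), c(0.5, 2, 1), c(1, 1, 2), c(2, 2, 0.5),
              c(0.25, 1, 2))
  neg <- function(p) {
    mu <- p[1]
    a <- if ("a" %in% paths) p[1 + match("a", paths)] else 0
    c_ <- if ("c" %in% paths) p[1 + match("c", paths)] else 0
    e <- p[1 + match("e", paths)]
    v <- ll_ace(ss, mu, a, c_, e)
    if (is.finite(v)) -v else 1e10
  }
  best <- NULL
  for (r in seq_len(min(n_restarts + 1, length(jit)))) {
    sh <- jit[[r]]
    sc <- setNames(sh[seq_along(paths)], paths)
    p0 <- c(ss$mean,
            vapply(paths, function(pn) sqrt(max(start_shares[[pn]] * sc[[pn]], 0.01) * v0),
                   numeric(1)))
    opt <- optim(p0, neg, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$value >= 1e10) {
    stop("twin model likelihood maximisation failed to find a finite optimum",
         call. = FALSE)
  }
  par <- best$par
  comps <- c(a = 0, c = 0, e = 0)
  for (pn in paths) comps[pn] <- par[1 + match(pn, paths)]^2
  list(loglik = -best$value, mu = par[1], comps = comps,
       n_params = 1 + length(paths), convergence = best$convergence)
}

#' Evaluate the twin-model log-likelihood at fixed parameter values
#'
#' Computes the exact log-likelihood of the ACE-family model (bivariate
#' normal per pair with covariance `a2 + c2` of the total variance for MZ
#' and `0.5*a2 + c2` for DZ; univariate normal per singleton) at
#' user-supplied parameter values, without any optimisation. Useful for
#' checking the likelihood against an independent density computation.
#'
#' @param cohort,trait as in [fit_twin_model()].
#' @param mean,total_variance trait mean and total phenotypic variance.
#' @param a2,c2 variance shares (e2 is the remainder).
#' @return the log-likelihood (a single number).
#' @export
twin_loglik <- function(cohort, trait, mean, total_variance, a2, c2) {
  stopifnot(total_variance > 0, a2 >= 0, c2 >= 0, a2 + c2 <= 1)
  ss <- twin_suffstats(cohort, trait)
  ll_ace(ss, mean, sqrt(a2 * total_variance), sqrt(c2 * total_variance),
         sqrt((1 - a2 - c2) * total_variance))
}

#' Fit one twin variance-decomposition model to a trait by maximum likelihood
#'
#' Non-saturated models (`ACE`, `AE`, `CE`, `E`) share a single mean and total
#' variance across zygosity groups and decompose the covariance of a pair
#' into additive-genetic and common-environment parts (`a^2 + c^2` for MZ,
#' `0.5*a^2 + c^2` for DZ). The `saturated` model frees mean, variance and
#' within-pair correlation per zygosity group and is the fit ceiling for AIC
#' comparison. Optimisation is over unconstrained path coefficients, squared
#' on output, so variance components are non-negative by construction
#' (boundary estimates allowed).
#'
#' @param cohort data.frame with `family_id`, `zygosity`
#'   (`MZ`/`DZ`/`SINGLETON`) and the trait column; each family has 1 or 2
#'   members.
#' @param trait name of the trait column (no missing values).
#' @param model one of `"saturated"`, `"ACE"`, `"AE"`, `"CE"`, `"E"`.
#' @param n_restarts extra deterministic restarts of the optimiser.
#' @return an object of class `"twin_fit"`: list with `model`, `trait`,
#'   variance shares `a2`, `c2`, `e2` (exactly 0 for components absent from
#'   the model; `NA` for the saturated model), `total_variance`, `mean`,
#'   `loglik`, `n_params`, `aic`, and `NULL` confidence-interval slots filled
#'   by [confidence_intervals()].
#' @export
fit_twin_model <- function(cohort, trait, model = "ACE", n_restarts = 5) {
  model <- match.arg(model, TWIN_MODELS)
  ss <- twin_suffstats(cohort, trait)
  if (model %in% c("ACE") && (ss$mz$n < 2 || ss$dz$n < 2)) {
    stop("ACE needs at least 2 MZ and 2 DZ pairs", call. = FALSE)
  }
  fit <- fit_model_ml(ss, model, n_restarts)
  if (fit$convergence != 0) {
    stop("optimizer did not converge for model ", model,
         " (optim code ", fit$convergence, ")", call. = FALSE)
  }
  if (model == "saturated") {
    res <- list(model = model, trait = trait,
                a2 = NA_real_, c2 = NA_real_, e2 = NA_real_,
                total_variance = NA_real_, mean = NA_real_,
                loglik = fit$loglik, n_params = fit$n_params,
                aic = -2 * fit$loglik + 2 * fit$n_params,
                sat_par = fit$par)
  } else {
    tot <- sum(fit$comps)
    res <- list(model = model, trait = trait,
                a2 = fit$comps[["a"]] / tot, c2 = fit$comps[["c"]] / tot,
                e2 = fit$comps[["e"]] / tot,
                total_variance = tot, mean = fit$mu,
                loglik = fit$loglik, n_params = fit$n_params,
                aic = -2 * fit$loglik + 2 * fit$n_params)
  }
  res$ci_a2 <- res$ci_c2 <- res$ci_e2 <- NULL
  res$n_mz <- ss$mz$n; res$n_dz <- ss$dz$n; res$n_singletons <- ss$single$n
  class(res) <- "twin_fit"
  res
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("twin %s fit for '%s' (%d MZ, %d DZ pairs, %d singletons)\n",
              x$model, x$trait, x$n_mz, x$n_dz, x$n_singletons))
  if (!is.na(x$a2)) {
    fmt_ci <- function(ci) if (is.null(ci)) "" else
      sprintf(" [%.3f, %.3f]", ci[1], ci[2])
    cat(sprintf("  a2 = %.3f%s  c2 = %.3f%s  e2 = %.3f%s\n",
                x$a2, fmt_ci(x$ci_a2), x$c2, fmt_ci(x$ci_c2),
                x$e2, fmt_ci(x$ci_e2)))
  }
  cat(sprintf("  loglik = %.3f, k = %d, AIC = %.3f\n",
              x$loglik, x$n_params, x$aic))
  invisible(x)
}

#' Select the best-fitting twin model by AIC
#'
#' Returns the fit with the lowest AIC; ties are broken toward fewer
#' parameters, then toward the fixed preference order ACE, AE, CE, E.
#'
#' @param fits list of [fit_twin_model()] results on the same trait and data.
#' @return the selected `"twin_fit"`.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  ks <- vapply(fits, function(f) f$n_params, numeric(1))
  pref <- match(vapply(fits, function(f) f$model, character(1)),
                c("ACE", "AE", "CE", "E", "saturated"))
  fits[[order(aics, ks, pref)[1]]]
}

## internal: profile log-likelihood with one variance share fixed at s
profile_ll_share <- function(ss, model, comp, s, fit) {
  paths <- model_paths(model)
  rest_paths <- setdiff(paths, comp)  # shares sharing the remaining 1 - s
  neg <- function(p) {
    mu <- p[1]; tot <- exp(p[2])
    shares <- c(a = 0, c = 0, e = 0)
    shares[comp] <- s
    if (length(rest_paths) == 2) {
      u <- 1 / (1 + exp(-p[3]))
      shares[rest_paths] <- (1 - s) * c(u, 1 - u)
    } else {
      shares[rest_paths] <- 1 - s
    }
    v <- ll_ace(ss, mu, sqrt(shares[["a"]] * tot), sqrt(shares[["c"]] * tot),
                sqrt(shares[["e"]] * tot))
    if (is.finite(v)) -v else 1e10
  }
  p0 <- c(fit$mean, log(max(fit$total_variance, 1e-8)))
  if (length(rest_paths) == 2) {
    shares_hat <- c(a = fit$a2, c = fit$c2, e = fit$e2)
    u0 <- shares_hat[[rest_paths[1]]] / max(1 - shares_hat[[comp]], 1e-6)
    u0 <- min(max(u0, 1e-4), 1 - 1e-4)
    p0 <- c(p0, log(u0 / (1 - u0)))
  }
  -optim(p0, neg, method = "BFGS",
         control = list(maxit = 500, reltol = 1e-13))$value
}

#' Profile-likelihood confidence intervals for twin variance shares
#'
#' Inverts the likelihood-ratio statistic for each free variance share:
#' the interval is the set of share values whose profile log-likelihood is
#' within `qchisq(level, 1)/2` of the maximum, truncated to `[0, 1]`.
#' Shares estimated on a boundary get a one-sided interval and a
#' `boundary` flag. Components fixed at 0 by the model get the degenerate
#' interval `[0, 0]`; the `E` model's `e2` gets `[1, 1]`.
#'
#' @param cohort,trait the data the fit came from.
#' @param fit a converged non-saturated [fit_twin_model()] result.
#' @param level coverage level (default 0.95).
#' @param method `"profile"` (default) or `"delta"` (Wald interval from a
#'   finite-difference Hessian on the path-coefficient scale, as a
#'   cross-check).
#' @return the fit with `ci_a2`, `ci_c2`, `ci_e2` filled in (each a
#'   `c(lower, upper)` with attribute `"boundary"` where one-sided).
#' @export
confidence_intervals <- function(cohort, fit, level = 0.95, method = "profile") {
  stopifnot(inherits(fit, "twin_fit"))
  method <- match.arg(method, c("profile", "delta"))
  if (fit$model == "saturated") {
    stop("confidence intervals are defined for the variance-share models",
         call. = FALSE)
  }
  ss <- twin_suffstats(cohort, fit$trait)
  paths <- model_paths(fit$model)
  crit <- qchisq(level, 1)
  shares <- c(a = fit$a2, c = fit$c2, e = fit$e2)
  cis <- list(a = c(0, 0), c = c(0, 0), e = c(0, 0))
  if (fit$model == "E") {
    cis$e <- c(1, 1)
  } else if (method == "delta") {
    cis <- delta_cis(ss, fit, level)
  } else {
    free <- paths
    eps <- 1e-6
    for (comp in free) {
      s_hat <- shares[[comp]]
      f <- function(s) 2 * (fit$loglik - profile_ll_share(ss, fit$model, comp, s, fit)) - crit
      lower <- 0; upper <- 1; bnd <- FALSE
      if (s_hat > eps) {
        flo <- f(eps)
        if (flo > 0) lower <- uniroot(f, c(eps, s_hat), tol = 1e-6)$root
        else bnd <- TRUE           # likelihood flat to the boundary
      } else bnd <- TRUE
      if (s_hat < 1 - eps) {
        fhi <- f(1 - eps)
        if (fhi > 0) upper <- uniroot(f, c(s_hat, 1 - eps), tol = 1e-6)$root
        else bnd <- TRUE
      } else bnd <- TRUE
      ci <- c(max(0, min(lower, s_hat)), min(1, max(upper, s_hat)))
      if (bnd) attr(ci, "boundary") <- TRUE
      cis[[comp]] <- ci
    }
  }
  fit$ci_a2 <- cis$a; fit$ci_c2 <- cis$c; fit$ci_e2 <- cis$e
  fit$ci_level <- level
  fit$ci_method <- method
  fit
}

## internal: delta-method intervals on shares via the path-coefficient Hessian
delta_cis <- function(ss, fit, level) {
  paths <- model_paths(fit$model)
  par_hat <- c(fit$mean,
               vapply(paths, function(pn)
                 sqrt(c(a = fit$a2, c = fit$c2, e = fit$e2)[[pn]] *
                        fit$total_variance), numeric(1)))
  neg <- function(p) {
    a <- if ("a" %in% paths) p[1 + match("a", paths)] else 0
    c_ <- if ("c" %in% paths) p[1 + match("c", paths)] else 0
    e <- p[1 + match("e", paths)]
    v <- ll_ace(ss, p[1], a, c_, e)
    if (is.finite(v)) -v else 1e10
  }
  H <- num_hessian(neg, par_hat)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(par_hat),
                                                     length(par_hat)))
  z <- qnorm(1 - (1 - level) / 2)
  cis <- list(a = c(0, 0), c = c(0, 0), e = c(0, 0))
  coefs <- setNames(par_hat[-1], paths)
  tot <- sum(coefs^2)
  for (comp in paths) {
    # gradient of share_comp = coef_comp^2 / sum(coef^2) wrt all path coefs
    grad <- numeric(length(par_hat))
    for (pn in paths) {
      i <- 1 + match(pn, paths)
      grad[i] <- if (pn == comp) 2 * coefs[[pn]] * (tot - coefs[[comp]]^2) / tot^2
      else -2 * coefs[[pn]] * coefs[[comp]]^2 / tot^2
    }
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    s_hat <- coefs[[comp]]^2 / tot
    cis[[comp]] <- c(max(0, s_hat - z * se), min(1, s_hat + z * se))
  }
  cis
}

#' Fit, compare and summarise twin models for several traits
#'
#' Fits the requested models to each trait, selects the AIC-best one, and
#' (optionally) attaches profile-likelihood intervals to the selected fit.
#'
#' @param cohort twin cohort data.frame (see [fit_twin_model()]).
#' @param traits character vector of trait column names.
#' @param models models to fit (default all five).
#' @param ci compute profile-likelihood intervals on the selected fit.
#' @param level CI coverage.
#' @return a `data.frame` with one row per trait: selected model, variance
#'   shares with CI bounds, and the AIC of every fitted model.
#' @export
heritability_table <- function(cohort, traits,
                               models = TWIN_MODELS, ci = TRUE, level = 0.95) {
  rows <- lapply(traits, function(tr) {
    fits <- lapply(models, function(mm) fit_twin_model(cohort, tr, mm))
    best <- select_model(fits)
    if (ci && best$model != "saturated") {
      best <- confidence_intervals(cohort, best, level)
    }
    aics <- setNames(vapply(fits, function(f) f$aic, numeric(1)),
                     paste0("aic_", models))
    cbind(data.frame(trait = tr, best_model = best$model,
                     a2 = best$a2, c2 = best$c2, e2 = best$e2,
                     a2_lo = if (!is.null(best$ci_a2)) best$ci_a2[1] else NA_real_,
                     a2_hi = if (!is.null(best$ci_a2)) best$ci_a2[2] else NA_real_,
                     c2_lo = if (!is.null(best$ci_c2)) best$ci_c2[1] else NA_real_,
                     c2_hi = if (!is.null(best$ci_c2)) best$ci_c2[2] else NA_real_,
                     e2_lo = if (!is.null(best$ci_e2)) best$ci_e2[1] else NA_real_,
                     e2_hi = if (!is.null(best$ci_e2)) best$ci_e2[2] else NA_real_,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(aics)))
  })
  do.call(rbind, rows)
}
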