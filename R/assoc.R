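#' Default physiological-range exclusion rules
#'
#' Named list of `c(lower, upper)` bounds (NA = unbounded) encoding the
#' standard outlier exclusions for the traits analysed: values strictly
#' outside a bound are set to missing for that trait only. Bounds are
#' boundaries of normal physiological or behavioural ranges: weight below
#' 36.28 kg, birth weight above 6.8 kg, systolic BP above 200 mmHg,
#' diastolic BP above 120 mmHg, height below 120 cm, hip circumference
#' outside 50-175 cm, waist outside 40-160 cm, grip strength above 70 kg,
#' age at first intercourse below 12 years. Comparisons are strict, so a
#' value exactly on a bound is retained.
#'
#' @return Named list of numeric length-2 bounds.
#' @export
default_exclusions <- function() {
  list(
    weight = c(36.28, NA),
    birth_weight = c(NA, 6.8),
    systolic_bp = c(NA, 200),
    diastolic_bp = c(NA, 120),
    height = c(120, NA),
    hip = c(50, 175),
    waist = c(40, 160),
    grip_strength = c(NA, 70),
    afs = c(12, NA)
  )
}

#' Apply trait-wise range exclusions to a phenotype table
#'
#' Values outside a trait's bounds are set to `NA` for that trait only
#' (trait-wise, not sample-wise, exclusion): the individual remains in the
#' table for all other traits.
#'
#' @param pheno data.frame of phenotypes.
#' @param rules named list of `c(lower, upper)` bounds, as from
#'   [default_exclusions()]; every name must be a column of `pheno`.
#' @return `pheno` with out-of-range values replaced by `NA`.
#' @export
apply_exclusions <- function(pheno, rules = default_exclusions()) {
  missing_cols <- setdiff(names(rules), names(pheno))
  if (length(missing_cols)) {
    abort_autozyg(
      paste("exclusion rules reference unknown column(s):", paste(missing_cols, collapse = ", ")),
      "autozyg_config_error"
    )
  }
  for (trait in names(rules)) {
    b <- rules[[trait]]
    x <- pheno[[trait]]
    bad <- (!is.na(b[1]) & x < b[1]) | (!is.na(b[2]) & x > b[2])
    x[which(bad)] <- NA
    pheno[[trait]] <- x
  }
  pheno
}

#' Standardize a quantitative trait within sex strata
#'
#' Each sex stratum is centred and scaled to unit variance (denominator
#' n - 1); missing values propagate. Inbreeding-depression betas on this
#' scale read as trait standard deviations per unit of the F statistic.
#'
#' @param values numeric vector.
#' @param sex stratum labels, same length as `values`.
#' @return Numeric vector of within-sex z-scores.
#' @export
standardize_within_sex <- function(values, sex) {
  stopifnot(length(values) == length(sex))
  out <- rep(NA_real_, length(values))
  for (s in unique(sex[!is.na(sex)])) {
    i <- which(!is.na(sex) & sex == s & !is.na(values))
    if (length(i) < 2L) {
      abort_autozyg(
        sprintf("stratum '%s' has fewer than 2 non-missing values", s),
        "autozyg_config_error"
      )
    }
    sd_s <- stats::sd(values[i])
    if (sd_s == 0) {
      abort_autozyg(sprintf("stratum '%s' has zero variance", s), "autozyg_config_error")
    }
    out[i] <- (values[i] - mean(values[i])) / sd_s
  }
  out
}

# build the model data.frame (complete cases) and formula for a burden fit
build_design <- function(data, trait, predictors, covariates) {
  vars <- c(trait, predictors, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort_autozyg(
      paste("column(s) not found in data:", paste(missing_cols, collapse = ", ")),
      "autozyg_config_error"
    )
  }
  d <- data[, vars, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  const <- vapply(
    covariates,
    function(v) length(unique(d[[v]])) < 2L, logical(1)
  )
  if (any(const)) {
    abort_autozyg(
      paste("constant covariate(s) after complete-case filtering:",
            paste(covariates[const], collapse = ", ")),
      "autozyg_config_error"
    )
  }
  rhs <- paste(c(predictors, covariates), collapse = " + ")
  list(data = d, formula = stats::as.formula(paste(trait, "~", rhs)))
}

#' Fit an ROH-burden regression
#'
#' The core trait model: `Y = b0 + b1 * F + gamma' C + e`, fitted by
#' ordinary least squares for quantitative traits and by maximum-likelihood
#' logistic regression (beta reported as a log odds ratio) for binary
#' traits. Rows with a missing value in any model variable are dropped
#' (complete-case per model); categorical covariates such as genotyping
#' batch are expanded to indicators by the usual factor contrasts. Several
#' focal predictors may be given (e.g. `c("f_roh", "f_snp")` for the joint
#' common/rare partition model, or long and short F_ROH together); a
#' coefficient row is reported for each.
#'
#' @param data data.frame holding trait, predictors and covariates.
#' @param trait response column name. Binary traits must be coded 0/1.
#' @param predictors character vector of focal predictor column names.
#' @param covariates character vector of adjustment covariate column names.
#' @param family `"gaussian"` (linear) or `"binomial"` (logistic).
#' @return An object of class `roh_burden` with components `coefficients`
#'   (data.frame: term, beta, se, p for each focal predictor), `n`, `fit`
#'   (the underlying `lm`/`glm`), `trait`, `predictors`, `covariates`,
#'   `family`.
#' @examples
#' d <- data.frame(y = rnorm(100), f_roh = runif(100, 0, 0.1),
#'                 age = rnorm(100))
#' fit <- fit_roh_burden(d, "y", "f_roh", "age")
#' coef(fit)
#' @export
fit_roh_burden <- function(data, trait, predictors, covariates = character(0),
                           family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  des <- build_design(data, trait, predictors, covariates)
  d <- des$data
  if (family == "binomial") {
    y <- d[[trait]]
    if (!all(y %in% c(0, 1))) {
      abort_autozyg("binary trait must be coded 0/1", "autozyg_config_error")
    }
    if (length(unique(y)) < 2L) {
      abort_autozyg("binary trait has a single class", "autozyg_config_error")
    }
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm(des$formula, data = d, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep_warn <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    saturated <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
    if (sep_warn || !fit$converged || saturated) {
      abort_autozyg(
        "logistic fit did not converge (possible perfect separation)",
        "autozyg_convergence_error"
      )
    }
  } else {
    fit <- stats::lm(des$formula, data = d)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    abort_autozyg(
      paste("rank-deficient design; collinear column(s):",
            paste(names(cf)[is.na(cf)], collapse = ", ")),
      "autozyg_rank_error"
    )
  }
  sm <- suppressWarnings(summary(fit))$coefficients # perfect toy fits warn harmlessly
  rows <- match(predictors, rownames(sm))
  if (anyNA(rows)) {
    abort_autozyg("focal predictor absent from fitted coefficients", "autozyg_rank_error")
  }
  structure(
    list(
      coefficients = data.frame(
        term = predictors,
        beta = sm[rows, 1], se = sm[rows, 2], p = sm[rows, 4],
        row.names = NULL
      ),
      n = nrow(d),
      fit = fit,
      trait = trait, predictors = predictors, covariates = covariates,
      family = family
    ),
    class = "roh_burden"
  )
}

#' Fit a linear ROH-burden model
#'
#' Thin wrapper over [fit_roh_burden()] with `family = "gaussian"`.
#' @inheritParams fit_roh_burden
#' @return A `roh_burden` object.
#' @export
fit_linear <- function(data, trait, predictors, covariates = character(0)) {
  fit_roh_burden(data, trait, predictors, covariates, family = "gaussian")
}

#' Fit a logistic ROH-burden model
#'
#' Thin wrapper over [fit_roh_burden()] with `family = "binomial"`; the
#' focal beta is a log odds ratio with a Wald p-value.
#' @inheritParams fit_roh_burden
#' @return A `roh_burden` object.
#' @export
fit_logistic <- function(data, trait, predictors, covariates = character(0)) {
  fit_roh_burden(data, trait, predictors, covariates, family = "binomial")
}

#' @export
print.roh_burden <- function(x, ...) {
  cat(sprintf(
    "<roh_burden> %s model of '%s' on %s (n = %d, %d covariates)\n",
    if (x$family == "binomial") "logistic" else "linear",
    x$trait, paste(x$predictors, collapse = " + "), x$n, length(x$covariates)
  ))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.roh_burden <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
summary.roh_burden <- function(object, ...) summary(object$fit, ...)

#' @export
confint.roh_burden <- function(object, parm, level = 0.95, ...) {
  if (missing(parm)) parm <- object$predictors
  if (object$family == "binomial") {
    # Wald intervals, matching the reported Wald p-values
    sm <- summary(object$fit)$coefficients
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- cbind(sm[parm, 1] - z * sm[parm, 2], sm[parm, 1] + z * sm[parm, 2])
    colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)), "%")
    ci
  } else {
    stats::confint(object$fit, parm = parm, level = level, ...)
  }
}

#' Bonferroni significance threshold
#'
#' `alpha = 0.05 / n_traits`, the per-test threshold when a family of
#' traits is tested against one F statistic (26 traits gives 0.002; the 19
#' non-sociodemographic traits of the joint common/rare models give 0.003).
#'
#' @param n_traits number of traits tested in the model set.
#' @param alpha family-wise error rate.
#' @return The per-test threshold.
#' @export
bonferroni_alpha <- function(n_traits, alpha = 0.05) {
  stopifnot(is_count(n_traits), n_traits >= 1)
  alpha / n_traits
}

#' Run the nested model sets for a family of traits
#'
#' Three nested covariate sets per trait: set 1 adjusts for the minimal
#' technical/demographic covariates (genotyping batch, per-sample
#' missingness, ancestry PCs, age, age squared, sex); set 2 adds the
#' sociodemographic covariates (which proxy parental background and absorb
#' confounding via assortative outbreeding); set 3 additionally enters
#' `f_snp` as a focal predictor alongside the main F statistic, so the
#' recessive signal is partitioned into common-variant (`f_snp`) and
#' rare-plus-common (`f_roh`) homozygosity. Traits that are themselves
#' sociodemographic are skipped in sets 2 and 3 (they appear on both sides
#' of the adjustment). Each set gets its own Bonferroni threshold,
#' `0.05 / (traits tested in that set)`.
#'
#' @param data data.frame with traits, F statistics and covariates.
#' @param traits character vector of trait column names.
#' @param predictor main inbreeding predictor (`"f_roh"`, `"f_roh_long"`,
#'   `"f_roh_short"`, or a vector for a joint model).
#' @param minimal_covariates covariate columns of the first model set.
#' @param sociodemographic_covariates covariate columns added in set 2.
#' @param trait_kinds named character vector (`"quantitative"` or
#'   `"binary"`) per trait; defaults to quantitative for all.
#' @param sociodemographic_traits traits skipped in sets 2 and 3.
#' @param sets which model sets to run (subset of 1:3).
#' @param fsnp_column column holding the excess-homozygosity statistic used
#'   in set 3.
#' @return data.frame of class `roh_burden_scan`: one row per trait x set x
#'   reported term with `n`, `beta`, `se`, `p`, `alpha` (the set's
#'   Bonferroni threshold) and `significant`.
#' @export
run_model_sets <- function(data, traits, predictor = "f_roh",
                           minimal_covariates,
                           sociodemographic_covariates = character(0),
                           trait_kinds = NULL,
                           sociodemographic_traits = character(0),
                           sets = 1:3, fsnp_column = "f_snp") {
  stopifnot(all(sets %in% 1:3))
  if (is.null(trait_kinds)) {
    trait_kinds <- stats::setNames(rep("quantitative", length(traits)), traits)
  }
  out <- list()
  for (set in sort(sets)) {
    set_traits <- if (set == 1) traits else setdiff(traits, sociodemographic_traits)
    alpha <- bonferroni_alpha(length(set_traits))
    covs <- switch(as.character(set),
      "1" = minimal_covariates,
      "2" = c(minimal_covariates, sociodemographic_covariates),
      "3" = c(minimal_covariates, sociodemographic_covariates)
    )
    preds <- if (set == 3) unique(c(predictor, fsnp_column)) else predictor
    for (trait in set_traits) {
      family <- if (identical(trait_kinds[[trait]], "binary")) "binomial" else "gaussian"
      fit <- tryCatch(
        fit_roh_burden(data, trait, preds, covs, family = family),
        autozyg_error = function(e) {
          abort_autozyg(
            sprintf("trait '%s', set %d: %s", trait, set, conditionMessage(e)),
            class(e)[1]
          )
        }
      )
      cf <- fit$coefficients
      out[[length(out) + 1L]] <- data.frame(
        trait = trait, set = set, predictor = cf$term, n = fit$n,
        beta = cf$beta, se = cf$se, p = cf$p,
        alpha = alpha, significant = cf$p < alpha
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("roh_burden_scan", "data.frame")
  res
}

#' Attenuation of a coefficient after adjustment
#'
#' Percent change in absolute effect size when covariates are added:
#' `100 * (|beta_main| - |beta_adjusted|) / |beta_main|`. Positive values
#' mean the adjusted effect is smaller; negative values mean it grew.
#'
#' @param beta_main coefficient from the unadjusted (smaller) model.
#' @param beta_adjusted coefficient after adding the adjustment covariates.
#' @return Percent attenuation (vectorized).
#' @examples
#' attenuation(4.355, 3.479) # ~20.1
#' @export
attenuation <- function(beta_main, beta_adjusted) {
  if (any(beta_main == 0)) {
    abort_autozyg("attenuation undefined for beta_main = 0", "autozyg_config_error")
  }
  100 * (abs(beta_main) - abs(beta_adjusted)) / abs(beta_main)
}

#' Test for a sex-specific inbreeding effect
#'
#' Adds a sex-by-predictor product term to the adjusted model and reports
#' the interaction coefficient with its Wald p-value.
#'
#' @param data data.frame.
#' @param trait response column.
#' @param predictor inbreeding predictor column.
#' @param covariates adjustment covariates; must include the sex column.
#' @param sex_column name of the sex column (numeric or two-level).
#' @param family model family as in [fit_roh_burden()].
#' @return A list with `beta`, `se`, `p` for the interaction term and the
#'   underlying fit.
#' @export
sex_interaction_test <- function(data, trait, predictor, covariates,
                                 sex_column = "sex",
                                 family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (!sex_column %in% names(data)) {
    abort_autozyg(paste("no column", sex_column), "autozyg_config_error")
  }
  sx <- data[[sex_column]]
  if (length(unique(sx[!is.na(sx)])) < 2L) {
    abort_autozyg("both sexes must be present", "autozyg_config_error")
  }
  d <- data
  if (!is.numeric(sx)) sx <- as.numeric(factor(sx)) - 1
  d[[".sex_x_f"]] <- sx * d[[predictor]]
  fit <- fit_roh_burden(
    d, trait, c(predictor, ".sex_x_f"),
    unique(c(covariates, sex_column)),
    family = family
  )
  i <- match(".sex_x_f", fit$coefficients$term)
  list(
    beta = fit$coefficients$beta[i],
    se = fit$coefficients$se[i],
    p = fit$coefficients$p[i],
    fit = fit
  )
}

#' Bootstrap test for an indirect (mediated) effect
#'
#' Coefficient-difference estimator of the indirect effect of the
#' predictor on the trait through a set of mediators: the total effect
#' (model without the mediators) minus the direct effect (model with
#' them), both on the same complete-case rows. The sampling distribution
#' comes from a nonparametric bootstrap over individuals; the effect is
#' called significant when the 95 percent percentile interval excludes
#' zero. A resample that leaves any model column constant is redrawn (and
#' counted), up to a cap.
#'
#' @param data data.frame.
#' @param trait response column.
#' @param predictor inbreeding predictor column.
#' @param mediators columns whose joint mediation is tested.
#' @param covariates adjustment covariates present in both models.
#' @param n_boot number of bootstrap resamples (at least 1000).
#' @param seed RNG seed.
#' @param level confidence level of the percentile interval.
#' @param max_redraw cap on degenerate-resample redraws.
#' @return List with `estimate` (point estimate from the original data,
#'   unaffected by the bootstrap), `ci`, `significant`, `boot` (the
#'   resampled differences), `n_redrawn`.
#' @export
indirect_effect_bootstrap <- function(data, trait, predictor, mediators,
                                      covariates = character(0),
                                      n_boot = 1000, seed = NULL,
                                      level = 0.95, max_redraw = 1000) {
  if (n_boot < 1000) {
    abort_autozyg("n_boot must be at least 1000", "autozyg_config_error")
  }
  vars <- c(trait, predictor, mediators, covariates)
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  diff_beta <- function(dd) {
    total <- fit_roh_burden(dd, trait, predictor, covariates)
    direct <- fit_roh_burden(dd, trait, predictor, c(covariates, mediators))
    total$coefficients$beta[1] - direct$coefficients$beta[1]
  }
  estimate <- diff_beta(d)
  seed_rng(seed)
  boot <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(nrow(d), replace = TRUE)
      dd <- d[idx, , drop = FALSE]
      degenerate <- any(vapply(dd, function(col) length(unique(col)) < 2L, logical(1)))
      if (!degenerate) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_redraw) {
        abort_autozyg("too many degenerate bootstrap resamples", "autozyg_convergence_error")
      }
    }
    boot[b] <- diff_beta(dd)
  }
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(a, 1 - a)))
  list(
    estimate = estimate, ci = ci,
    significant = ci[1] > 0 || ci[2] < 0,
    boot = boot, n_redrawn = n_redrawn
  )
}
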