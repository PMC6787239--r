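#' Fit a case-control logistic regression model
#'
#' Maximum-likelihood logistic regression (via `glm`, i.e. iteratively
#' reweighted least squares) of a binary outcome on a set of covariates,
#' with the reporting conventions used throughout the package: complete-case
#' analysis over the named covariates, reference levels HRT = never,
#' smoking = never, diabetes = no, odds ratios with Wald 95% CIs
#' (`exp(b +/- 1.96 se)`), and per-term p-values from likelihood-ratio tests
#' (chi-square difference of deviances, via `drop1`).
#'
#' @param data data.frame of subject records.
#' @param outcome name of the binary outcome column (factor or 0/1; for
#'   `status` columns the level `"case"` is the event).
#' @param covariates character vector of covariate column names.
#' @return An object of class `fit_result`: list with `table` (one row per
#'   coefficient: term, estimate, se, or, or_lo, or_hi, p_lrt), `fit` (the
#'   glm object), `log_likelihood` and `n_used`.
#' @export
fit_logistic <- function(data, outcome, covariates) {
  df <- data[, c(outcome, covariates), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n_used <- nrow(df)
  y <- df[[outcome]]
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    if (nlevels(y) != 2) stop("outcome must have exactly 2 classes")
    ref <- if ("control" %in% levels(y)) "control" else levels(y)[1]
    df[[outcome]] <- as.integer(y != ref)
  }
  if (length(unique(df[[outcome]])) < 2)
    stop("outcome must have exactly 2 classes")
  df <- set_reference_levels(df)
  n_par <- length(covariates) + 1
  if (n_used < 10 * n_par)
    warning(sprintf("only %d complete cases for %d parameters (< 10 per parameter)",
                    n_used, n_par))
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(covariates, collapse = " + ")))
  # glm's "fitted probabilities numerically 0 or 1" chatter is replaced by
  # the explicit separation diagnostic below
  fit <- suppressWarnings(stats::glm(fml, data = df,
                                     family = stats::binomial()))
  if (any(is.na(stats::coef(fit))))
    stop("singular design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  check_separation(fit)
  sm <- summary(fit)$coefficients
  est <- sm[, 1]; se <- sm[, 2]
  # per-term LRT p; map each coefficient to its model term
  dr <- stats::drop1(fit, test = "LRT")
  term_p <- stats::setNames(dr[["Pr(>Chi)"]][-1], rownames(dr)[-1])
  assign_idx <- attr(stats::model.matrix(fit), "assign")
  terms_lab <- attr(stats::terms(fit), "term.labels")
  coef_term <- c("(Intercept)", terms_lab)[assign_idx + 1]
  p_lrt <- ifelse(coef_term == "(Intercept)", NA_real_,
                  term_p[coef_term])
  tab <- data.frame(
    term = rownames(sm),
    estimate = est, se = se,
    or = exp(est),
    or_lo = exp(est - 1.96 * se),
    or_hi = exp(est + 1.96 * se),
    p_lrt = as.numeric(p_lrt),
    row.names = NULL
  )
  structure(list(table = tab, fit = fit,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n_used = n_used),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> n = %d, logLik = %.2f\n", x$n_used,
              x$log_likelihood))
  tab <- x$table
  tab$or <- sprintf("%.3f", tab$or)
  tab$ci <- sprintf("(%.3f, %.3f)", x$table$or_lo, x$table$or_hi)
  tab$p <- ifelse(is.na(x$table$p_lrt), "",
                  format(x$table$p_lrt, digits = 2))
  print(tab[, c("term", "or", "ci", "p")], row.names = FALSE)
  invisible(x)
}

set_reference_levels <- function(df) {
  refs <- c(hrt = "never", smoking = "never", diabetes = "no",
            breastfeeding = "never")
  for (nm in names(refs)) {
    if (nm %in% names(df) && (is.factor(df[[nm]]) || is.character(df[[nm]]))) {
      f <- factor(df[[nm]])
      if (refs[[nm]] %in% levels(f)) f <- stats::relevel(f, ref = refs[[nm]])
      df[[nm]] <- f
    }
  }
  df
}

# Perfect separation: the fitted model classifies every observation exactly
# (all fitted probabilities at the observed outcomes). Quasi-separation of a
# single sparse factor level (a +/-infinite coefficient with otherwise
# ordinary fitted values) is left to stand, as in routine practice -- it
# yields a huge CI for that level, not an invalid model.
check_separation <- function(fit) {
  p <- stats::fitted(fit)
  y <- fit$y
  if (max(abs(p - y)) < 1e-6) {
    worst <- names(which.max(abs(stats::coef(fit)[-1])))
    stop("perfect separation detected (covariate: ", worst, ")")
  }
  invisible(fit)
}

#' Rescale an odds ratio to a different covariate increment
#'
#' For a continuous covariate with per-unit odds ratio `or`, the odds ratio
#' for a difference of `delta` units is `exp(delta * log(or)) = or^delta`;
#' e.g. a per-percent PD odds ratio of 1.022 corresponds to an OR of about
#' 5.1 for a 75-point difference in percent density.
#'
#' @param or per-unit odds ratio.
#' @param delta covariate increment.
#' @export
or_scale <- function(or, delta) {
  exp(delta * log(or))
}

#' Combine parity, breastfeeding and age at first birth into 9 categories
#'
#' Because breastfeeding and age at first birth (AFB) are defined only for
#' parous women, the three variables are combined into one categorical
#' covariate with 9 levels: nulliparous women form their own level; parous
#' women are cross-classified by breastfeeding (never/ever) and AFB tertile
#' strata (< 23, 23-27, > 27 years), giving 6 levels; parous women with
#' known breastfeeding but missing AFB form 2 further levels (by
#' breastfeeding status). Parous women with missing breastfeeding (or women
#' with missing parity) cannot be classified and are flagged for exclusion
#' from models using this covariate.
#'
#' @param data data.frame with columns `parity`, `breastfeeding`
#'   (never/ever, NA allowed) and `age_first_birth_yr` (NA allowed).
#' @param afb_breaks two AFB cut points (default `c(23, 27)`; strata are
#'   `< breaks[1]`, `[breaks[1], breaks[2]]`, `> breaks[2]`).
#' @return list with `category` (factor of length `nrow(data)` with 9
#'   levels, NA where unclassifiable) and `exclude` (logical flag).
#' @export
build_reproductive_covariate <- function(data, afb_breaks = c(23, 27)) {
  parity <- data$parity
  bf <- as.character(data$breastfeeding)
  afb <- data$age_first_birth_yr
  levs <- c("nulliparous",
            paste0(rep(c("never_bf", "ever_bf"), each = 3), "_afb_",
                   rep(c("lo", "mid", "hi"), 2)),
            "never_bf_afb_missing", "ever_bf_afb_missing")
  out <- rep(NA_character_, nrow(data))
  known_par <- !is.na(parity)
  out[known_par & parity == 0] <- "nulliparous"
  parous <- known_par & parity > 0
  bf_known <- parous & !is.na(bf) & bf %in% c("never", "ever")
  stratum <- rep(NA_character_, nrow(data))
  has_afb <- !is.na(afb)
  stratum[has_afb & afb < afb_breaks[1]] <- "lo"
  stratum[has_afb & afb >= afb_breaks[1] & afb <= afb_breaks[2]] <- "mid"
  stratum[has_afb & afb > afb_breaks[2]] <- "hi"
  pref <- ifelse(bf == "ever", "ever_bf", "never_bf")
  out[bf_known & has_afb] <-
    paste0(pref[bf_known & has_afb], "_afb_", stratum[bf_known & has_afb])
  out[bf_known & !has_afb] <- paste0(pref[bf_known & !has_afb], "_afb_missing")
  list(category = factor(out, levels = levs),
       exclude = is.na(out))
}

#' Concordance statistic (AUC) with ties counted as 1/2
#'
#' @param scores numeric risk scores (higher = more case-like).
#' @param y binary outcome (0/1 or logical).
#' @return the c-statistic in `[0, 1]`.
#' @export
c_statistic <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes required")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimism-corrected ("honest") AUC by bootstrap
#'
#' Internal validation of a logistic model's discrimination following
#' Harrell's bootstrap: the apparent AUC is the c-statistic of the model
#' fitted and evaluated on the full data; for each bootstrap resample the
#' model is refitted, and the optimism is the AUC on the resample minus the
#' AUC of that refit evaluated on the original data. The honest AUC is the
#' apparent AUC minus the mean optimism. If a covariate separates the
#' outcome perfectly (apparent AUC 1), the degenerate answer
#' apparent = honest = 1 is returned without resampling.
#'
#' @param data data.frame of subject records.
#' @param outcome,covariates as in [fit_logistic()].
#' @param n_boot number of bootstrap resamples (>= 100; the reference
#'   analysis used 1000).
#' @param seed integer seed; results are bit-for-bit reproducible for a
#'   fixed seed and `n_boot`.
#' @return list with `apparent_auc`, `optimism`, `honest_auc`, `n_boot`.
#' @export
honest_auc <- function(data, outcome, covariates, n_boot = 1000, seed = 1) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  df <- data[, c(outcome, covariates), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  y <- df[[outcome]]
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    ref <- if ("control" %in% levels(y)) "control" else levels(y)[1]
    y <- as.integer(y != ref)
  }
  df[[outcome]] <- y
  df <- set_reference_levels(df)
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(covariates, collapse = " + ")))
  quiet_glm <- function(d) {
    suppressWarnings(stats::glm(fml, data = d, family = stats::binomial()))
  }
  full <- quiet_glm(df)
  apparent <- c_statistic(stats::predict(full, type = "link"), y)
  if (apparent >= 1 - 1e-12) {
    return(list(apparent_auc = 1, optimism = 0, honest_auc = 1,
                n_boot = 0L))
  }
  set.seed(seed)
  n <- nrow(df)
  optimism <- numeric(n_boot)
  done <- 0L; attempts <- 0L
  while (done < n_boot) {
    attempts <- attempts + 1L
    if (attempts > 5 * n_boot)
      stop("too many non-convergent bootstrap fits (cap 5 * n_boot)")
    idx <- sample.int(n, n, replace = TRUE)
    db <- df[idx, , drop = FALSE]
    if (length(unique(db[[outcome]])) < 2) next
    fb <- tryCatch(quiet_glm(db), error = function(e) NULL)
    if (is.null(fb) || !fb$converged) next
    auc_boot <- c_statistic(stats::predict(fb, type = "link"), db[[outcome]])
    auc_orig <- c_statistic(stats::predict(fb, newdata = df, type = "link"), y)
    done <- done + 1L
    optimism[done] <- auc_boot - auc_orig
  }
  opt <- mean(optimism)
  list(apparent_auc = apparent, optimism = opt,
       honest_auc = apparent - opt, n_boot = n_boot)
}

#' Age-adjusted risk-factor scan over controls
#'
#' For each risk factor, fits a logistic regression of the presence of
#' microcalcification clusters (binary: 0 vs 1+) on that factor plus age,
#' among cancer-free controls only, and reports the factor's odds ratio,
#' Wald 95% CI and likelihood-ratio p-value, plus a Bonferroni flag at the
#' stated family size (conservative, as the factors are correlated).
#'
#' @param controls data.frame of control records with an `mcc_total` column.
#' @param factors character vector of factor column names (use `"age_yr"` to
#'   test age itself, which is then the only covariate in its model).
#' @param family_size Bonferroni family size (default `length(factors)`).
#' @return data.frame with one row per fitted coefficient of each factor:
#'   `factor`, `term`, `or`, `or_lo`, `or_hi`, `p_lrt`, `n`,
#'   `bonferroni_significant`.
#' @export
riskfactor_scan <- function(controls, factors,
                            family_size = length(factors)) {
  if ("status" %in% names(controls) &&
      any(as.character(controls$status) != "control"))
    stop("riskfactor_scan expects controls only")
  if (all(controls$mcc_total == 0, na.rm = TRUE) ||
      all(controls$mcc_total >= 1, na.rm = TRUE))
    stop("cluster-presence outcome has a single class")
  controls$mcc_present <- as.integer(controls$mcc_total >= 1)
  rows <- list()
  for (f in factors) {
    vals <- controls[[f]][!is.na(controls[[f]])]
    if (length(unique(vals)) < 2) {
      warning("factor ", f, " is constant in controls; skipped")
      next
    }
    covs <- if (f == "age_yr") "age_yr" else c("age_yr", f)
    fit <- fit_logistic(controls, "mcc_present", covs)
    tab <- fit$table
    keep <- grepl(paste0("^", f), tab$term) & tab$term != "(Intercept)"
    if (f != "age_yr") keep <- keep & !grepl("^age_yr", tab$term)
    sel <- tab[keep, , drop = FALSE]
    if (nrow(sel) == 0) next
    rows[[f]] <- data.frame(
      factor = f, term = sel$term, or = sel$or,
      or_lo = sel$or_lo, or_hi = sel$or_hi, p_lrt = sel$p_lrt,
      n = fit$n_used,
      bonferroni_significant = sel$p_lrt < 0.05 / family_size,
      row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
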