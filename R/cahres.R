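#' Published key characteristics of the CAHRES short-term risk study
#'
#' Summary table of the case-control study the statistical workflow was
#' designed around: 253 incident invasive breast-cancer cases with a
#' negative mammogram 3-24 months before diagnosis and 728 controls, all
#' postmenopausal Swedish women aged 50-74. Counts and percentages are given
#' for categorical characteristics, means and standard deviations for
#' continuous ones; the starred reproductive variables (age at first birth,
#' breastfeeding, breastfeeding duration) refer to parous women only, with
#' complete-case denominators. These published marginals are the calibration
#' targets of [cohort_spec()].
#'
#' @return data.frame with columns `characteristic`, `level`,
#'   `cases_count`, `cases_pct`, `controls_count`, `controls_pct`,
#'   `cases_mean`, `cases_sd`, `controls_mean`, `controls_sd`, `p_value`.
#' @export
cahres_table1 <- function() {
  utils::read.csv(system.file("extdata", "cahres_table1.csv",
                              package = "mammocalc"),
                  stringsAsFactors = FALSE)
}

#' Expand published categorical counts into subject-level records
#'
#' Utility for refitting unadjusted models from published contingency
#' counts: turns a named vector of per-level counts for cases and controls
#' into a long data.frame with one row per woman.
#'
#' @param levels character vector of category levels.
#' @param cases,controls integer counts per level.
#' @param varname name for the covariate column.
#' @return data.frame with columns `status` (control/case) and `varname`.
#' @export
expand_counts <- function(levels, cases, controls, varname = "x") {
  df <- data.frame(
    status = factor(rep(c("case", "control"),
                        c(sum(cases), sum(controls))),
                    levels = c("control", "case")),
    x = factor(c(rep(levels, cases), rep(levels, controls)),
               levels = levels)
  )
  names(df)[2] <- varname
  df
}
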