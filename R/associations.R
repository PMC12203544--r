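# Statistical layer: annualized changes, standardized cross-sectional
# regressions, random-intercept mixed models with time and baseline-by-time
# terms, deterministic p-value stepwise selection, and Benjamini-Hochberg
# correction. Standardization follows the reporting convention of adjusted
# standardized coefficients: continuous variables are z-scored, categorical
# covariates are dummy-coded unstandardized, and follow-up time stays in
# years.

#' Analysis configuration
#'
#' @param covariates Adjustment covariates used by every model: age, gender,
#'   disease duration at assessment, and treatment class.
#' @param fdr_q Significance threshold on Benjamini-Hochberg adjusted
#'   p-values.
#' @param enter_p,remove_p Stepwise entry/removal p-value thresholds
#'   (`enter_p < remove_p`).
#' @param ventricle_adjust If `TRUE`, models additionally adjust for
#'   normalized lateral ventricle volume.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(covariates = c("age", "gender",
                                           "duration_years", "dmt"),
                            fdr_q = 0.05, enter_p = 0.05, remove_p = 0.10,
                            ventricle_adjust = FALSE) {
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must be in (0, 1)")
  if (enter_p >= remove_p) stop("enter_p must be < remove_p")
  structure(list(covariates = covariates, fdr_q = fdr_q,
                 enter_p = enter_p, remove_p = remove_p,
                 ventricle_adjust = isTRUE(ventricle_adjust)),
            class = "analysis_config")
}

#' Mean annualized change across a subject's follow-up intervals
#'
#' For each consecutive visit interval the change per year is computed; the
#' result is the mean across intervals. A subject with a single visit has no
#' interval and yields `NA`.
#'
#' @param times Visit times in years, strictly increasing.
#' @param values Outcome values at those visits, finite.
#' @return Change per year, or `NA_real_` for a single visit.
#' @examples
#' annualized_change(c(0, 0.5), c(10, 12))        # 4 per year
#' annualized_change(c(0, 1, 1.5), c(10, 11, 12.5))  # mean(1, 3) = 2
#' @export
annualized_change <- function(times, values) {
  if (length(times) != length(values)) stop("times and values differ in length")
  if (any(!is.finite(values)) || any(!is.finite(times)))
    stop("times and values must be finite")
  if (length(times) < 2) return(NA_real_)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  mean(diff(values) / diff(times))
}

#' z-score a numeric vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1.
#'
#' @param values Numeric vector, length >= 2, nonzero spread.
#' @return Standardized vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to z-score")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero spread: cannot z-score")
  (values - mean(values)) / s
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: with `p_(1) <= ... <= p_(m)`, the adjusted
#' value at rank i is `min_{j >= i} (p_(j) * m / j)`, capped at 1, returned
#' in the original order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, `p_fdr >= p` elementwise.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# --- internal model plumbing -------------------------------------------------

# z-score the continuous columns of a model table in place. The reference
# location/scale is taken from the baseline rows (one per subject) when the
# table is longitudinal, so the standardized unit is the cohort's baseline
# distribution and subjects with more visits do not get extra weight.
standardize_columns <- function(tab, cols) {
  ref <- if ("time_years" %in% names(tab)) tab$time_years == 0 else
    rep(TRUE, nrow(tab))
  for (cl in intersect(cols, names(tab))) {
    if (!is.numeric(tab[[cl]])) next
    mu <- mean(tab[[cl]][ref])
    s <- stats::sd(tab[[cl]][ref])
    if (!is.finite(s) || s == 0) stop("zero spread: cannot z-score ", cl)
    tab[[cl]] <- (tab[[cl]] - mu) / s
  }
  tab
}

model_result_row <- function(term, est, se, p, adj_r2 = NA_real_) {
  data.frame(term = term, beta_std = est, se = se,
             ci_lo = est - stats::qnorm(0.975) * se,
             ci_hi = est + stats::qnorm(0.975) * se,
             p = p, p_fdr = NA_real_, adj_r2 = adj_r2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Adjusted standardized cross-sectional regression
#'
#' Ordinary least squares of the z-scored outcome on the z-scored predictor
#' plus covariates (continuous covariates z-scored, categoricals
#' dummy-coded), on baseline rows.
#'
#' @param outcome,predictor Column names in `table`.
#' @param table A `cohort_table` (or compatible data frame). Only baseline
#'   rows (`time_years == 0`) are used when a `time_years` column exists.
#' @param config An [analysis_config()].
#' @return One-row data frame (`term`, `beta_std`, `se`, `ci_lo`, `ci_hi`,
#'   `p`, `p_fdr`, `adj_r2`) for the predictor.
#' @export
fit_cross_sectional <- function(outcome, predictor, table,
                                config = analysis_config()) {
  tab <- as.data.frame(table)
  if ("time_years" %in% names(tab)) tab <- tab[tab$time_years == 0, ]
  covs <- config$covariates
  if (config$ventricle_adjust) covs <- union(covs, "nlvv")
  use <- stats::complete.cases(tab[, c(outcome, predictor, covs)])
  tab <- tab[use, ]
  npar <- length(covs) + 2
  if (nrow(tab) < 10 + npar)
    stop("too few complete cases for cross-sectional fit")
  tab <- standardize_columns(tab, c(outcome, predictor, covs))
  f <- stats::reformulate(c(predictor, covs), response = outcome)
  fit <- stats::lm(f, data = tab)
  cf <- summary(fit)$coefficients
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  model_result_row(predictor, cf[predictor, 1], cf[predictor, 2],
                   cf[predictor, 4], adj_r2 = summary(fit)$adj.r.squared)
}

#' Random-intercept mixed model for longitudinal change
#'
#' Linear mixed model with a random intercept per subject, fitted by
#' maximum likelihood, with Wald confidence intervals. The fixed part is
#' follow-up time (years), the adjustment covariates, and optionally a
#' baseline measure with its baseline-by-time interaction (main effects are
#' always included with the interaction). Continuous variables, including
#' the baseline measure, are z-scored; time stays in years so time
#' coefficients read as standardized change per year.
#'
#' @param outcome Column name of the longitudinal outcome.
#' @param table A `cohort_table` with repeated visits.
#' @param interaction_with Optional column name of a baseline measure whose
#'   baseline value interacts with time.
#' @param config An [analysis_config()].
#' @return Data frame of model-result rows for all fixed terms except the
#'   intercept, with attribute `singular` flagging a degenerate
#'   random-effect variance (the fit is retained).
#' @export
fit_longitudinal <- function(outcome, table, interaction_with = NULL,
                             config = analysis_config()) {
  tab <- as.data.frame(table)
  nvis <- table(tab$subject_id)
  if (sum(nvis >= 2) < 20)
    stop("need at least 20 subjects with repeated visits")
  covs <- config$covariates
  # in a model that already contains follow-up time, duration at assessment
  # would be collinear with it within subject; the longitudinal models
  # adjust for baseline disease duration instead
  if ("duration_years" %in% covs && "duration_baseline" %in% names(tab))
    covs[covs == "duration_years"] <- "duration_baseline"
  if (config$ventricle_adjust) covs <- union(covs, "nlvv")
  fixed <- c("time_years", covs)
  if (!is.null(interaction_with)) {
    bl <- tab[tab$time_years == 0, c("subject_id", interaction_with)]
    names(bl)[2] <- ".baseline"
    tab <- merge(tab, bl, by = "subject_id", sort = FALSE)
    fixed <- c(fixed, ".baseline", "time_years:.baseline")
  }
  cont <- c(outcome, covs, if (!is.null(interaction_with)) ".baseline")
  tab <- standardize_columns(tab, cont)
  f <- stats::as.formula(paste(outcome, "~",
                               paste(fixed, collapse = " + "),
                               "+ (1 | subject_id)"))
  fit <- lme4::lmer(f, data = tab, REML = FALSE)
  singular <- lme4::isSingular(fit)
  if (singular)
    message("random-intercept variance is singular; fit retained")
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  keep <- setdiff(names(cf), "(Intercept)")
  z <- cf[keep] / se[keep]
  out <- do.call(rbind, lapply(keep, function(tm)
    model_result_row(sub("\\.baseline", paste0("baseline_", interaction_with), tm),
                     cf[tm], se[tm], 2 * stats::pnorm(-abs(z[tm])))))
  attr(out, "singular") <- singular
  out
}

#' Deterministic bidirectional stepwise selection
#'
#' p-value based stepwise regression on baseline rows: candidates enter when
#' their partial p-value is below `enter_p` and leave when it rises above
#' `remove_p`; the adjustment covariates are always retained. Candidates are
#' scanned in ascending order of their current p-value, making the procedure
#' deterministic.
#'
#' @param outcome Column name of the outcome.
#' @param candidates Character vector of candidate predictor columns.
#' @param table A `cohort_table` or data frame.
#' @param config An [analysis_config()].
#' @return Data frame of model-result rows for the selected candidates (zero
#'   rows if none survive), with attribute `selected` (character vector) and
#'   `adj_r2` of the final model.
#' @export
stepwise_select <- function(outcome, candidates, table,
                            config = analysis_config()) {
  tab <- as.data.frame(table)
  if ("time_years" %in% names(tab)) tab <- tab[tab$time_years == 0, ]
  covs <- config$covariates
  if (config$ventricle_adjust) covs <- union(covs, "nlvv")
  tab <- tab[stats::complete.cases(tab[, c(outcome, candidates, covs)]), ]
  tab <- standardize_columns(tab, c(outcome, candidates, covs))

  p_of <- function(included, term) {
    f <- stats::reformulate(c(covs, included, term), response = outcome)
    cf <- summary(stats::lm(f, data = tab))$coefficients
    if (!term %in% rownames(cf)) return(1)
    cf[term, 4]
  }
  included <- character(0)
  repeat {
    changed <- FALSE
    # forward: best excluded candidate, scanned by ascending p
    out_c <- setdiff(candidates, included)
    if (length(out_c)) {
      ps <- vapply(out_c, function(tm) p_of(included, tm), numeric(1))
      ordc <- out_c[order(ps)]
      if (ps[order(ps)][1] < config$enter_p) {
        included <- c(included, ordc[1])
        changed <- TRUE
      }
    }
    # backward: remove the worst included candidate above remove_p
    if (length(included)) {
      f <- stats::reformulate(c(covs, included), response = outcome)
      cf <- summary(stats::lm(f, data = tab))$coefficients
      pin <- vapply(included, function(tm)
        if (tm %in% rownames(cf)) cf[tm, 4] else 1, numeric(1))
      worst <- which.max(pin)
      if (pin[worst] > config$remove_p) {
        included <- included[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  f <- stats::reformulate(c(covs, if (length(included)) included else NULL),
                          response = outcome)
  fit <- stats::lm(f, data = tab)
  cf <- summary(fit)$coefficients
  rows <- lapply(included, function(tm)
    model_result_row(tm, cf[tm, 1], cf[tm, 2], cf[tm, 4],
                     adj_r2 = summary(fit)$adj.r.squared))
  out <- if (length(rows)) do.call(rbind, rows) else
    model_result_row("", NA_real_, NA_real_, NA_real_)[0, ]
  attr(out, "selected") <- included
  attr(out, "adj_r2") <- summary(fit)$adj.r.squared
  out
}

#' Run the full association analysis on a cohort
#'
#' Reproduces the structure of the study's result tables: cross-sectional
#' associations of the two choroid-plexus measures with the other MRI
#' measures, stepwise models of clinical/neuropsychological outcomes on MRI
#' candidates, longitudinal time effects, and baseline-by-time interaction
#' models. Benjamini-Hochberg adjustment is applied within each family
#' (one family per table); stepwise results are exempt, as selection makes
#' their p-values non-independent.
#'
#' @param table A `cohort_table`.
#' @param config An [analysis_config()].
#' @return Named list of result data frames: `cross_sectional`, `stepwise`,
#'   `longitudinal_time`, `interactions`.
#' @export
association_tables <- function(table, config = analysis_config()) {
  mri <- c("nbv", "ncgmv", "ndgmv", "nwmv", "lesion")
  clin <- c("edss", "sdmt", "bvmt", "cvlt")

  cs <- do.call(rbind, lapply(mri, function(oc) {
    do.call(rbind, lapply(c("nchpv", "t1t2"), function(pr) {
      r <- fit_cross_sectional(oc, pr, table, config)
      r$outcome <- oc
      r
    }))
  }))
  cs$p_fdr <- bh_fdr(cs$p)

  sw <- do.call(rbind, lapply(clin, function(oc) {
    r <- stepwise_select(oc, c("nchpv", "t1t2", mri), table, config)
    r$outcome <- if (nrow(r)) oc else character(0)
    r
  }))

  lt <- do.call(rbind, lapply(c("nchpv", "t1t2", mri, clin), function(oc) {
    r <- fit_longitudinal(oc, table, config = config)
    r <- r[r$term == "time_years", , drop = FALSE]
    r$outcome <- oc
    r
  }))
  lt$p_fdr <- bh_fdr(lt$p)

  ia <- do.call(rbind, lapply(c(mri, clin), function(oc) {
    do.call(rbind, lapply(c("nchpv", "t1t2"), function(bl) {
      r <- fit_longitudinal(oc, table, interaction_with = bl,
                            config = config)
      r <- r[grepl(":", r$term), , drop = FALSE]
      r$outcome <- oc
      r
    }))
  }))
  ia$p_fdr <- bh_fdr(ia$p)

  list(cross_sectional = cs, stepwise = sw, longitudinal_time = lt,
       interactions = ia)
}
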