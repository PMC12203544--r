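# Synthetic longitudinal cohort with the study's visit structure (baseline,
# ~6-month and ~18-month follow-ups with dropout), published marginal
# distributions, latent non-linear long-term curves over disease duration,
# and configurable standardized effect sizes. All effects are defined on a
# latent z-scale with a unit-variance construction, so standardized
# coefficients recovered downstream have well-posed generating targets.

#' Long-term latent curve parameters
#'
#' Shapes of the latent disease-duration trajectories, in z-units. The
#' choroid-plexus volume curve rises as a saturating exponential to a
#' plateau, then declines subtly; the T1/T2 ratio follows a parabola with a
#' nadir; ventricle volume grows linearly.
#'
#' @param chp_plateau_years Duration (years) at which the volume curve
#'   plateaus (default 12).
#' @param chp_late_decline Linear decline in z-units/year beyond the plateau
#'   (default 0.005).
#' @param ratio_nadir_years Duration (years) of the T1/T2 minimum
#'   (default 10).
#' @param ventricle_slope Linear ventricular growth in z-units/year.
#' @param amplitudes Named z-unit amplitudes `chp_volume` and `t1t2_ratio`.
#' @return List of class `curve_params`.
#' @export
curve_params <- function(chp_plateau_years = 12, chp_late_decline = 0.005,
                         ratio_nadir_years = 10, ventricle_slope = 0.03,
                         amplitudes = c(chp_volume = 1.5, t1t2_ratio = 0.1)) {
  if (chp_plateau_years <= 0 || ratio_nadir_years <= 0)
    stop("plateau and nadir must be > 0")
  if (any(amplitudes <= 0)) stop("amplitudes must be > 0")
  if (ventricle_slope <= 0) stop("ventricle_slope must be > 0")
  structure(list(chp_plateau_years = chp_plateau_years,
                 chp_late_decline = chp_late_decline,
                 ratio_nadir_years = ratio_nadir_years,
                 ventricle_slope = ventricle_slope,
                 amplitudes = amplitudes),
            class = "curve_params")
}

#' Standardized generating effect sizes
#'
#' Cross-sectional effects are partial standardized coefficients in the
#' generating linear equations; longitudinal effects are z-units per year of
#' follow-up time; interactions couple a baseline measure (z-scored) with
#' follow-up time.
#'
#' @param cross_sectional Data frame with columns `predictor`, `outcome`,
#'   `beta`.
#' @param longitudinal_time Named numeric vector of time slopes (z/year).
#' @param interactions Data frame with columns `baseline`, `outcome`, `beta`
#'   (z/year per baseline z).
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(
    cross_sectional = data.frame(
      predictor = "nchpv",
      outcome = c("lesion", "nbv", "ndgmv", "edss", "bvmt"),
      beta = c(0.35, -0.30, -0.29, 0.13, -0.16)),
    longitudinal_time = c(nchpv = 0.45, t1t2 = 0.29, nbv = -0.05,
                          cvlt = 0.13),
    interactions = data.frame(
      baseline = "t1t2",
      outcome = c("nbv", "ndgmv", "bvmt"),
      beta = c(-0.21, -0.25, -0.23))) {
  if (any(abs(cross_sectional$beta) >= 1) ||
      any(abs(interactions$beta) >= 1))
    stop("standardized effect sizes must have |beta| < 1")
  structure(list(cross_sectional = cross_sectional,
                 longitudinal_time = longitudinal_time,
                 interactions = interactions),
            class = "effect_spec")
}

#' Evaluate a latent long-term curve at given disease durations
#'
#' @param kind One of `"chp_volume"`, `"t1t2_ratio"`, `"ventricle"`.
#' @param d Disease duration(s) in years, non-negative.
#' @param params A [curve_params()] object.
#' @return Curve value(s) in z-units. The volume curve is
#'   `A (1 - exp(-3 d / plateau)) - decline * max(0, d - plateau)`; the
#'   ratio curve is `a ((d - nadir)^2 / nadir^2) - a`, minimized exactly at
#'   the nadir; the ventricle curve is `slope * d`.
#' @export
true_curve <- function(kind = c("chp_volume", "t1t2_ratio", "ventricle"),
                       d, params = curve_params()) {
  kind <- match.arg(kind)
  if (any(d < 0)) stop("disease duration must be non-negative")
  switch(kind,
    chp_volume = {
      A <- params$amplitudes[["chp_volume"]]
      A * (1 - exp(-3 * d / params$chp_plateau_years)) -
        params$chp_late_decline * pmax(0, d - params$chp_plateau_years)
    },
    t1t2_ratio = {
      a <- params$amplitudes[["t1t2_ratio"]]
      nd <- params$ratio_nadir_years
      a * ((d - nd)^2 / nd^2) - a
    },
    ventricle = params$ventricle_slope * d)
}

#' Specification of a synthetic longitudinal cohort
#'
#' Defaults reproduce the published study conditions: 422 subjects, 65% with
#' a first follow-up at a median of 7.2 months, 80/276 of those with a
#' second follow-up at a median of 19.2 months, and the published marginal
#' location/scale for each variable. Disease duration is Gamma-distributed
#' (mean 9.5, SD 17.4 years, capped at 70) because the published SD exceeds
#' the mean, forcing heavy right skew on a non-negative support.
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param p_fu1 Probability of at least one follow-up.
#' @param p_fu2_given_fu1 Probability of a second follow-up given a first.
#' @param fu1_months,fu2_months Median follow-up times in months.
#' @param fu1_iqr_months,fu2_iqr_months IQRs of the follow-up times, used to
#'   set the log-normal jitter scale.
#' @param marginals Named list of `c(location, scale)` per variable, in
#'   natural units (volumes on the x1000 normalized scale).
#' @param gender_probs Probabilities for male/female/non-binary.
#' @param dmt_prob_high Probability of the high-efficacy treatment class.
#' @param duration_mean,duration_sd,duration_cap Disease-duration Gamma
#'   moments (years) and tail cap.
#' @param age_mean,age_sd Baseline age distribution (years).
#' @param curve A [curve_params()] object.
#' @param effects An [effect_spec()] object.
#' @param icc Fraction of each variable's residual (non-structural) variance
#'   assigned to the subject random intercept.
#' @param noise_sd_within Within-subject noise SD: `NULL` to derive it from
#'   the unit-variance construction, or a scalar / named vector override.
#' @param random_intercept_sd `NULL` to derive from `icc`, or an override
#'   (0 disables random intercepts).
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 422L,
                        p_fu1 = 0.65,
                        p_fu2_given_fu1 = 80 / 276,
                        fu1_months = 7.2, fu1_iqr_months = c(6.0, 9.6),
                        fu2_months = 19.2, fu2_iqr_months = c(18.0, 22.8),
                        marginals = list(
                          nchpv = c(1.6, 0.6), t1t2 = c(0.5, 0.1),
                          nlvv = c(12, 6), lesion = c(11.9, 14.1),
                          nbv = c(774.7, 24.3), ncgmv = c(416.9, 12.5),
                          ndgmv = c(27.5, 3.0), nwmv = c(315.7, 16.2),
                          sdmt = c(50.6, 14.7), bvmt = c(25.0, 7.6),
                          cvlt = c(53.1, 12.0)),
                        gender_probs = c(male = 150, female = 270,
                                         nonbinary = 2) / 422,
                        dmt_prob_high = 257 / 422,
                        duration_mean = 9.5, duration_sd = 17.4,
                        duration_cap = 70,
                        age_mean = 40.8, age_sd = 10.9,
                        curve = curve_params(),
                        effects = effect_spec(),
                        icc = 0.85,
                        noise_sd_within = NULL,
                        random_intercept_sd = NULL,
                        seed = 1L) {
  if (n_subjects < 10) stop("n_subjects must be >= 10")
  if (p_fu1 < 0 || p_fu1 > 1 || p_fu2_given_fu1 < 0 || p_fu2_given_fu1 > 1)
    stop("follow-up probabilities must be in [0, 1]")
  if (any(vapply(marginals, function(m) m[2] <= 0, logical(1))))
    stop("all marginal scales must be > 0")
  if (icc < 0 || icc > 1) stop("icc must be in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects), p_fu1 = p_fu1,
                 p_fu2_given_fu1 = p_fu2_given_fu1,
                 fu1_months = fu1_months, fu1_iqr_months = fu1_iqr_months,
                 fu2_months = fu2_months, fu2_iqr_months = fu2_iqr_months,
                 marginals = marginals, gender_probs = gender_probs,
                 dmt_prob_high = dmt_prob_high,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 duration_cap = duration_cap,
                 age_mean = age_mean, age_sd = age_sd,
                 curve = curve, effects = effects, icc = icc,
                 noise_sd_within = noise_sd_within,
                 random_intercept_sd = random_intercept_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# log-normal jitter sd matched to a median/IQR pair
lognorm_sdlog <- function(iqr) log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))

# EDSS: monotone map from a latent standard-normal score to the 0-10
# half-point scale, calibrated so the median is 2.0 and the IQR 1.5-3.5.
edss_from_z <- function(z) {
  p_knots <- c(0, 0.10, 0.25, 0.50, 0.75, 0.90, 0.995, 1)
  e_knots <- c(0, 1.0, 1.5, 2.0, 3.5, 5.0, 8.0, 9.5)
  p <- stats::pnorm(z)
  e <- stats::approx(p_knots, e_knots, xout = p, rule = 2)$y
  pmin(pmax(round(e * 2) / 2, 0), 10)
}

#' Sample a synthetic longitudinal cohort
#'
#' Generates subjects, visits and outcomes per the specification. Outcomes
#' are built on a latent z-scale as structural value (long-term curve over
#' disease duration, time slopes, cross-sectional and baseline-by-time
#' effects) plus a subject random intercept and within-subject noise, with
#' the residual variance chosen so each variable's baseline z has unit
#' variance; they are then mapped to natural units by the marginal
#' location/scale (EDSS through its calibrated ordinal transform).
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` of class `cohort_table`, one row per
#'   subject-visit, with a `ground_truth` attribute carrying the generating
#'   parameters, the latent z-values, random intercepts and residual
#'   variances.
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  eff <- spec$effects
  vars <- c("nchpv", "t1t2", "nlvv", "lesion", "nbv", "ncgmv", "ndgmv",
            "nwmv", "edss", "sdmt", "bvmt", "cvlt")
  bad <- setdiff(c(eff$cross_sectional$predictor, eff$cross_sectional$outcome,
                   names(eff$longitudinal_time), eff$interactions$baseline,
                   eff$interactions$outcome), vars)
  if (length(bad)) stop("unknown variables in effect_spec: ",
                        paste(bad, collapse = ", "))

  with_seed(spec$seed, {
    n <- spec$n_subjects
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    gender <- factor(sample(names(spec$gender_probs), n, replace = TRUE,
                            prob = spec$gender_probs),
                     levels = names(spec$gender_probs))
    dmt <- factor(ifelse(stats::runif(n) < spec$dmt_prob_high,
                         "high", "moderate_low"),
                  levels = c("moderate_low", "high"))
    shape <- (spec$duration_mean / spec$duration_sd)^2
    rate <- shape / spec$duration_mean
    d0 <- pmin(stats::rgamma(n, shape, rate), spec$duration_cap)

    fu1 <- stats::runif(n) < spec$p_fu1
    fu2 <- fu1 & (stats::runif(n) < spec$p_fu2_given_fu1)
    t1 <- stats::rlnorm(n, log(spec$fu1_months / 12),
                        lognorm_sdlog(spec$fu1_iqr_months))
    t2 <- stats::rlnorm(n, log(spec$fu2_months / 12),
                        lognorm_sdlog(spec$fu2_iqr_months))

    sid <- c(seq_len(n), which(fu1), which(fu2))
    tim <- c(rep(0, n), t1[fu1], t2[fu2])
    vis <- c(rep(0L, n), rep(1L, sum(fu1)), rep(2L, sum(fu2)))
    ord <- order(sid, tim)
    sid <- sid[ord]; tim <- tim[ord]; vis <- vis[ord]
    m <- length(sid)
    dur <- d0[sid] + tim
    is_base <- vis == 0L

    curve_of <- c(nchpv = "chp_volume", t1t2 = "t1t2_ratio",
                  nlvv = "ventricle")
    z <- matrix(NA_real_, m, length(vars), dimnames = list(NULL, vars))
    u_draws <- matrix(NA_real_, n, length(vars),
                      dimnames = list(NULL, vars))
    resid_vars <- stats::setNames(numeric(length(vars)), vars)
    e_override <- spec$noise_sd_within

    for (v in vars) {
      struct <- numeric(m)
      # The long-term curve anchors each subject's level at baseline
      # duration; short-term within-subject change is carried by the
      # calibrated time slopes, so published short-term and long-term
      # dynamics are not double-counted.
      if (v %in% names(curve_of))
        struct <- struct + true_curve(curve_of[[v]], d0[sid], spec$curve)
      bt <- eff$longitudinal_time
      if (v %in% names(bt)) struct <- struct + bt[[v]] * tim
      cs <- eff$cross_sectional[eff$cross_sectional$outcome == v, ,
                                drop = FALSE]
      for (r in seq_len(nrow(cs)))
        struct <- struct + cs$beta[r] * z[, cs$predictor[r]]
      ia <- eff$interactions[eff$interactions$outcome == v, , drop = FALSE]
      for (r in seq_len(nrow(ia))) {
        zb <- z[is_base, ia$baseline[r]][sid]   # baseline value per subject
        struct <- struct + ia$beta[r] * zb * tim
      }
      if (anyNA(struct))
        stop("effect specification for '", v, "' references a variable ",
             "that is generated after it; only nchpv, t1t2 and nlvv can ",
             "serve as predictors")
      # centre on the baseline cohort so natural-unit means match the
      # configured marginal locations
      struct <- struct - mean(struct[is_base])
      rv <- 1 - stats::var(struct[is_base])
      if (rv <= 0)
        stop("infeasible effect specification: structural variance of '",
             v, "' is >= 1 (no room for residual variance)")
      resid_vars[v] <- rv
      u_sd <- if (!is.null(spec$random_intercept_sd))
        spec$random_intercept_sd else sqrt(spec$icc * rv)
      e_sd <- if (!is.null(e_override)) {
        if (length(e_override) > 1) e_override[[v]] else e_override
      } else sqrt((1 - spec$icc) * rv)
      u <- stats::rnorm(n, 0, u_sd)
      e <- stats::rnorm(m, 0, e_sd)
      if (is.null(spec$random_intercept_sd) && is.null(e_override)) {
        # empirical standardization: rescale the realized noise so the
        # baseline sample variance of z hits 1 exactly up to the small
        # struct-noise covariance, keeping the unit-variance construction
        # tight at finite n
        vb <- stats::var(u[sid[is_base]] + e[is_base])
        if (is.finite(vb) && vb > 0) {
          scl <- sqrt(rv / vb)
          u <- u * scl
          e <- e * scl
        }
      }
      u_draws[, v] <- u
      z[, v] <- struct + u[sid] + e
    }

    nat <- as.data.frame(z)
    for (v in setdiff(vars, "edss")) {
      ms <- spec$marginals[[v]]
      nat[[v]] <- ms[1] + ms[2] * z[, v]
    }
    nat$edss <- edss_from_z(z[, "edss"])

    tab <- data.frame(subject_id = sid, visit = vis,
                      time_years = tim,
                      age = age[sid], gender = gender[sid], dmt = dmt[sid],
                      duration_baseline = d0[sid], duration_years = dur,
                      nat, row.names = NULL)
    attr(tab, "ground_truth") <- list(
      curve = spec$curve, effects = eff, icc = spec$icc,
      resid_vars = resid_vars, random_intercepts = u_draws,
      latent_z = z, seed = spec$seed)
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}

#' Export a cohort to CSV with a ground-truth JSON companion
#'
#' Writes the subject-visit table in tidy long format (missing follow-ups
#' are absent rows) and a `<path-without-ext>_truth.json` companion holding
#' the generating curve parameters, effect sizes, residual variances and
#' random-intercept draws.
#'
#' @param table A `cohort_table` from [sample_cohort()].
#' @param path CSV output path.
#' @return Invisibly, `c(csv = path, truth = json_path)`.
#' @export
export_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  ok <- try(utils::write.csv(table, path, row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write cohort CSV: ", path)
  gt <- attr(table, "ground_truth")
  jp <- paste0(sub("\\.csv$", "", path), "_truth.json")
  out <- list(
    curve = unclass(gt$curve),
    effects = list(
      cross_sectional = gt$effects$cross_sectional,
      longitudinal_time = as.list(gt$effects$longitudinal_time),
      interactions = gt$effects$interactions),
    icc = gt$icc,
    resid_vars = as.list(gt$resid_vars),
    random_intercepts = gt$random_intercepts,
    seed = gt$seed)
  jsonlite::write_json(out, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv = path, truth = jp))
}

#' Read a cohort CSV written by [export_cohort()]
#'
#' @param path CSV path.
#' @return A `cohort_table` data frame (without the ground-truth attribute).
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$gender <- factor(tab$gender,
                       levels = c("male", "female", "nonbinary"))
  tab$dmt <- factor(tab$dmt, levels = c("moderate_low", "high"))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
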