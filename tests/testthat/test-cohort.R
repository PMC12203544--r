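test_that("latent curves follow their closed forms", {
  cp <- curve_params()
  expect_equal(true_curve("chp_volume", 0, cp), 0)
  # parabola vertex sits exactly at the nadir
  d <- seq(0, 40, by = 0.01)
  v <- true_curve("t1t2_ratio", d, cp)
  expect_equal(d[which.min(v)], cp$ratio_nadir_years)
  # derivative beyond the plateau is negative when a late decline is set
  dpl <- 2 * cp$chp_plateau_years
  eps <- 1e-6
  deriv <- (true_curve("chp_volume", dpl + eps, cp) -
              true_curve("chp_volume", dpl - eps, cp)) / (2 * eps)
  expect_lt(deriv, 0)
  expect_equal(true_curve("ventricle", 10, cp), 10 * cp$ventricle_slope)
  expect_error(true_curve("chp_volume", -1, cp), "non-negative")
})

test_that("cohort has the study's size, visit structure and reproducibility", {
  ch <- default_cohort1()
  n_fu <- sum(table(ch$subject_id) >= 2)
  expect_equal(nrow(ch), 422 + sum(ch$visit == 1) + sum(ch$visit == 2))
  expect_equal(length(unique(ch$subject_id)), 422)
  # realized follow-up proportion within binomial bounds of 65%
  expect_lt(abs(n_fu / 422 - 0.65), 2 * sqrt(0.65 * 0.35 / 422))
  # seeded reproducibility
  again <- sample_cohort(cohort_spec(seed = 1L))
  expect_identical(as.data.frame(ch), as.data.frame(again))
})

test_that("cohort marginals match their configured targets", {
  ch <- default_cohort1()
  b <- ch[ch$time_years == 0, ]
  expect_lt(abs(mean(b$age) - 40.8), 2 * 10.9 / sqrt(422))
  expect_lt(abs(mean(b$sdmt) - 50.6), 2 * 14.7 / sqrt(422))
  expect_equal(median(b$edss), 2.0, tolerance = 0.51)
  expect_lt(abs(mean(b$nchpv) - 1.6), 2 * 0.6 / sqrt(422))
  expect_true(all(b$duration_baseline >= 0))
  expect_true(all(b$edss >= 0 & b$edss <= 10 & (b$edss * 2) %% 1 == 0))
})

test_that("latent variables keep unit variance at the study size", {
  for (s in c(1, 7, 13)) {
    ch <- sample_cohort(cohort_spec(seed = s))
    z <- attr(ch, "ground_truth")$latent_z[ch$time_years == 0, ]
    expect_true(all(abs(apply(z, 2, var) - 1) < 0.1))
  }
})

test_that("zero noise and zero random effects give the structural values", {
  sp <- cohort_spec(n_subjects = 50, seed = 2, noise_sd_within = 0,
                    random_intercept_sd = 0)
  ch <- sample_cohort(sp)
  gt <- attr(ch, "ground_truth")
  # nchpv latent equals curve(baseline duration) + time slope exactly,
  # centred on the baseline cohort
  expected <- true_curve("chp_volume", ch$duration_baseline, sp$curve) +
    sp$effects$longitudinal_time[["nchpv"]] * ch$time_years
  expected <- expected - mean(expected[ch$time_years == 0])
  expect_equal(unname(gt$latent_z[, "nchpv"]), unname(expected))
  # and a downstream outcome equals its linear structural equation
  expected_lesion <- 0.35 * gt$latent_z[, "nchpv"]
  expect_equal(unname(gt$latent_z[, "lesion"]), unname(expected_lesion))
})

test_that("generator is self-consistent: OLS recovers the generating betas", {
  big <- sample_cohort(cohort_spec(n_subjects = 20000, p_fu1 = 0, seed = 3))
  eff <- attr(big, "ground_truth")$effects$cross_sectional
  for (i in seq_len(nrow(eff))) {
    oc <- eff$outcome[i]
    if (oc == "edss") next  # ordinal transform attenuates; checked separately
    r <- fit_cross_sectional(oc, eff$predictor[i], big)
    expect_lt(abs(r$beta_std - eff$beta[i]), 0.02)
  }
})

test_that("infeasible effect sizes are rejected with the equation named", {
  eff <- effect_spec(cross_sectional = data.frame(
    predictor = c("nchpv", "t1t2", "nlvv"), outcome = "lesion",
    beta = c(0.7, 0.6, 0.5)))
  expect_error(sample_cohort(cohort_spec(n_subjects = 100, effects = eff,
                                         seed = 1)),
               "lesion")
})

test_that("cohort export round-trips and carries the ground truth", {
  ch <- sample_cohort(cohort_spec(n_subjects = 40, seed = 9))
  dir <- withr::local_tempdir()
  paths <- export_cohort(ch, file.path(dir, "cohort.csv"))
  back <- read_cohort(paths[["csv"]])
  expect_equal(nrow(back), nrow(ch))
  expect_equal(back$nchpv, ch$nchpv, tolerance = 1e-9)
  expect_identical(back$gender, ch$gender)
  # absent rows, not NA rows, for missing follow-ups
  expect_false(anyNA(back))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  eff <- attr(ch, "ground_truth")$effects
  expect_equal(nrow(truth$effects$cross_sectional),
               nrow(eff$cross_sectional))
  expect_equal(truth$effects$longitudinal_time$nchpv,
               unname(eff$longitudinal_time["nchpv"]))
  expect_equal(nrow(truth$effects$interactions), nrow(eff$interactions))
})
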