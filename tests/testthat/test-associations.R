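test_that("annualized change follows its closed forms", {
  expect_equal(annualized_change(c(0, 0.5), c(10, 12)), 4)
  expect_equal(annualized_change(c(0, 1, 1.5), c(10, 11, 12.5)), 2)
  expect_true(is.na(annualized_change(0, 10)))
  # a single interval is exactly the two-point slope
  expect_equal(annualized_change(c(1, 3), c(5, 6)), 0.5)
  expect_error(annualized_change(c(0, 0), c(1, 2)), "strictly increasing")
})

test_that("z-scoring standardizes exactly and guards degenerate input", {
  x <- c(3, 9, 1, 7)
  z <- zscore(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_error(zscore(5), "at least 2")
  expect_error(zscore(rep(2, 10)), "zero spread")
})

test_that("BH adjustment matches the step-up formula and brute force", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(c(0.5, 0.5)), c(0.5, 0.5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  plexdyn:::with_seed(99, {
    for (rep in 1:1000) {
      p <- runif(sample(1:20, 1))^sample(1:3, 1)
      adj <- bh_fdr(p)
      expect_equal(adj, bh_oracle(p))
      expect_true(all(adj >= p - 1e-12))
    }
  })
})

test_that("cross-sectional regression recovers known coefficients", {
  # outcome identical to predictor, no covariate signal
  tab <- plexdyn:::with_seed(21, {
    n <- 200
    x <- rnorm(n)
    data.frame(subject_id = 1:n, time_years = 0, y = x, x = x,
               age = rnorm(n, 40, 10),
               gender = factor(sample(c("male", "female"), n, TRUE)),
               duration_years = rexp(n, 0.2),
               dmt = factor(sample(c("high", "moderate_low"), n, TRUE)))
  })
  r <- suppressWarnings(fit_cross_sectional("y", "x", tab))  # perfect fit
  expect_equal(r$beta_std, 1, tolerance = 1e-8)
  expect_equal(r$adj_r2, 1, tolerance = 1e-8)
  expect_true(r$ci_lo <= r$beta_std && r$beta_std <= r$ci_hi)
})

test_that("standardized betas are invariant to affine input rescaling", {
  ch <- default_cohort1()
  r1 <- fit_cross_sectional("lesion", "nchpv", ch)
  ch2 <- ch
  ch2$nchpv <- 1000 * ch2$nchpv + 3
  ch2$lesion <- 0.1 * ch2$lesion - 7
  r2 <- fit_cross_sectional("lesion", "nchpv", ch2)
  expect_equal(r1$beta_std, r2$beta_std, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("null cross-sectional effects keep their type-I error", {
  # t1t2 -> sdmt has no generating path; at n=422 the standardized effect
  # should be inside +-2 SE in at least 93 of 100 replicates
  hits <- 0L
  for (s in 1:100) {
    ch <- sample_cohort(cohort_spec(seed = 1000 + s))
    r <- fit_cross_sectional("sdmt", "t1t2", ch)
    if (abs(r$beta_std) < 2 * r$se) hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})

test_that("mixed model matches OLS when the grouping is uninformative", {
  tab <- plexdyn:::with_seed(31, {
    n <- 120
    id <- rep(1:(n / 2), each = 2)
    t <- rep(c(0, 1), n / 2)
    x <- rnorm(n)
    data.frame(subject_id = id, time_years = t,
               y = 0.3 * t + x + rnorm(n, 0, 0.01), x = x,
               age = rnorm(n, 40, 10)[id],
               gender = factor(sample(c("male", "female"), n / 2,
                                      TRUE))[id],
               duration_years = rexp(n / 2, 0.2)[id],
               duration_baseline = rexp(n / 2, 0.2)[id],
               dmt = factor(sample(c("high", "moderate_low"), n / 2,
                                   TRUE))[id])
  })
  suppressMessages({
    r <- fit_longitudinal("y", tab)
  })
  ols <- lm(zy ~ time_years + zage + gender + zdur + dmt,
            data = transform(tab,
                             zy = (y - mean(y[tab$time_years == 0])) /
                               sd(y[tab$time_years == 0]),
                             zage = scale(age)[, 1],
                             zdur = scale(duration_baseline)[, 1]))
  r_time <- r[r$term == "time_years", ]
  # with near-zero residual noise the mixed fit collapses onto OLS
  expect_equal(r_time$beta_std, unname(coef(ols)["time_years"]),
               tolerance = 1e-3)
})

test_that("mixed model recovers generating time and interaction effects", {
  ch <- default_cohort1()
  gt <- attr(ch, "ground_truth")$effects
  r <- fit_longitudinal("nchpv", ch)
  rt <- r[r$term == "time_years", ]
  expect_lt(abs(rt$beta_std - gt$longitudinal_time[["nchpv"]]), 2 * rt$se)
  ri <- fit_longitudinal("nbv", ch, interaction_with = "t1t2")
  rti <- ri[grepl(":", ri$term), ]
  expect_lt(abs(rti$beta_std - (-0.21)), 2 * rti$se)
  # interaction model always carries both main effects
  expect_true(any(ri$term == "time_years"))
  expect_true(any(grepl("baseline_t1t2$", ri$term)))
})

test_that("mixed-model coverage of a null time effect is near nominal", {
  # ncgmv has no generating path at all (ndgmv would inherit a mediated
  # time trend through its nchpv dependence)
  hits <- 0L
  for (s in 1:60) {
    ch <- sample_cohort(cohort_spec(seed = 2000 + s))
    r <- suppressMessages(fit_longitudinal("ncgmv", ch))
    rt <- r[r$term == "time_years", ]
    if (rt$ci_lo <= 0 && 0 <= rt$ci_hi) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.90)
})

test_that("stepwise selection is deterministic and calibrated", {
  ch <- default_cohort1()
  # a single strong candidate (generating beta 0.35) is always picked up
  r <- stepwise_select("lesion", "nchpv", ch)
  expect_true("nchpv" %in% attr(r, "selected"))
  # candidates with no generating effect enter at roughly the entry rate
  sel <- integer(40)
  for (s in 1:40) {
    chs <- sample_cohort(cohort_spec(seed = 3000 + s))
    rs <- stepwise_select("sdmt", c("t1t2", "nlvv"), chs)
    sel[s] <- length(attr(rs, "selected"))
  }
  # mean selected count under the null ~ 2 * enter_p; allow binomial slack
  expect_lt(mean(sel), 0.40)
  # no candidates: covariate-only model with zero result rows
  r0 <- stepwise_select("lesion", character(0), ch)
  expect_equal(nrow(r0), 0)
  expect_true(is.finite(attr(r0, "adj_r2")))
  # reruns are identical
  expect_identical(stepwise_select("bvmt", c("nchpv", "t1t2", "lesion"), ch),
                   stepwise_select("bvmt", c("nchpv", "t1t2", "lesion"), ch))
})

test_that("ventricle adjustment keeps the plexus-volume time effect", {
  ch <- default_cohort1()
  r0 <- fit_longitudinal("nchpv", ch)
  r1 <- fit_longitudinal("nchpv", ch,
                         config = analysis_config(ventricle_adjust = TRUE))
  t0 <- r0[r0$term == "time_years", ]
  t1 <- r1[r1$term == "time_years", ]
  expect_gt(t0$beta_std, 0)
  expect_gt(t1$beta_std, 0)
  expect_lt(t1$p, 0.05)
})

test_that("the full association layer mirrors the table families", {
  ch <- default_cohort1()
  res <- association_tables(ch)
  expect_named(res, c("cross_sectional", "stepwise", "longitudinal_time",
                      "interactions"))
  expect_equal(nrow(res$cross_sectional), 10)  # 5 MRI outcomes x 2 measures
  expect_true(all(res$cross_sectional$p_fdr >= res$cross_sectional$p - 1e-12))
  expect_true(all(res$longitudinal_time$term == "time_years"))
  # the strongest generated signals survive correction
  lesion <- res$cross_sectional[res$cross_sectional$outcome == "lesion" &
                                  res$cross_sectional$term == "nchpv", ]
  expect_lt(lesion$p_fdr, 0.05)
})
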