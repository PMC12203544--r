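test_that("ECDF rescaling follows Hazen plotting positions", {
  expect_equal(ecdf_rescale(c(3, 1, 2)), c(5, 1, 3) / 6)
  # rank invariance under strictly monotone transforms
  x <- plexdyn:::with_seed(3, rnorm(50))
  expect_equal(ecdf_rescale(x), ecdf_rescale(exp(2 * x)))
  # ties get average ranks; all-tied input maps to 0.5
  expect_equal(ecdf_rescale(rep(4, 5)), rep(0.5, 5))
  expect_true(all(ecdf_rescale(x) > 0 & ecdf_rescale(x) < 1))
  expect_error(ecdf_rescale(1), "at least 2")
})

test_that("trajectory fit recovers a quadratic curve from sparse visits", {
  sim <- plexdyn:::with_seed(42, {
    ns <- 400
    nv <- sample(1:3, ns, replace = TRUE)
    id <- rep(seq_len(ns), nv)
    d <- runif(length(id), 0, 10)
    g <- function(x) 0.05 * (x - 4)^2
    rg <- diff(range(g(seq(0, 10, 0.1))))
    list(id = id, d = d, g = g, rg = rg,
         y = g(d) + rnorm(length(id), 0, 0.1 * rg))
  })
  f <- fit_grace(sim$d, sim$y, sim$id, control = grace_control(n_boot = 0))
  central <- f$grid >= quantile(sim$d, 0.1) & f$grid <= quantile(sim$d, 0.9)
  expect_lt(max(abs(f$g_hat[central] - sim$g(f$grid[central]))),
            0.05 * sim$rg)
  expect_true(f$converged)
  expect_lt(abs(mean(f$alpha)), 1e-8)
  expect_true(all(diff(f$grid) > 0))
})

test_that("degenerate and limiting cases collapse as designed", {
  d <- plexdyn:::with_seed(6, runif(80, 0, 5))
  id <- rep(1:40, each = 2)
  # constant outcome: flat curve, zero offsets
  f <- fit_grace(d, rep(3, 80), id, control = grace_control(n_boot = 0))
  expect_equal(f$g_hat, rep(3, 100))
  expect_equal(unname(f$alpha), rep(0, 40))
  # infinite shrinkage with single visits: plain scatterplot smooth
  one <- seq(1, 80, by = 2)
  f2 <- fit_grace(d[one], (2 * d + 1)[one], seq_along(one),
                  control = grace_control(ridge_lambda = Inf, n_boot = 0))
  expect_equal(unname(f2$alpha), rep(0, 40))
  sc <- plexdyn:::local_linear(d[one], (2 * d + 1)[one], f2$grid,
                               f2$bandwidth)
  expect_equal(f2$g_hat, sc)
  expect_error(fit_grace(d[1:10], rep(1, 10), 1:10), "20 subjects")
  expect_error(fit_grace(rep(1, 40), rnorm(40), 1:40), "range")
})

test_that("objective decreases monotonically and shifts are equivariant", {
  sim <- plexdyn:::with_seed(8, {
    id <- rep(1:60, each = 3)
    d <- runif(180, 0, 20)
    list(id = id, d = d,
         y = sin(d / 4) + rep(rnorm(60, 0, 0.5), each = 3) +
           rnorm(180, 0, 0.2))
  })
  f <- fit_grace(sim$d, sim$y, sim$id, control = grace_control(n_boot = 0))
  expect_true(all(diff(f$msr_path) <= 1e-12))
  expect_gt(f$n_iter, 1)
  f2 <- fit_grace(sim$d, sim$y + 7, sim$id,
                  control = grace_control(n_boot = 0))
  expect_equal(f2$g_hat, f$g_hat + 7)
  expect_equal(f2$alpha, f$alpha)
  # ecdf route is invariant to monotone transforms of the outcome
  fa <- fit_grace(sim$d, sim$y, sim$id, rescale = "ecdf",
                  control = grace_control(n_boot = 0))
  fb <- fit_grace(sim$d, exp(sim$y), sim$id, rescale = "ecdf",
                  control = grace_control(n_boot = 0))
  expect_equal(fa$g_hat, fb$g_hat)
})

test_that("bootstrap band is well-formed and contains the estimate", {
  sim <- plexdyn:::with_seed(10, {
    id <- rep(1:80, each = 2)
    d <- runif(160, 0, 15)
    list(id = id, d = d, y = 0.2 * d + rnorm(160, 0, 0.4))
  })
  f <- fit_grace(sim$d, sim$y, sim$id,
                 control = grace_control(n_boot = 50, seed = 2))
  expect_true(all(f$ci_lo <= f$g_hat & f$g_hat <= f$ci_hi))
  # seeded bootstrap reproduces exactly
  f2 <- fit_grace(sim$d, sim$y, sim$id,
                  control = grace_control(n_boot = 50, seed = 2))
  expect_identical(f$ci_lo, f2$ci_lo)
})

test_that("turning points are read off the fitted curve correctly", {
  d <- plexdyn:::with_seed(12, runif(3000, 0, 25))
  id <- seq_along(d)
  fp <- fit_grace(d, (d - 10)^2, id,
                  control = grace_control(bandwidth_frac = 0.15, n_boot = 0))
  tp <- find_turning_points(fp)
  expect_equal(tp$extremum_kind, "nadir")
  expect_lt(abs(tp$extremum_years - 10), diff(fp$grid[1:2]) + 0.5)
  # strictly linear curve: no plateau, no extremum
  fl <- fit_grace(d, 2 * d + 1, id, control = grace_control(n_boot = 0))
  tpl <- find_turning_points(fl)
  expect_true(is.na(tpl$plateau_onset_years))
  expect_true(is.na(tpl$extremum_years))
  expect_equal(tpl$extremum_kind, "none")
  # saturating curve: plateau detected once the relative slope collapses
  fs <- fit_grace(d, 1 - exp(-d / 2), id,
                  control = grace_control(bandwidth_frac = 0.1, n_boot = 0))
  tps <- find_turning_points(fs)
  expect_false(is.na(tps$plateau_onset_years))
  unconv <- fp
  unconv$converged <- FALSE
  expect_error(find_turning_points(unconv), "converged")
})

test_that("model-object methods are coherent", {
  ch <- default_cohort1()
  f <- grace(nchpv ~ duration_years | subject_id, ch, rescale = "ecdf",
             control = grace_control(n_boot = 0))
  expect_s3_class(f, "grace")
  expect_equal(length(coef(f)), 422)
  expect_equal(length(fitted(f)), nrow(ch))
  expect_equal(residuals(f) + fitted(f), f$data$y)
  expect_equal(predict(f), f$g_hat)
  p5 <- predict(f, newdata = f$grid[1:5])
  expect_equal(length(p5), 5)
  expect_output(print(f), "trajectory")
  s <- summary(f)
  expect_s3_class(s, "summary.grace")
  expect_output(print(s), "plateau")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
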