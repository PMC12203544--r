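# Self-modeling estimation of a shared long-term trajectory g(duration)
# plus subject offsets from short, staggered longitudinal observations.
# The fit alternates between (i) a local-linear kernel smooth of the
# offset-corrected observations against disease duration and (ii) ridge-
# shrunken subject offsets, in the spirit of alternating conditional
# expectation (ACE) self-modeling regression. Because the time axis is
# anchored to observed disease duration, subject-specific latent time
# shifts are unnecessary; an offsets-only model identifies g directly.

#' Rescale values to (0, 1) by the empirical cumulative distribution
#'
#' Hazen plotting positions `(rank - 0.5) / n` with average ranks for ties.
#' Puts outcomes with different units on a common scale before trajectory
#' fitting; the transform depends only on ranks, so any strictly monotone
#' transformation of the input yields identical output.
#'
#' @param values Numeric vector (length >= 2).
#' @return Values strictly inside (0, 1).
#' @examples
#' ecdf_rescale(c(3, 1, 2))  # 0.833, 0.167, 0.5
#' @export
ecdf_rescale <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to rescale")
  (rank(values, ties.method = "average") - 0.5) / length(values)
}

#' Control parameters for the trajectory fit
#'
#' @param bandwidth_frac Smoother bandwidth as a fraction of the observed
#'   duration range (default 0.3).
#' @param ridge_lambda Ridge shrinkage of the subject offsets; the offset
#'   update is `n_i / (n_i + lambda)` times the subject's mean residual,
#'   mimicking a random-intercept BLUP (default 1).
#' @param tol Convergence tolerance on the sup-norm change of the fitted
#'   curve (default 1e-4).
#' @param max_iter Maximum alternation iterations (default 50).
#' @param n_boot Subject-level bootstrap resamples for the pointwise 95%
#'   confidence band (default 200; 0 disables the band).
#' @param n_grid Grid size spanning the observed duration range.
#' @param seed Integer seed for the bootstrap.
#' @return List of class `grace_control`.
#' @export
grace_control <- function(bandwidth_frac = 0.3, ridge_lambda = 1,
                          tol = 1e-4, max_iter = 50L, n_boot = 200L,
                          n_grid = 100L, seed = 1L) {
  if (bandwidth_frac <= 0 || bandwidth_frac > 1)
    stop("bandwidth_frac must be in (0, 1]")
  if (ridge_lambda < 0) stop("ridge_lambda must be >= 0")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(bandwidth_frac = bandwidth_frac,
                 ridge_lambda = ridge_lambda, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_boot = as.integer(n_boot), n_grid = as.integer(n_grid),
                 seed = as.integer(seed)),
            class = "grace_control")
}

# Local-linear smoothing with tricube kernel weights. The kernel matrices
# depend only on the design (x, xout, h), so they are computed once per fit
# and reused across alternation iterations and bootstrap resamples, where
# only the response changes.
ll_kernel <- function(x, xout, h, min_pts = 5L) {
  U <- outer(xout, x, function(a, b) (b - a) / h)
  W <- (1 - pmin(abs(U), 1)^3)^3
  if (any(rowSums(W > 0) < min_pts))
    stop("degenerate bandwidth: a smoothing window holds fewer than ",
         min_pts, " points; increase bandwidth_frac")
  WD <- W * (U * h)                # weights times centred x - xout
  k <- list(W = W, WD = WD,
            S0 = rowSums(W), S1 = rowSums(WD), S2 = rowSums(WD * (U * h)))
  k$den <- k$S0 * k$S2 - k$S1^2
  k$flat <- k$den < 1e-12 * pmax(k$S0 * k$S2, 1e-300)
  k
}

# subset a kernel to observation columns `cols`, re-evaluating at rows
# `rows` (for the obs-by-obs kernel the two coincide)
ll_kernel_subset <- function(k, rows, cols, min_pts = 5L) {
  W <- k$W[rows, cols, drop = FALSE]
  if (any(rowSums(W > 0) < min_pts))
    stop("degenerate bandwidth in a bootstrap resample")
  WD <- k$WD[rows, cols, drop = FALSE]
  s <- list(W = W, WD = WD, S0 = rowSums(W), S1 = rowSums(WD))
  s$S2 <- rowSums(WD^2 / pmax(W, 1e-300))   # WD^2 / W = W D^2
  s$den <- s$S0 * s$S2 - s$S1^2
  s$flat <- s$den < 1e-12 * pmax(s$S0 * s$S2, 1e-300)
  s
}

ll_apply <- function(k, y) {
  T0 <- drop(k$W %*% y)
  T1 <- drop(k$WD %*% y)
  out <- (k$S2 * T0 - k$S1 * T1) / k$den
  bad <- k$flat | !is.finite(out)
  out[bad] <- (T0 / pmax(k$S0, 1e-300))[bad]
  out
}

# one-shot convenience wrapper (used by predict and tests)
local_linear <- function(x, y, xout, h, min_pts = 5L) {
  ll_apply(ll_kernel(x, xout, h, min_pts), y)
}

# One full alternation run; returns curve on grid, offsets, diagnostics.
# Each iteration updates the ridge-shrunken offsets against the current
# curve, then re-smooths the offset-corrected data. The iteration is
# accepted only if the mean squared residual does not increase; otherwise
# the previous iterate is kept and the alternation stops (offsets of
# independent subjects carry no duration signal, so once they are absorbed
# further smoothing passes only add noise).
grace_engine <- function(y, subj, k_obs, k_grid, lambda, tol, max_iter) {
  subj <- as.integer(factor(subj))
  ns <- max(subj)
  n_i <- tabulate(subj, ns)
  alpha <- numeric(ns)
  g_obs <- ll_apply(k_obs, y)
  g_grid <- ll_apply(k_grid, y)
  msr_path <- mean((y - g_obs)^2)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    resid_mean <- tapply(y - g_obs, subj, mean)[as.character(seq_len(ns))]
    alpha_new <- as.numeric(n_i / (n_i + lambda) * resid_mean)
    alpha_new[!is.finite(alpha_new)] <- 0   # lambda = Inf
    alpha_new <- alpha_new - mean(alpha_new)
    yc <- y - alpha_new[subj]
    g_obs_new <- ll_apply(k_obs, yc)
    g_grid_new <- ll_apply(k_grid, yc)
    msr <- mean((yc - g_obs_new)^2)
    if (msr > msr_path[length(msr_path)] + 1e-12) {
      converged <- TRUE   # alternation no longer reduces the objective
      break
    }
    n_iter <- it
    msr_path <- c(msr_path, msr)
    delta <- max(abs(g_grid_new - g_grid))
    alpha <- alpha_new
    g_obs <- g_obs_new
    g_grid <- g_grid_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(g_grid = g_grid, g_obs = g_obs, alpha = alpha, subj = subj,
       msr_path = msr_path, n_iter = n_iter, converged = converged)
}

#' Fit a long-term trajectory from short-term longitudinal observations
#'
#' Estimates a shared curve `g(duration)` and mean-zero subject offsets by
#' alternating a tricube local-linear smooth of the offset-corrected data
#' with a ridge-shrunken offset update, until the fitted curve stabilizes.
#' Pointwise 95% confidence bands come from a subject-level (cluster)
#' bootstrap that re-runs the full alternation on each resample.
#'
#' @param formula A formula of the form `y ~ duration | subject`.
#' @param data Data frame holding the variables.
#' @param rescale `"none"` or `"ecdf"`; with `"ecdf"` the outcome is first
#'   rank-rescaled into (0, 1) via [ecdf_rescale()].
#' @param control A [grace_control()] object.
#' @return An object of class `grace`: list with `grid`, `g_hat`, `ci_lo`,
#'   `ci_hi`, `alpha` (named subject offsets, mean zero), `n_iter`,
#'   `converged`, `msr_path` (mean squared residual per iteration),
#'   `bandwidth`, the model frame `data`, and `call`.
#' @seealso [find_turning_points()], [predict.grace()], [plot.grace()]
#' @export
grace <- function(formula, data, rescale = c("none", "ecdf"),
                  control = grace_control()) {
  rescale <- match.arg(rescale)
  pf <- parse_grace_formula(formula, data)
  fit_grace(durations = pf$d, y = pf$y, subjects = pf$subj,
            rescale = rescale, control = control,
            call = match.call())
}

parse_grace_formula <- function(formula, data) {
  if (length(formula) != 3) stop("formula must look like y ~ duration | subject")
  rhs <- formula[[3]]
  if (!(is.call(rhs) && identical(rhs[[1]], as.name("|"))))
    stop("formula must look like y ~ duration | subject")
  list(y = eval(formula[[2]], data, environment(formula)),
       d = eval(rhs[[2]], data, environment(formula)),
       subj = eval(rhs[[3]], data, environment(formula)))
}

#' @rdname grace
#' @param durations,y,subjects Vector interface equivalent to the formula:
#'   disease duration at observation (years, >= 0), outcome value, and
#'   subject identifier.
#' @param call Internal.
#' @export
fit_grace <- function(durations, y, subjects, rescale = c("none", "ecdf"),
                      control = grace_control(), call = sys.call()) {
  rescale <- match.arg(rescale)
  if (any(durations < 0)) stop("durations must be >= 0")
  if (any(!is.finite(durations)) || any(!is.finite(y)))
    stop("durations and y must be finite")
  ids <- as.character(subjects)
  if (length(unique(ids)) < 20) stop("need at least 20 subjects")
  rng <- range(durations)
  if (diff(rng) <= 0) stop("duration range must be positive")
  if (rescale == "ecdf") y <- ecdf_rescale(y)

  grid <- seq(rng[1], rng[2], length.out = control$n_grid)
  h <- control$bandwidth_frac * diff(rng)
  k_obs <- ll_kernel(durations, durations, h)
  k_grid <- ll_kernel(durations, grid, h)
  fit <- grace_engine(y, ids, k_obs, k_grid, control$ridge_lambda,
                      control$tol, control$max_iter)
  if (!fit$converged)
    warning("trajectory fit did not converge in ", control$max_iter,
            " iterations")

  ci_lo <- ci_hi <- rep(NA_real_, length(grid))
  if (control$n_boot > 0) {
    uid <- unique(ids)
    row_of <- split(seq_along(ids), factor(ids, levels = uid))
    boot_g <- with_seed(control$seed, {
      vapply(seq_len(control$n_boot), function(b) {
        take <- sample(length(uid), length(uid), replace = TRUE)
        rows <- row_of[take]
        cols <- unlist(rows, use.names = FALSE)
        bs <- rep(seq_along(take), lengths(rows))  # duplicates stay distinct
        bf <- try({
          kob <- ll_kernel_subset(k_obs, cols, cols)
          kgb <- ll_kernel_subset(k_grid, seq_along(grid), cols)
          grace_engine(y[cols], bs, kob, kgb, control$ridge_lambda,
                       control$tol, min(control$max_iter, 25L))
        }, silent = TRUE)
        if (inherits(bf, "try-error")) rep(NA_real_, length(grid))
        else bf$g_grid
      }, numeric(length(grid)))
    })
    ci_lo <- apply(boot_g, 1, stats::quantile, probs = 0.025, na.rm = TRUE)
    ci_hi <- apply(boot_g, 1, stats::quantile, probs = 0.975, na.rm = TRUE)
    # the band is widened, where necessary, to contain the point estimate
    ci_lo <- pmin(ci_lo, fit$g_grid)
    ci_hi <- pmax(ci_hi, fit$g_grid)
  }

  alpha <- fit$alpha
  names(alpha) <- levels(factor(ids))
  structure(list(grid = grid, g_hat = fit$g_grid, ci_lo = ci_lo,
                 ci_hi = ci_hi, alpha = alpha,
                 n_iter = fit$n_iter, converged = fit$converged,
                 msr_path = fit$msr_path, bandwidth = h,
                 rescale = rescale,
                 data = data.frame(duration = durations, y = y,
                                   subject = ids,
                                   fitted = fit$g_obs + alpha[ids],
                                   stringsAsFactors = FALSE),
                 control = control, call = call),
            class = "grace")
}

#' Locate turning points of a fitted trajectory
#'
#' Differentiates the fitted curve by central differences on the grid. The
#' plateau onset is the first grid point after the point of steepest slope
#' at which the absolute slope falls below `slope_eps` times its maximum and
#' stays below it for the following five grid points. The extremum is the
#' interior global minimum ("nadir") or maximum ("peak") of the curve, if
#' one lies at least two grid points from each boundary.
#'
#' @param fit A converged [grace()] fit.
#' @param slope_eps Plateau threshold as a fraction of the maximum absolute
#'   slope (default 0.1).
#' @return List with `plateau_onset_years` (or `NA`), `extremum_years` (or
#'   `NA`) and `extremum_kind` (`"nadir"`, `"peak"` or `"none"`).
#' @export
find_turning_points <- function(fit, slope_eps = 0.1) {
  stopifnot(inherits(fit, "grace"))
  if (!isTRUE(fit$converged))
    stop("turning points require a converged trajectory fit")
  g <- fit$g_hat
  x <- fit$grid
  n <- length(g)
  s <- numeric(n)
  s[1] <- (g[2] - g[1]) / (x[2] - x[1])
  s[n] <- (g[n] - g[n - 1]) / (x[n] - x[n - 1])
  mid <- 2:(n - 1)
  s[mid] <- (g[mid + 1] - g[mid - 1]) / (x[mid + 1] - x[mid - 1])

  smax <- max(abs(s))
  imax <- which.max(abs(s))
  thr <- slope_eps * smax
  plateau <- NA_real_
  if (imax < n) {
    for (i in (imax + 1):n) {
      run <- i:min(i + 5L, n)
      if (all(abs(s[run]) < thr)) { plateau <- x[i]; break }
    }
  }

  extremum <- NA_real_
  kind <- "none"
  imin <- which.min(g)
  imx <- which.max(g)
  if (imin >= 3 && imin <= n - 2) {
    extremum <- x[imin]; kind <- "nadir"
  } else if (imx >= 3 && imx <= n - 2) {
    extremum <- x[imx]; kind <- "peak"
  }
  list(plateau_onset_years = plateau, extremum_years = extremum,
       extremum_kind = kind)
}

#' @export
print.grace <- function(x, ...) {
  cat("Long-term trajectory fit (alternating self-modeling regression)\n")
  cat(sprintf("  %d observations, %d subjects\n", nrow(x$data),
              length(x$alpha)))
  cat(sprintf("  duration range: %.2f - %.2f years; bandwidth %.2f years\n",
              min(x$grid), max(x$grid), x$bandwidth))
  cat(sprintf("  outcome rescale: %s\n", x$rescale))
  cat(sprintf("  %d iterations, converged: %s, final MSR %.5g\n",
              x$n_iter, x$converged,
              if (length(x$msr_path)) x$msr_path[length(x$msr_path)] else NA))
  invisible(x)
}

#' @export
summary.grace <- function(object, slope_eps = 0.1, ...) {
  tp <- if (isTRUE(object$converged))
    find_turning_points(object, slope_eps) else
    list(plateau_onset_years = NA_real_, extremum_years = NA_real_,
         extremum_kind = "none")
  out <- list(fit = object, turning_points = tp,
              alpha_sd = stats::sd(object$alpha),
              msr = if (length(object$msr_path))
                object$msr_path[length(object$msr_path)] else NA_real_)
  class(out) <- "summary.grace"
  out
}

#' @export
print.summary.grace <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  subject offset SD: %.4f\n", x$alpha_sd))
  tp <- x$turning_points
  cat(sprintf("  plateau onset: %s years; extremum: %s years (%s)\n",
              format(tp$plateau_onset_years, digits = 3),
              format(tp$extremum_years, digits = 3), tp$extremum_kind))
  invisible(x)
}

#' @export
coef.grace <- function(object, ...) object$alpha

#' Evaluate a fitted trajectory at new durations
#'
#' Re-applies the fitted local-linear smoother (offset-corrected data,
#' final offsets) at the requested durations.
#'
#' @param object A [grace()] fit.
#' @param newdata Numeric vector of durations, or a data frame with a
#'   `duration` column; defaults to the fit grid.
#' @param ... Unused.
#' @return Numeric vector of curve values.
#' @export
predict.grace <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$g_hat)
  x <- if (is.data.frame(newdata)) newdata$duration else as.numeric(newdata)
  yc <- object$data$y - object$alpha[object$data$subject]
  local_linear(object$data$duration, yc, x, object$bandwidth)
}

#' @export
fitted.grace <- function(object, ...) object$data$fitted

#' @export
residuals.grace <- function(object, ...) object$data$y - object$data$fitted

#' Plot a fitted trajectory with its bootstrap confidence band
#'
#' @param x A [grace()] fit.
#' @param show_points Overlay the (offset-corrected) observations.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.grace <- function(x, show_points = TRUE, ...) {
  yl <- range(c(x$g_hat, x$ci_lo, x$ci_hi, if (show_points) x$data$y),
              na.rm = TRUE)
  graphics::plot(x$grid, x$g_hat, type = "n", ylim = yl,
                 xlab = "disease duration (years)", ylab = "outcome", ...)
  if (all(is.finite(x$ci_lo)))
    graphics::polygon(c(x$grid, rev(x$grid)), c(x$ci_lo, rev(x$ci_hi)),
                      col = grDevices::adjustcolor("grey60", 0.4),
                      border = NA)
  if (show_points)
    graphics::points(x$data$duration,
                     x$data$y - x$alpha[x$data$subject],
                     pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor("steelblue", 0.35))
  graphics::lines(x$grid, x$g_hat, lwd = 2)
  invisible(x)
}
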