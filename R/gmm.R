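# One-dimensional Gaussian mixture fitting by EM with k-means initialization
# and multiple seeded restarts. The segmentation only relies on the
# highest-mean-component selection rule, so a deterministic maximum-likelihood
# EM keeps that rule reproducible and easy to verify against ground truth.

#' Control parameters for segmentation
#'
#' @param susan_sigma_mm Spatial standard deviation of the SUSAN smoothing
#'   kernel in mm (default 1).
#' @param susan_brightness_frac Brightness threshold as a fraction of the
#'   robust (2nd-98th percentile) intensity range of the in-ventricle voxels
#'   (default 0.1). Expressing it as a fraction makes the whole pipeline
#'   invariant to affine intensity rescaling of the input.
#' @param gmm_restarts Number of seeded EM restarts (best log-likelihood wins).
#' @param gmm_tol Convergence tolerance on the log-likelihood change.
#' @param gmm_max_iter Maximum EM iterations per restart.
#' @param seed Integer seed controlling the restarts.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(susan_sigma_mm = 1, susan_brightness_frac = 0.1,
                       gmm_restarts = 5L, gmm_tol = 1e-8,
                       gmm_max_iter = 200L, seed = 1L) {
  if (susan_sigma_mm <= 0) stop("susan_sigma_mm must be > 0")
  if (susan_brightness_frac <= 0 || susan_brightness_frac > 1)
    stop("susan_brightness_frac must be in (0, 1]")
  structure(list(susan_sigma_mm = susan_sigma_mm,
                 susan_brightness_frac = susan_brightness_frac,
                 gmm_restarts = as.integer(gmm_restarts),
                 gmm_tol = gmm_tol, gmm_max_iter = as.integer(gmm_max_iter),
                 seed = as.integer(seed)),
            class = "seg_params")
}

#' Fit a univariate Gaussian mixture model by EM
#'
#' Expectation-maximization with k-means initialization; the best of
#' `gmm_restarts` seeded restarts by log-likelihood is returned. Components
#' are reported sorted by ascending mean. Hard assignments take the argmax
#' responsibility, with ties broken toward the lower-mean component.
#'
#' @param values Numeric vector of intensities (at least `10 * k`, finite,
#'   with nonzero spread).
#' @param k Number of mixture components.
#' @param params A [seg_params()] object.
#' @return A list of class `gmm_fit` with `k`, `means`, `variances`,
#'   `weights`, `responsibilities` (n x k), `assignment` (hard labels 1..k),
#'   `log_likelihood` and `converged`.
#' @export
fit_gmm <- function(values, k, params = seg_params()) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (n < 10 * k) stop("need at least 10*k values to fit a ", k,
                       "-component mixture (got ", n, ")")
  if (stats::sd(values) == 0) stop("degenerate intensities: zero spread")

  if (k == 1) {
    mu <- mean(values)
    v <- mean((values - mu)^2)  # biased (ML) variance
    resp <- matrix(1, n, 1)
    ll <- sum(stats::dnorm(values, mu, sqrt(v), log = TRUE))
    return(structure(list(k = 1L, means = mu, variances = v, weights = 1,
                          responsibilities = resp,
                          assignment = rep(1L, n),
                          log_likelihood = ll, converged = TRUE),
                     class = "gmm_fit"))
  }

  var_floor <- 1e-4 * stats::var(values)
  em_once <- function(mu0) {
    mu <- mu0
    sg2 <- rep(stats::var(values) / k, k)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    converged <- FALSE
    resp <- NULL
    for (it in seq_len(params$gmm_max_iter)) {
      logd <- vapply(seq_len(k), function(j)
        log(w[j]) + stats::dnorm(values, mu[j], sqrt(sg2[j]), log = TRUE),
        numeric(n))
      m <- apply(logd, 1, max)
      lse <- m + log(rowSums(exp(logd - m)))
      ll <- sum(lse)
      resp <- exp(logd - lse)
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * values) / nk
      sg2 <- pmax(colSums(resp * (outer(values, mu, "-"))^2) / nk, var_floor)
      if (is.finite(ll_old) && abs(ll - ll_old) < params$gmm_tol) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    list(mu = mu, sg2 = sg2, w = w, resp = resp, ll = ll_old,
         converged = converged)
  }

  best <- NULL
  with_seed(params$seed, {
    for (r in seq_len(params$gmm_restarts)) {
      km <- suppressWarnings(stats::kmeans(values, centers = k, nstart = 1,
                                           iter.max = 50))
      fit <- em_once(as.numeric(km$centers))
      if (is.null(best) || fit$ll > best$ll) best <- fit
    }
  })

  ord <- order(best$mu)
  resp <- best$resp[, ord, drop = FALSE]
  # ties in the argmax responsibility break toward the lower-mean component
  assignment <- max.col(resp, ties.method = "first")
  structure(list(k = as.integer(k), means = best$mu[ord],
                 variances = best$sg2[ord], weights = best$w[ord],
                 responsibilities = resp, assignment = assignment,
                 log_likelihood = best$ll, converged = best$converged),
            class = "gmm_fit")
}
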