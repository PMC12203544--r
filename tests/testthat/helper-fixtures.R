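# Shared fixtures, built in code at test time.

# small, fast phantom specs
clean_phantom_spec <- function(seed = 1L, noise_sd = 0, bias_amplitude = 0,
                               ...)
  phantom_spec(noise_sd = noise_sd, bias_amplitude = bias_amplitude,
               seed = seed, ...)

# the default-noise regression phantom pinned to seed 7
noisy_phantom7 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom(phantom_spec(seed = 7L))
    cache
  }
})

# one default study cohort, cached across tests
default_cohort1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sample_cohort(cohort_spec(seed = 1L))
    cache
  }
})

# brute-force SUSAN oracle: direct evaluation of the weight formula
susan_oracle <- function(volume, mask, sigma, thresh, vd = c(1, 1, 1)) {
  d <- dim(volume)
  out <- volume
  r <- floor(3 * sigma / vd)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    num <- 0; den <- 0
    for (di in -r[1]:r[1]) for (dj in -r[2]:r[2]) for (dk in -r[3]:r[3]) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      if (!mask[ii, jj, kk]) next
      dist2 <- (di * vd[1])^2 + (dj * vd[2])^2 + (dk * vd[3])^2
      if (dist2 > (3 * sigma)^2) next
      w <- exp(-dist2 / (2 * sigma^2)) *
        exp(-((volume[ii, jj, kk] - volume[i, j, k]) / thresh)^2)
      num <- num + w * volume[ii, jj, kk]
      den <- den + w
    }
    if (den >= 1e-12) out[i, j, k] <- num / den
  }
  out
}

# brute-force Benjamini-Hochberg step-up oracle: for each p, the smallest
# q at which the step-up rule rejects it
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  vapply(seq_len(m), function(i) {
    pi <- p[i]
    # smallest q such that some threshold j has p_(j) <= q j / m and p_i
    # is among the j smallest
    rank_i <- which(o == i)
    cand <- vapply(rank_i:m, function(j) p[o[j]] * m / j, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}
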