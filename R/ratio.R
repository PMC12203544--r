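# Calibrated T1w/T2w intensity-ratio mapping. Raw weighted-image intensities
# are in arbitrary scanner units; anchoring each contrast to the histogram
# peaks of bone, soft tissue and CSF reference regions puts both on a common
# dimensionless scale so their voxelwise quotient is comparable across
# scanners and sessions.

#' Calibration parameters for ratio mapping
#'
#' Anchor targets are dimensionless intensities assigned to the reference
#' classes after calibration. Their rank order states the expected class
#' ordering for the contrast: on T2w the conventional ordering is
#' bone < soft tissue < CSF; on T1w it is reversed.
#'
#' @param anchor_targets_t1,anchor_targets_t2 Named numeric vectors with
#'   entries `bone`, `soft_tissue`, `csf`.
#' @param kde_bandwidth_frac Kernel bandwidth for peak detection as a
#'   fraction of each reference region's intensity SD (default 0.25).
#' @param bias_poly_order Degree of the log-domain polynomial bias corrector
#'   (default 2).
#' @return A list of class `calibration_params`.
#' @export
calibration_params <- function(anchor_targets_t1 = c(bone = 1.0,
                                                     soft_tissue = 0.6,
                                                     csf = 0.2),
                               anchor_targets_t2 = c(bone = 0.2,
                                                     soft_tissue = 0.6,
                                                     csf = 1.0),
                               kde_bandwidth_frac = 0.25,
                               bias_poly_order = 2L) {
  chk <- function(a) {
    if (!all(c("bone", "soft_tissue", "csf") %in% names(a)))
      stop("anchor targets must name bone, soft_tissue and csf")
    if (anyDuplicated(a)) stop("anchor targets must be distinct")
  }
  chk(anchor_targets_t1); chk(anchor_targets_t2)
  if (kde_bandwidth_frac <= 0) stop("kde_bandwidth_frac must be > 0")
  structure(list(anchor_targets_t1 = anchor_targets_t1[c("bone", "soft_tissue", "csf")],
                 anchor_targets_t2 = anchor_targets_t2[c("bone", "soft_tissue", "csf")],
                 kde_bandwidth_frac = kde_bandwidth_frac,
                 bias_poly_order = as.integer(bias_poly_order)),
            class = "calibration_params")
}

#' Correct smooth multiplicative intensity inhomogeneity
#'
#' Fits a polynomial of the given degree to the log-intensities over the
#' mask by least squares, divides its (mean-centred) exponential out of the
#' whole volume, and rescales so the in-mask median is unchanged. The mask
#' should cover a single, spatially extended tissue class (e.g. the
#' soft-tissue reference region), so the fit captures the smooth
#' multiplicative field rather than anatomy; the estimated field is then
#' valid everywhere because it is a global low-order polynomial.
#'
#' @param volume 3D intensity array, strictly positive inside the mask.
#' @param head_mask Logical array, non-empty: the fitting region.
#' @param order Polynomial degree (default 2).
#' @return Corrected array of the same dimension.
#' @export
correct_bias <- function(volume, head_mask, order = 2L) {
  if (!identical(dim(volume), dim(head_mask)))
    stop("volume and head_mask dimensions differ")
  idx <- which(head_mask)
  if (!length(idx)) stop("head_mask is empty")
  if (any(volume[idx] <= 0))
    stop("non-positive intensities inside the mask; cannot take logs")
  d <- dim(volume)
  ai <- arrayInd(idx, d)
  # normalized coordinates in [-1, 1]
  norm_coord <- function(m)
    sweep(sweep(m, 2, (d + 1) / 2, "-"), 2, pmax((d - 1) / 2, 1), "/")
  X <- poly_design(norm_coord(ai), order)
  lv <- log(volume[idx])
  beta <- stats::lm.fit(X, lv)$coefficients
  beta[is.na(beta)] <- 0
  fit_in <- drop(X %*% beta)
  all_ai <- arrayInd(seq_len(prod(d)), d)
  field <- array(exp(drop(poly_design(norm_coord(all_ai), order) %*% beta) -
                       mean(fit_in)), d)
  out <- volume / field
  med_in <- stats::median(volume[idx])
  med_out <- stats::median(out[idx])
  if (med_out > 0) out <- out * (med_in / med_out)
  out
}

# full polynomial design matrix in 3 coordinates up to total degree `order`
poly_design <- function(nc, order) {
  terms <- list(rep(1, nrow(nc)))
  for (total in seq_len(order)) {
    for (i in 0:total) for (j in 0:(total - i)) {
      k <- total - i - j
      terms[[length(terms) + 1L]] <- nc[, 1]^i * nc[, 2]^j * nc[, 3]^k
    }
  }
  do.call(cbind, terms)
}

#' Locate the dominant intensity peak of a sample by kernel density
#'
#' Mode of a Gaussian kernel density estimate evaluated on a 512-point grid
#' spanning the value range; ties resolve to the lowest-intensity mode.
#'
#' @param values Numeric vector (at least 50 values).
#' @param bandwidth Kernel bandwidth in intensity units.
#' @return The peak intensity.
#' @export
histogram_peak <- function(values, bandwidth) {
  values <- as.numeric(values)
  if (length(values) < 50) stop("need at least 50 values for peak detection")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  # duplicate sample values (near-constant regions) trigger a harmless
  # tie-collapsing warning inside density()
  dens <- suppressWarnings(stats::density(values, bw = bandwidth, n = 512,
                                          from = rng[1], to = rng[2]))
  dens$x[which.max(dens$y)]
}

#' Calibrate a contrast against reference-tissue histogram peaks
#'
#' Detects the intensity peak of each reference region (bone, soft tissue,
#' CSF) and maps the detected peaks onto the dimensionless anchor targets by
#' a monotone piecewise-linear function, linearly extrapolated beyond the
#' outer anchors, applied voxelwise. The detected peaks must be strictly
#' ordered consistently with the anchor targets, otherwise the reference
#' regions are not separable on this contrast.
#'
#' @param volume 3D intensity array.
#' @param ref_masks List with logical arrays `bone`, `soft_tissue`, `csf`
#'   (all non-empty).
#' @param anchor_targets Named targets for this contrast, e.g.
#'   `calibration_params()$anchor_targets_t2`.
#' @param kde_bandwidth_frac Peak-detection bandwidth as a fraction of each
#'   region's intensity SD.
#' @return Calibrated array, with attribute `peaks` (detected peak per
#'   class).
#' @export
calibrate_intensities <- function(volume, ref_masks, anchor_targets,
                                  kde_bandwidth_frac = 0.25) {
  classes <- c("bone", "soft_tissue", "csf")
  if (!all(classes %in% names(ref_masks))) stop("ref_masks must name ", paste(classes, collapse = ", "))
  peaks <- vapply(classes, function(cl) {
    m <- ref_masks[[cl]]
    if (!any(m)) stop("reference mask '", cl, "' is empty")
    v <- volume[m]
    s <- stats::sd(v)
    if (s == 0) return(v[1])
    histogram_peak(v, kde_bandwidth_frac * s)
  }, numeric(1))
  tg <- anchor_targets[classes]
  ord <- order(tg)
  if (any(diff(peaks[ord]) <= 0))
    stop("calibration anchors not separable: detected peaks (",
         paste(signif(peaks, 4), collapse = ", "),
         ") are not strictly ordered like the anchor targets")
  out <- piecewise_linear(as.numeric(volume), peaks[ord], tg[ord])
  out <- array(out, dim(volume))
  attr(out, "peaks") <- peaks
  out
}

# monotone piecewise-linear interpolation through (xs, ys) with linear
# extrapolation using the end-segment slopes
piecewise_linear <- function(x, xs, ys) {
  y <- stats::approx(xs, ys, xout = x, rule = 2, ties = "ordered")$y
  sl_lo <- (ys[2] - ys[1]) / (xs[2] - xs[1])
  sl_hi <- (ys[length(ys)] - ys[length(ys) - 1]) /
           (xs[length(xs)] - xs[length(xs) - 1])
  below <- x < xs[1]
  above <- x > xs[length(xs)]
  y[below] <- ys[1] + sl_lo * (x[below] - xs[1])
  y[above] <- ys[length(ys)] + sl_hi * (x[above] - xs[length(xs)])
  y
}

#' One-voxel binary erosion (6-connectivity)
#'
#' Single-iteration morphological erosion with the face-connected structuring
#' element; used to shave the boundary layer of a mask before extracting
#' intensity statistics, reducing partial-volume contamination.
#'
#' @param mask Logical 3D array.
#' @return Eroded logical array.
#' @export
erode_one_voxel <- function(mask) {
  m <- mask
  for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    m <- m & shift3d(mask, o[1], o[2], o[3], fill = FALSE)
  m
}

#' Compute the calibrated T1/T2 ratio map and the mean ratio within a mask
#'
#' Divides the calibrated T1w volume by the calibrated T2w volume wherever
#' the denominator exceeds a small fraction of its in-mask median, and
#' averages the ratio over the one-voxel-eroded region mask. If erosion
#' empties the mask the mean falls back to the un-eroded mask with a
#' warning.
#'
#' @param t1_cal,t2_cal Calibrated volumes on the same grid.
#' @param chp_mask Logical array: the region (e.g. segmented choroid plexus)
#'   over which the mean ratio is taken. Must be non-empty.
#' @return Object of class `ratio_result`: `ratio_map` (NA where undefined),
#'   `eroded_mask`, `mean_ratio`, and detected `peaks_t1`/`peaks_t2` when
#'   present on the inputs.
#' @export
compute_ratio <- function(t1_cal, t2_cal, chp_mask) {
  if (!identical(dim(t1_cal), dim(t2_cal)) ||
      !identical(dim(t1_cal), dim(chp_mask)))
    stop("volumes and mask must share one grid")
  if (!any(chp_mask)) stop("chp_mask is empty")
  eps <- 1e-6 * stats::median(t2_cal[chp_mask])
  ratio <- array(NA_real_, dim(t1_cal))
  defined <- t2_cal > eps
  ratio[defined] <- t1_cal[defined] / t2_cal[defined]
  er <- erode_one_voxel(chp_mask)
  use <- er
  if (!any(er)) {
    warning("eroded mask is empty; mean ratio computed on the un-eroded mask")
    use <- chp_mask
  }
  vals <- ratio[use]
  structure(list(ratio_map = ratio, eroded_mask = er,
                 mean_ratio = mean(vals, na.rm = TRUE),
                 peaks_t1 = attr(t1_cal, "peaks"),
                 peaks_t2 = attr(t2_cal, "peaks")),
            class = "ratio_result")
}

#' Full ratio-mapping stage on a phantom-style input
#'
#' Convenience wrapper: bias-corrects both contrasts over the head mask,
#' calibrates each against the reference-region peaks, and extracts the mean
#' ratio over the (eroded) region mask.
#'
#' @param t1w,t2w Raw intensity volumes on one grid.
#' @param chp_mask Region mask for ratio extraction.
#' @param ref_masks List of reference masks (`bone`, `soft_tissue`, `csf`).
#' @param head_mask Single-tissue fitting mask for bias correction; defaults
#'   to the soft-tissue reference region (restricted to positive voxels of
#'   both contrasts).
#' @param params A [calibration_params()] object.
#' @param correct_bias_first If `FALSE`, skip the polynomial bias corrector.
#' @return A `ratio_result` (see [compute_ratio()]).
#' @export
ratio_pipeline <- function(t1w, t2w, chp_mask, ref_masks,
                           head_mask = NULL,
                           params = calibration_params(),
                           correct_bias_first = TRUE) {
  if (is.null(head_mask))
    head_mask <- ref_masks$soft_tissue & (t1w > 0) & (t2w > 0)
  if (correct_bias_first) {
    t1w <- correct_bias(t1w, head_mask, params$bias_poly_order)
    t2w <- correct_bias(t2w, head_mask, params$bias_poly_order)
  }
  t1c <- calibrate_intensities(t1w, ref_masks, params$anchor_targets_t1,
                               params$kde_bandwidth_frac)
  t2c <- calibrate_intensities(t2w, ref_masks, params$anchor_targets_t2,
                               params$kde_bandwidth_frac)
  compute_ratio(t1c, t2c, chp_mask)
}
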