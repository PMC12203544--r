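# Two-stage intensity-cluster segmentation of the choroid plexus inside a
# lateral-ventricle mask. Stage 1 splits ventricular voxels into CSF-dark and
# bright clusters with a two-component Gaussian mixture; the bright cluster
# is SUSAN-smoothed and a three-component mixture on the smoothed intensities
# retains the highest-mean component as the final plexus mask.

#' Segment the choroid plexus within a ventricle mask
#'
#' @param t1w 3D T1-weighted intensity array.
#' @param ventricle_mask Logical array of the same dimension; non-empty.
#' @param voxel_dims Voxel size in mm per axis.
#' @param icv_ml Total intracranial volume in ml (> 0), used for
#'   normalization.
#' @param params A [seg_params()] object.
#' @return Object of class `chp_segmentation`: `mask` (logical array),
#'   `volume_ml`, `normalized_volume` (volume / ICV), `stage1_fit`,
#'   `stage2_fit` (both [fit_gmm()] results), `stage1_mask`, and
#'   `brightness_thresh` used for smoothing.
#' @export
segment_chp <- function(t1w, ventricle_mask, voxel_dims = c(1, 1, 1),
                        icv_ml, params = seg_params()) {
  if (!identical(dim(t1w), dim(ventricle_mask)))
    stop("t1w and ventricle_mask dimensions differ")
  if (!any(ventricle_mask)) stop("ventricle_mask is empty")
  if (icv_ml <= 0) stop("icv_ml must be > 0")

  vals <- t1w[ventricle_mask]
  stage1 <- fit_gmm(vals, 2L, params)
  keep <- stage1$assignment == 2L   # higher-mean component
  if (!any(keep)) stop("stage-1 high-intensity cluster is empty")
  stage1_mask <- array(FALSE, dim(t1w))
  stage1_mask[which(ventricle_mask)[keep]] <- TRUE

  # brightness threshold as a fraction of the robust in-ventricle range, so
  # the pipeline is invariant to affine intensity rescaling
  q <- stats::quantile(vals, c(0.02, 0.98), names = FALSE)
  bt <- params$susan_brightness_frac * max(q[2] - q[1],
                                           .Machine$double.eps)
  smoothed <- susan_smooth(t1w, stage1_mask, params$susan_sigma_mm, bt,
                           voxel_dims)
  stage2 <- fit_gmm(smoothed[stage1_mask], 3L, params)
  final <- array(FALSE, dim(t1w))
  final[which(stage1_mask)[stage2$assignment == 3L]] <- TRUE

  vol_ml <- sum(final) * prod(voxel_dims) / 1000
  structure(list(mask = final, volume_ml = vol_ml,
                 normalized_volume = normalized_volume(vol_ml, icv_ml),
                 stage1_fit = stage1, stage2_fit = stage2,
                 stage1_mask = stage1_mask, brightness_thresh = bt),
            class = "chp_segmentation")
}

#' Normalize a regional volume by intracranial volume
#'
#' Plain quotient `volume_ml / icv_ml`; regional volumes are conventionally
#' reported as this ratio multiplied by 1000.
#'
#' @param volume_ml Regional volume in ml (>= 0).
#' @param icv_ml Total intracranial volume in ml (> 0).
#' @return Unitless normalized volume.
#' @examples
#' normalized_volume(1.6, 1000) * 1000  # 1.6, typical choroid plexus scale
#' @export
normalized_volume <- function(volume_ml, icv_ml) {
  if (icv_ml <= 0) stop("icv_ml must be > 0")
  volume_ml / icv_ml
}
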