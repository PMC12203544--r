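# Synthetic co-registered T1w/T2w phantom with ventricles, embedded choroid
# plexus, reference-tissue regions, multiplicative bias and noise. Everything
# the imaging stages consume is generated here with full ground truth, so the
# segmentation and ratio pipelines are testable without scanner data.

#' Specification of a synthetic T1w/T2w phantom
#'
#' Bundles the geometry, per-class intensities, noise and bias settings used
#' by [make_phantom()]. Tissue classes are `csf`, `chp` (choroid plexus),
#' `soft_tissue`, `bone` and `background`. On T1w the choroid plexus must be
#' brighter than ventricular CSF; on T2w CSF must be brighter than the plexus
#' (that intensity reversal is what the two-stage segmentation exploits).
#'
#' @param grid_shape Integer vector of length 3, voxels per axis (all >= 16).
#' @param voxel_dims Numeric vector of length 3, voxel size in mm (all > 0).
#' @param chp_voxel_count Number of choroid-plexus voxels to grow.
#' @param tissue_means_t1,tissue_means_t2 Named numeric vectors of class mean
#'   intensities (`csf`, `chp`, `soft_tissue`, `bone`, `background`).
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param bias_amplitude Half-range `a` of the multiplicative bias field,
#'   which is rescaled into `[1 - a, 1 + a]` (>= 0).
#' @param rician If `TRUE`, noise is applied as the magnitude of a complex
#'   Gaussian perturbation (Rician-like) instead of plain additive Gaussian.
#' @param seed Integer seed; phantoms are bit-reproducible given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 56L, 44L),
                         voxel_dims = c(1, 1, 1),
                         chp_voxel_count = 500L,
                         tissue_means_t1 = c(background = 0, csf = 20, chp = 70,
                                             soft_tissue = 100, bone = 140),
                         tissue_means_t2 = c(background = 0, csf = 140, chp = 70,
                                             soft_tissue = 60, bone = 20),
                         noise_sd = 5,
                         bias_amplitude = 0.1,
                         rician = FALSE,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 16))
    stop("grid_shape must be three integers, all >= 16")
  if (length(voxel_dims) != 3 || any(voxel_dims <= 0))
    stop("voxel_dims must be three positive numbers")
  need <- c("background", "csf", "chp", "soft_tissue", "bone")
  if (!all(need %in% names(tissue_means_t1)) ||
      !all(need %in% names(tissue_means_t2)))
    stop("tissue means must name classes: ", paste(need, collapse = ", "))
  if (tissue_means_t1[["chp"]] <= tissue_means_t1[["csf"]])
    stop("on T1w the choroid plexus must be brighter than CSF")
  if (tissue_means_t2[["csf"]] <= tissue_means_t2[["chp"]])
    stop("on T2w CSF must be brighter than the choroid plexus")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (bias_amplitude < 0) stop("bias_amplitude must be >= 0")
  if (chp_voxel_count < 1) stop("chp_voxel_count must be positive")
  structure(list(grid_shape = grid_shape, voxel_dims = as.numeric(voxel_dims),
                 chp_voxel_count = as.integer(chp_voxel_count),
                 tissue_means_t1 = tissue_means_t1[need],
                 tissue_means_t2 = tissue_means_t2[need],
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 rician = isTRUE(rician), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth strictly positive multiplicative field: exponential of a random
# degree-2 polynomial over [-1,1]^3 coordinates, linearly rescaled into
# [1 - a, 1 + a]. Returns all-ones when a = 0.
random_bias_field <- function(grid_shape, amplitude) {
  d <- grid_shape
  if (amplitude == 0) return(array(1, d))
  cx <- seq(-1, 1, length.out = d[1])
  cy <- seq(-1, 1, length.out = d[2])
  cz <- seq(-1, 1, length.out = d[3])
  X <- array(rep(cx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)
  b <- stats::rnorm(9, sd = 0.5)
  f <- exp(b[1] * X + b[2] * Y + b[3] * Z + b[4] * X * Y + b[5] * X * Z +
           b[6] * Y * Z + b[7] * X^2 + b[8] * Y^2 + b[9] * Z^2)
  rng <- range(f)
  if (rng[2] - rng[1] < .Machine$double.eps) return(array(1, d))
  (1 - amplitude) + 2 * amplitude * (f - rng[1]) / (rng[2] - rng[1])
}

# mm coordinate arrays for a grid.
coord_arrays <- function(grid_shape, voxel_dims) {
  d <- grid_shape
  x <- (seq_len(d[1]) - 0.5) * voxel_dims[1]
  y <- (seq_len(d[2]) - 0.5) * voxel_dims[2]
  z <- (seq_len(d[3]) - 0.5) * voxel_dims[3]
  list(X = array(rep(x, times = d[2] * d[3]), d),
       Y = array(rep(rep(y, each = d[1]), times = d[3]), d),
       Z = array(rep(z, each = d[1] * d[2]), d))
}

#' Generate a synthetic co-registered T1w/T2w phantom pair
#'
#' Builds a head-like volume: an outer bone shell, soft-tissue interior, a
#' pair of curved tube-shaped lateral ventricles filled with CSF, and a
#' connected frond-like choroid plexus grown by seeded region growth along
#' the medial ventricular wall. Intensities are class mean times a smooth
#' multiplicative bias field plus additive Gaussian noise (clipped at zero);
#' the boundary voxels of the curved ventricle create the partial-volume-like
#' intensity gradations that stress the mixture-model segmentation.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_pair`: list with `t1w`, `t2w`
#'   (3D intensity arrays), `ventricle_mask`, `chp_truth_mask`, `ref_masks`
#'   (list `csf`, `bone`, `soft_tissue`, pairwise disjoint), `bias_t1`,
#'   `bias_t2`, `icv_ml`, `voxel_dims`, and the generating `spec`.
#' @examples
#' p <- make_phantom(phantom_spec(noise_sd = 0, bias_amplitude = 0))
#' sum(p$chp_truth_mask) * prod(p$voxel_dims) / 1000  # ground-truth ChP ml
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$grid_shape
    vd <- spec$voxel_dims
    co <- coord_arrays(d, vd)
    ctr <- c(d[1] / 2 * vd[1], d[2] / 2 * vd[2], d[3] / 2 * vd[3])
    ext <- d * vd

    # Outer head and inner cranial-cavity ellipsoids.
    s_out <- 0.46 * ext
    s_in <- 0.88 * s_out
    r_out <- ((co$X - ctr[1]) / s_out[1])^2 + ((co$Y - ctr[2]) / s_out[2])^2 +
             ((co$Z - ctr[3]) / s_out[3])^2
    r_in <- ((co$X - ctr[1]) / s_in[1])^2 + ((co$Y - ctr[2]) / s_in[2])^2 +
            ((co$Z - ctr[3]) / s_in[3])^2
    head_mask <- r_out <= 1
    cavity <- r_in <= 1
    bone_mask <- head_mask & !cavity

    # Lateral ventricles: two curved tubes running anterior-posterior.
    vent <- array(FALSE, d)
    n_samp <- 160
    u <- seq(0, 1, length.out = n_samp)
    for (side in c(-1, 1)) {
      px <- ctr[1] + side * (0.10 * ext[1] + 0.05 * ext[1] * sin(pi * u))
      py <- ctr[2] + (u - 0.5) * 0.55 * ext[2]
      pz <- ctr[3] + 0.06 * ext[3] * cos(pi * u)
      rad <- (2.3 + 1.2 * sin(pi * u)) * min(vd)
      for (s in seq_len(n_samp)) {
        dd <- (co$X - px[s])^2 + (co$Y - py[s])^2 + (co$Z - pz[s])^2
        vent <- vent | (dd <= rad[s]^2)
      }
    }
    vent <- vent & cavity

    # Choroid plexus: seeded region growth on the medial wall of the left
    # ventricle; priority favors voxels near the midline with jitter so the
    # mask develops irregular fronds while staying 6-connected.
    left <- vent & (co$X < ctr[1])
    cand <- which(left)
    if (spec$chp_voxel_count > length(cand))
      stop("chp_voxel_count exceeds ventricle capacity (",
           length(cand), " voxels available)")
    medial_dist <- abs(co$X - ctr[1])
    ap_dist <- abs(co$Y - ctr[2])
    prio <- medial_dist + 0.15 * ap_dist +
      array(stats::runif(prod(d), 0, 0.5 * min(vd)), d)
    seed_vox <- cand[which.min(medial_dist[cand] + 0.01 * ap_dist[cand])]
    chp <- grow_region(left, seed_vox, spec$chp_voxel_count, prio, d)

    # Reference regions: disjoint by construction; the CSF reference keeps
    # clear of the partial-volume boundary layers below.
    ref_csf <- erode_one_voxel(vent) & !dilate6(chp)
    ref_soft <- cavity & (r_in <= 0.8) & !dilate6(vent)
    ref_bone <- bone_mask

    class_idx <- array(1L, d)                    # background
    class_idx[bone_mask] <- 5L
    class_idx[cavity & !vent] <- 4L              # soft tissue
    class_idx[vent] <- 2L                        # csf
    class_idx[chp] <- 3L
    cls_names <- c("background", "csf", "chp", "soft_tissue", "bone")

    # Partial-volume boundary layers: CSF voxels facing the choroid plexus
    # mix CSF with plexus signal, CSF voxels on the ventricular wall mix CSF
    # with parenchyma. These intermediate intensities are what the second,
    # three-component clustering stage has to strip from the plexus mask.
    # Class interiors (including every true plexus voxel) stay exact.
    pv_chp <- vent & !chp & dilate6(chp)
    pv_wall <- vent & !chp & !pv_chp & !erode_one_voxel(vent)
    # the ventricle mask is drawn conservatively, so wall voxels stay
    # majority-CSF; plexus-facing voxels span a wider mixing range
    f_chp <- stats::runif(sum(pv_chp), 0.2, 0.7)
    f_wall <- stats::runif(sum(pv_wall), 0.15, 0.55)

    bias_t1 <- random_bias_field(d, spec$bias_amplitude)
    bias_t2 <- random_bias_field(d, spec$bias_amplitude)

    mk_vol <- function(means, bias) {
      base <- array(means[cls_names][class_idx], d)
      base[pv_chp] <- (1 - f_chp) * means[["csf"]] + f_chp * means[["chp"]]
      base[pv_wall] <- (1 - f_wall) * means[["csf"]] +
        f_wall * means[["soft_tissue"]]
      v <- base * bias
      if (spec$noise_sd > 0) {
        if (spec$rician) {
          v <- sqrt((v + stats::rnorm(length(v), sd = spec$noise_sd))^2 +
                    stats::rnorm(length(v), sd = spec$noise_sd)^2)
        } else {
          v <- v + stats::rnorm(length(v), sd = spec$noise_sd)
        }
      }
      pmax(v, 0)
    }
    t1w <- mk_vol(spec$tissue_means_t1, bias_t1)
    t2w <- mk_vol(spec$tissue_means_t2, bias_t2)

    icv_ml <- sum(cavity) * prod(vd) / 1000

    structure(list(t1w = t1w, t2w = t2w,
                   ventricle_mask = vent, chp_truth_mask = chp,
                   ref_masks = list(csf = ref_csf, bone = ref_bone,
                                    soft_tissue = ref_soft),
                   bias_t1 = bias_t1, bias_t2 = bias_t2,
                   head_mask = head_mask, icv_ml = icv_ml,
                   voxel_dims = vd, spec = spec),
              class = "phantom_pair")
  })
}

# Seeded region growth: repeatedly take the lowest-priority frontier voxel
# (6-connectivity, restricted to `domain`) until `n` voxels are collected.
grow_region <- function(domain, seed_vox, n, prio, d) {
  grown <- array(FALSE, d)
  in_frontier <- array(FALSE, d)
  frontier <- seed_vox
  in_frontier[seed_vox] <- TRUE
  strides <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -(d[1] * d[2]))
  total <- prod(d)
  count <- 0L
  while (count < n) {
    if (!length(frontier))
      stop("chp_voxel_count exceeds the connected ventricle region")
    pick <- which.min(prio[frontier])
    v <- frontier[pick]
    frontier <- frontier[-pick]
    grown[v] <- TRUE
    count <- count + 1L
    ai <- arrayInd(v, d)
    for (k in seq_len(6)) {
      # guard axis wrap-around at array faces
      if ((k == 1L && ai[1] == d[1]) || (k == 2L && ai[1] == 1L) ||
          (k == 3L && ai[2] == d[2]) || (k == 4L && ai[2] == 1L) ||
          (k == 5L && ai[3] == d[3]) || (k == 6L && ai[3] == 1L)) next
      nb <- v + strides[k]
      if (nb < 1L || nb > total) next
      if (domain[nb] && !grown[nb] && !in_frontier[nb]) {
        frontier <- c(frontier, nb)
        in_frontier[nb] <- TRUE
      }
    }
  }
  grown
}

#' Write a phantom pair to NIfTI files with a JSON ground-truth sidecar
#'
#' Writes `t1w.nii.gz`, `t2w.nii.gz`, all masks and the two bias fields as
#' NIfTI-1 volumes with a diagonal affine carrying the voxel dimensions, plus
#' `ground_truth.json` with the intracranial volume, class means and seed.
#'
#' @param pair A `phantom_pair` from [make_phantom()].
#' @param directory Output directory (created if missing).
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_phantom <- function(pair, directory) {
  stopifnot(inherits(pair, "phantom_pair"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", directory)
  vols <- list(t1w = pair$t1w, t2w = pair$t2w,
               ventricle_mask = pair$ventricle_mask * 1,
               chp_truth_mask = pair$chp_truth_mask * 1,
               ref_csf = pair$ref_masks$csf * 1,
               ref_bone = pair$ref_masks$bone * 1,
               ref_soft_tissue = pair$ref_masks$soft_tissue * 1,
               head_mask = pair$head_mask * 1,
               bias_t1 = pair$bias_t1, bias_t2 = pair$bias_t2)
  paths <- character(0)
  for (nm in names(vols)) {
    f <- file.path(directory, paste0(nm, ".nii.gz"))
    img <- RNifti::asNifti(vols[[nm]])
    RNifti::pixdim(img) <- pair$voxel_dims
    ok <- try(RNifti::writeNifti(img, f), silent = TRUE)
    if (inherits(ok, "try-error")) stop("failed to write NIfTI file: ", f)
    paths[nm] <- f
  }
  side <- file.path(directory, "ground_truth.json")
  gt <- list(icv_ml = pair$icv_ml,
             chp_voxel_count = sum(pair$chp_truth_mask),
             chp_volume_ml = sum(pair$chp_truth_mask) *
               prod(pair$voxel_dims) / 1000,
             voxel_dims = pair$voxel_dims,
             tissue_means_t1 = as.list(pair$spec$tissue_means_t1),
             tissue_means_t2 = as.list(pair$spec$tissue_means_t2),
             noise_sd = pair$spec$noise_sd,
             bias_amplitude = pair$spec$bias_amplitude,
             seed = pair$spec$seed)
  jsonlite::write_json(gt, side, auto_unbox = TRUE, digits = NA)
  paths["ground_truth"] <- side
  invisible(paths)
}
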