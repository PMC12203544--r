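# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Shift a 3D array by integer voxel offsets; out[i,j,k] = a[i-dx, j-dy, k-dz],
# padding with `fill`. Used by erosion/dilation and the SUSAN kernel loop.
shift3d <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, off) {
    from <- max(1L, 1L - off); to <- min(n, n - off)
    if (from > to) integer(0) else from:to
  }
  sx <- src(d[1], dx); sy <- src(d[2], dy); sz <- src(d[3], dz)
  if (!length(sx) || !length(sy) || !length(sz)) return(out)
  out[sx + dx, sy + dy, sz + dz] <- a[sx, sy, sz]
  out
}

# One-voxel binary dilation, 6-connectivity.
dilate6 <- function(mask) {
  m <- mask
  for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    m <- m | shift3d(mask, o[1], o[2], o[3], fill = FALSE)
  m
}

# Connected-component count under 6-connectivity (flood fill); used to check
# mask topology.
n_components6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  comp <- 0L
  nbr_off <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  for (start in idx) {
    if (lab[start]) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(v, d)
      for (r in seq_len(6)) {
        p <- ai + nbr_off[r, , drop = FALSE]
        if (any(p < 1L) || any(p > d)) next
        li <- p[1] + (p[2] - 1L) * d[1] + (p[3] - 1L) * d[1] * d[2]
        if (mask[li] && !lab[li]) {
          lab[li] <- comp
          queue <- c(queue, li)
        }
      }
    }
  }
  comp
}

#' Dice overlap coefficient between two binary masks
#'
#' Computes \eqn{2|A \cap B| / (|A| + |B|)}, the standard spatial-overlap
#' metric for comparing a segmentation against a reference mask.
#'
#' @param a,b Logical arrays of identical dimension.
#' @return A number in \[0, 1\]; 1 for identical non-empty masks. Two empty
#'   masks give 1 by convention.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Summarize the voxelwise difference between two masks
#'
#' A small QC utility reporting where two segmentations disagree, in place of
#' interactive manual mask editing.
#'
#' @param a,b Logical arrays of identical dimension (e.g. automatic vs
#'   reference segmentation).
#' @return List with counts `only_a`, `only_b`, `both`, and `dice`.
#' @export
mask_diff <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  list(only_a = sum(a & !b), only_b = sum(!a & b), both = sum(a & b),
       dice = dice_coefficient(a, b))
}
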