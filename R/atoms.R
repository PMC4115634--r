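# Registration atoms: the elementary image operations every pipeline is
# built from. All atoms are deterministic (fixed iteration counts, no
# randomized starts): identical inputs give bit-identical outputs.

#' Gaussian blur of a volume
#'
#' @param v `mp_volume`.
#' @param fwhm kernel full-width-at-half-maximum in mm (>= 0; 0 = no-op).
#' @return blurred `mp_volume` (mask carried through unchanged).
#' @export
gaussian_blur <- function(v, fwhm) {
  stopifnot(inherits(v, "mp_volume"))
  smooth_field(v, fwhm)
}

#' Resample a volume through a transform
#'
#' Pull-back convention: `t` maps the `like` grid's world coordinates into
#' `v`'s world space; the output lives on `like`'s grid. Intensities are
#' interpolated trilinearly, labels nearest-neighbour; points mapping
#' outside `v`'s field of view become 0.
#'
#' @param v `mp_volume` or `mp_labels` to resample.
#' @param t transform (affine, field or chain) mapping like-space to
#'   v-space; `NULL` means identity.
#' @param like volume defining the output grid (defaults to `v`).
#' @return resampled object of the same kind as `v`.
#' @export
resample_volume <- function(v, t = NULL, like = v) {
  g <- grid_spec(like)
  pts <- grid_world_points(g$affine, g$dim)
  if (!is.null(t)) pts <- apply_transform(t, pts)
  if (inherits(v, "mp_labels")) {
    vals <- sample_labels(v, pts)
    label_volume(array(vals, g$dim), g$affine)
  } else {
    vals <- sample_volume(v, pts, outside = "zero")
    volume(array(vals, g$dim), g$affine,
           mask = if (inherits(like, "mp_volume")) like$mask)
  }
}

#' Voxel-wise average of volumes
#'
#' @param vs list of `mp_volume`s on a common grid.
#' @return `mp_volume` holding the arithmetic mean.
#' @export
average_volumes <- function(vs) {
  stopifnot(length(vs) >= 1)
  d0 <- dim(vs[[1]]$data)
  a0 <- vs[[1]]$affine
  for (v in vs) {
    if (!identical(dim(v$data), d0) || max(abs(v$affine - a0)) > 1e-6)
      stop("volumes must share a common grid")
  }
  acc <- array(0, d0)
  for (v in vs) acc <- acc + v$data
  masks <- Filter(Negate(is.null), lapply(vs, `[[`, "mask"))
  mask <- if (length(masks)) Reduce(`|`, masks)
  volume(acc / length(vs), a0, mask)
}

#' Global intensity normalization
#'
#' Rescales a volume multiplicatively so its mean intensity inside the mask
#' (or everywhere, if unmasked) equals `reference_mean`.
#'
#' @param v `mp_volume`.
#' @param reference_mean target mean intensity (> 0).
#' @return rescaled `mp_volume`.
#' @export
normalize_intensity <- function(v, reference_mean) {
  stopifnot(inherits(v, "mp_volume"), reference_mean > 0)
  m <- if (!is.null(v$mask)) mean(v$data[v$mask]) else mean(v$data)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize: non-positive mean intensity")
  volume(v$data * (reference_mean / m), v$affine, v$mask)
}

#' Majority-vote label fusion
#'
#' Per-voxel modal label over a stack of aligned label volumes; ties are
#' broken by the smallest label value.
#'
#' @param labels list of `mp_labels` on a common grid.
#' @return fused `mp_labels`.
#' @export
voxel_vote <- function(labels) {
  stopifnot(length(labels) >= 1)
  d0 <- dim(labels[[1]]$data)
  a0 <- labels[[1]]$affine
  for (l in labels) {
    if (!identical(dim(l$data), d0) || max(abs(l$affine - a0)) > 1e-6)
      stop("label volumes must share a common grid")
  }
  stack <- vapply(labels, function(l) as.integer(l$data),
                  integer(prod(d0)))
  stack <- matrix(stack, nrow = prod(d0))
  cand <- sort(unique(as.vector(stack)))
  fused <- cpp_voxel_vote(stack, as.integer(cand))
  label_volume(array(fused, d0), a0)
}

# ---- similarity metrics (internal) ----------------------------------------

# Both metrics are formulated as losses (smaller is better).
metric_value <- function(moving_vals, fixed_vals, metric) {
  if (metric == "ssd") {
    mean((moving_vals - fixed_vals)^2)
  } else if (metric == "ncc") {
    mm <- moving_vals - mean(moving_vals)
    ff <- fixed_vals - mean(fixed_vals)
    denom <- sqrt(sum(mm^2) * sum(ff^2))
    if (denom < .Machine$double.eps) return(1)
    1 - (sum(mm * ff) / denom)^2
  } else stop("unknown metric: ", metric)
}

#' Dice overlap of one label between two segmentations
#'
#' @param a,b `mp_labels` on a common grid.
#' @param label label value to score.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b, label) {
  aa <- a$data == label
  bb <- b$data == label
  denom <- sum(aa) + sum(bb)
  if (denom == 0) return(NA_real_)
  2 * sum(aa & bb) / denom
}
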