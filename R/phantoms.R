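# Labeled ellipsoid "brain" phantoms and synthetic cohorts.
#
# These stand in for real structural scans: an outer tissue ellipsoid
# (the brain) containing nested/offset ellipsoidal structures with
# distinct intensities and labels 1..n on background 0, optionally pushed
# through known affine + smooth nonlinear deformations with additive
# noise. Every generator is deterministic given its seed, and ground
# truth is returned so registration accuracy can be scored exactly.

#' Phantom specification
#'
#' @param shape integer triple of grid dimensions.
#' @param spacing isotropic voxel size in mm.
#' @param n_structures number of labeled internal ellipsoids (1..6).
#' @param noise_sd additive Gaussian noise, as a fraction of the intensity
#'   contrast range.
#' @param seed RNG seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48, 48, 48), spacing = 1.0,
                         n_structures = 4, noise_sd = 0.02, seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 16), spacing > 0,
            n_structures >= 1, n_structures <= 6, noise_sd >= 0)
  structure(list(shape = as.integer(shape), spacing = spacing,
                 n_structures = as.integer(n_structures),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ellipsoid membership on a voxel grid: centre and semi-axes are given as
# fractions of the grid extent.
ellipsoid_mask <- function(shape, centre_frac, semi_frac) {
  i <- (0:(shape[1] - 1)) / (shape[1] - 1)
  j <- (0:(shape[2] - 1)) / (shape[2] - 1)
  k <- (0:(shape[3] - 1)) / (shape[3] - 1)
  di <- (i - centre_frac[1]) / semi_frac[1]
  dj <- (j - centre_frac[2]) / semi_frac[2]
  dk <- (k - centre_frac[3]) / semi_frac[3]
  outer(outer(di^2, dj^2, `+`), dk^2, `+`) <= 1
}

# Fixed layout of internal structures (fractional centres/semi-axes and
# intensities), chosen to be non-overlapping inside the brain ellipsoid.
phantom_layout <- function() {
  list(
    list(c = c(0.38, 0.40, 0.42), s = c(0.10, 0.09, 0.10), int = 0.95),
    list(c = c(0.63, 0.58, 0.55), s = c(0.09, 0.10, 0.08), int = 0.75),
    list(c = c(0.50, 0.36, 0.58), s = c(0.07, 0.06, 0.07), int = 0.60),
    list(c = c(0.42, 0.62, 0.38), s = c(0.06, 0.07, 0.06), int = 0.85),
    list(c = c(0.62, 0.40, 0.40), s = c(0.05, 0.05, 0.06), int = 0.55),
    list(c = c(0.54, 0.55, 0.36), s = c(0.05, 0.05, 0.05), int = 0.90))
}

#' Generate a labeled phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (`mp_volume`, masked), `labels`
#'   (`mp_labels`) and `mask` (logical array).
#' @export
make_labeled_phantom <- function(spec = phantom_spec()) {
  shape <- spec$shape
  affine <- diag(c(spec$spacing, spec$spacing, spec$spacing, 1))
  brain <- ellipsoid_mask(shape, c(0.5, 0.5, 0.5), c(0.38, 0.33, 0.30))
  img <- array(0, shape)
  img[brain] <- 0.35
  lab <- array(0L, shape)
  layout <- phantom_layout()
  for (s in seq_len(spec$n_structures)) {
    el <- layout[[s]]
    m <- ellipsoid_mask(shape, el$c, el$s) & brain
    img[m] <- el$int
    lab[m] <- s
  }
  # soften edges so gradients are informative, then add noise
  v <- smooth_field(volume(img, affine), 1.5 * spec$spacing)
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(spec$seed)
    v$data <- v$data + array(rnorm(prod(shape), sd = spec$noise_sd),
                             shape)
    .Random.seed_restore(old)
  }
  mask_dil <- ellipsoid_mask(shape, c(0.5, 0.5, 0.5), c(0.42, 0.37, 0.34))
  v$mask <- mask_dil
  list(volume = v, labels = label_volume(lab, affine), mask = mask_dil)
}

# Save/restore the global RNG state so seeded generators do not perturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Random smooth invertible deformation
#'
#' Gaussian-smoothed white-noise displacement rescaled to a maximum
#' magnitude, redrawn (bounded retries) until its Jacobian determinant is
#' strictly positive everywhere.
#'
#' @param grid grid description (volume or `list(affine, dim)`).
#' @param max_mm maximum displacement magnitude in mm (must stay below
#'   `fwhm_mm` for invertibility).
#' @param fwhm_mm smoothing kernel fwhm in mm.
#' @param seed RNG seed.
#' @return `mp_field`.
#' @export
random_smooth_deformation <- function(grid, max_mm, fwhm_mm, seed = 1) {
  g <- grid_spec(grid)
  if (max_mm == 0)
    return(displacement_field(array(0, c(g$dim, 3)), g$affine))
  if (max_mm >= fwhm_mm)
    stop("max_mm must be below fwhm_mm for an invertible field")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (try in 1:10) {
    raw <- array(rnorm(prod(g$dim) * 3), c(g$dim, 3))
    f <- smooth_field(displacement_field(raw, g$affine), fwhm_mm)
    mag <- sqrt(apply(f$vectors^2, 1:3, sum))
    f$vectors <- f$vectors * (max_mm / max(mag))
    det <- jacobian_determinant(f)$data
    if (min(det) > 0) return(f)
  }
  stop("could not draw a positive-Jacobian deformation in 10 tries")
}

#' Synthetic cross-sectional cohort with known ground truth
#'
#' Each subject is the base phantom pushed through a known affine
#' (per-subject scales, small rotations/translations) composed with a
#' random smooth warp, plus fresh noise. The returned ground-truth chains
#' map each subject's grid into base space (pull-back), so
#' `resample_volume(base, gt[[i]])` reproduces subject i up to noise and
#' interpolation.
#'
#' @param spec a [phantom_spec()].
#' @param n number of subjects (>= 2).
#' @param scales per-subject isotropic scale factors (recycled to `n`);
#'   these enter the pull-back affine as `1/scale`, so subject i appears
#'   `scales[i]` times larger than base.
#' @param rot_sd_deg sd of per-axis rotations (degrees).
#' @param trans_sd_mm sd of per-axis translations (mm).
#' @param warp_max_mm maximum magnitude of the per-subject smooth warp.
#' @param warp_fwhm_mm smoothness of the warp.
#' @return list with `base` (phantom list), `subjects` (list of
#'   `mp_volume`), `masks`, `truth` (list of `mp_chain`), `scales`.
#' @export
make_cohort <- function(spec = phantom_spec(), n = 4, scales = 1,
                        rot_sd_deg = 2, trans_sd_mm = 1,
                        warp_max_mm = 1.5, warp_fwhm_mm = 8) {
  stopifnot(n >= 2)
  base <- make_labeled_phantom(spec)
  scales <- rep_len(scales, n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1000L)
  d <- dim(base$volume$data)
  centre <- as.numeric(voxel_to_world(base$volume$affine,
                                      matrix((d - 1) / 2, 1)))
  subjects <- vector("list", n)
  masks <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ang <- rnorm(3, sd = rot_sd_deg) * pi / 180
    tr <- rnorm(3, sd = trans_sd_mm)
    p <- c(tr, ang, rep(log(1 / scales[i]), 3), 0, 0, 0)
    A <- affine_transform(params_to_affine(p, centre, 12),
                          dof_tag = "lsq12")
    warp_seed <- spec$seed + 2000L + i
    chain <- if (warp_max_mm > 0) {
      W <- random_smooth_deformation(base$volume, warp_max_mm,
                                     warp_fwhm_mm, seed = warp_seed)
      transform_chain(A, W)
    } else transform_chain(A)
    vol <- resample_volume(base$volume, chain, like = base$volume)
    labm <- resample_volume(label_volume(base$mask + 0L,
                                         base$volume$affine),
                            chain, like = base$volume)
    if (spec$noise_sd > 0)
      vol$data <- vol$data + array(rnorm(prod(d), sd = spec$noise_sd), d)
    vol$mask <- labm$data > 0L
    subjects[[i]] <- vol
    masks[[i]] <- vol$mask
    truth[[i]] <- chain
  }
  list(base = base, subjects = subjects, masks = masks, truth = truth,
       scales = scales)
}

#' Synthetic longitudinal series with known incremental warps
#'
#' Timepoint 1 of each subject is a (rigidly jittered) phantom; each later
#' timepoint applies one more incremental smooth warp of magnitude
#' `growth_per_step_mm`. The incremental ground-truth field `w[t]` maps
#' timepoint `t+1` space to timepoint `t` space (pull-back), so the chain
#' `[w[t2], w[t1]]` maps timepoint 3 back to timepoint 1.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of subjects.
#' @param n_timepoints timepoints per subject (>= 2).
#' @param growth_per_step_mm maximum incremental displacement in mm.
#' @param warp_fwhm_mm smoothness of each incremental warp.
#' @return list with `scans` (list over subjects of lists of
#'   `mp_volume`), `table` (data.frame `subject`, `timepoint`),
#'   `steps` (list over subjects of incremental `mp_field`s),
#'   `cumulative` (list over subjects of `mp_chain` per timepoint, mapping
#'   that timepoint's space back to timepoint 1).
#' @export
make_longitudinal_series <- function(spec = phantom_spec(), n_subjects = 2,
                                     n_timepoints = 3,
                                     growth_per_step_mm = 2,
                                     warp_fwhm_mm = 8) {
  stopifnot(n_timepoints >= 2)
  base <- make_labeled_phantom(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 5000L)
  d <- dim(base$volume$data)
  scans <- vector("list", n_subjects)
  steps <- vector("list", n_subjects)
  cumulative <- vector("list", n_subjects)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    scans[[s]] <- vector("list", n_timepoints)
    steps[[s]] <- vector("list", n_timepoints - 1)
    cumulative[[s]] <- vector("list", n_timepoints)
    base_s <- base$volume
    if (s > 1) {  # distinguish subjects with a small rigid jitter
      ang <- rnorm(3, sd = 1.5) * pi / 180
      tr <- rnorm(3, sd = 1)
      centre <- as.numeric(voxel_to_world(base_s$affine,
                                          matrix((d - 1) / 2, 1)))
      A <- affine_transform(params_to_affine(c(tr, ang, rep(0, 6)),
                                             centre, 12), "lsq6")
      base_s <- resample_volume(base$volume, A, like = base$volume)
      base_s$mask <- base$mask
    }
    cumulative[[s]][[1]] <- transform_chain()
    for (t in seq_len(n_timepoints)) {
      if (t > 1) {
        w <- if (growth_per_step_mm > 0)
          random_smooth_deformation(base_s, growth_per_step_mm,
                                    warp_fwhm_mm,
                                    seed = spec$seed + 100L * s + t)
        else displacement_field(array(0, c(d, 3)), base_s$affine)
        steps[[s]][[t - 1]] <- w
        cumulative[[s]][[t]] <- do.call(
          transform_chain, c(list(w), unclass(cumulative[[s]][[t - 1]])))
      }
      vol <- resample_volume(base_s, cumulative[[s]][[t]], like = base_s)
      if (spec$noise_sd > 0)
        vol$data <- vol$data + array(rnorm(prod(d), sd = spec$noise_sd), d)
      vol$mask <- base$mask
      scans[[s]][[t]] <- vol
      rows[[length(rows) + 1]] <- data.frame(subject = s, timepoint = t)
    }
  }
  list(scans = scans, table = do.call(rbind, rows), steps = steps,
       cumulative = cumulative, base = base)
}
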