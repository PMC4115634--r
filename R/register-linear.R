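# Rigid (6 dof) and full-affine (12 dof) registration by coarse-to-fine
# Nelder-Mead simplex optimization of an intensity similarity metric.
#
# Direction convention: linear_register(source, target) returns the affine
# mapping TARGET world coordinates into SOURCE world coordinates (the
# pull-back needed to resample the source onto the target grid).
#
# Parameterization (about the centre c of the target field of view):
#   y = R(angles) diag(exp(log_scales)) Shear(sh) (x - c) + c + translation
# so rigid parameters are exactly rigid and scales compose multiplicatively.

params_to_affine <- function(p, center, dof) {
  tr <- p[1:3]
  ang <- p[4:6]
  sc <- if (dof >= 12) exp(p[7:9]) else c(1, 1, 1)
  sh <- if (dof >= 12) p[10:12] else c(0, 0, 0)
  rx <- ang[1]; ry <- ang[2]; rz <- ang[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  U <- diag(sc) %*% rbind(c(1, sh[1], sh[2]), c(0, 1, sh[3]), c(0, 0, 1))
  M <- R %*% U
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- center + tr - M %*% center
  A
}

# Inverse of params_to_affine: decompose a 4x4 into the 12-parameter vector
# (translation, ZYX Euler angles, log-scales, shears) about `center`.
affine_to_params <- function(A, center) {
  M <- A[1:3, 1:3]
  qrd <- qr(M)
  Q <- qr.Q(qrd); Rr <- qr.R(qrd)
  s <- sign(diag(Rr)); s[s == 0] <- 1
  Q <- Q %*% diag(s); Rr <- diag(s) %*% Rr
  if (det(Q) < 0) stop("cannot decompose an orientation-reversing affine")
  ry <- -asin(max(-1, min(1, Q[3, 1])))
  rx <- atan2(Q[3, 2], Q[3, 3])
  rz <- atan2(Q[2, 1], Q[1, 1])
  d <- diag(Rr)
  sh <- c(Rr[1, 2] / d[1], Rr[1, 3] / d[1], Rr[2, 3] / d[2])
  tr <- A[1:3, 4] - center + M %*% center
  c(as.numeric(tr), rx, ry, rz, log(d), sh)
}

# Intensity centroid (masked if available), in world mm.
intensity_centroid <- function(v) {
  w <- v$data - min(v$data)
  if (!is.null(v$mask)) w <- w * v$mask
  tot <- sum(w)
  if (tot <= 0) return(voxel_to_world(v$affine,
                                      matrix((dim(v$data) - 1) / 2, 1)))
  d <- dim(v$data)
  ix <- sum(slice_sums(w, 1) * (0:(d[1] - 1))) / tot
  iy <- sum(slice_sums(w, 2) * (0:(d[2] - 1))) / tot
  iz <- sum(slice_sums(w, 3) * (0:(d[3] - 1))) / tot
  voxel_to_world(v$affine, matrix(c(ix, iy, iz), 1))
}

slice_sums <- function(a, axis) {
  apply(a, axis, sum)
}

# Evaluation sample for one level: world points on the target grid
# (subsampled by `step` mm, restricted to the target mask when present)
# plus the fixed target intensities at those points.
level_sample <- function(target_blur, step) {
  sp <- voxel_spacing(target_blur)
  d <- dim(target_blur$data)
  stride <- pmax(1L, as.integer(round(step / sp)))
  ii <- seq(1L, d[1], by = stride[1])
  jj <- seq(1L, d[2], by = stride[2])
  kk <- seq(1L, d[3], by = stride[3])
  idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  if (!is.null(target_blur$mask)) {
    keep <- target_blur$mask[idx]
    idx <- idx[keep, , drop = FALSE]
  } else {
    # implicit foreground mask: drop far-background voxels, which carry
    # no alignment information but dominate the evaluation cost
    vals <- target_blur$data[idx]
    thr <- 0.02 * max(vals)
    if (sum(vals > thr) >= 500) idx <- idx[vals > thr, , drop = FALSE]
  }
  if (nrow(idx) == 0) stop("empty mask overlap: no evaluation points")
  list(pts = voxel_to_world(target_blur$affine, idx - 1),
       fixed = target_blur$data[idx])
}

#' Linear (rigid or affine) registration
#'
#' Coarse-to-fine simplex (Nelder-Mead) minimization of the protocol
#' metric over a 6-dof (translations + rotations) or 12-dof (+ log-scales
#' and shears) parameterization. Each level works on correspondingly
#' blurred images, evaluated on the target grid subsampled at the level's
#' `step` and restricted to the target mask when one is present. The
#' optimization starts from `init`; with the default identity start, the
#' translation is first initialized by aligning intensity centroids.
#' Deterministic given its inputs.
#'
#' @param source moving `mp_volume`.
#' @param target fixed `mp_volume` whose grid defines the evaluation space.
#' @param dof 6 (rigid) or 12 (full affine).
#' @param protocol protocol data.frame; default
#'   [default_linear_protocol()] at the target voxel size.
#' @param init `mp_affine` mapping target space to source space to start
#'   from, or `NULL` for identity + centroid initialization.
#' @return `mp_affine` (tagged `lsq6` or `lsq12`) mapping target world
#'   coordinates to source world coordinates.
#' @export
linear_register <- function(source, target, dof = 6, protocol = NULL,
                            init = NULL) {
  stopifnot(dof %in% c(6, 12))
  if (is.null(protocol))
    protocol <- default_linear_protocol(min(voxel_spacing(target)))
  protocol <- registration_protocol(protocol)
  d <- dim(target$data)
  center <- as.numeric(voxel_to_world(target$affine, matrix((d - 1) / 2, 1)))
  if (is.null(init)) {
    p <- numeric(12)
    cs <- as.numeric(intensity_centroid(source))
    ct <- as.numeric(intensity_centroid(target))
    p[1:3] <- cs - ct
  } else {
    p <- affine_to_params(init$matrix, center)
  }
  sp <- min(voxel_spacing(target))
  fresh_start <- is.null(init)
  for (row in seq_len(nrow(protocol))) {
    pr <- protocol[row, ]
    # for 12 dof, settle the rigid parameters alone at the coarsest level
    # before opening up scales and shears
    n_par <- if (dof == 12 && (row > 1 || nrow(protocol) == 1)) 12L else 6L
    fw <- if (is.na(pr$blur_fwhm)) 0 else pr$blur_fwhm
    tb <- gaussian_blur(target, fw)
    sb <- gaussian_blur(source, fw)
    samp <- level_sample(tb, pr$step)
    objective <- function(q) {
      full <- p
      full[seq_len(n_par)] <- q
      A <- params_to_affine(full, center, dof)
      mapped <- voxel_to_world(A, samp$pts)  # affine application
      vals <- sample_volume(sb, mapped, outside = "zero")
      metric_value(vals, samp$fixed, pr$metric)
    }
    if (row == 1 && fresh_start) {
      # deterministic rotation grid search at the coarsest level: the
      # simplex refines reliably within ~6 degrees, so seed it from the
      # best of a 7-degree-spaced rotation grid
      grid_deg <- seq(-14, 14, by = 7) * pi / 180
      best <- objective(p[seq_len(n_par)])
      best_rot <- p[4:6]
      for (rx in grid_deg) for (ry in grid_deg) for (rz in grid_deg) {
        q <- p[seq_len(n_par)]
        q[4:6] <- c(rx, ry, rz)
        val <- objective(q)
        if (val < best) { best <- val; best_rot <- c(rx, ry, rz) }
      }
      p[4:6] <- best_rot
    }
    q <- p[seq_len(n_par)]
    if (n_par == 6L) {
      # rigid: the simplex is robust over the whole capture range
      scale <- c(rep(2 * sp, 3), rep(0.05, 3)) * pr$param
      for (restart in 1:2) {
        fit <- optim(q, objective, method = "Nelder-Mead",
                     control = list(maxit = pr$iterations, reltol = 1e-10,
                                    parscale = scale))
        q <- fit$par
        scale <- scale * 0.25  # re-start with a tighter simplex
      }
    }
    # quasi-Newton descent: polishes the rigid fit and carries the whole
    # 12-dof refinement, where simplex progress stalls in 12 dimensions
    for (round in 1:2) {
      fit <- optim(q, objective, method = "BFGS",
                   control = list(maxit = pr$iterations, reltol = 1e-9,
                                  parscale = c(rep(1, 3),
                                               rep(0.02, n_par - 3)),
                                  ndeps = rep(1e-4, n_par)))
      q <- fit$par
      if (fit$convergence == 0 && round == 1) break
    }
    p[seq_len(n_par)] <- q
  }
  if (dof == 6) p[7:12] <- 0
  affine_transform(params_to_affine(p, center, dof),
                   dof_tag = if (dof == 6) "lsq6" else "lsq12")
}

# Average affines in parameter space (translations, Euler angles,
# log-scales, shears), used by the pairwise 12-dof consensus: keeps a
# single interpolation per subject and averages scale multiplicatively.
# include_identity adds the subject's own (identity) transform to the
# mean, which centres the consensus space exactly: without it the
# parameter mean over the n-1 transforms to the other subjects
# amplifies each subject's deviation by n/(n-1).
average_affines <- function(affs, center = c(0, 0, 0),
                            include_identity = FALSE) {
  ps <- vapply(affs, function(a) affine_to_params(a$matrix, center),
               numeric(12))
  ps <- matrix(ps, nrow = 12)
  if (include_identity) ps <- cbind(ps, 0)
  p <- rowMeans(ps)
  affine_transform(params_to_affine(p, center, 12), dof_tag = "lsq12")
}
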