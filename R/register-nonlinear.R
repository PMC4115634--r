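# Dense nonlinear registration by demons-style iterative updates.
#
# The displacement field u lives on the target grid and maps target world
# coordinates into source world coordinates: source(x + u(x)) ~ target(x).
# Each protocol row blurs both images, then iterates: per-voxel force from
# the intensity difference and the symmetric image gradient, capped at the
# row's `step` (mm), Gaussian-regularized with the row's `param` fwhm, and
# added to the field. Fixed iteration counts keep the atom deterministic.

# World-space image gradient (nvox x 3) by central differences.
world_gradient <- function(v) {
  inv3 <- solve(v$affine[1:3, 1:3])
  gv <- lapply(1:3, function(ax) diff_axis(v$data, ax))
  g <- matrix(0, length(v$data), 3)
  for (b in 1:3)
    for (c in 1:3)
      g[, b] <- g[, b] + as.vector(gv[[c]]) * inv3[c, b]
  g
}

# Robust intensity scale for normalizing demons forces.
intensity_scale <- function(v) {
  vals <- if (!is.null(v$mask)) v$data[v$mask] else v$data
  q <- quantile(vals, 0.99, names = FALSE)
  if (q <= 0) q <- max(v$data)
  if (q <= 0) q <- 1
  q
}

#' Nonlinear (demons-style) registration
#'
#' Iterative dense registration of a source to a target that are already
#' approximately linearly aligned (run LSQ6/LSQ12 upstream). Returns the
#' full displacement field on the target grid, including the effect of
#' `init` when provided, mapping target world coordinates to source world
#' coordinates.
#'
#' @param source moving `mp_volume`.
#' @param target fixed `mp_volume`; its grid carries the output field and
#'   its mask (when present) restricts the force region.
#' @param protocol protocol data.frame; default
#'   [default_nonlinear_protocol()] at the target voxel size.
#' @param init optional transform or chain (e.g. an LSQ12 affine) mapping
#'   target space to source space, folded into the returned field.
#' @param elastic_fwhm fwhm (mm) of the light total-field smoothing
#'   applied each iteration to keep the field diffeomorphic (default:
#'   two voxels).
#' @return `mp_field` on the target grid.
#' @export
nonlinear_register <- function(source, target, protocol = NULL, init = NULL,
                               elastic_fwhm = NULL) {
  if (is.null(protocol))
    protocol <- default_nonlinear_protocol(min(voxel_spacing(target)))
  protocol <- registration_protocol(protocol)
  if (is.null(elastic_fwhm)) elastic_fwhm <- 2 * min(voxel_spacing(target))
  d <- dim(target$data)
  pts <- grid_world_points(target$affine, d)
  u <- if (is.null(init)) matrix(0, nrow(pts), 3)
       else apply_transform(init, pts) - pts
  u0 <- u  # smooth only the refinement, not any affine initialization
  in_mask <- if (!is.null(target$mask)) {
    as.vector(target$mask)
  } else {
    # implicit foreground: keep forces off the background, where the
    # intensity difference is pure noise and the field would random-walk
    fg <- (target$data > 0.02 * max(target$data)) + 0
    dil <- cpp_gauss_smooth3d(as.numeric(fg), d,
                              rep(2, 3))  # ~2-voxel dilation
    as.vector(array(dil, d) > 0.02)
  }
  lncc_fwhm <- 5 * min(voxel_spacing(target))  # local-window size
  gauss <- function(vec) as.numeric(cpp_gauss_smooth3d(
    vec, d, rep(lncc_fwhm / (2 * sqrt(2 * log(2))), 3)))
  for (row in seq_len(nrow(protocol))) {
    pr <- protocol[row, ]
    fw <- if (is.na(pr$blur_fwhm)) 0 else pr$blur_fwhm
    tb <- gaussian_blur(target, fw)
    sb <- gaussian_blur(source, fw)
    sc <- intensity_scale(tb)
    fvals <- as.vector(tb$data) / sc
    sb_n <- volume(sb$data / sc, sb$affine, sb$mask)
    gf <- world_gradient(volume(tb$data / sc, tb$affine))
    gm_arrs <- lapply(1:3, function(ax) diff_axis(sb_n$data, ax))
    inv3_s <- solve(sb$affine[1:3, 1:3])
    dims_s <- dim(sb$data)
    use_lncc <- pr$metric == "ncc"
    if (use_lncc) {
      mu_f <- gauss(fvals)
      f_c <- fvals - mu_f
      var_f <- pmax(gauss(f_c^2), 1e-8)
    }
    for (it in seq_len(pr$iterations)) {
      warped_pts <- pts + u
      w <- sample_volume(sb_n, warped_pts, outside = "zero")
      # symmetric gradient: fixed-image gradient + moving gradient at the
      # warped position, halved
      vox <- world_to_voxel(sb$affine, warped_pts)
      gm <- matrix(0, nrow(pts), 3)
      for (b in 1:3) {
        acc <- numeric(nrow(pts))
        for (c in 1:3) {
          gv <- cpp_sample_trilinear(as.numeric(gm_arrs[[c]]), dims_s, vox,
                                     0L, 0)
          acc <- acc + gv * inv3_s[c, b]
        }
        gm[, b] <- acc
      }
      g <- 0.5 * (gf + gm)
      force <- matrix(0, nrow(pts), 3)
      if (use_lncc) {
        # local-correlation (CC) ascent force: insensitive to the local
        # contrast mismatch between a sharp subject and a blurred
        # evolving average
        mu_w <- gauss(w)
        w_c <- w - mu_w
        cross <- gauss(f_c * w_c)
        var_w <- pmax(gauss(w_c^2), 1e-8)
        coef <- 2 * cross / (var_f * var_w) *
          (f_c - (cross / var_w) * w_c)
        mag_scale <- sqrt(var_f * var_w)
        ok <- mag_scale > 1e-6
        coef[!ok] <- 0
        force <- (coef * mag_scale) * g  # normalized units, capped below
      } else {
        diffv <- w - fvals
        gmag2 <- rowSums(g^2)
        den <- gmag2 + diffv^2
        ok <- den > 1e-12
        force[ok, ] <- -diffv[ok] * g[ok, , drop = FALSE] / den[ok]
      }
      if (!is.null(in_mask)) force[!in_mask, ] <- 0
      # cap the per-iteration update at `step` mm
      mag <- sqrt(rowSums(force^2))
      cap <- pmin(1, pr$step / pmax(mag, 1e-12))
      force <- force * cap
      # fluid regularization of the incremental update
      if (pr$param > 0) {
        ff <- displacement_field(array(force, c(d, 3)), target$affine)
        force <- matrix(smooth_field(ff, pr$param)$vectors, ncol = 3)
      }
      u <- u + force
      if (elastic_fwhm > 0) {
        resid <- displacement_field(array(u - u0, c(d, 3)), target$affine)
        u <- u0 + matrix(smooth_field(resid, elastic_fwhm)$vectors,
                         ncol = 3)
      }
    }
  }
  displacement_field(array(u, c(d, 3)), target$affine)
}

#' Hierarchical registration (linear then nonlinear)
#'
#' Optional 12-dof linear alignment followed by the multi-blur nonlinear
#' refinement, each stage consuming the previous transform. The returned
#' chain maps target space to source space.
#'
#' @param source moving `mp_volume`.
#' @param target fixed `mp_volume`.
#' @param nlin_protocol nonlinear protocol (default at target voxel size).
#' @param lsq12_protocol linear protocol for the initial affine stage.
#' @param do_lsq12 run the 12-dof linear stage first (default `TRUE`).
#' @return `mp_chain` containing the affine (when `do_lsq12`) and the
#'   residual displacement field.
#' @export
hierarchical_register <- function(source, target, nlin_protocol = NULL,
                                  lsq12_protocol = NULL, do_lsq12 = TRUE) {
  init <- NULL
  if (do_lsq12)
    init <- linear_register(source, target, dof = 12,
                            protocol = lsq12_protocol)
  full <- nonlinear_register(source, target, protocol = nlin_protocol,
                             init = init)
  transform_chain(full)
}
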