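# World-space spatial transforms: affines, dense displacement fields, and
# chains, together with composition, inversion, linear-part extraction,
# Jacobian determinants and Gaussian smoothing.
#
# Conventions: all transforms map world coordinates (mm) to world
# coordinates. A displacement field stores u(x) so the mapping is
# x -> x + u(x), with u interpolated trilinearly off its own grid
# (replicate-edge beyond the grid). A chain [t1, t2, ...] is applied
# left-to-right: x -> t2(t1(x)) ...; the empty chain is the identity.

#' Construct an affine transform
#'
#' @param matrix 4x4 matrix with last row `(0,0,0,1)`.
#' @param dof_tag `"lsq6"` (rigid), `"lsq12"` (full affine) or `"general"`.
#'   `lsq6`-tagged matrices must have an orthonormal 3x3 part.
#' @return An object of class `mp_affine`.
#' @export
affine_transform <- function(matrix = diag(4),
                             dof_tag = c("general", "lsq6", "lsq12")) {
  dof_tag <- match.arg(dof_tag)
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("last affine row must be (0,0,0,1)")
  if (abs(det(matrix[1:3, 1:3])) < 1e-12) stop("affine is singular")
  if (dof_tag == "lsq6") {
    r <- matrix[1:3, 1:3]
    if (max(abs(crossprod(r) - diag(3))) > 1e-6)
      stop("lsq6 affine must have an orthonormal rotation part")
  }
  structure(list(matrix = unname(matrix), dof_tag = dof_tag),
            class = "mp_affine")
}

#' Construct a displacement field
#'
#' @param vectors 4-D array `(nx, ny, nz, 3)` of world-mm displacements.
#' @param affine 4x4 voxel-to-world matrix of the field's grid.
#' @return An object of class `mp_field`.
#' @export
displacement_field <- function(vectors, affine = diag(4)) {
  d <- dim(vectors)
  stopifnot(length(d) == 4, d[4] == 3, all(is.finite(vectors)))
  check_affine(affine)
  structure(list(vectors = vectors, affine = unname(affine)),
            class = "mp_field")
}

#' Construct a transform chain
#'
#' @param ... transforms (`mp_affine`, `mp_field` or `mp_chain`; chains are
#'   flattened), applied left-to-right.
#' @return An object of class `mp_chain`.
#' @export
transform_chain <- function(...) {
  parts <- list(...)
  flat <- list()
  for (p in parts) {
    if (inherits(p, "mp_chain")) flat <- c(flat, unclass(p))
    else if (inherits(p, c("mp_affine", "mp_field"))) flat <- c(flat, list(p))
    else stop("not a transform: ", class(p)[1])
  }
  structure(flat, class = "mp_chain")
}

#' @export
print.mp_affine <- function(x, ...) {
  cat("<mp_affine> (", x$dof_tag, ")\n", sep = "")
  print(signif(x$matrix, 5)); invisible(x)
}

#' @export
print.mp_field <- function(x, ...) {
  cat("<mp_field> ", paste(dim(x$vectors)[1:3], collapse = " x "),
      " grid, max |u| = ", signif(max(abs(x$vectors)), 4), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.mp_chain <- function(x, ...) {
  cat("<mp_chain> of", length(x), "transform(s):",
      paste(vapply(x, function(t) class(t)[1], ""), collapse = " -> "), "\n")
  invisible(x)
}

as_chain <- function(t) {
  if (inherits(t, "mp_chain")) t else transform_chain(t)
}

#' Apply a transform to world points
#'
#' @param t an `mp_affine`, `mp_field` or `mp_chain`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped world coordinates.
#' @export
apply_transform <- function(t, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  if (inherits(t, "mp_affine")) {
    voxel_to_world(t$matrix, pts)  # same 3x3+offset arithmetic
  } else if (inherits(t, "mp_field")) {
    pts + field_at(t, pts)
  } else if (inherits(t, "mp_chain")) {
    for (part in t) pts <- apply_transform(part, pts)
    pts
  } else stop("not a transform: ", class(t)[1])
}

# Interpolate the displacement vectors of a field at world points
# (per-component trilinear, replicate-edge outside the grid).
field_at <- function(f, pts) {
  vox <- world_to_voxel(f$affine, pts)
  d <- dim(f$vectors)[1:3]
  u <- matrix(0, nrow(pts), 3)
  for (c in 1:3)
    u[, c] <- cpp_sample_trilinear(as.numeric(f$vectors[, , , c]), d, vox,
                                   1L, 0)
  u
}

# Sample any transform as a displacement field on a grid.
chain_to_field <- function(t, grid) {
  g <- grid_spec(grid)
  pts <- grid_world_points(g$affine, g$dim)
  mapped <- apply_transform(t, pts)
  u <- mapped - pts
  displacement_field(array(u, c(g$dim, 3)), g$affine)
}

# Accept a volume, field, or list(affine, dim) as a grid description.
grid_spec <- function(grid) {
  if (inherits(grid, c("mp_volume", "mp_labels")))
    list(affine = grid$affine, dim = dim(grid$data),
         mask = if (!is.null(grid$mask)) grid$mask)
  else if (inherits(grid, "mp_field"))
    list(affine = grid$affine, dim = dim(grid$vectors)[1:3], mask = NULL)
  else if (is.list(grid) && !is.null(grid$affine) && !is.null(grid$dim))
    list(affine = grid$affine, dim = grid$dim, mask = grid$mask)
  else stop("cannot interpret grid specification")
}

#' Compose a transform chain
#'
#' All-affine chains compose exactly to a single matrix product; chains
#' containing a displacement field are sampled pointwise on `grid`.
#'
#' @param t transform or chain.
#' @param grid grid on which to sample a mixed chain (volume, field, or
#'   `list(affine, dim)`); required unless all members are affine.
#' @return `mp_affine` (all-affine chain) or `mp_field`.
#' @export
compose_transform <- function(t, grid = NULL) {
  ch <- as_chain(t)
  if (length(ch) == 0) return(affine_transform(diag(4)))
  if (all(vapply(ch, inherits, TRUE, what = "mp_affine"))) {
    m <- diag(4)
    for (part in ch) m <- part$matrix %*% m
    return(affine_transform(m))
  }
  if (is.null(grid)) stop("grid required to compose a chain with fields")
  chain_to_field(ch, grid)
}

#' Invert a transform
#'
#' Affines invert exactly; chains invert member-wise (reversed order of
#' inverted members). Displacement fields invert by damped fixed-point
#' iteration on `v(x) = -u(x + v(x))` over the field's own grid,
#' stopping when the maximum update falls below the 0.01 mm tolerance
#' (at most 200 iterations); requires displacements small relative to
#' the grid extent.
#' Convergence is assessed at grid points whose iterates stay inside the
#' field's grid — voxels mapping beyond it have no data to invert and
#' keep their extrapolated value.
#'
#' @param t `mp_affine`, `mp_field` or `mp_chain`.
#' @param tol convergence tolerance in mm.
#' @param max_iter iteration cap.
#' @return transform of the same kind (a chain for a chain).
#' @export
invert_transform <- function(t, tol = 0.01, max_iter = 200) {
  if (inherits(t, "mp_affine"))
    return(affine_transform(solve(t$matrix), dof_tag = t$dof_tag))
  if (inherits(t, "mp_chain"))
    return(do.call(transform_chain,
                   lapply(rev(unclass(t)), invert_transform,
                          tol = tol, max_iter = max_iter)))
  if (!inherits(t, "mp_field")) stop("can only invert an affine or a field")
  d <- dim(t$vectors)[1:3]
  pts <- grid_world_points(t$affine, d)
  inside_grid <- function(world) {
    vox <- world_to_voxel(t$affine, world)
    vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
      vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
      vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  }
  v <- matrix(0, nrow(pts), 3)
  resid <- Inf
  # damped iteration: halves the contraction rate but converges for
  # fields whose local Jacobian would make the undamped update oscillate
  for (it in seq_len(max_iter)) {
    v_new <- v + 0.5 * (-field_at(t, pts + v) - v)
    inside <- inside_grid(pts + v_new)
    resid <- if (any(inside)) max(abs((v_new - v)[inside, ])) else Inf
    v <- v_new
    if (resid < tol / 2) break
  }
  if (resid >= tol)
    stop(sprintf("field inversion did not converge (residual %.4f mm)",
                 resid))
  displacement_field(array(v, c(d, 3)), t$affine)
}

#' Extract the best-fit linear (affine) part of a transform
#'
#' Least-squares affine fit of the mapping over the grid's voxel centres
#' (restricted to the grid's mask if one is present).
#'
#' @param t transform or chain.
#' @param grid grid description (volume, field, or `list(affine, dim)`).
#' @return `mp_affine` tagged `"general"`.
#' @export
extract_linear_part <- function(t, grid) {
  g <- grid_spec(grid)
  pts <- grid_world_points(g$affine, g$dim)
  if (!is.null(g$mask)) pts <- pts[as.vector(g$mask), , drop = FALSE]
  if (nrow(pts) < 4) stop("degenerate point set for linear fit")
  y <- apply_transform(t, pts)
  x1 <- cbind(pts, 1)
  b <- tryCatch(qr.solve(x1, y), error = function(e)
    stop("rank-deficient point set for linear fit"))
  m <- diag(4)
  m[1:3, 1:3] <- t(b[1:3, ])
  m[1:3, 4] <- b[4, ]
  affine_transform(m)
}

#' Pure nonlinear component of a full transform
#'
#' Removes the best-fit linear part: the returned field is the displacement
#' of `linear_part o full^{-1}` sampled on `grid`. For an affine-only chain
#' this is (numerically) zero.
#'
#' @param full transform chain mapping common/target space to the subject.
#' @param grid grid description.
#' @return `mp_field`.
#' @export
pure_nonlinear_component <- function(full, grid) {
  lin <- extract_linear_part(full, grid)
  inv <- invert_transform(as_chain(full))
  chain_to_field(transform_chain(lin, inv), grid)
}

# Finite differences of a 3-D array along one axis (central in the
# interior, one-sided at the boundary), in voxel units.
diff_axis <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  denom <- (idx_p - idx_m)
  sel <- function(i) switch(axis,
                            a[i, , , drop = FALSE],
                            a[, i, , drop = FALSE],
                            a[, , i, drop = FALSE])
  out <- (sel(idx_p) - sel(idx_m))
  sweep_dim <- c(1, n, 1)
  scale <- array(rep(1 / denom, each = prod(d[seq_len(axis - 1)])),
                 dim = d)
  out * scale
}

#' Jacobian determinant of a displacement field
#'
#' Determinant of the 3x3 Jacobian of the mapping `x -> x + u(x)`,
#' with gradients taken by central differences in world mm (one-sided at
#' the grid boundary): local volume expansion (>1) or contraction (<1).
#'
#' @param f `mp_field`.
#' @param log_scale return the natural log of the determinant.
#' @return `mp_volume` on the field's grid.
#' @export
jacobian_determinant <- function(f, log_scale = FALSE) {
  stopifnot(inherits(f, "mp_field"))
  d <- dim(f$vectors)[1:3]
  inv3 <- solve(f$affine[1:3, 1:3])
  # G[[a]][[b]] = d u_a / d voxel_b
  jac <- vector("list", 9)  # world-space J entries, row-major a,b
  g_vox <- list()
  for (a in 1:3) {
    ua <- f$vectors[, , , a]
    for (b in 1:3) g_vox[[(a - 1) * 3 + b]] <- diff_axis(ua, b)
  }
  for (a in 1:3) for (b in 1:3) {
    acc <- array(0, d)
    for (c in 1:3)
      acc <- acc + g_vox[[(a - 1) * 3 + c]] * inv3[c, b]
    if (a == b) acc <- acc + 1
    jac[[(a - 1) * 3 + b]] <- acc
  }
  j <- function(a, b) jac[[(a - 1) * 3 + b]]
  det <- j(1, 1) * (j(2, 2) * j(3, 3) - j(2, 3) * j(3, 2)) -
    j(1, 2) * (j(2, 1) * j(3, 3) - j(2, 3) * j(3, 1)) +
    j(1, 3) * (j(2, 1) * j(3, 2) - j(2, 2) * j(3, 1))
  det <- array(det, d)
  if (log_scale) det <- log(det)
  volume(det, f$affine)
}

#' Gaussian smoothing of a volume or displacement field
#'
#' Per-component separable Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` mm, converted to voxel units by the
#' grid spacing; replicate-edge boundary handling. `fwhm = 0` returns the
#' input unchanged.
#'
#' @param f `mp_volume` or `mp_field`.
#' @param fwhm full-width-at-half-maximum of the kernel, in mm (>= 0).
#' @return object of the same kind.
#' @export
smooth_field <- function(f, fwhm) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(f)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  sp <- voxel_spacing(f)
  sigma_vox <- sigma_mm / sp
  if (inherits(f, "mp_volume")) {
    sm <- cpp_gauss_smooth3d(as.numeric(f$data), dim(f$data), sigma_vox)
    volume(array(sm, dim(f$data)), f$affine, f$mask)
  } else if (inherits(f, "mp_field")) {
    d <- dim(f$vectors)
    out <- f$vectors
    for (c in 1:3)
      out[, , , c] <- array(cpp_gauss_smooth3d(as.numeric(f$vectors[, , , c]),
                                               d[1:3], sigma_vox), d[1:3])
    displacement_field(out, f$affine)
  } else stop("smooth_field expects a volume or a displacement field")
}
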