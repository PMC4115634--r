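# Transform algebra: composition, inversion, linear-part extraction,
# Jacobians, smoothing, serialization.

test_that("affine chains compose to matrix products and invert exactly", {
  A <- random_affine(1)
  B <- random_affine(2)
  # [T, T^-1] is the identity
  I <- compose_transform(transform_chain(A, invert_transform(A)))
  expect_lt(max(abs(I$matrix - diag(4))), 1e-9)
  # pure translations cancel
  tr <- function(d) affine_transform(p2a(c(d, rep(0, 9)), c(0, 0, 0), 12))
  I2 <- compose_transform(transform_chain(tr(c(1, 2, 3)),
                                          tr(c(-1, -2, -3))))
  expect_lt(max(abs(I2$matrix - diag(4))), 1e-12)
  # left-to-right order: chain [A, B] maps x -> B(A(x))
  pts <- matrix(rnorm(30), 10)
  expect_equal(apply_transform(transform_chain(A, B), pts),
               apply_transform(B, apply_transform(A, pts)))
  # empty chain is the identity
  expect_equal(apply_transform(transform_chain(), pts), pts)
  # composition is associative on points
  C <- random_affine(3)
  M1 <- compose_transform(transform_chain(A, B, C))$matrix
  M2 <- compose_transform(
    transform_chain(compose_transform(transform_chain(A, B)), C))$matrix
  expect_lt(max(abs(M1 - M2)), 1e-9)
})

test_that("mixed chains sampled on a grid match per-point evaluation", {
  g <- small_grid(9)
  A <- random_affine(4)
  u <- random_smooth_deformation(g, 1.5, 6, seed = 5)
  f <- compose_transform(transform_chain(A, u), grid = g)
  expect_s3_class(f, "mp_field")
  pts <- grid_pts(g$affine, g$dim)
  # brute-force oracle: apply A then add the interpolated displacement
  mid <- apply_transform(A, pts)
  oracle <- mid + morphopipe:::field_at(u, mid) - pts
  expect_lt(max(abs(f$vectors - array(oracle, c(g$dim, 3)))), 1e-9)
})

test_that("field inversion satisfies the composition residual bound", {
  g <- small_grid(24)
  # identity and uniform translation invert in closed form
  zero <- displacement_field(array(0, c(g$dim, 3)), g$affine)
  expect_equal(invert_transform(zero)$vectors, zero$vectors)
  d <- c(1.5, -2, 0.5)
  tr_field <- displacement_field(
    array(rep(d, each = prod(g$dim)), c(g$dim, 3)), g$affine)
  inv <- invert_transform(tr_field)
  interior <- inv$vectors[8:17, 8:17, 8:17, ]
  expect_lt(max(abs(sweep(array(interior, c(10, 10, 10, 3)), 4, -d))),
            0.01)
  # smooth random field: |(u o u^-1)(x) - x| < 0.05 mm in the interior
  u <- random_smooth_deformation(g, 2, 6, seed = 7)
  comp <- compose_transform(transform_chain(u, invert_transform(u)),
                            grid = g)
  expect_lt(max(abs(comp$vectors[6:19, 6:19, 6:19, ])), 0.05)
  # chains invert member-wise
  A <- random_affine(8)
  ch <- transform_chain(A, u)
  ich <- invert_transform(ch)
  pts <- grid_pts(g$affine, g$dim)[seq(200, 13000, by = 400), ]
  round_trip <- apply_transform(ich, apply_transform(ch, pts))
  expect_lt(max(abs(round_trip - pts)), 0.08)
})

test_that("extract_linear_part recovers affine maps and ignores
           zero-mean residuals", {
  g <- small_grid(9)
  A <- random_affine(10)
  expect_lt(max(abs(extract_linear_part(transform_chain(A), g)$matrix -
                      A$matrix)), 1e-6)
  expect_lt(max(abs(extract_linear_part(transform_chain(), g)$matrix -
                      diag(4))), 1e-12)
  # affine plus a residual orthogonal to the affine basis: the fit stays
  # within 1% of A (Frobenius, relative). The residual field's grid is
  # pre-warped by A so its samples land exactly on the evaluated points.
  g2 <- small_grid(16)
  u <- random_smooth_deformation(g2, 1, 6, seed = 11)
  pts <- grid_pts(g2$affine, g2$dim)
  x1 <- cbind(pts, 1)
  resid <- qr.resid(qr(x1), matrix(u$vectors, ncol = 3))
  u_warped <- displacement_field(array(resid, c(g2$dim, 3)),
                                 A$matrix %*% g2$affine)
  L <- extract_linear_part(transform_chain(A, u_warped), g2)
  relerr <- norm(L$matrix - A$matrix, "F") / norm(A$matrix, "F")
  expect_lt(relerr, 0.01)
})

test_that("pure nonlinear component removes exactly the linear part", {
  g <- small_grid(16)
  A <- random_affine(12)
  # affine-only chain: residual < 0.05 mm
  pn <- pure_nonlinear_component(transform_chain(A), g)
  expect_lt(max(abs(pn$vectors)), 0.05)
  # identity chain: zero field
  pn0 <- pure_nonlinear_component(transform_chain(), g)
  expect_lt(max(abs(pn0$vectors)), 1e-9)
  # known warp o affine: recovered nonlinear residual matches the
  # constructed warp within 0.1 mm in the interior. The warp's linear
  # trend is projected out first — a linear trend in the residual is,
  # by definition, part of the linear component being removed.
  V <- random_smooth_deformation(g, 1.0, 6, seed = 13)
  pts2 <- grid_pts(g$affine, g$dim)
  V$vectors <- array(qr.resid(qr(cbind(pts2, 1)),
                              matrix(V$vectors, ncol = 3)),
                     c(g$dim, 3))
  W <- invert_transform(V)
  full <- transform_chain(W, A)
  rec <- pure_nonlinear_component(full, g)
  err <- abs(rec$vectors - V$vectors)[5:12, 5:12, 5:12, ]
  expect_lt(max(err), 0.1)
})

test_that("jacobian determinants match closed forms", {
  g <- small_grid(24)
  # zero field -> 1 everywhere
  zero <- displacement_field(array(0, c(g$dim, 3)), g$affine)
  expect_equal(jacobian_determinant(zero)$data,
               array(1, g$dim))
  # global scaling about the centre: det = s^3
  pts <- grid_pts(g$affine, g$dim)
  ctr <- colMeans(pts)
  for (s in c(1.1, 0.9)) {
    u <- (s - 1) * sweep(pts, 2, ctr)
    f <- displacement_field(array(u, c(g$dim, 3)), g$affine)
    det <- jacobian_determinant(f)$data
    expect_lt(max(abs(det[5:20, 5:20, 5:20] / s^3 - 1)), 0.01)
  }
  # sinusoidal field against the analytic derivative
  g3 <- list(affine = diag(c(0.5, 0.5, 0.5, 1)), dim = c(48, 16, 16))
  pts3 <- grid_pts(g3$affine, g3$dim)
  u3 <- cbind(0.05 * sin(pts3[, 1] / 4), 0, 0)
  f3 <- displacement_field(array(u3, c(g3$dim, 3)), g3$affine)
  det3 <- jacobian_determinant(f3)$data
  truth <- array(1 + 0.0125 * cos(pts3[, 1] / 4), g3$dim)
  expect_lt(max(abs(det3[3:46, , ] / truth[3:46, , ] - 1)), 0.005)
  # log scale flag
  expect_equal(jacobian_determinant(zero, log_scale = TRUE)$data,
               array(0, g$dim))
})

test_that("volume-preserving fields have near-zero mean log-determinant", {
  g <- small_grid(24)
  u <- random_smooth_deformation(g, 1.5, 8, seed = 17)
  ld <- jacobian_determinant(u, log_scale = TRUE)$data
  expect_lt(abs(mean(ld[6:19, 6:19, 6:19])), 0.02)
})

test_that("gaussian smoothing has the right kernel and edge cases", {
  v <- tiny_phantom(16, seed = 3)$volume
  expect_identical(smooth_field(v, 0)$data, v$data)
  expect_error(smooth_field(v, -1), "fwhm")
  # constant volume unchanged (replicate-edge boundary)
  const <- volume(array(3.5, c(12, 12, 12)))
  expect_lt(max(abs(smooth_field(const, 4)$data - 3.5)), 1e-12)
  # unit impulse, fwhm = 2.3548 mm on a 1 mm grid: centre value matches
  # the 3-D gaussian peak (2 pi)^(-3/2) at sigma = 1
  imp <- array(0, c(25, 25, 25)); imp[13, 13, 13] <- 1
  sm <- smooth_field(volume(imp, diag(4)), 2 * sqrt(2 * log(2)))
  expect_lt(abs(sm$data[13, 13, 13] / (2 * pi)^(-3 / 2) - 1), 0.01)
  # anisotropic spacing: sigma is converted per axis
  aff <- diag(c(1, 2, 1, 1))
  sm2 <- smooth_field(volume(imp, aff), 2 * sqrt(2 * log(2)))
  expect_gt(sm2$data[13, 13, 13], sm$data[13, 13, 13])
})

test_that("transforms serialize and deserialize faithfully", {
  td <- withr::local_tempdir()
  A <- random_affine(20)
  pa <- file.path(td, "a.aff.txt")
  write_transform(A, pa)
  A2 <- read_transform(pa)
  expect_lt(max(abs(A2$matrix - A$matrix)), 1e-12)
  expect_identical(A2$dof_tag, A$dof_tag)
  g <- small_grid(10)
  u <- random_smooth_deformation(g, 1, 5, seed = 21)
  pf <- file.path(td, "u.field.nii.gz")
  write_transform(u, pf)
  u2 <- read_transform(pf)
  expect_equal(u2$vectors, u$vectors, tolerance = 1e-12)
  ch <- transform_chain(A, u)
  pc <- file.path(td, "c.chain.json")
  write_transform(ch, pc)
  ch2 <- read_transform(pc)
  expect_length(ch2, 2)
  expect_lt(max(abs(ch2[[1]]$matrix - A$matrix)), 1e-12)
  expect_equal(ch2[[2]]$vectors, u$vectors, tolerance = 1e-12)
})
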