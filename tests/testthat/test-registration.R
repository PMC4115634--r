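# Registration atoms: parameter recovery at small problem sizes (the
# full-size capture-range sweep lives in the acceptance suite).

test_that("registering a volume to itself gives the identity", {
  ph <- tiny_phantom(24, seed = 11)
  A <- linear_register(ph$volume, ph$volume, dof = 6)
  pars <- a2p(A$matrix, c(11.5, 11.5, 11.5))
  expect_lt(max(abs(pars[1:3])), 0.1)          # < 0.1 mm
  expect_lt(max(abs(pars[4:6])) * 180 / pi, 0.1)  # < 0.1 degrees
  expect_identical(A$dof_tag, "lsq6")
  f <- nonlinear_register(ph$volume, ph$volume,
                          protocol = default_nonlinear_protocol(
                            1, iterations = c(10, 10)))
  expect_lt(max(abs(f$vectors)), 0.1)          # < 0.1 voxel
})

test_that("small rigid and affine perturbations are recovered", {
  ph <- tiny_phantom(32, seed = 12)
  base <- ph$volume
  ctr <- c(15.5, 15.5, 15.5)
  gt <- c(2, -3, 1, c(4, -3, 2) * pi / 180, rep(0, 6))
  T <- affine_transform(p2a(gt, ctr, 12))
  subj <- resample_volume(base, T, like = base)
  subj$mask <- base$mask
  A <- linear_register(base, subj, dof = 6)
  rec <- a2p(A$matrix, ctr)
  expect_lt(max(abs(rec[1:3] - gt[1:3])), 0.25)
  expect_lt(max(abs(rec[4:6] - gt[4:6])) * 180 / pi, 0.5)
  # anisotropic scaling needs the 12-dof model
  gt2 <- c(0.5, 0, -0.5, rep(0, 3), log(c(1.10, 0.95, 1.05)), rep(0, 3))
  T2 <- affine_transform(p2a(gt2, ctr, 12))
  subj2 <- resample_volume(base, T2, like = base)
  subj2$mask <- base$mask
  A2 <- linear_register(base, subj2, dof = 12)
  rec2 <- a2p(A2$matrix, ctr)
  expect_lt(max(abs(exp(rec2[7:9] - gt2[7:9]) - 1)), 0.02)
})

test_that("an explicit initial transform is honored", {
  ph <- tiny_phantom(24, seed = 13)
  base <- ph$volume
  ctr <- c(11.5, 11.5, 11.5)
  T <- affine_transform(p2a(c(1.5, -1, 0.5, rep(0, 9)), ctr, 12))
  subj <- resample_volume(base, T, like = base)
  subj$mask <- base$mask
  # start from the truth with a one-row protocol: stays at the truth
  prot <- registration_protocol(data.frame(level = 1, blur_fwhm = 2,
                                           step = 1, param = 1,
                                           iterations = 40,
                                           metric = "ssd"))
  A <- linear_register(base, subj, dof = 6, protocol = prot, init = T)
  expect_lt(max(abs(A$matrix - T$matrix)), 0.05)
})

test_that("masks restrict the evaluation region and empty masks error", {
  ph <- tiny_phantom(24, seed = 14)
  v <- ph$volume
  v$mask <- array(FALSE, dim(v$data))
  expect_error(linear_register(v, v, dof = 6), "empty mask")
})

test_that("demons recovers a known smooth warp and stays diffeomorphic", {
  ph <- tiny_phantom(32, seed = 15)
  base <- ph$volume
  W <- random_smooth_deformation(base, 2, 7, seed = 16)
  subj <- resample_volume(base, W, like = base)
  subj$data <- subj$data + array(rnorm(length(subj$data), sd = 0.02),
                                 dim(subj$data))
  subj$mask <- base$mask
  f <- nonlinear_register(base, subj)
  err <- sqrt(apply((f$vectors - W$vectors)^2, 1:3, sum))
  expect_lt(mean(err[ph$mask]), 0.5)
  expect_gt(min(jacobian_determinant(f)$data[ph$mask]), 0)
})

test_that("the registration metric does not degrade across levels", {
  ph <- tiny_phantom(32, seed = 17)
  base <- ph$volume
  ctr <- c(15.5, 15.5, 15.5)
  T <- affine_transform(p2a(c(2, 1, -1, c(3, 0, -2) * pi / 180,
                              rep(0, 6)), ctr, 12))
  subj <- resample_volume(base, T, like = base)
  subj$mask <- base$mask
  # evaluate the finest-level metric after each truncated protocol
  prot <- default_linear_protocol(1)
  finest_metric <- function(A) {
    tb <- gaussian_blur(subj, 2); sb <- gaussian_blur(base, 2)
    samp <- morphopipe:::level_sample(tb, 1)
    vals <- morphopipe:::sample_volume(
      sb, morphopipe:::voxel_to_world(A$matrix, samp$pts))
    morphopipe:::metric_value(vals, samp$fixed, "ncc")
  }
  ms <- vapply(1:3, function(L)
    finest_metric(linear_register(base, subj, dof = 6,
                                  protocol = prot[1:L, ])), numeric(1))
  expect_true(all(diff(ms) <= 1e-6))
})

test_that("hierarchical registration composes linear and nonlinear", {
  ph <- tiny_phantom(32, seed = 18)
  base <- ph$volume
  ctr <- c(15.5, 15.5, 15.5)
  T <- affine_transform(p2a(c(1, -1, 0.5, c(2, -1, 1) * pi / 180,
                              log(c(1.04, 0.98, 1.02)), rep(0, 3)),
                            ctr, 12))
  subj <- resample_volume(base, T, like = base)
  subj$mask <- base$mask
  ch <- hierarchical_register(base, subj,
                              nlin_protocol = default_nonlinear_protocol(
                                1, iterations = c(15, 10)))
  # affine-only ground truth: nonlinear residual below 0.2 mm mean
  g <- list(affine = base$affine, dim = dim(base$data))
  pts <- grid_pts(g$affine, g$dim)
  mapped <- apply_transform(ch, pts)
  truth <- apply_transform(T, pts)
  err <- sqrt(rowSums((mapped - truth)^2))
  expect_lt(mean(err[as.vector(ph$mask)]), 0.2)
  # identity pair: chain composes to (near) identity
  ch0 <- hierarchical_register(base, base,
                               nlin_protocol = default_nonlinear_protocol(
                                 1, iterations = c(10, 5)))
  disp0 <- apply_transform(ch0, pts) - pts
  expect_lt(mean(abs(disp0[as.vector(ph$mask), ])), 0.15)
})
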