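test_that("bead detection recovers the manifest centroids sub-voxel", {
  ph <- full_phantom()
  low <- full_renders()$low
  fs <- detect_fiducials(low)
  expect_equal(nrow(fs$centroids), 10)
  pairs <- match_fiducials(fs$centroids, ph$bead_centroids)
  d <- sqrt(rowSums((fs$centroids[pairs[, 1], ] -
                     ph$bead_centroids[pairs[, 2], ])^2))
  expect_lt(max(d) / ph$spec$spacing, 0.5)
  # component sizes bracket a 1.6-mm bead; rods and tubes were filtered out
  expect_true(all(fs$voxel_count > 700 & fs$voxel_count < 4500))
})

test_that("detection fails informatively on empty or oversized components", {
  air <- ct_volume(array(-1000, dim = c(20, 20, 20)))
  expect_error(detect_fiducials(air), "no voxels above threshold")
  # a solid bright block forms one component far above the bead size range
  block <- ct_volume(array(1000, dim = c(30, 30, 30)))
  expect_error(detect_fiducials(block), "component sizes found")
})

test_that("marker matching is permutation-invariant and drops outliers", {
  set.seed(42)
  pts <- matrix(runif(30, 0, 16), ncol = 3)
  pts <- pts[as.matrix(dist(pts)) |> apply(1, function(r) min(r[r > 0])) > 2, ]
  n <- nrow(pts)
  expect_gte(n, 4)
  id <- match_fiducials(pts, pts, min_markers = 3)
  expect_equal(id[, "a"], id[, "b"])
  perm <- sample(n)
  m <- match_fiducials(pts[perm, ], pts, min_markers = 3)
  expect_equal(nrow(m), n)
  expect_equal(unname(m[, "b"]), unname(perm[m[, "a"]]))
  # small rigid motion keeps all pairs correct
  t_small <- rigid_transform(euler_rotation(c(1, 1, -1)), c(0.2, 0.2, -0.1))
  m2 <- match_fiducials(transform_points(t_small, pts), pts, min_markers = 3)
  expect_equal(unname(m2[, "a"]), unname(m2[, "b"]))
  expect_error(match_fiducials(pts[1:2, ], pts[1:2, ], min_markers = 3),
               "at least|matched")
})

test_that("rigid fit recovers exact transforms and refuses reflections", {
  set.seed(7)
  pts <- matrix(rnorm(30, sd = 5), ncol = 3)
  expect_equal(fit_rigid(pts, pts)$rotation, diag(3), tolerance = 1e-12)
  r_true <- euler_rotation(c(10, -20, 35))
  t_true <- c(1.5, -2, 0.7)
  moved <- transform_points(rigid_transform(r_true, t_true), pts)
  fit <- fit_rigid(pts, moved)
  expect_lt(max(abs(fit$rotation - r_true)), 1e-9)
  expect_lt(max(abs(fit$translation - t_true)), 1e-9)
  # near-planar points + noise: the unconstrained optimum can be a
  # reflection; the returned rotation must stay proper
  set.seed(8)
  flat <- cbind(matrix(rnorm(20, sd = 5), ncol = 2), rnorm(10, sd = 1e-4))
  target <- flat
  target[, 3] <- -target[, 3] + rnorm(10, sd = 0.05)
  fit2 <- fit_rigid(flat, target)
  expect_gt(det(fit2$rotation), 0.999)
  # collinear configurations error
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_rigid(line, line), "collinear|degenerate")
})

test_that("rigid fit is equivariant under a common rigid motion", {
  set.seed(9)
  a <- matrix(rnorm(24, sd = 4), ncol = 3)
  b <- transform_points(rigid_transform(euler_rotation(c(3, 4, 5)), c(1, 2, 3)), a) +
    matrix(rnorm(24, sd = 0.01), ncol = 3)
  base <- fit_rigid(a, b)
  g <- rigid_transform(euler_rotation(c(-15, 25, 40)), c(5, -3, 2))
  moved_fit <- fit_rigid(transform_points(g, a), transform_points(g, b))
  # conjugation: moved_fit == g base g^-1
  expected <- compose_transforms(compose_transforms(g, base), invert_transform(g))
  expect_lt(max(abs(moved_fit$rotation - expected$rotation)), 1e-8)
  expect_lt(max(abs(moved_fit$translation - expected$translation)), 1e-6)
})

test_that("registration error measures residuals faithfully", {
  set.seed(10)
  pts <- matrix(rnorm(30, sd = 5), ncol = 3)
  t0 <- rigid_transform(euler_rotation(c(2, -1, 4)), c(0.5, 0.2, -0.3))
  moved <- transform_points(t0, pts)
  perfect <- registration_error(t0, pts, moved)
  expect_equal(perfect$fre, 0, tolerance = 1e-12)
  # isotropic noise sigma_n on the fixed points: FRE below 2 sigma_n
  sigma_n <- 0.05
  fre_mc <- replicate(20, {
    noisy <- moved + matrix(rnorm(30, sd = sigma_n), ncol = 3)
    registration_error(fit_rigid(pts, noisy), pts, noisy)$fre
  })
  expect_lt(max(fre_mc), 2 * sigma_n * sqrt(3))
  expect_lt(mean(fre_mc), 2 * sigma_n)
  # a single outlier inflates exactly one residual
  out <- moved
  out[4, ] <- out[4, ] + c(3, 0, 0)
  res <- registration_error(t0, pts, out)$residuals
  expect_equal(which(res > 1), 4L)
})

test_that("resampling aligns misaligned volumes sub-voxel", {
  ph <- small_phantom()
  low <- render_ct(ph, basis_filtered(), "low", noise_sigma = 0)
  # identity resample reproduces the volume on the shared grid
  same <- resample(low, rigid_transform(), low)
  expect_equal(same$values, low$values, tolerance = 1e-12)
  # shift + shift-back round trip: small interpolation error on smooth areas
  t_half <- rigid_transform(translation = c(0.05, 0.05, 0))  # half voxel
  there <- misalign(low, t_half)
  back <- resample(there, invert_transform(t_half), low)
  # uniform soft-tissue region (3+ voxels clear of any structure):
  # round-trip error is pure interpolation error
  core <- low$values[88:94, 74:82, 20:40]
  core_b <- back$values[88:94, 74:82, 20:40]
  expect_true(all(core == 37))
  expect_lt(mean(abs(core - core_b)), 1)
  # across the whole tissue cylinder (with its sharp bone and vessel edges)
  # the error stays bounded by trilinear smoothing of those edges
  tis <- ph$labels %in% 1:3
  expect_lt(mean(abs(low$values[tis] - back$values[tis])), 60)
  # bead centroids after registration-style resampling match the reference
  t_mis <- rigid_about(small_center, euler_rotation(c(1, -0.5, 1.5)),
                       c(0.3, 0.2, -0.2))
  moved <- misalign(low, t_mis)
  aligned <- resample(moved, invert_transform(t_mis), low)
  fs_ref <- detect_fiducials(low)
  fs_ali <- detect_fiducials(aligned)
  pairs <- match_fiducials(fs_ali, fs_ref)
  d <- sqrt(rowSums((fs_ali$centroids[pairs[, 1], ] -
                     fs_ref$centroids[pairs[, 2], ])^2))
  expect_lt(max(d) / ph$spec$spacing, 0.5)
})

test_that("end-to-end rigid recovery is sub-voxel under noise", {
  ph <- small_phantom()
  b <- basis_filtered()
  low <- render_ct(ph, b, "low", noise_sigma = 60, seed = 100)
  center <- small_center
  for (i in 1:3) {
    set.seed(200 + i)
    t_true <- rigid_about(small_center, euler_rotation(runif(3, -3, 3)),
                          runif(3, -0.5, 0.5))
    high <- misalign(render_ct(ph, b, "high", noise_sigma = 60,
                               seed = 300 + i), t_true)
    reg <- register_volumes(low, high)
    resid <- compose_transforms(reg$transform, t_true)
    tre <- sqrt(sum((transform_points(resid, center) - center)^2))
    expect_lt(tre / ph$spec$spacing, 0.5)
    expect_lt(reg$fre, 0.1)  # centroid noise at sigma = 60 HU stays sub-voxel
  }
})
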