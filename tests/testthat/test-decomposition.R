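filtered_basis <- function() basis_filtered()

test_that("the calibration basis is well-conditioned and validated", {
  b <- filtered_basis()
  expect_true(is.finite(b$condition_number))
  expect_equal(unname(b$matrix[3, ]), c(1, 1, 1))
  # two identical material columns make the system singular
  expect_error(build_basis(rbind(c(37, 2743, 2743), c(0, 1909, 1909))),
               "singular|ill-conditioned")
  # losing the spectral-shaping filters degrades the conditioning
  expect_gt(basis_unfiltered()$condition_number, b$condition_number)
})

test_that("pure calibration voxels decompose to pure fractions", {
  b <- filtered_basis()
  mk <- function(l, h) list(
    low = ct_volume(array(l, dim = c(1, 1, 1))),
    high = ct_volume(array(h, dim = c(1, 1, 1))))
  v <- mk(2743, 1909)   # the bone calibration pair
  maps <- decompose(v$low, v$high, b)
  expect_equal(maps$bone$values[1, 1, 1], 10000, tolerance = 1e-9)
  expect_equal(maps$soft_tissue$values[1, 1, 1], 0, tolerance = 1e-9)
  expect_equal(maps$vessel$values[1, 1, 1], 0, tolerance = 1e-9)
  # midpoint of the bone and vessel columns splits 50/50
  v2 <- mk((2743 + 1659) / 2, (1909 + 2059) / 2)
  maps2 <- decompose(v2$low, v2$high, b)
  expect_equal(maps2$bone$values[1, 1, 1], 5000, tolerance = 1e-9)
  expect_equal(maps2$vessel$values[1, 1, 1], 5000, tolerance = 1e-9)
})

test_that("decomposition is linear in the input CT values", {
  b <- filtered_basis()
  set.seed(13)
  alphas <- matrix(runif(30), ncol = 3)
  alphas <- alphas / rowSums(alphas)       # random convex combinations
  l <- alphas %*% b$ct_values["low", ]
  h <- alphas %*% b$ct_values["high", ]
  maps <- decompose(ct_volume(array(l, dim = c(10, 1, 1))),
                    ct_volume(array(h, dim = c(10, 1, 1))), b)
  expect_equal(as.numeric(maps$soft_tissue$values), alphas[, 1] * 10000,
               tolerance = 1e-9)
  expect_equal(as.numeric(maps$bone$values), alphas[, 2] * 10000,
               tolerance = 1e-9)
  expect_equal(as.numeric(maps$vessel$values), alphas[, 3] * 10000,
               tolerance = 1e-9)
})

test_that("unclamped fractions always sum to exactly 10000", {
  b <- filtered_basis()
  set.seed(14)
  l <- ct_volume(array(rnorm(1000, 500, 1500), dim = c(10, 10, 10)))
  h <- ct_volume(array(rnorm(1000, 800, 1500), dim = c(10, 10, 10)))
  maps <- decompose(l, h, b)
  sums <- maps$soft_tissue$values + maps$bone$values + maps$vessel$values
  expect_lt(max(abs(sums - 10000)), 1e-8)
  # clamping clips to the physical range and warns about the sum property
  expect_message(mc <- decompose(l, h, b, clamp = TRUE), "sums may deviate")
  expect_gte(min(mc$soft_tissue$values), 0)
  expect_lte(max(mc$bone$values), 10000)
})

test_that("grid mismatches are refused", {
  b <- filtered_basis()
  l <- ct_volume(array(0, dim = c(4, 4, 4)))
  h <- ct_volume(array(0, dim = c(4, 4, 5)))
  expect_error(decompose(l, h, b), "same grid")
  h2 <- ct_volume(array(0, dim = c(4, 4, 4)), spacing = 0.2)
  expect_error(decompose(l, h2, b), "same grid")
})

test_that("decompose-render inversion is exact on noiseless data", {
  ph <- full_phantom()
  r <- full_renders()
  maps <- decompose(r$low, r$high, basis_filtered())
  m <- pure_material_mask(ph)
  expect_gt(sum(m), 1e6)
  for (t in c("soft_tissue", "bone", "vessel")) {
    expect_lt(max(abs(maps[[t]]$values[m] - ph$fractions[[t]][m])), 1)
  }
})

test_that("misclassification is the identity for a perfect decomposition", {
  r <- full_renders()
  maps <- decompose(r$low, r$high, basis_filtered())
  tab <- misclassification_table(maps, phantom_rois("eval"))
  expect_equal(unname(diag(tab$mean)), rep(100, 3), tolerance = 1e-6)
  expect_lt(max(abs(tab$mean[row(tab$mean) != col(tab$mean)])), 1e-6)
  expect_equal(unname(colSums(tab$mean)), rep(100, 3), tolerance = 0.01)
})

test_that("misclassification columns are normalised for any input", {
  b <- filtered_basis()
  set.seed(15)
  l <- render_ct(full_phantom(), b, "low", noise_sigma = 60, seed = 21)
  h <- render_ct(full_phantom(), b, "high", noise_sigma = 60, seed = 22)
  tab <- misclassification_table(decompose(l, h, b), phantom_rois("eval"))
  expect_equal(unname(colSums(tab$mean)), rep(100, 3), tolerance = 0.01)
})

test_that("an uncorrected misalignment degrades the vessel diagonal", {
  ph <- small_phantom()
  b <- filtered_basis()
  low <- render_ct(ph, b, "low", noise_sigma = 60, seed = 31)
  high <- render_ct(ph, b, "high", noise_sigma = 60, seed = 32)
  rois <- small_rois()
  aligned <- misclassification_table(decompose(low, high, b), rois)
  shifted <- misalign(high, rigid_transform(translation = c(0.3, 0, 0)))
  degraded <- misclassification_table(decompose(low, shifted, b), rois)
  expect_lt(degraded$mean["vessel", "vessel"], aligned$mean["vessel", "vessel"])
})

test_that("calibration is a fixed point on noiseless data", {
  r <- full_renders()
  cal <- calibrate_basis(r$low, r$high, phantom_rois("calib"),
                         phantom_rois("eval"))
  expect_equal(cal$basis$ct_values, basis_filtered()$ct_values,
               tolerance = 1e-6)
  expect_equal(cal$trace[1], 0, tolerance = 1e-6)
})

test_that("calibration descends monotonically from perturbed starts", {
  r <- full_renders()
  init <- basis_filtered()$ct_values + 200
  cal <- calibrate_basis(r$low, r$high, phantom_rois("calib"),
                         phantom_rois("eval"), init = init)
  expect_true(all(diff(cal$trace) <= 1e-9))
  expect_lt(cal$trace[length(cal$trace)], cal$trace[1])
})

test_that("calibration recovers the true basis under noise", {
  ph <- full_phantom()
  b <- basis_filtered()
  n_roi <- 125                       # 5x5x5 voxels per 0.5-mm ROI
  lim <- 2 * 60 / sqrt(n_roi)        # 2 sigma of an ROI mean
  errs <- sapply(1:10, function(i) {
    low <- render_ct(ph, b, "low", noise_sigma = 60, seed = 500 + i)
    high <- render_ct(ph, b, "high", noise_sigma = 60, seed = 600 + i)
    cal <- calibrate_basis(low, high, phantom_rois("calib"),
                           phantom_rois("eval"))
    abs(cal$basis$ct_values - b$ct_values)
  })
  expect_lt(max(rowMeans(errs)), lim)  # per-entry mean abs error, 10 seeds
})

test_that("degenerate calibration ROIs are rejected", {
  r <- full_renders()
  rois <- phantom_rois("calib")
  same <- list(rois[[1]],
               roi_spec(rois[[1]]$center_mm, label = "bone"),
               rois[[3]])
  expect_error(calibrate_basis(r$low, r$high, same, phantom_rois("eval")),
               "degenerate")
})
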