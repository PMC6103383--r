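#' Specification of the digital dual-energy phantom
#'
#' A hindlimb-like digital phantom on a 160 x 160 x 200 grid of 0.1-mm
#' isotropic voxels (16 x 16 x 20 mm): a soft-tissue cylinder containing a
#' cortical-bone tube (marrow inside), two contrast-filled vessels and a
#' bone-mimicking calibrator rod; water and air vials in the surrounding
#' (radiolucent, air-equivalent) holder; and PTFE fiducial beads (1.6 mm
#' diameter, >= 8, minimum spacing 4 mm) on a peripheral ring at staggered
#' heights so the marker cloud is non-coplanar.  All cylinders run along z.
#'
#' @param shape Grid dimensions (voxels).
#' @param spacing Isotropic voxel spacing in mm.
#' @param tissue_center,tissue_radius Soft-tissue cylinder (xy center, mm).
#' @param bone_center,bone_inner_radius,bone_outer_radius Cortical tube.
#' @param vessels List of vessels, each `list(center = c(x, y), radius = r)`.
#' @param calibrator_center,calibrator_radius Bone-mimicking rod (aux).
#' @param water_vial_center,air_vial_center,vial_radius Rescaling vials (aux).
#' @param n_beads,bead_diameter,bead_ring_radius PTFE fiducial layout;
#'   beads are placed at equal angles (offset 18 deg from the vial axis) and
#'   staggered z between `bead_z_range`.
#' @param bead_z_range Range of bead center heights, mm.
#' @param noise_sigma Gaussian image noise in HU (sigma; the scanner's
#'   "+/- 60 HU" noise level).
#' @param seed Base random seed for noise realisations.
#' @param misalignment Optional [rigid_transform()] applied to the
#'   high-energy volume (NULL = aligned).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160, 160, 200), spacing = 0.1,
                         tissue_center = c(7.95, 7.95), tissue_radius = 4.5,
                         bone_center = c(6.45, 7.95),
                         bone_inner_radius = 0.9, bone_outer_radius = 1.5,
                         vessels = list(
                           list(center = c(9.45, 8.85), radius = 0.45),
                           list(center = c(9.15, 6.55), radius = 0.35)),
                         calibrator_center = c(7.95, 11.15),
                         calibrator_radius = 0.5,
                         water_vial_center = c(1.35, 7.95),
                         air_vial_center = c(14.55, 7.95),
                         vial_radius = 0.8,
                         n_beads = 10, bead_diameter = 1.6,
                         bead_ring_radius = 6.55,
                         bead_z_range = c(3, 17),
                         noise_sigma = 60, seed = 1L,
                         misalignment = NULL) {
  stopifnot(length(shape) == 3L, all(shape >= 8), spacing > 0,
            n_beads >= 8, noise_sigma >= 0)
  angles <- 18 + 360 / n_beads * (seq_len(n_beads) - 1)
  bead_centers <- cbind(
    tissue_center[1] + bead_ring_radius * cos(angles * pi / 180),
    tissue_center[2] + bead_ring_radius * sin(angles * pi / 180),
    seq(bead_z_range[1], bead_z_range[2], length.out = n_beads))
  spec <- structure(list(
    shape = as.integer(shape), spacing = spacing,
    tissue_center = tissue_center, tissue_radius = tissue_radius,
    bone_center = bone_center, bone_inner_radius = bone_inner_radius,
    bone_outer_radius = bone_outer_radius, vessels = vessels,
    calibrator_center = calibrator_center,
    calibrator_radius = calibrator_radius,
    water_vial_center = water_vial_center,
    air_vial_center = air_vial_center, vial_radius = vial_radius,
    n_beads = as.integer(n_beads), bead_diameter = bead_diameter,
    bead_centers = bead_centers,
    noise_sigma = noise_sigma, seed = as.integer(seed),
    misalignment = misalignment), class = "phantom_spec")
  .validate_phantom_geometry(spec)
  spec
}

.validate_phantom_geometry <- function(spec) {
  ext <- (spec$shape - 1) * spec$spacing + spec$spacing  # world box edge
  lo <- -spec$spacing / 2
  r_b <- spec$bead_diameter / 2
  bc <- spec$bead_centers
  if (any(bc[, 1] - r_b < lo | bc[, 2] - r_b < lo | bc[, 3] - r_b < lo |
          bc[, 1] + r_b > ext[1] + lo | bc[, 2] + r_b > ext[2] + lo |
          bc[, 3] + r_b > ext[3] + lo)) {
    stop("fiducial beads extend outside the grid")
  }
  if (spec$n_beads >= 2) {
    dm <- as.matrix(stats::dist(bc))
    if (min(dm[upper.tri(dm)]) < 4) {
      stop("fiducial beads closer than the 4 mm minimum spacing")
    }
  }
  for (vc in list(spec$water_vial_center, spec$air_vial_center)) {
    if (sqrt(sum((vc - spec$tissue_center)^2)) <
        spec$tissue_radius + spec$vial_radius) {
      stop("calibration vial overlaps the tissue cylinder")
    }
  }
  tr <- sqrt(sum((spec$tissue_center - c(ext[1], ext[2]) / 2 + spec$spacing / 2)^2))
  if (tr + spec$tissue_radius > min(ext[1:2]) / 2) {
    stop("tissue cylinder extends outside the grid")
  }
  invisible(spec)
}

# label codes for phantom materials
.PH_AIR <- 0L; .PH_SOFT <- 1L; .PH_BONE <- 2L; .PH_VESSEL <- 3L
.PH_PTFE <- 4L; .PH_WATER <- 5L; .PH_AIRVIAL <- 6L; .PH_CAL <- 7L

# vectorised material label at arbitrary world points (n x 3 matrix)
.phantom_label <- function(spec, pts) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  lab <- rep.int(.PH_AIR, length(x))
  r2 <- function(c2) (x - c2[1])^2 + (y - c2[2])^2
  lab[r2(spec$tissue_center) <= spec$tissue_radius^2] <- .PH_SOFT
  rb <- r2(spec$bone_center)
  lab[rb <= spec$bone_outer_radius^2 & rb >= spec$bone_inner_radius^2] <- .PH_BONE
  for (v in spec$vessels) lab[r2(v$center) <= v$radius^2] <- .PH_VESSEL
  lab[r2(spec$calibrator_center) <= spec$calibrator_radius^2] <- .PH_CAL
  lab[r2(spec$water_vial_center) <= spec$vial_radius^2] <- .PH_WATER
  lab[r2(spec$air_vial_center) <= spec$vial_radius^2] <- .PH_AIRVIAL
  rbead <- (spec$bead_diameter / 2)^2
  for (i in seq_len(spec$n_beads)) {
    b <- spec$bead_centers[i, ]
    hit <- (x - b[1])^2 + (y - b[2])^2 + (z - b[3])^2 <= rbead
    lab[hit] <- .PH_PTFE
  }
  lab
}

#' Build the digital phantom with ground truth
#'
#' Rasterises the phantom geometry into per-voxel material fractions.
#' Interior voxels are pure; voxels on a material boundary (any 6-neighbour
#' label differs) are supersampled on a 3 x 3 x 3 sub-voxel grid, each
#' sub-voxel center contributing 1/27 to its material's fraction.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `dect_phantom`:
#'   `fractions` - list of eight 3-D arrays (`soft_tissue`, `bone`,
#'     `vessel`, `ptfe`, `water`, `air_vial`, `calibrator`, `air`) on the
#'     0-10000 scale, summing to 10000 per voxel across all eight;
#'   `labels` - majority material label per voxel (codes in
#'     `phantom_label_codes()`);
#'   `bead_centroids` - n x 3 matrix of ground-truth bead centers (mm);
#'   `spec` - the input specification.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  ref <- ct_volume(array(0, dim = d), spacing = spec$spacing)
  pts <- voxel_to_world(ref, .index_grid(d))
  lab <- .phantom_label(spec, pts)
  dim(lab) <- d
  # boundary voxels: any face neighbour with a different label
  boundary <- array(FALSE, dim = d)
  for (ax in 1:3) {
    idx_a <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_b <- idx_a
    idx_a[[ax]] <- seq_len(d[ax] - 1L)
    idx_b[[ax]] <- seq_len(d[ax] - 1L) + 1L
    neq <- do.call(`[`, c(list(lab), idx_a)) !=
           do.call(`[`, c(list(lab), idx_b))
    ba <- do.call(`[`, c(list(boundary), idx_a)) | neq
    bb <- do.call(`[`, c(list(boundary), idx_b)) | neq
    boundary <- do.call(`[<-`, c(list(boundary), idx_a, list(ba)))
    boundary <- do.call(`[<-`, c(list(boundary), idx_b, list(bb)))
  }
  n_lab <- 8L
  counts <- matrix(0L, nrow = sum(boundary), ncol = n_lab)
  b_idx <- which(boundary)
  if (length(b_idx)) {
    b_pts <- pts[b_idx, , drop = FALSE]
    offs <- (c(-1, 0, 1) / 3) * spec$spacing
    for (ox in offs) for (oy in offs) for (oz in offs) {
      sub <- .phantom_label(spec, cbind(b_pts[, 1] + ox, b_pts[, 2] + oy,
                                        b_pts[, 3] + oz))
      for (l in 0:(n_lab - 1L)) {
        counts[, l + 1L] <- counts[, l + 1L] + (sub == l)
      }
    }
  }
  frac_names <- c("air", "soft_tissue", "bone", "vessel", "ptfe", "water",
                  "air_vial", "calibrator")
  fractions <- list()
  for (l in 0:(n_lab - 1L)) {
    f <- array(0, dim = d)
    f[lab == l] <- 10000
    if (length(b_idx)) f[b_idx] <- counts[, l + 1L] / 27 * 10000
    fractions[[frac_names[l + 1L]]] <- f
  }
  # majority label on boundary voxels
  if (length(b_idx)) {
    lab[b_idx] <- max.col(counts, ties.method = "first") - 1L
  }
  ord <- c("soft_tissue", "bone", "vessel", "ptfe", "water", "air_vial",
           "calibrator", "air")
  structure(list(fractions = fractions[ord], labels = lab,
                 bead_centroids = spec$bead_centers, spec = spec),
            class = "dect_phantom")
}

#' @export
print.dect_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<dect_phantom> %d x %d x %d voxels | %d beads | sigma %.3g HU\n",
              d[1], d[2], d[3], nrow(x$bead_centroids), x$spec$noise_sigma))
  invisible(x)
}

#' Voxels fully inside the three-material system
#'
#' Logical mask of voxels whose entire volume is soft tissue, bone and/or
#' vessel (fractions summing to 10000 across the three).  Only on these
#' voxels is the rendered HU an exact linear combination of the calibration
#' values, so only there can decomposition invert the forward model exactly;
#' voxels bordering air, vials, beads or the calibrator mix in auxiliary
#' materials outside the decomposition basis.
#'
#' @param phantom A [build_phantom()] result.
#' @return Logical 3-D array.
#' @export
pure_material_mask <- function(phantom) {
  f <- phantom$fractions
  (f$soft_tissue + f$bone + f$vessel) > 10000 - 1e-6
}

#' Phantom label codes
#' @return Named integer vector mapping material names to label codes.
#' @export
phantom_label_codes <- function() {
  c(air = .PH_AIR, soft_tissue = .PH_SOFT, bone = .PH_BONE,
    vessel = .PH_VESSEL, ptfe = .PH_PTFE, water = .PH_WATER,
    air_vial = .PH_AIRVIAL, calibrator = .PH_CAL)
}

#' Render a CT volume from phantom ground truth
#'
#' Forward model: each voxel's HU is the fraction-weighted sum of pure
#' material CT values, where soft tissue / bone / vessel take the calibration
#' values of `basis` at the requested energy and the auxiliary materials take
#' fixed values (`water` 0, `air` -1000, `ptfe` +1000 by default, calibrator
#' = the bone calibration value).  Optional additive Gaussian noise.
#'
#' @param phantom A [build_phantom()] result.
#' @param basis A [build_basis()] decomposition basis supplying the six
#'   calibration CT values.
#' @param energy `"low"` or `"high"`.
#' @param noise_sigma Gaussian noise sigma in HU; defaults to the phantom
#'   spec value.  Must be >= 0.
#' @param seed Random seed for the noise realisation (NULL = do not touch
#'   the RNG state).
#' @param aux_hu Named vector of auxiliary HU overrides
#'   (`ptfe`, `water`, `air`, `calibrator`).
#' @return A `ct_volume` in HU.
#' @export
render_ct <- function(phantom, basis, energy = c("low", "high"),
                      noise_sigma = NULL, seed = NULL,
                      aux_hu = c(ptfe = 1000, water = 0, air = -1000,
                                 calibrator = NA)) {
  stopifnot(inherits(phantom, "dect_phantom"),
            inherits(basis, "decomposition_basis"))
  energy <- match.arg(energy)
  if (is.null(noise_sigma)) noise_sigma <- phantom$spec$noise_sigma
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  ct <- basis$ct_values[energy, ]
  if (is.na(aux_hu["calibrator"])) aux_hu["calibrator"] <- ct[["bone"]]
  f <- phantom$fractions
  hu <- (f$soft_tissue * ct[["soft_tissue"]] + f$bone * ct[["bone"]] +
         f$vessel * ct[["vessel"]] + f$ptfe * aux_hu[["ptfe"]] +
         f$water * aux_hu[["water"]] +
         (f$air + f$air_vial) * aux_hu[["air"]] +
         f$calibrator * aux_hu[["calibrator"]]) / 10000
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    hu <- hu + stats::rnorm(length(hu), sd = noise_sigma)
    dim(hu) <- dim(phantom$labels)
  }
  ct_volume(hu, spacing = phantom$spec$spacing)
}

#' Apply a known misalignment to a volume
#'
#' Resamples the volume so that its content is moved by the rigid transform
#' `t` (a point at p appears at t(p)); voxels sampling outside the original
#' field of view are set to air (-1000 HU).  An identity transform
#' short-circuits to the unchanged volume.
#'
#' @param v A `ct_volume`.
#' @param t A [rigid_transform()].
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @return The misaligned `ct_volume`.
#' @export
misalign <- function(v, t, interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(v, "ct_volume"), inherits(t, "rigid_transform"))
  interpolation <- match.arg(interpolation)
  if (max(abs(t$rotation - diag(3))) < 1e-12 &&
      max(abs(t$translation)) < 1e-12) {
    return(v)
  }
  d <- dim(v$values)
  idx <- .rigid_grid_indices(d, v$spacing, v$origin, v, t)
  out <- if (interpolation == "trilinear") {
    .sample_trilinear(v$values, idx, fill = -1000)
  } else {
    .sample_nearest(v$values, idx, fill = -1000)
  }
  dim(out) <- d
  ct_volume(out, spacing = v$spacing, origin = v$origin)
}

#' Simulate an aluminium step-wedge exposure
#'
#' Expected detector counts behind each step of an absorber wedge:
#' `n0 * transmission(t_i)`, with optional Poisson sampling.  Feeding the
#' noiseless counts to [hvl()]'s slope-fit method reproduces the step-wedge
#' HVL analysis.
#'
#' @param s An `xray_spectrum`.
#' @param thicknesses_mm Step thicknesses in mm (>= 0).
#' @param n0 Open-beam count (> 0).
#' @param seed If non-NULL, Poisson-sample the counts with this seed.
#' @param absorber Wedge material (default "Al").
#' @param weighting Flux weighting, as in [beam_transmission()].
#' @return Data frame with `thickness_mm`, `expected`, and `counts`.
#' @export
step_wedge_counts <- function(s, thicknesses_mm, n0, seed = NULL,
                              absorber = "Al",
                              weighting = c("detected", "photons")) {
  weighting <- match.arg(weighting)
  if (n0 <= 0) stop("n0 must be > 0")
  if (any(thicknesses_mm < 0)) stop("thicknesses must be >= 0")
  tr <- vapply(thicknesses_mm, function(t_mm) {
    if (t_mm == 0) 1 else beam_transmission(
      s, filter_layer(absorber, thickness_mm = t_mm), weighting)
  }, numeric(1))
  expected <- n0 * tr
  counts <- expected
  if (!is.null(seed)) {
    set.seed(seed)
    counts <- stats::rpois(length(expected), expected)
  }
  data.frame(thickness_mm = thicknesses_mm, expected = expected,
             counts = counts)
}
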