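#' Build a three-material decomposition basis
#'
#' The decomposition needs six calibration CT values: soft tissue, bone and
#' contrast-vessel intensities at the low and the high energy.  They define
#' the system matrix
#' \deqn{M = \begin{pmatrix} L_{st} & L_{bone} & L_{ves} \\
#'                           H_{st} & H_{bone} & H_{ves} \\
#'                           1 & 1 & 1 \end{pmatrix},}
#' whose unit row enforces volume conservation; a voxel's fractions solve
#' \eqn{M f = (L, H, 1)^T}.
#'
#' @param six_values 2 x 3 numeric matrix (rows `low`, `high`; columns
#'   `soft_tissue`, `bone`, `vessel`), or a numeric vector of length 6 in
#'   column order (st_low, st_high, bone_low, bone_high, ves_low, ves_high).
#' @param condition_cap Error if the matrix condition number exceeds this
#'   (default 1e6).
#' @return An object of class `decomposition_basis`: list with `ct_values`
#'   (2 x 3), `matrix` (3 x 3), `inverse`, and `condition_number`.
#' @examples
#' b <- build_basis(rbind(low = c(37, 2743, 1659), high = c(0, 1909, 2059)))
#' b$condition_number
#' @export
build_basis <- function(six_values, condition_cap = 1e6) {
  if (is.matrix(six_values)) {
    stopifnot(all(dim(six_values) == c(2L, 3L)))
    ct <- six_values
  } else {
    stopifnot(length(six_values) == 6L)
    ct <- matrix(as.numeric(six_values), nrow = 2L)
  }
  dimnames(ct) <- list(c("low", "high"), c("soft_tissue", "bone", "vessel"))
  if (any(!is.finite(ct))) stop("calibration CT values must be finite")
  m <- rbind(ct, rep(1, 3))
  kap <- kappa(m, exact = TRUE)
  if (!is.finite(kap) || kap > condition_cap) {
    stop("singular or ill-conditioned basis (condition number ",
         format(kap, digits = 4), " > cap ", condition_cap, ")")
  }
  structure(list(ct_values = ct, matrix = unname(m), inverse = solve(m),
                 condition_number = kap),
            class = "decomposition_basis")
}

#' @export
print.decomposition_basis <- function(x, ...) {
  cat("<decomposition_basis> condition number",
      format(x$condition_number, digits = 5), "\n")
  print(x$ct_values)
  invisible(x)
}

#' Filtered-protocol and unfiltered calibration values
#'
#' `basis_filtered()` returns the six calibration CT values measured with
#' the spectral-shaping filters in place (soft tissue 37/0, bone 2743/1909,
#' vessel 1659/2059 HU at low/high energy); `basis_unfiltered()` the set
#' measured without added filtration (45/45, 2930/2572, 2647/2768), whose
#' poorer spectral separation shows up directly as a larger condition
#' number.
#'
#' @return A [build_basis()] object.
#' @export
basis_filtered <- function() {
  build_basis(rbind(low = c(37, 2743, 1659), high = c(0, 1909, 2059)))
}

#' @rdname basis_filtered
#' @export
basis_unfiltered <- function() {
  build_basis(rbind(low = c(45, 2930, 2647), high = c(45, 2572, 2768)))
}

#' Decompose a co-registered dual-energy volume pair
#'
#' Solves \eqn{M f = (L, H, 1)^T} per voxel and scales the fractions by
#' 10000.  The unclamped solution (default) preserves the exact
#' sum-to-10000 bookkeeping but may leave individual fractions outside
#' \[0, 10000\] in noisy data; `clamp = TRUE` clips to the physical range,
#' after which the sum property no longer holds (a message notes this).
#'
#' @param low,high `ct_volume`s on the same grid (co-registered).
#' @param basis A [build_basis()] object.
#' @param clamp Clip fractions to \[0, 10000\]?
#' @return An object of class `fraction_maps`: list of three `ct_volume`s
#'   (`soft_tissue`, `bone`, `vessel`) on the 0-10000 scale, plus `basis`
#'   and `clamped`.
#' @export
decompose <- function(low, high, basis, clamp = FALSE) {
  stopifnot(inherits(low, "ct_volume"), inherits(high, "ct_volume"),
            inherits(basis, "decomposition_basis"))
  if (!identical(dim(low$values), dim(high$values)) ||
      abs(low$spacing - high$spacing) > 1e-9 ||
      max(abs(low$origin - high$origin)) > 1e-9) {
    stop("low- and high-energy volumes are not on the same grid")
  }
  d <- dim(low$values)
  inv <- basis$inverse
  l <- as.numeric(low$values); h <- as.numeric(high$values)
  # f = M^-1 (L, H, 1)'; one factorisation reused across all voxels
  maps <- lapply(1:3, function(r) {
    f <- (inv[r, 1] * l + inv[r, 2] * h + inv[r, 3]) * 10000
    if (clamp) f <- pmin(pmax(f, 0), 10000)
    dim(f) <- d
    ct_volume(f, spacing = low$spacing, origin = low$origin)
  })
  names(maps) <- c("soft_tissue", "bone", "vessel")
  if (clamp) message("clamped fractions: per-voxel sums may deviate from 10000")
  structure(c(maps, list(basis = basis, clamped = clamp)),
            class = "fraction_maps")
}

#' @export
print.fraction_maps <- function(x, ...) {
  d <- dim(x$soft_tissue$values)
  cat(sprintf("<fraction_maps> %d x %d x %d voxels | %s\n", d[1], d[2], d[3],
              if (x$clamped) "clamped [0, 10000]" else "unclamped"))
  invisible(x)
}

#' Cubic region of interest
#'
#' An axis-aligned cube (default edge 0.5 mm, i.e. 5 voxels at 0.1-mm
#' spacing) tagged with the tissue it is known to contain.  Voxels only
#' partially inside the cube are excluded (the ROI snaps to whole voxels).
#'
#' @param center_mm Cube center in world mm (length 3).
#' @param edge_mm Cube edge length in mm.
#' @param label Tissue label: `"soft_tissue"`, `"bone"` or `"vessel"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center_mm, edge_mm = 0.5,
                     label = c("soft_tissue", "bone", "vessel")) {
  label <- match.arg(label)
  stopifnot(length(center_mm) == 3L, edge_mm > 0)
  structure(list(center_mm = as.numeric(center_mm), edge_mm = edge_mm,
                 label = label), class = "roi_spec")
}

# linear voxel indices of voxels fully inside an ROI cube
.roi_voxels <- function(v, roi) {
  d <- dim(v$values)
  half <- roi$edge_mm / 2 - v$spacing / 2  # voxel centers of fully-inside voxels
  rng <- lapply(1:3, function(ax) {
    lo <- roi$center_mm[ax] - half; hi <- roi$center_mm[ax] + half
    ilo <- ceiling((lo - v$origin[ax]) / v$spacing - 1e-9) + 1
    ihi <- floor((hi - v$origin[ax]) / v$spacing + 1e-9) + 1
    if (ilo < 1 || ihi > d[ax]) stop("ROI extends outside the volume grid")
    ilo:ihi
  })
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  g[, 1] + (g[, 2] - 1) * d[1] + (g[, 3] - 1) * d[1] * d[2]
}

#' Mean map value in an ROI
#'
#' @param map A `ct_volume` (e.g. one decomposed fraction map).
#' @param roi A [roi_spec()].
#' @return Mean voxel value over the whole voxels inside the cube.
#' @export
roi_mean <- function(map, roi) {
  mean(map$values[.roi_voxels(map, roi)])
}

#' Misclassification table of a decomposition
#'
#' For each known-pure-tissue ROI, the mean value of each decomposed volume
#' inside the ROI, expressed in percent and normalised so every known-tissue
#' column sums to 100%.  Diagonal entries are correctly classified
#' fractions; off-diagonal mass quantifies misclassification.  Several
#' replicate map sets can be pooled, giving per-cell mean and sd.
#'
#' @param maps A `fraction_maps` object, or a list of them (replicates).
#' @param rois List of three [roi_spec()]s, one per tissue label.
#' @return An object of class `misclassification_table`: list with `mean`
#'   (3 x 3 percent matrix, rows = decomposed volumes, columns = known
#'   components), `sd` (same shape; NA for a single sample) and `n`.
#' @export
misclassification_table <- function(maps, rois) {
  if (inherits(maps, "fraction_maps")) maps <- list(maps)
  labs <- vapply(rois, function(r) r$label, character(1))
  if (!setequal(labs, c("soft_tissue", "bone", "vessel"))) {
    stop("need exactly one ROI per tissue label")
  }
  rois <- rois[match(c("soft_tissue", "bone", "vessel"), labs)]
  per_sample <- lapply(maps, function(m) {
    tab <- vapply(rois, function(roi) {
      col <- vapply(c("soft_tissue", "bone", "vessel"),
                    function(t) roi_mean(m[[t]], roi), numeric(1))
      col / sum(col) * 100
    }, numeric(3))
    dimnames(tab) <- list(decomposed = c("soft_tissue", "bone", "vessel"),
                          known = c("soft_tissue", "bone", "vessel"))
    tab
  })
  arr <- simplify2array(per_sample)
  structure(list(mean = apply(arr, 1:2, mean),
                 sd = if (length(maps) > 1L) apply(arr, 1:2, stats::sd) else
                   array(NA_real_, dim = c(3, 3), dimnames = dimnames(arr)[1:2]),
                 n = length(maps)),
            class = "misclassification_table")
}

#' @export
print.misclassification_table <- function(x, digits = 2, ...) {
  cat("<misclassification_table> (% of known component; n =", x$n, ")\n")
  print(round(x$mean, digits))
  invisible(x)
}

#' Iteratively calibrate the six decomposition values
#'
#' Initialises the six calibration values at the ROI means of the low- and
#' high-energy volumes, then refines them by coordinate descent: each value
#' in turn is perturbed up and down by the current step, keeping any change
#' that lowers the total off-diagonal mass of the misclassification table on
#' the evaluation ROIs; when a full sweep yields no improvement the step
#' shrinks.  Stops at relative improvement below `tol` or `max_iter` sweeps.
#'
#' @param low,high Co-registered `ct_volume`s.
#' @param calib_rois Three [roi_spec()]s in known-pure regions used for the
#'   initial values.
#' @param eval_rois Three [roi_spec()]s (typically elsewhere) on which the
#'   objective is evaluated.
#' @param step_init,step_min Initial / final perturbation step in HU.
#' @param tol Relative-improvement stopping threshold.
#' @param max_iter Maximum number of sweeps.
#' @param init Optional 2 x 3 matrix of starting values overriding the
#'   calibration-ROI means (e.g. deliberately perturbed values).
#' @return List with `basis` (a [build_basis()] object), `trace` (objective
#'   per sweep, starting with the initial objective) and `initial` (2 x 3
#'   starting values).
#' @export
calibrate_basis <- function(low, high, calib_rois, eval_rois,
                            step_init = 50, step_min = 0.5,
                            tol = 1e-4, max_iter = 200, init = NULL) {
  labs <- vapply(calib_rois, function(r) r$label, character(1))
  calib_rois <- calib_rois[match(c("soft_tissue", "bone", "vessel"), labs)]
  ct0 <- vapply(calib_rois, function(roi)
    c(roi_mean(low, roi), roi_mean(high, roi)), numeric(2))
  if (!is.null(init)) {
    stopifnot(all(dim(init) == c(2L, 3L)))
    ct0 <- unname(as.matrix(init))
  }
  dimnames(ct0) <- list(c("low", "high"), c("soft_tissue", "bone", "vessel"))
  for (j in 1:2) for (k in (j + 1):3) {
    if (max(abs(ct0[, j] - ct0[, k])) < 1e-6) {
      stop("degenerate ROIs: two material ROIs have identical means at both energies")
    }
  }
  # pre-extract the evaluation ROI voxel values once
  labs_e <- vapply(eval_rois, function(r) r$label, character(1))
  eval_rois <- eval_rois[match(c("soft_tissue", "bone", "vessel"), labs_e)]
  lv <- lapply(eval_rois, function(roi) low$values[.roi_voxels(low, roi)])
  hv <- lapply(eval_rois, function(roi) high$values[.roi_voxels(high, roi)])
  objective <- function(ct) {
    m <- rbind(ct, rep(1, 3))
    inv <- tryCatch(solve(m), error = function(e) NULL)
    if (is.null(inv)) return(Inf)
    off <- 0
    for (j in 1:3) {
      f <- inv %*% rbind(mean(lv[[j]]), mean(hv[[j]]), 1) * 10000
      off <- off + sum(abs(f[-j]))
    }
    off
  }
  ct <- ct0
  obj <- objective(ct)
  trace <- obj
  step <- step_init
  for (iter in seq_len(max_iter)) {
    improved <- FALSE
    for (idx in seq_len(6L)) {
      for (delta in c(step, -step)) {
        cand <- ct
        cand[idx] <- cand[idx] + delta
        o <- objective(cand)
        if (o < obj) { ct <- cand; obj <- o; improved <- TRUE; break }
      }
    }
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (!improved) {
      step <- step / 2
      if (step < step_min) break
    } else if (prev > 0 && (prev - obj) / prev < tol) {
      break
    }
  }
  list(basis = build_basis(ct), trace = trace, initial = ct0)
}
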