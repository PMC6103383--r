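#' Detect fiducial beads in a volume
#'
#' Thresholds the volume, labels 26-connected components, discards components
#' outside a voxel-count window, and returns the intensity-weighted centroid
#' of each remaining component in world coordinates.  Weights are the HU
#' excess above the threshold, which gives sub-voxel centroid precision for
#' bright beads on a dark background.
#'
#' @param v A `ct_volume`.
#' @param hu_threshold Threshold between background and bead HU.  The default
#'   518 is the midpoint between soft tissue (37 HU) and PTFE (+1000 HU).
#' @param size_range Acceptable component size in voxels; the default brackets
#'   a 1.6-mm bead (~2100 voxels at 0.1 mm) and excludes rods and tubes.
#' @return An object of class `fiducial_set`: list with `centroids`
#'   (n x 3 mm, ordered by component size) and `voxel_count`.
#' @export
detect_fiducials <- function(v, hu_threshold = 518, size_range = c(700, 4000)) {
  stopifnot(inherits(v, "ct_volume"))
  mask <- v$values > hu_threshold
  n_fg <- sum(mask)
  if (n_fg == 0) {
    stop("no voxels above threshold ", hu_threshold, "; no components found")
  }
  labels <- .label_components_26(mask)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= size_range[1] & sizes <= size_range[2])
  if (!length(keep)) {
    census <- paste(sort(sizes, decreasing = TRUE), collapse = ", ")
    stop("no connected component within size range [", size_range[1], ", ",
         size_range[2], "]; component sizes found: ", census)
  }
  idx <- which(mask)
  comp <- labels[idx]
  sel <- comp %in% keep
  idx <- idx[sel]; comp <- comp[sel]
  d <- dim(v$values)
  i <- (idx - 1L) %% d[1] + 1L
  j <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  k <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  w <- v$values[idx] - hu_threshold
  cen <- t(vapply(keep, function(cc) {
    s <- comp == cc
    ws <- w[s]
    c(sum(ws * i[s]), sum(ws * j[s]), sum(ws * k[s])) / sum(ws)
  }, numeric(3)))
  structure(list(centroids = voxel_to_world(v, cen),
                 voxel_count = sizes[keep]),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %d markers | %d-%d voxels each\n",
              nrow(x$centroids), min(x$voxel_count), max(x$voxel_count)))
  invisible(x)
}

# 26-connected component labelling by minimum-label propagation with path
# compression over the foreground voxels; neighbour ranks are precomputed
# once so each sweep is a handful of vectorised pmin operations
.label_components_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  rank <- array(0L, dim = d)
  rank[idx] <- seq_len(n)
  i <- (idx - 1L) %% d[1] + 1L
  j <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  k <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nb <- matrix(0L, nrow = n, ncol = nrow(offs))
  for (r in seq_len(nrow(offs))) {
    ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
    ok <- ii >= 1L & jj >= 1L & kk >= 1L &
      ii <= d[1] & jj <= d[2] & kk <= d[3]
    lin <- ii + (jj - 1L) * d[1] + (kk - 1L) * d[1] * d[2]
    col <- rep.int(0L, n)
    col[ok] <- rank[lin[ok]]
    nb[, r] <- col
  }
  cur <- seq_len(n)
  repeat {
    new <- cur
    for (r in seq_len(ncol(nb))) {
      has <- nb[, r] > 0L
      new[has] <- pmin(new[has], cur[nb[has, r]])
    }
    # path compression: follow representatives to accelerate convergence
    for (z in 1:3) new <- new[new]
    if (identical(new, cur)) break
    cur <- new
  }
  labels <- array(0L, dim = d)
  labels[idx] <- match(cur, sort(unique(cur)))
  labels
}

#' Match fiducial markers between two sets
#'
#' Centers both point clouds on their centroid-of-centroids, then keeps
#' mutual nearest-neighbour pairs.  Valid when the residual misalignment is
#' small relative to the inter-marker spacing (the phantom enforces >= 4 mm
#' bead spacing against <= ~1 mm misalignments).
#'
#' @param a,b `fiducial_set` objects (or n x 3 centroid matrices).
#' @param min_markers Minimum number of matched pairs (default 8, the
#'   protocol minimum; hard floor 3).
#' @return Integer matrix with columns `a`, `b` of matched indices.
#' @export
match_fiducials <- function(a, b, min_markers = 8) {
  pa <- if (inherits(a, "fiducial_set")) a$centroids else rbind(a)
  pb <- if (inherits(b, "fiducial_set")) b$centroids else rbind(b)
  min_markers <- max(3L, as.integer(min_markers))
  ca <- sweep(pa, 2L, colMeans(pa), `-`)
  cb <- sweep(pb, 2L, colMeans(pb), `-`)
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * tcrossprod(ca, cb)
  near_ab <- apply(d2, 1L, which.min)
  near_ba <- apply(d2, 2L, which.min)
  mutual <- which(near_ba[near_ab] == seq_len(nrow(pa)))
  pairs <- cbind(a = mutual, b = near_ab[mutual])
  dropped <- nrow(pa) - nrow(pairs)
  if (dropped > 0) {
    warning(dropped, " marker(s) had no mutual nearest neighbour and were dropped")
  }
  if (nrow(pairs) < min_markers) {
    stop("only ", nrow(pairs), " matched marker pairs; need >= ", min_markers)
  }
  pairs
}

#' Least-squares rigid transform between paired point sets
#'
#' Closed-form solution of \eqn{\min_{R,t} \sum_i \|R m_i + t - f_i\|^2} via
#' SVD of the cross-covariance matrix, with the sign of the smallest singular
#' direction corrected so that the returned rotation is proper
#' (det(R) = +1, never a reflection).
#'
#' @param moving,fixed n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear).
#' @return A [rigid_transform()] mapping `moving` onto `fixed`.
#' @export
fit_rigid <- function(moving, fixed) {
  moving <- rbind(moving); fixed <- rbind(fixed)
  if (nrow(moving) != nrow(fixed)) stop("point counts differ")
  if (nrow(moving) < 3L) stop("need at least 3 point pairs")
  mu_m <- colMeans(moving); mu_f <- colMeans(fixed)
  mm <- sweep(moving, 2L, mu_m, `-`)
  ff <- sweep(fixed, 2L, mu_f, `-`)
  sv_m <- svd(mm)$d
  if (sv_m[2] < 1e-9 * max(sv_m[1], 1)) {
    stop("degenerate (collinear) marker configuration")
  }
  h <- crossprod(mm, ff)              # 3x3 cross-covariance
  s <- svd(h)
  dsign <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  rigid_transform(r, mu_f - as.numeric(r %*% mu_m))
}

#' Resample a volume through a rigid transform onto a reference grid
#'
#' `out(x) = moving(t^{-1}(x))` for every voxel center x of the reference
#' grid, by trilinear interpolation; out-of-field voxels become air
#' (-1000 HU).  With `t` from [fit_rigid()] (moving markers onto fixed
#' markers) this carries the moving (high-energy) volume into the fixed
#' (low-energy) space.
#'
#' @param moving A `ct_volume`.
#' @param t A [rigid_transform()].
#' @param reference A `ct_volume` defining the output grid.
#' @return A `ct_volume` on the reference grid.
#' @export
resample <- function(moving, t, reference) {
  stopifnot(inherits(moving, "ct_volume"), inherits(t, "rigid_transform"),
            inherits(reference, "ct_volume"))
  d <- dim(reference$values)
  idx <- .rigid_grid_indices(d, reference$spacing, reference$origin, moving, t)
  out <- .sample_trilinear(moving$values, idx, fill = -1000)
  dim(out) <- d
  ct_volume(out, spacing = reference$spacing, origin = reference$origin)
}

#' Fiducial registration error
#'
#' @param t A fitted [rigid_transform()].
#' @param moving,fixed The matched marker coordinates the transform was
#'   fitted to.
#' @return List with `fre` (RMS residual, mm) and `residuals` (per-marker
#'   distances, mm).
#' @export
registration_error <- function(t, moving, fixed) {
  moving <- rbind(moving); fixed <- rbind(fixed)
  res <- sqrt(rowSums((transform_points(t, moving) - fixed)^2))
  list(fre = sqrt(mean(res^2)), residuals = res)
}

#' Register a high-energy to a low-energy volume by fiducials
#'
#' Convenience wrapper: detect beads in both volumes, match them, fit the
#' rigid transform and resample the moving volume onto the fixed grid.
#'
#' @param fixed,moving `ct_volume`s (low- and high-energy).
#' @param hu_threshold,size_range Passed to [detect_fiducials()].
#' @param min_markers Passed to [match_fiducials()].
#' @return List with `volume` (resampled moving volume), `transform`, `fre`,
#'   `n_markers`, and the detected `fixed_fiducials` / `moving_fiducials`.
#' @export
register_volumes <- function(fixed, moving, hu_threshold = 518,
                             size_range = c(700, 4000), min_markers = 8) {
  ff <- detect_fiducials(fixed, hu_threshold, size_range)
  mf <- detect_fiducials(moving, hu_threshold, size_range)
  pairs <- match_fiducials(mf, ff, min_markers = min_markers)
  t_fit <- fit_rigid(mf$centroids[pairs[, "a"], , drop = FALSE],
                     ff$centroids[pairs[, "b"], , drop = FALSE])
  err <- registration_error(t_fit,
                            mf$centroids[pairs[, "a"], , drop = FALSE],
                            ff$centroids[pairs[, "b"], , drop = FALSE])
  list(volume = resample(moving, t_fit, fixed), transform = t_fit,
       fre = err$fre, n_markers = nrow(pairs),
       fixed_fiducials = ff, moving_fiducials = mf)
}
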