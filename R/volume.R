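#' CT volume container
#'
#' A 3-D scalar grid in Hounsfield units with isotropic voxel spacing and a
#' world-space origin.  World coordinates are in mm; the world position of
#' voxel (i, j, k) (1-based array index) is `origin + (c(i,j,k) - 1) *
#' spacing`, i.e. a voxel's world position is its center.
#'
#' @param values 3-D numeric array (HU).
#' @param spacing Isotropic voxel spacing in mm (> 0).
#' @param origin World position of the first voxel center, mm (length 3).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing = 0.1, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            is.numeric(spacing), length(spacing) == 1L, spacing > 0,
            length(origin) == 3L, all(is.finite(values)))
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels | %.3g mm isotropic | HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], x$spacing, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

#' Convert voxel indices to world coordinates
#'
#' @param v A `ct_volume`.
#' @param idx n x 3 matrix of 1-based (possibly fractional) voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- rbind(idx)
  sweep((idx - 1) * v$spacing, 2L, v$origin, `+`)
}

#' Convert world coordinates to (fractional) voxel indices
#'
#' @param v A `ct_volume`.
#' @param xyz n x 3 matrix of world coordinates in mm.
#' @return n x 3 matrix of 1-based fractional voxel indices.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- rbind(xyz)
  sweep(xyz, 2L, v$origin, `-`) / v$spacing + 1
}

#' Read / write CT volumes as NIfTI-1
#'
#' Volumes are stored as int16 HU with the voxel spacing in the header.  The
#' world origin is kept in the NIfTI sform translation.
#'
#' @param v A `ct_volume`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `ct_volume`; `write_volume` returns `path`
#'   invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "ct_volume"))
  sp <- v$spacing
  a <- round(v$values)
  attr(a, "pixdim") <- c(sp, sp, sp)
  img <- RNifti::asNifti(a, datatype = "int16")
  xform <- rbind(cbind(diag(sp, 3), v$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(xform, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (max(abs(sp - sp[1])) > 1e-6) stop("anisotropic voxels are not supported")
  ct_volume(array(as.numeric(img), dim = dim(img)), spacing = sp[1],
            origin = xf[1:3, 4])
}

#' Proper rigid transform
#'
#' Rotation (proper orthogonal 3x3) plus translation (mm), mapping points
#' from one world space to another as `R x + t`.
#'
#' @param rotation 3x3 rotation matrix; `R'R = I` within 1e-9 and
#'   `det(R) = +1` are enforced.
#' @param translation Length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation is not orthogonal (R'R != I within 1e-9)")
  }
  if (det(rotation) < 0) stop("rotation is a reflection (det(R) = -1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3g deg | translation (%.3g, %.3g, %.3g) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply, compose and invert rigid transforms
#'
#' @param t,a,b `rigid_transform` objects.
#' @param pts n x 3 matrix of points (mm).
#' @return `transform_points`: n x 3 matrix; `compose_transforms`: transform
#'   equal to applying `b` first, then `a`; `invert_transform`: the inverse.
#' @export
transform_points <- function(t, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(t$rotation), 2L, t$translation, `+`)
}

#' @rdname transform_points
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname transform_points
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.numeric(t(t$rotation) %*% t$translation))
}

#' Rigid transform rotating about an arbitrary center
#'
#' Builds the transform that rotates by `rotation` about the point `center`
#' and then translates by `translation`: `x -> R (x - c) + c + t`.  Scanner
#' bed/gantry misalignments are naturally expressed this way (the effective
#' rotation axis passes near the isocenter, not the volume corner).
#'
#' @param center Rotation center in world mm (length 3).
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation in mm.
#' @return A [rigid_transform()].
#' @export
rigid_about <- function(center, rotation = diag(3), translation = c(0, 0, 0)) {
  center <- as.numeric(center)
  rigid_transform(rotation,
                  center - as.numeric(rotation %*% center) + translation)
}

#' Small-angle rotation matrix from Euler angles
#'
#' Intrinsic rotations about the x, y then z axes, in degrees.
#'
#' @param angles_deg Length-3 vector of rotation angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_rotation <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# fractional voxel indices (columns x, y, z) into `moving` for every voxel
# center of the reference grid mapped through t^-1; exploits the separable
# structure of a rigid map over a regular grid
.rigid_grid_indices <- function(ref_dim, ref_spacing, ref_origin, moving, t) {
  inv <- invert_transform(t)
  a <- inv$rotation; b <- inv$translation
  wx <- ref_origin[1] + (seq_len(ref_dim[1]) - 1) * ref_spacing
  wy <- ref_origin[2] + (seq_len(ref_dim[2]) - 1) * ref_spacing
  wz <- ref_origin[3] + (seq_len(ref_dim[3]) - 1) * ref_spacing
  n12 <- ref_dim[1] * ref_dim[2]
  axis <- function(r) {
    vx <- a[r, 1] * wx
    vy <- a[r, 2] * wy
    vz <- a[r, 3] * wz + b[r]
    src <- rep(vx, times = ref_dim[2] * ref_dim[3]) +
      rep(rep(vy, each = ref_dim[1]), times = ref_dim[3]) +
      rep(vz, each = n12)
    (src - moving$origin[r]) / moving$spacing + 1
  }
  list(x = axis(1), y = axis(2), z = axis(3))
}

# trilinear sampling of a volume at fractional voxel indices;
# points outside the grid return `fill`
.sample_trilinear <- function(values, idx, fill = -1000) {
  d <- dim(values)
  if (is.matrix(idx)) {
    x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  } else {
    x <- idx$x; y <- idx$y; z <- idx$z
  }
  # points on the grid boundary (including exactly the last voxel center)
  # are inside; the lower cell index is clamped so the 8-corner stencil
  # stays legal and the fractional weight absorbs the shift
  eps <- 1e-9
  inside <- x >= 1 - eps & y >= 1 - eps & z >= 1 - eps &
    x <= d[1] + eps & y <= d[2] + eps & z <= d[3] + eps
  x0c <- pmin(pmax(floor(x), 1), d[1] - 1)
  y0c <- pmin(pmax(floor(y), 1), d[2] - 1)
  z0c <- pmin(pmax(floor(z), 1), d[3] - 1)
  fxc <- x - x0c; fyc <- y - y0c; fzc <- z - z0c
  base <- x0c + (y0c - 1) * d[1] + (z0c - 1) * d[1] * d[2]
  sxy <- d[1] * d[2]
  v000 <- values[base]
  v100 <- values[base + 1]
  v010 <- values[base + d[1]]
  v110 <- values[base + d[1] + 1]
  v001 <- values[base + sxy]
  v101 <- values[base + sxy + 1]
  v011 <- values[base + sxy + d[1]]
  v111 <- values[base + sxy + d[1] + 1]
  out <- (v000 * (1 - fxc) + v100 * fxc) * (1 - fyc) * (1 - fzc) +
         (v010 * (1 - fxc) + v110 * fxc) * fyc       * (1 - fzc) +
         (v001 * (1 - fxc) + v101 * fxc) * (1 - fyc) * fzc +
         (v011 * (1 - fxc) + v111 * fxc) * fyc       * fzc
  out[!inside] <- fill
  out
}

# nearest-neighbour sampling, same conventions as .sample_trilinear
.sample_nearest <- function(values, idx, fill = -1000) {
  d <- dim(values)
  if (is.matrix(idx)) {
    i <- round(idx[, 1]); j <- round(idx[, 2]); k <- round(idx[, 3])
  } else {
    i <- round(idx$x); j <- round(idx$y); k <- round(idx$z)
  }
  inside <- i >= 1 & j >= 1 & k >= 1 & i <= d[1] & j <= d[2] & k <= d[3]
  ic <- pmin(pmax(i, 1), d[1]); jc <- pmin(pmax(j, 1), d[2])
  kc <- pmin(pmax(k, 1), d[3])
  out <- values[ic + (jc - 1) * d[1] + (kc - 1) * d[1] * d[2]]
  out[!inside] <- fill
  out
}

# full index grid of a volume as an n x 3 matrix (column-major order)
.index_grid <- function(d) {
  cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
        rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}
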