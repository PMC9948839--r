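#' Rigid 3D rotation specification
#'
#' Rotation angles in degrees about the world x, y and z axes, applied
#' extrinsically (fixed world axes) in the order x, then y, then z;
#' right-handed, counter-clockwise positive looking down each axis towards
#' the origin. The rotation center is the volume center by default, the
#' intensity center-of-mass (`"mass_center"`, e.g. of the intracranial
#' volume), or an explicit point in mm.
#'
#' @param angles_deg Numeric length-3 (x, y, z) or length-2 (x, y; z = 0)
#'   rotation angles in degrees.
#' @param center_mode One of `"volume_center"`, `"mass_center"`,
#'   `"explicit"`.
#' @param explicit_center_mm Length-3 point in mm, required when
#'   `center_mode == "explicit"`.
#' @return An object of class `rigid_rotation`.
#' @export
rigid_rotation <- function(angles_deg,
                           center_mode = c("volume_center", "mass_center",
                                           "explicit"),
                           explicit_center_mm = NULL) {
  center_mode <- match.arg(center_mode)
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) == 2L) angles_deg <- c(angles_deg, 0)
  if (length(angles_deg) != 3L || any(!is.finite(angles_deg)))
    stop("angles_deg must be 2 or 3 finite angles in degrees")
  if (center_mode == "explicit") {
    if (is.null(explicit_center_mm) || length(explicit_center_mm) != 3L)
      stop("explicit center_mode requires explicit_center_mm (3-vector, mm)")
    explicit_center_mm <- as.numeric(explicit_center_mm)
  }
  structure(list(angles_deg = angles_deg, center_mode = center_mode,
                 explicit_center_mm = explicit_center_mm),
            class = "rigid_rotation")
}

#' Rotation matrix for a rigid rotation
#'
#' Composes the extrinsic rotation Rz(az) Ry(ay) Rx(ax) (x applied first,
#' about fixed world axes; right-handed, counter-clockwise positive).
#'
#' @param angles_deg Length-3 angles in degrees, or a [rigid_rotation()].
#' @return A 3x3 orthonormal rotation matrix.
#' @export
rotation_matrix <- function(angles_deg) {
  if (inherits(angles_deg, "rigid_rotation"))
    angles_deg <- angles_deg$angles_deg
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

resolve_center_mm <- function(v, r) {
  d <- spatial_dim(v)
  switch(r$center_mode,
    volume_center = (d - 1) / 2 * v$voxel_size,
    mass_center = {
      img <- v$image
      if (length(dim(img)) == 4L) img <- img[, , , 1]
      w <- img - min(img)
      tw <- sum(w)
      if (tw <= 0) return((d - 1) / 2 * v$voxel_size)
      idx <- voxel_index_grid(d)
      c(sum(idx$i * w), sum(idx$j * w), sum(idx$k * w)) / tw * v$voxel_size
    },
    explicit = r$explicit_center_mm)
}

# 0-based voxel index grids for a 3D shape, as vectors in array order
voxel_index_grid <- function(d) {
  list(i = rep.int(0:(d[1] - 1), d[2] * d[3]),
       j = rep.int(rep(0:(d[2] - 1), each = d[1]), d[3]),
       k = rep(0:(d[3] - 1), each = d[1] * d[2]))
}

# Source voxel coordinates (0-based, fractional, 3 x N) for resampling:
# each output voxel is pulled from R^-1 (x - c) + c in mm space.
source_coords <- function(d, voxel_size, rot_inv, center_mm) {
  idx <- voxel_index_grid(d)
  mm <- rbind(idx$i * voxel_size[1] - center_mm[1],
              idx$j * voxel_size[2] - center_mm[2],
              idx$k * voxel_size[3] - center_mm[3])
  src <- rot_inv %*% mm + center_mm
  src / voxel_size
}

# Nearest-neighbor gather plan: linear indices + validity mask
nearest_plan <- function(src, d) {
  r1 <- round(src[1, ]); r2 <- round(src[2, ]); r3 <- round(src[3, ])
  valid <- r1 >= 0 & r1 <= d[1] - 1 & r2 >= 0 & r2 <= d[2] - 1 &
    r3 >= 0 & r3 <= d[3] - 1
  lin <- r1 + d[1] * (r2 + d[2] * r3) + 1
  lin[!valid] <- 1L
  list(lin = lin, valid = valid)
}

apply_nearest <- function(arr, plan, pad = 0L) {
  out <- arr[plan$lin]
  out[!plan$valid] <- pad
  out
}

# Trilinear gather plan: 8 corner index vectors with weights; corners that
# fall outside the volume contribute the padding value.
trilinear_plan <- function(src, d) {
  f1 <- floor(src[1, ]); f2 <- floor(src[2, ]); f3 <- floor(src[3, ])
  w1 <- src[1, ] - f1; w2 <- src[2, ] - f2; w3 <- src[3, ] - f3
  corners <- vector("list", 8L)
  n <- 1L
  for (o3 in 0:1) for (o2 in 0:1) for (o1 in 0:1) {
    c1 <- f1 + o1; c2 <- f2 + o2; c3 <- f3 + o3
    valid <- c1 >= 0 & c1 <= d[1] - 1 & c2 >= 0 & c2 <= d[2] - 1 &
      c3 >= 0 & c3 <= d[3] - 1
    w <- (if (o1) w1 else 1 - w1) * (if (o2) w2 else 1 - w2) *
      (if (o3) w3 else 1 - w3)
    lin <- c1 + d[1] * (c2 + d[2] * c3) + 1
    lin[!valid] <- 1L
    corners[[n]] <- list(lin = lin, w = w, valid = valid)
    n <- n + 1L
  }
  corners
}

apply_trilinear <- function(arr, plan, pad = 0) {
  out <- numeric(length(plan[[1]]$lin))
  for (cr in plan) {
    val <- arr[cr$lin]
    val[!cr$valid] <- pad
    out <- out + cr$w * val
  }
  out
}

# Shared worker: resample image (trilinear) + labels (nearest) by an
# arbitrary rotation matrix about a center in mm. Used directly for the
# inverse back-transformations of the sensitivity engine.
resample_rigid <- function(v, rot, center_mm, image_pad = 0, label_pad = 0L) {
  d <- spatial_dim(v)
  src <- source_coords(d, v$voxel_size, t(rot), center_mm)
  tp <- trilinear_plan(src, d)
  np <- nearest_plan(src, d)
  img <- v$image
  if (length(dim(img)) == 4L) {
    nvol <- dim(img)[4]
    out_img <- array(0, dim(img))
    for (t in seq_len(nvol))
      out_img[, , , t] <- array(apply_trilinear(img[, , , t], tp, image_pad), d)
  } else {
    out_img <- array(apply_trilinear(img, tp, image_pad), d)
  }
  out_lab <- array(apply_nearest(v$labels, np, label_pad), d)
  storage.mode(out_lab) <- "integer"
  res <- v
  res$image <- out_img
  res$labels <- out_lab
  attr(res, "valid_mask") <- array(np$valid, d)
  res
}

#' Rotate a labeled volume
#'
#' Rigidly rotates image and labels onto the same voxel grid: the image is
#' resampled with trilinear interpolation, the labels with nearest-neighbor
#' so that label IDs stay integral and no new IDs appear. Voxels pulled from
#' outside the field of view take the padding value (0 for both image and
#' labels). A 4D image rotates every 3D sub-volume with the same transform.
#' Identity angles return the input unchanged (no resampling error).
#'
#' @param v A [labeled_volume()].
#' @param r A [rigid_rotation()].
#' @return A rotated [labeled_volume()]; attribute `"valid_mask"` marks
#'   voxels whose value originates inside the input field of view.
#' @export
rotate_volume <- function(v, r) {
  stopifnot(inherits(v, "labeled_volume"), inherits(r, "rigid_rotation"))
  if (all(r$angles_deg == 0)) {
    attr(v, "valid_mask") <- array(TRUE, spatial_dim(v))
    return(v)
  }
  resample_rigid(v, rotation_matrix(r), resolve_center_mm(v, r))
}

#' Mirror a labeled volume along image axes
#'
#' Reverses image and labels along the chosen axes. Applying the same mirror
#' twice restores the input exactly (involution).
#'
#' @param v A [labeled_volume()].
#' @param axes Axes to mirror: subset of `c("x","y","z")` (or integers 1:3).
#'   Empty means identity.
#' @return The mirrored [labeled_volume()].
#' @export
mirror_volume <- function(v, axes = character()) {
  stopifnot(inherits(v, "labeled_volume"))
  if (is.character(axes)) {
    if (!all(axes %in% c("x", "y", "z")))
      stop("axes must be a subset of x, y, z")
    axes <- match(axes, c("x", "y", "z"))
  }
  axes <- unique(as.integer(axes))
  if (length(axes) == 0L) return(v)
  if (any(axes < 1L | axes > 3L)) stop("axes out of range")
  d <- spatial_dim(v)
  ix <- lapply(1:3, function(a)
    if (a %in% axes) d[a]:1 else seq_len(d[a]))
  if (length(dim(v$image)) == 4L) {
    v$image <- v$image[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
  } else {
    v$image <- v$image[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  }
  v$labels <- v$labels[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  v
}

#' Linear intensity transform of a volume
#'
#' Every image voxel value i becomes `scale * i + offset` (scale applied
#' before offset); labels are unchanged. This is the test-time intensity
#' perturbation swept by the intensity sensitivity grid.
#'
#' @param v A [labeled_volume()].
#' @param scale Non-zero finite multiplier.
#' @param offset Finite additive term, in the intensity units of the image
#'   (normalized units if the volume was z-normalized).
#' @return The transformed [labeled_volume()].
#' @export
apply_intensity_affine <- function(v, scale, offset) {
  stopifnot(inherits(v, "labeled_volume"))
  if (!is.finite(scale) || scale == 0) stop("scale must be finite, non-zero")
  if (!is.finite(offset)) stop("offset must be finite")
  v$image <- v$image * scale + offset
  v
}

#' Second-degree polynomial intensity transform
#'
#' Every image voxel value i becomes `c1 * i^2 + c2 * i + c3`. This is the
#' transfer function applied during histogram-landmark intensity
#' augmentation, with coefficients drawn from [sample_intensity_augmentation()].
#'
#' @param v A [labeled_volume()].
#' @param coefficients Numeric length-3 `(c1, c2, c3)`, all finite.
#' @return The transformed [labeled_volume()]; labels unchanged.
#' @export
polynomial_intensity_transform <- function(v, coefficients) {
  stopifnot(inherits(v, "labeled_volume"))
  cf <- as.numeric(coefficients)
  if (length(cf) != 3L || any(!is.finite(cf)))
    stop("coefficients must be 3 finite values (c1, c2, c3)")
  v$image <- cf[1] * v$image^2 + cf[2] * v$image + cf[3]
  v
}

#' Co-rotate a diffusion gradient scheme
#'
#' Applies the same rotation matrix used on the volume to every
#' diffusion-weighting direction, so that the gradient table stays consistent
#' with the rotated 4D data. b-values are unchanged; unit norms are
#' preserved.
#'
#' @param g A [gradient_scheme()].
#' @param r A [rigid_rotation()].
#' @return The rotated [gradient_scheme()].
#' @export
rotate_gradient_scheme <- function(g, r) {
  stopifnot(inherits(g, "gradient_scheme"), inherits(r, "rigid_rotation"))
  g$bvecs <- rotation_matrix(r) %*% g$bvecs
  g
}
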