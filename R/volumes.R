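#' Labeled image volume
#'
#' Container pairing a 3D (or 4D, last axis = diffusion volumes) image with an
#' integer label volume of the same spatial shape, plus the voxel geometry
#' needed to express rotation centers in millimetres.
#'
#' @param image Numeric 3D or 4D array of voxel intensities.
#' @param labels Integer-valued 3D array of non-negative label IDs; 0 is
#'   background. Must match the spatial shape of `image`.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param orientation_code Three-letter anatomical axis code (e.g. "LPS",
#'   "PSR") recording which world direction each voxel axis points along.
#' @param subject_id Opaque identifier string.
#'
#' @return An object of class `labeled_volume`: a list with elements `image`,
#'   `labels`, `voxel_size`, `orientation_code`, `subject_id`.
#' @export
#' @examples
#' img <- array(rnorm(8^3), dim = c(8, 8, 8))
#' lab <- array(0L, dim = c(8, 8, 8)); lab[3:5, 3:5, 3:5] <- 1L
#' v <- labeled_volume(img, lab)
labeled_volume <- function(image, labels,
                           voxel_size = c(1, 1, 1),
                           orientation_code = "LPS",
                           subject_id = "subject") {
  image <- as.array(image)
  labels <- as.array(labels)
  nd <- length(dim(image))
  if (!nd %in% c(3L, 4L))
    stop("image must be a 3D or 4D array, got ", nd, " dimensions")
  spatial <- dim(image)[1:3]
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (!identical(as.integer(dim(labels)), as.integer(spatial)))
    stop(sprintf("spatial shape mismatch: image %s vs labels %s",
                 paste(spatial, collapse = "x"),
                 paste(dim(labels), collapse = "x")))
  if (anyNA(labels) || any(labels < 0))
    stop("labels must be non-negative")
  if (max(abs(labels - round(labels))) > 1e-6)
    stop("labels contain non-integer values")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be 3 positive finite lengths in mm")
  if (!is.character(orientation_code) || nchar(orientation_code) != 3L)
    stop("orientation_code must be a 3-letter string")
  storage.mode(labels) <- "integer"
  structure(list(image = image, labels = labels, voxel_size = voxel_size,
                 orientation_code = toupper(orientation_code),
                 subject_id = as.character(subject_id)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<labeled_volume '%s'> %s voxels, %s mm, %s, labels: %s\n",
              x$subject_id, paste(d, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              x$orientation_code,
              paste(setdiff(sort(unique(as.vector(x$labels))), 0L),
                    collapse = ",")))
  invisible(x)
}

spatial_dim <- function(v) dim(v$image)[1:3]

#' Read an image/label NIfTI pair
#'
#' Reads an image volume and its label volume from NIfTI-1/2 files. Geometry
#' (voxel size, orientation) is taken from the image header; label values are
#' cast to integers with exact value preservation.
#'
#' @param image_path Path to the image NIfTI file (.nii / .nii.gz).
#' @param labels_path Path to the label NIfTI file; spatial dimensions must
#'   match the image.
#' @param subject_id Identifier stored on the result; defaults to the image
#'   file name without extension.
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(image_path, labels_path,
                                subject_id = NULL) {
  img <- RNifti::readNifti(image_path)
  lab <- RNifti::readNifti(labels_path)
  lab_arr <- as.array(lab)
  if (length(dim(lab_arr)) > 3L) {
    if (all(dim(lab_arr)[-(1:3)] == 1L)) {
      dim(lab_arr) <- dim(lab_arr)[1:3]
    } else stop("labels file must be a single 3D volume")
  }
  img_arr <- as.array(img)
  if (!identical(as.integer(dim(img_arr)[1:3]), as.integer(dim(lab_arr))))
    stop(sprintf("spatial shape mismatch: image %s vs labels %s",
                 paste(dim(img_arr)[1:3], collapse = "x"),
                 paste(dim(lab_arr), collapse = "x")))
  if (max(abs(lab_arr - round(lab_arr))) > 1e-6)
    stop("labels contain non-integer values beyond tolerance 1e-6")
  lab_arr <- round(lab_arr)
  pix <- RNifti::pixdim(img)[1:3]
  orient <- tryCatch(RNifti::orientation(img), error = function(e) "LPS")
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(image_path))
  labeled_volume(img_arr, lab_arr, voxel_size = pix,
                 orientation_code = orient, subject_id = subject_id)
}

#' Write a labeled volume as a NIfTI image/label pair
#'
#' @param v A [labeled_volume()].
#' @param image_path,labels_path Output paths (.nii or .nii.gz).
#' @return Invisibly, `c(image_path, labels_path)`.
#' @export
write_labeled_volume <- function(v, image_path, labels_path) {
  stopifnot(inherits(v, "labeled_volume"))
  img_arr <- v$image
  storage.mode(img_arr) <- "double"
  img <- RNifti::asNifti(img_arr, internal = FALSE)
  RNifti::pixdim(img) <- v$voxel_size
  RNifti::writeNifti(img, image_path)
  lab <- RNifti::asNifti(v$labels, internal = FALSE)
  RNifti::pixdim(lab) <- v$voxel_size
  RNifti::writeNifti(lab, labels_path)
  invisible(c(image_path, labels_path))
}

#' Diffusion gradient scheme
#'
#' b-values and diffusion-weighting directions accompanying a 4D
#' diffusion-weighted volume. Non-zero directions must be unit vectors; b = 0
#' rows may be zero vectors.
#'
#' @param bvals Numeric vector of non-negative b-values in s/mm^2.
#' @param bvecs 3 x n numeric matrix of direction vectors (one column per
#'   diffusion volume).
#' @return An object of class `gradient_scheme` with elements `bvals`,
#'   `bvecs`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L)
    stop("bvecs must have 3 rows (x, y, z components)")
  if (length(bvals) != ncol(bvecs))
    stop(sprintf("entry count mismatch: %d b-values vs %d b-vectors",
                 length(bvals), ncol(bvecs)))
  if (any(bvals < 0) || any(!is.finite(bvals)))
    stop("b-values must be non-negative and finite")
  nrm <- sqrt(colSums(bvecs^2))
  nz <- bvals > 0
  if (any(nz)) {
    off <- abs(nrm[nz] - 1)
    if (any(off > 1e-3))
      stop("non-zero b-vector norm deviates from 1 by more than 1e-3")
    bvecs[, nz] <- sweep(bvecs[, nz, drop = FALSE], 2, nrm[nz], "/")
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_scheme")
}

#' Read an FSL-dialect bval/bvec gradient table
#'
#' Parses whitespace-separated bval/bvec text files. The canonical FSL layout
#' is one row of b-values and a 3-row b-vector matrix; a transposed (3-column)
#' bvec file is accepted with a warning. Non-zero vectors off unit norm by at
#' most 1e-3 are renormalized.
#'
#' @param bval_path,bvec_path Paths to the text files.
#' @return A [gradient_scheme()].
#' @export
read_gradient_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  lines <- readLines(bvec_path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  nc <- vapply(rows, length, integer(1))
  if (length(unique(nc)) != 1L)
    stop("ragged bvec file: rows have differing lengths")
  m <- do.call(rbind, rows)
  if (nrow(m) != 3L && ncol(m) == 3L) {
    warning("bvec file appears transposed (3 columns); transposing")
    m <- t(m)
  }
  if (nrow(m) != 3L)
    stop("bvec file must have 3 rows (or 3 columns)")
  if (ncol(m) != length(bvals))
    stop(sprintf("entry count mismatch: %d b-values vs %d b-vectors",
                 length(bvals), ncol(m)))
  gradient_scheme(bvals, m)
}

#' Write a gradient scheme as FSL bval/bvec text files
#' @param g A [gradient_scheme()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, `c(bval_path, bvec_path)`.
#' @export
write_gradient_scheme <- function(g, bval_path, bvec_path) {
  stopifnot(inherits(g, "gradient_scheme"))
  writeLines(paste(format(g$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(g$bvecs, 1, function(r)
    paste(format(r, trim = TRUE), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Normalize a volume to zero mean and unit variance
#'
#' Volume-wise z-normalization over all voxels (population variance), the
#' standard preprocessing applied before feeding a volume to a segmentation
#' network. Labels are untouched. Idempotent to numerical precision.
#'
#' @param v A [labeled_volume()] whose image has at least 2 distinct values.
#' @return A [labeled_volume()] with normalized image.
#' @export
normalize_volume <- function(v) {
  stopifnot(inherits(v, "labeled_volume"))
  x <- v$image
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0)
    stop("degenerate input: constant image has no variance to normalize")
  v$image <- (x - m) / sqrt(s2)
  v
}
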