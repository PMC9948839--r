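#' Default histogram landmark fractions
#'
#' Percentile fractions from 12.5% to 87.5% in steps of 12.5% (7 landmarks),
#' the positions used to summarize an intensity histogram for
#' landmark-matching intensity augmentation.
#' @return Numeric vector of 7 fractions.
#' @export
default_landmark_fractions <- function() seq(0.125, 0.875, by = 0.125)

#' Extract histogram landmarks from an image
#'
#' Returns the intensity quantiles of all voxels at the given percentile
#' fractions (linear interpolation between order statistics).
#'
#' @param image Numeric array (or vector) of voxel intensities; must be
#'   non-constant.
#' @param fractions Strictly increasing fractions in (0, 1).
#' @return Non-decreasing numeric vector of landmark intensities.
#' @export
extract_landmarks <- function(image, fractions = default_landmark_fractions()) {
  x <- as.vector(image)
  if (length(unique(range(x))) == 1L)
    stop("degenerate input: constant image has no histogram landmarks")
  fractions <- as.numeric(fractions)
  if (any(fractions <= 0) || any(fractions >= 1) ||
      is.unsorted(fractions, strictly = TRUE))
    stop("fractions must be strictly increasing and inside (0, 1)")
  unname(stats::quantile(x, probs = fractions, type = 7, names = FALSE))
}

#' Fit a quadratic transfer function between two landmark sets
#'
#' Least-squares fit of the coefficients (c1, c2, c3) of the second-degree
#' polynomial `b = c1 a^2 + c2 a + c3` mapping the histogram landmarks of one
#' dataset onto another's.
#'
#' @param landmarks_a,landmarks_b Equal-length numeric vectors (length >= 3):
#'   source and target landmark intensities.
#' @return Numeric length-3 `(c1, c2, c3)`.
#' @export
fit_transfer_function <- function(landmarks_a, landmarks_b) {
  a <- as.numeric(landmarks_a)
  b <- as.numeric(landmarks_b)
  if (length(a) != length(b)) stop("landmark vectors must have equal length")
  if (length(a) < 3L) stop("need at least 3 landmarks to fit 3 coefficients")
  if (diff(range(a)) == 0)
    stop("singular fit: all source landmarks identical")
  x <- cbind(a^2, a, 1)
  cf <- qr.solve(x, b)
  unname(cf)
}

#' Fit a population transfer-function model from many landmark sets
#'
#' Fits the quadratic transfer function for every ordered pair of landmark
#' sets (a -> b, a != b) and summarizes each coefficient's distribution by
#' its sample mean and sample standard deviation (normal-distribution
#' parameterization), ready for random sampling during training.
#'
#' @param landmark_sets List of >= 2 equal-length landmark vectors.
#' @param fractions The percentile fractions the landmarks were taken at
#'   (metadata, stored on the model).
#' @return An object of class `transfer_function_model`: list with `mean_c`,
#'   `std_c` (length-3 each), `n_pairs`, `landmark_fractions`.
#' @export
build_transfer_model <- function(landmark_sets,
                                 fractions = default_landmark_fractions()) {
  if (!is.list(landmark_sets) || length(landmark_sets) < 2L)
    stop("need at least 2 landmark sets")
  n <- length(landmark_sets)
  fits <- matrix(0, nrow = n * (n - 1), ncol = 3)
  row <- 1L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    fits[row, ] <- fit_transfer_function(landmark_sets[[i]],
                                         landmark_sets[[j]])
    row <- row + 1L
  }
  structure(list(mean_c = colMeans(fits),
                 std_c = apply(fits, 2, stats::sd),
                 n_pairs = n * (n - 1L),
                 landmark_fractions = as.numeric(fractions)),
            class = "transfer_function_model")
}

#' @export
print.transfer_function_model <- function(x, ...) {
  cat(sprintf(
    "<transfer_function_model> %d pairs; C = (%.4g, %.4g, %.4g) +/- (%.3g, %.3g, %.3g)\n",
    x$n_pairs, x$mean_c[1], x$mean_c[2], x$mean_c[3],
    x$std_c[1], x$std_c[2], x$std_c[3]))
  invisible(x)
}

#' Serialize / restore a transfer-function model as JSON
#'
#' @param model A `transfer_function_model`.
#' @param path File path for the JSON document.
#' @return `write_transfer_model` invisibly returns `path`;
#'   `read_transfer_model` returns the restored model.
#' @export
write_transfer_model <- function(model, path) {
  stopifnot(inherits(model, "transfer_function_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transfer_model
#' @export
read_transfer_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean_c = as.numeric(x$mean_c), std_c = as.numeric(x$std_c),
                 n_pairs = as.integer(x$n_pairs),
                 landmark_fractions = as.numeric(x$landmark_fractions)),
            class = "transfer_function_model")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Draw random transfer-function coefficients
#'
#' Draws each coefficient independently from Normal(mean_c, std_c) of a
#' fitted [build_transfer_model()], giving the randomized polynomial applied
#' by [polynomial_intensity_transform()] during intensity augmentation.
#'
#' @param model A `transfer_function_model`.
#' @param rng_seed Optional integer seed; the same seed yields the same
#'   triple and the caller's RNG state is untouched.
#' @return Numeric length-3 coefficient triple.
#' @export
sample_intensity_augmentation <- function(model, rng_seed = NULL) {
  stopifnot(inherits(model, "transfer_function_model"))
  with_seed(rng_seed, stats::rnorm(3, mean = model$mean_c, sd = model$std_c))
}

#' Rotation-augmentation configuration
#'
#' Type 1 mirrors the data independently along each image axis (x, y, z) with
#' a per-axis probability (default 50%). Type 2 additionally draws one random
#' rotation angle about the x-axis from a discrete choice set (default
#' 0, 30 or 50 degrees) — the x-axis because natural head movements (nodding)
#' occur mostly about it.
#'
#' @param aug_type `"type1"` or `"type2"`.
#' @param mirror_probability Per-axis mirror probability in \[0, 1\].
#' @param discrete_x_angles_deg Non-empty angle choice set for type 2.
#' @return An object of class `rotation_aug_config`.
#' @export
rotation_aug_config <- function(aug_type = c("type1", "type2"),
                                mirror_probability = 0.5,
                                discrete_x_angles_deg = c(0, 30, 50)) {
  aug_type <- match.arg(aug_type)
  if (mirror_probability < 0 || mirror_probability > 1)
    stop("mirror_probability must be in [0, 1]")
  discrete_x_angles_deg <- as.numeric(discrete_x_angles_deg)
  if (aug_type == "type2" && length(discrete_x_angles_deg) == 0L)
    stop("type2 requires a non-empty discrete_x_angles_deg")
  structure(list(aug_type = aug_type,
                 mirror_probability = mirror_probability,
                 discrete_x_angles_deg = discrete_x_angles_deg),
            class = "rotation_aug_config")
}

#' Draw one rotation-augmentation sample
#'
#' Each axis is mirrored independently with the configured probability; a
#' type-2 configuration additionally draws one x-rotation angle uniformly
#' from its choice set (type 1 always returns angle 0). Mirroring is applied
#' first, then the x-rotation.
#'
#' @param cfg A [rotation_aug_config()].
#' @param rng_seed Optional integer seed for reproducibility.
#' @return List with `mirror_axes` (character subset of x, y, z) and
#'   `x_angle_deg`.
#' @export
sample_rotation_augmentation <- function(cfg, rng_seed = NULL) {
  stopifnot(inherits(cfg, "rotation_aug_config"))
  with_seed(rng_seed, {
    ax <- c("x", "y", "z")[stats::runif(3) < cfg$mirror_probability]
    ang <- if (cfg$aug_type == "type2") {
      cfg$discrete_x_angles_deg[sample.int(
        length(cfg$discrete_x_angles_deg), 1L)]
    } else 0
    list(mirror_axes = ax, x_angle_deg = ang)
  })
}
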