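#' Sorensen-Dice coefficient of two binary masks
#'
#' DSC = 2 |A ∩ B| / (|A| + |B|), ranging from 0 (disjoint) to 1 (complete
#' overlap). When both masks are empty the formula is 0/0; by convention the
#' score is 1.0 (the segmentations agree that nothing is there) and the result
#' carries a `degenerate` flag so aggregation can exclude it.
#'
#' @param reference Logical/0-1 array, the reference (ground-truth) mask.
#' @param prediction Logical/0-1 array of the same shape.
#' @return An object of class `overlap_score`: list with `dsc`, `n_ref`,
#'   `n_pred`, `n_intersect`, `degenerate`.
#' @export
#' @examples
#' a <- array(c(1, 1, 0, 0), c(2, 2)); b <- array(c(1, 0, 1, 0), c(2, 2))
#' dice(a, b)$dsc  # 0.5
dice <- function(reference, prediction) {
  if (!identical(dim2(reference), dim2(prediction)))
    stop(sprintf("shape mismatch: reference %s vs prediction %s",
                 paste(dim2(reference), collapse = "x"),
                 paste(dim2(prediction), collapse = "x")))
  a <- as.logical(reference)
  b <- as.logical(prediction)
  n_ref <- sum(a)
  n_pred <- sum(b)
  n_int <- sum(a & b)
  if (n_ref + n_pred == 0L) {
    return(structure(list(dsc = 1.0, n_ref = 0L, n_pred = 0L,
                          n_intersect = 0L, degenerate = TRUE),
                     class = "overlap_score"))
  }
  structure(list(dsc = 2 * n_int / (n_ref + n_pred),
                 n_ref = as.integer(n_ref), n_pred = as.integer(n_pred),
                 n_intersect = as.integer(n_int), degenerate = FALSE),
            class = "overlap_score")
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' @export
print.overlap_score <- function(x, ...) {
  cat(sprintf("<overlap_score> DSC = %.4f (|ref| = %d, |pred| = %d, |int| = %d%s)\n",
              x$dsc, x$n_ref, x$n_pred, x$n_intersect,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Per-label Dice scores between two label volumes
#'
#' Binarizes both volumes per label ID and computes [dice()] for each,
#' e.g. to score each white-matter tract of a multi-tract segmentation
#' separately before averaging across tracts.
#'
#' @param reference,prediction Integer label arrays of identical shape.
#' @param label_ids Integer vector of label IDs to score (non-empty). Defaults
#'   to all non-background IDs present in `reference`.
#' @return Named list of `overlap_score`, one per label ID.
#' @export
dice_per_label <- function(reference, prediction, label_ids = NULL) {
  if (!identical(dim2(reference), dim2(prediction)))
    stop("shape mismatch between reference and prediction")
  if (is.null(label_ids))
    label_ids <- setdiff(sort(unique(as.vector(reference))), 0L)
  if (length(label_ids) == 0L)
    stop("label_ids must be non-empty")
  out <- lapply(label_ids, function(id)
    dice(reference == id, prediction == id))
  names(out) <- as.character(label_ids)
  out
}
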