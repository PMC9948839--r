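#' STAPLE consensus of binary segmentations
#'
#' Simultaneous Truth and Performance Level Estimation: an
#' expectation-maximization algorithm that estimates a hidden true binary
#' segmentation together with each input segmentation's sensitivity p_k and
#' specificity q_k. The E-step computes the voxelwise posterior foreground
#' probability from the current (p_k, q_k) and the foreground prior; the
#' M-step re-estimates (p_k, q_k) from the posteriors. Iteration stops when
#' the mean absolute change of the posteriors falls below `tol` or after
#' `max_iter` iterations. The incomplete-data log-likelihood is tracked and
#' is non-decreasing across iterations.
#'
#' Consensus quality depends on the inputs: the estimate is only meaningful
#' when a sufficiently large share of the segmentations is itself meaningful
#' — with mostly random raters the consensus degrades accordingly.
#'
#' @param raters List of >= 2 binary masks (logical/0-1 arrays) of identical
#'   shape. At least one voxel must be on in some mask and one off in some
#'   mask.
#' @param prior Global foreground prior probability, or `"auto"` (the mean
#'   foreground fraction across raters).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the mean absolute posterior change.
#' @param threshold Probability threshold for the binarized consensus mask.
#' @param valid_mask Optional logical array: voxels to include in the
#'   estimation (e.g. the region seen by all back-transformed raters).
#'   Excluded voxels get consensus probability 0.
#' @return An object of class `staple_result`: list with
#'   `consensus_probability` (array in \[0,1\]), `consensus_mask` (binary
#'   array, probability >= threshold), `sensitivities`, `specificities`
#'   (per-rater), `n_iterations`, `converged`, `log_likelihood` (trace),
#'   `prior`.
#' @references Warfield, Zou & Wells (2004) IEEE TMI 23(7):903-921.
#' @export
staple_consensus <- function(raters, prior = "auto", max_iter = 100L,
                             tol = 1e-6, threshold = 0.5,
                             valid_mask = NULL) {
  if (!is.list(raters) || length(raters) < 2L)
    stop("need at least 2 rater masks")
  dims <- dim2(raters[[1]])
  for (k in seq_along(raters)) {
    if (!identical(dim2(raters[[k]]), dims))
      stop(sprintf("shape mismatch: rater %d is %s, expected %s", k,
                   paste(dim2(raters[[k]]), collapse = "x"),
                   paste(dims, collapse = "x")))
  }
  keep <- if (is.null(valid_mask)) NULL else which(as.logical(valid_mask))
  d <- vapply(raters, function(m) {
    x <- as.numeric(as.logical(m))
    if (is.null(keep)) x else x[keep]
  }, numeric(if (is.null(keep)) prod(dims) else length(keep)))
  nvox <- nrow(d)
  nk <- ncol(d)
  fg_frac <- colMeans(d)
  if (all(fg_frac == 1) || all(fg_frac == 0))
    stop("degenerate input: all raters are everywhere-on or everywhere-off, ",
         "performance parameters are unidentifiable")
  pr <- if (identical(prior, "auto")) mean(fg_frac) else as.numeric(prior)
  if (pr <= 0 || pr >= 1) stop("prior must lie strictly inside (0, 1)")

  p <- rep(0.9999, nk)  # sensitivity per rater
  q <- rep(0.9999, nk)  # specificity per rater
  w_prev <- NULL
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  eps <- 1e-12
  repeat {
    iter <- iter + 1L
    # E-step in log space: posterior foreground probability per voxel
    la <- log(pr) + d %*% log(pmax(p, eps)) +
      (1 - d) %*% log(pmax(1 - p, eps))
    lb <- log(1 - pr) + d %*% log(pmax(1 - q, eps)) +
      (1 - d) %*% log(pmax(q, eps))
    m <- pmax(la, lb)
    ll_trace <- c(ll_trace, sum(m + log(exp(la - m) + exp(lb - m))))
    w <- 1 / (1 + exp(lb - la))
    if (!is.null(w_prev) && mean(abs(w - w_prev)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    w_prev <- w
    # M-step
    sw <- sum(w)
    sv <- sum(1 - w)
    p <- as.vector(crossprod(d, w)) / sw
    q <- as.vector(crossprod(1 - d, 1 - w)) / sv
  }

  prob <- array(0, dims)
  if (is.null(keep)) prob[] <- w else prob[keep] <- w
  structure(list(consensus_probability = prob,
                 consensus_mask = prob >= threshold,
                 sensitivities = as.vector(p),
                 specificities = as.vector(q),
                 n_iterations = iter,
                 converged = converged,
                 log_likelihood = ll_trace,
                 prior = pr),
            class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf(
    "<staple_result> %d raters, %d iterations (%s), prior %.3f\n",
    length(x$sensitivities), x$n_iterations,
    if (x$converged) "converged" else "not converged", x$prior))
  cat("  sensitivity p_k:", paste(sprintf("%.3f", x$sensitivities),
                                  collapse = " "), "\n")
  cat("  specificity q_k:", paste(sprintf("%.3f", x$specificities),
                                  collapse = " "), "\n")
  invisible(x)
}

#' Multi-label STAPLE consensus
#'
#' Runs binary STAPLE independently for each label ID of a set of label
#' volumes (per-structure consensus, e.g. per white-matter tract) and fuses
#' the binary consensus masks into one label volume. Voxels claimed by
#' several labels are assigned to the label with the highest consensus
#' probability.
#'
#' @param raters List of integer label arrays of identical shape.
#' @param label_ids Label IDs to estimate; defaults to all non-background IDs
#'   present in any rater.
#' @param ... Passed to [staple_consensus()].
#' @return List with `labels` (fused consensus label array) and `per_label`
#'   (named list of `staple_result`).
#' @export
staple_consensus_multilabel <- function(raters, label_ids = NULL, ...) {
  if (is.null(label_ids)) {
    label_ids <- sort(unique(unlist(lapply(raters, function(m)
      setdiff(unique(as.vector(m)), 0L)))))
  }
  if (length(label_ids) == 0L) stop("no foreground labels found")
  per <- lapply(label_ids, function(id)
    staple_consensus(lapply(raters, function(m) m == id), ...))
  names(per) <- as.character(label_ids)
  dims <- dim2(raters[[1]])
  best_p <- array(0, dims)
  fused <- array(0L, dims)
  for (i in seq_along(label_ids)) {
    pr <- per[[i]]$consensus_probability
    take <- per[[i]]$consensus_mask & pr > best_p
    fused[take] <- as.integer(label_ids[i])
    best_p <- pmax(best_p, pr * per[[i]]$consensus_mask)
  }
  list(labels = fused, per_label = per)
}

#' Simulate independent raters from a known truth
#'
#' Generates binary rater masks from a ground-truth mask under the STAPLE
#' rater model: rater k marks each true-foreground voxel with probability
#' p_k (sensitivity) and each true-background voxel with probability
#' 1 - q_k (1 - specificity), independently per voxel.
#'
#' @param truth Binary ground-truth mask.
#' @param sens,spec Equal-length vectors of per-rater sensitivities and
#'   specificities, values in (0, 1\].
#' @param rng_seed Optional integer seed; the same seed reproduces the same
#'   masks.
#' @return List of binary masks, one per rater.
#' @export
simulate_raters <- function(truth, sens, spec, rng_seed = NULL) {
  if (length(sens) != length(spec) || length(sens) < 1L)
    stop("sens and spec must be equal-length, length >= 1")
  if (any(sens <= 0) || any(sens > 1) || any(spec <= 0) || any(spec > 1))
    stop("sensitivities and specificities must lie in (0, 1]")
  tr <- as.logical(truth)
  dims <- dim2(truth)
  with_seed(rng_seed, {
    lapply(seq_along(sens), function(k) {
      u <- stats::runif(length(tr))
      m <- ifelse(tr, u < sens[k], u < (1 - spec[k]))
      array(m, dims)
    })
  })
}

#' Write a rater performance table as TSV
#'
#' @param result A `staple_result`.
#' @param path Output TSV path.
#' @param rater_ids Optional identifier column; defaults to `rater_1 ...`.
#' @return Invisibly, the written data frame (`rater_id`, `sensitivity`,
#'   `specificity`).
#' @export
write_performance_table <- function(result, path, rater_ids = NULL) {
  stopifnot(inherits(result, "staple_result"))
  n <- length(result$sensitivities)
  if (is.null(rater_ids)) rater_ids <- paste0("rater_", seq_len(n))
  df <- data.frame(rater_id = rater_ids,
                   sensitivity = result$sensitivities,
                   specificity = result$specificities)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
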