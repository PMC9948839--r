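#' N-dimensional perturbation parameter grid
#'
#' Ordered axes of perturbation values spanning the parameter space a
#' sensitivity analysis sweeps. The grid's points are evaluated in array
#' order (first axis fastest); total size is the product of axis lengths.
#'
#' @param axes Named list of numeric vectors (>= 1 axis, each non-empty,
#'   names unique).
#' @param kind One of `"rotation_xy"` (axes are x/y rotation angles in
#'   degrees), `"intensity_scale_offset"` (axes are intensity scale and
#'   offset) or `"custom"`.
#' @return An object of class `parameter_grid`.
#' @export
parameter_grid <- function(axes, kind = c("rotation_xy",
                                          "intensity_scale_offset",
                                          "custom")) {
  kind <- match.arg(kind)
  if (!is.list(axes) || length(axes) < 1L)
    stop("axes must be a non-empty named list")
  nms <- names(axes)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    stop("axis names must be unique and non-empty")
  axes <- lapply(axes, as.numeric)
  if (any(vapply(axes, length, integer(1)) < 1L))
    stop("every axis needs at least one value")
  structure(list(axes = axes, kind = kind), class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("<parameter_grid kind=%s> %d points\n", x$kind, grid_size(x)))
  for (nm in names(x$axes)) {
    v <- x$axes[[nm]]
    cat(sprintf("  %s: %d values in [%g, %g]\n", nm, length(v),
                min(v), max(v)))
  }
  invisible(x)
}

#' Grid size and point enumeration
#' @param grid A [parameter_grid()].
#' @return `grid_size`: total number of points. `grid_points`: data frame
#'   with one row per point (first axis varying fastest) and one column per
#'   axis.
#' @export
grid_size <- function(grid) prod(vapply(grid$axes, length, integer(1)))

#' @rdname grid_size
#' @export
grid_points <- function(grid) {
  do.call(expand.grid, c(grid$axes, KEEP.OUT.ATTRS = FALSE))
}

#' Full-circle x/y rotation grid
#'
#' Rotations about the x- and y-axes over the entire angular space, from
#' -180 to 180 degrees in 20-degree steps: 19 x 19 = 361 configurations.
#' Used to locate a test set's gross orientation relative to the training
#' sample.
#' @return A rotation [parameter_grid()].
#' @export
rotation_grid_case1 <- function() {
  a <- seq(-180, 180, by = 20)
  parameter_grid(list(x_angle_deg = a, y_angle_deg = a), "rotation_xy")
}

#' Intensity scale/offset grid
#'
#' Linear intensity perturbations: 17 scale factors between 1/5 and 5 in
#' non-linear steps (1/5, 1/4.5, 1/4, 1/3.5, 1/3, 1/2.5, 1/2, 1/1.5, 1.0,
#' 1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0) crossed with 17 offsets from
#' -3.0 to 3.0 in linear steps of 3/8: 17 x 17 = 289 configurations. Scale
#' is applied before offset.
#' @return An intensity [parameter_grid()].
#' @export
intensity_grid_case1 <- function() {
  scale <- c(1 / 5, 1 / 4.5, 1 / 4, 1 / 3.5, 1 / 3, 1 / 2.5, 1 / 2,
             1 / 1.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0)
  offset <- seq(-3, 3, by = 3 / 8)
  parameter_grid(list(scale = scale, offset = offset),
                 "intensity_scale_offset")
}

#' Fine x/y rotation grid
#'
#' Small-angle rotations about the x- and y-axes from -16 to 16 degrees in
#' 2-degree steps: 17 x 17 = 289 configurations, suited to probing
#' orientation bias around the native pose (typically with the
#' center-of-mass of the brain volume as rotation center).
#' @return A rotation [parameter_grid()].
#' @export
rotation_grid_case2 <- function() {
  a <- seq(-16, 16, by = 2)
  parameter_grid(list(x_angle_deg = a, y_angle_deg = a), "rotation_xy")
}

#' Segmenter contract
#'
#' Wraps any segmentation routine — a trained network, a classical method, a
#' toy model — as the callable the sensitivity engine drives. The function
#' receives the (possibly 4D) image array and, for diffusion data, the
#' accompanying gradient scheme, and must return a non-negative integer
#' label array matching the input's spatial shape.
#'
#' @param fn `function(image, scheme = NULL)` returning a label array.
#' @param id Opaque identifier recorded in map provenance.
#' @return An object of class `segmenter`.
#' @export
segmenter <- function(fn, id = "segmenter") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, id = as.character(id)), class = "segmenter")
}

run_segmenter <- function(seg, image, scheme = NULL, where = "input") {
  out <- seg$fn(image, scheme)
  out <- as.array(out)
  sp <- dim(image)[1:3]
  if (!identical(as.integer(dim2(out)), as.integer(sp)))
    stop(sprintf(
      "segmenter '%s' contract violation at %s: output %s, expected %s",
      seg$id, where, paste(dim2(out), collapse = "x"),
      paste(sp, collapse = "x")))
  if (any(out < 0) || max(abs(out - round(out))) > 0)
    stop(sprintf("segmenter '%s' returned non-integer or negative labels",
                 seg$id))
  storage.mode(out) <- "integer"
  out
}

#' Identity point of a grid
#'
#' The grid coordinates at which the input is unperturbed: 0 on every
#' rotation/offset axis and 1 on a scale axis. Used as the reference for
#' argmax-offset bias diagnostics.
#' @param grid A [parameter_grid()].
#' @return Named numeric vector, one value per axis.
#' @export
grid_identity_point <- function(grid) {
  vapply(names(grid$axes), function(nm)
    if (identical(nm, "scale")) 1 else 0, numeric(1))
}

transform_at_point <- function(v, grid, point, center_mode,
                               explicit_center_mm, scheme) {
  if (grid$kind == "rotation_xy") {
    r <- rigid_rotation(c(point[[1]], point[[2]]), center_mode,
                        explicit_center_mm)
    vt <- rotate_volume(v, r)
    st <- if (is.null(scheme)) NULL else rotate_gradient_scheme(scheme, r)
    list(volume = vt, scheme = st, rotation = r)
  } else if (grid$kind == "intensity_scale_offset") {
    list(volume = apply_intensity_affine(v, point[["scale"]],
                                         point[["offset"]]),
         scheme = scheme, rotation = NULL)
  } else {
    stop("custom grids need a transform_fn")
  }
}

#' Run a sensitivity analysis
#'
#' The three-step sensitivity workflow: for every grid point, (1) the test
#' volume is systematically modified (rotated, or intensity-transformed) —
#' always starting from the pristine input, (2) the segmenter is run on the
#' modified image, and (3) the segmentation is scored per label with the
#' Dice coefficient against the reference. In `"ground_truth"` mode the
#' reference is the identically transformed ground-truth labels (scores are
#' computed in the perturbed space). In `"staple"` mode no ground truth is
#' needed: every segmentation is first back-transformed to the unperturbed
#' space with the inverse rotation (nearest-neighbor), a STAPLE consensus
#' over all back-transformed segmentations serves as the reference for each
#' label, and voxels that left the field of view in any configuration are
#' excluded via a validity mask.
#'
#' @param v A [labeled_volume()] test volume. Ground-truth mode requires
#'   non-empty labels.
#' @param seg A [segmenter()].
#' @param grid A [parameter_grid()] (rotation or intensity kind, or
#'   `"custom"` with `transform_fn`).
#' @param reference_mode `"ground_truth"` or `"staple"`.
#' @param label_ids Label IDs to score; defaults to all non-background IDs in
#'   `v$labels` (ground-truth mode) or in the segmentations (staple mode).
#' @param center_mode Rotation center: `"volume_center"`, `"mass_center"` or
#'   `"explicit"`.
#' @param explicit_center_mm Rotation center in mm when
#'   `center_mode == "explicit"`.
#' @param scheme Optional [gradient_scheme()] accompanying a 4D diffusion
#'   volume; co-rotated and passed to the segmenter at every rotated point.
#' @param transform_fn For custom grids: `function(v, point)` returning the
#'   modified volume.
#' @param staple_args List of extra arguments for [staple_consensus()].
#' @return An object of class `sensitivity_map`: list with `grid`, `scores`
#'   (array, one dimension per grid axis plus a trailing label dimension),
#'   `degenerate` (logical array, same shape), `label_ids`,
#'   `reference_mode`, `provenance`.
#' @export
run_sensitivity <- function(v, seg, grid,
                            reference_mode = c("ground_truth", "staple"),
                            label_ids = NULL,
                            center_mode = "volume_center",
                            explicit_center_mm = NULL,
                            scheme = NULL,
                            transform_fn = NULL,
                            staple_args = list()) {
  stopifnot(inherits(v, "labeled_volume"), inherits(seg, "segmenter"),
            inherits(grid, "parameter_grid"))
  reference_mode <- match.arg(reference_mode)
  pts <- grid_points(grid)
  npts <- nrow(pts)
  if (reference_mode == "ground_truth") {
    if (is.null(label_ids))
      label_ids <- setdiff(sort(unique(as.vector(v$labels))), 0L)
    if (length(label_ids) == 0L)
      stop("ground_truth mode requires non-empty labels")
  }
  if (reference_mode == "staple" && npts < 2L)
    stop("staple mode needs a grid of size >= 2")

  axis_lens <- vapply(grid$axes, length, integer(1))
  preds <- if (reference_mode == "staple") vector("list", npts) else NULL
  valids <- if (reference_mode == "staple") vector("list", npts) else NULL
  refs <- if (reference_mode == "ground_truth") vector("list", npts) else NULL
  raw_preds <- vector("list", npts)

  for (ip in seq_len(npts)) {
    point <- as.list(pts[ip, , drop = FALSE])
    tr <- if (grid$kind == "custom") {
      if (is.null(transform_fn)) stop("custom grids need a transform_fn")
      list(volume = transform_fn(v, point), scheme = scheme, rotation = NULL)
    } else {
      transform_at_point(v, grid, point, center_mode, explicit_center_mm,
                         scheme)
    }
    where <- paste(names(pts), unlist(point), sep = "=", collapse = ", ")
    pred <- run_segmenter(seg, tr$volume$image, tr$scheme, where)
    raw_preds[[ip]] <- pred
    if (reference_mode == "ground_truth") {
      refs[[ip]] <- tr$volume$labels
    } else {
      if (!is.null(tr$rotation) && !all(tr$rotation$angles_deg == 0)) {
        # back-transform the segmentation to the unperturbed space
        pv <- v
        pv$labels <- pred
        bt <- resample_rigid(pv, t(rotation_matrix(tr$rotation)),
                             resolve_center_mm(v, tr$rotation))
        preds[[ip]] <- bt$labels
        valids[[ip]] <- attr(bt, "valid_mask")
      } else {
        preds[[ip]] <- pred
        valids[[ip]] <- array(TRUE, spatial_dim(v))
      }
    }
  }

  staple_info <- NULL
  if (reference_mode == "staple") {
    if (is.null(label_ids)) {
      label_ids <- sort(unique(unlist(lapply(preds, function(m)
        setdiff(unique(as.vector(m)), 0L)))))
    }
    if (length(label_ids) == 0L)
      stop("degenerate input: all segmentations empty, no consensus possible")
    common_valid <- Reduce(`&`, valids)
    staple_info <- list(valid_fraction = mean(common_valid))
    reference <- array(0L, spatial_dim(v))
    per_label <- list()
    for (id in label_ids) {
      res <- do.call(staple_consensus,
                     c(list(raters = lapply(preds, function(m) m == id),
                            valid_mask = common_valid), staple_args))
      reference[res$consensus_mask] <- as.integer(id)
      per_label[[as.character(id)]] <- res
    }
    staple_info$per_label <- per_label
  }

  scores <- array(NA_real_, unname(c(axis_lens, length(label_ids))))
  degen <- array(FALSE, dim(scores))
  for (ip in seq_len(npts)) {
    if (reference_mode == "ground_truth") {
      ref <- refs[[ip]]
      pred <- raw_preds[[ip]]
      mask_ok <- TRUE
    } else {
      ref <- reference
      pred <- preds[[ip]]
      mask_ok <- common_valid
    }
    for (il in seq_along(label_ids)) {
      id <- label_ids[il]
      sc <- dice((ref == id) & mask_ok, (pred == id) & mask_ok)
      idx <- (ip - 1L) + (il - 1L) * npts + 1L
      scores[idx] <- sc$dsc
      degen[idx] <- sc$degenerate
    }
  }
  dimnames(scores) <- c(lapply(grid$axes, as.character),
                        list(as.character(label_ids)))
  dimnames(degen) <- dimnames(scores)

  structure(list(grid = grid, scores = scores, degenerate = degen,
                 label_ids = label_ids, reference_mode = reference_mode,
                 staple = staple_info,
                 provenance = list(
                   segmenter_id = seg$id,
                   subject_id = v$subject_id,
                   center_mode = center_mode,
                   rotation_convention = paste(
                     "extrinsic world axes, order x then y then z,",
                     "right-handed, CCW positive"),
                   n_points = npts)),
            class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  s <- map_summary(x)
  cat(sprintf(
    "<sensitivity_map> %s '%s' on '%s': %d points x %d labels, mean DSC %.3f +/- %.3f\n",
    x$reference_mode, x$provenance$segmenter_id, x$provenance$subject_id,
    grid_size(x$grid), length(x$label_ids), s$mean, s$sd))
  invisible(x)
}

# per-grid-point score collapsed over the label axis, degenerate cells
# excluded from the mean (NaN where every label is degenerate)
collapse_labels <- function(m) {
  nd <- length(dim(m$scores))
  npts <- prod(dim(m$scores)[-nd])
  nl <- dim(m$scores)[nd]
  sc <- matrix(m$scores, npts, nl)
  dg <- matrix(m$degenerate, npts, nl)
  sc[dg] <- NA_real_
  out <- rowMeans(sc, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  array(out, dim(m$scores)[-nd],
        dimnames = dimnames(m$scores)[-nd])
}

#' Aggregate sensitivity maps
#'
#' Coordinatewise arithmetic mean of DSC maps, e.g. across test subjects
#' (per-label) or across labels/tracts (collapsing each map's label axis
#' first). Degenerate cells (empty-vs-empty Dice) are excluded from the
#' means.
#'
#' @param maps List of `sensitivity_map` objects sharing an identical grid.
#' @param over `"subjects"` (mean across maps, per label; requires identical
#'   label sets) or `"labels"` (collapse each map's label axis, then mean
#'   across maps).
#' @return A `sensitivity_map` whose provenance lists the constituents.
#' @export
aggregate_maps <- function(maps, over = c("subjects", "labels")) {
  over <- match.arg(over)
  if (!is.list(maps) || length(maps) < 1L)
    stop("need at least one map")
  g <- maps[[1]]$grid
  for (m in maps) {
    if (!identical(m$grid$axes, g$axes) || !identical(m$grid$kind, g$kind))
      stop("all maps must share an identical grid")
  }
  if (over == "subjects") {
    ids <- maps[[1]]$label_ids
    for (m in maps)
      if (!identical(m$label_ids, ids))
        stop("aggregation over subjects requires identical label sets")
    stack <- lapply(maps, function(m) {
      s <- m$scores
      s[m$degenerate] <- NA_real_
      s
    })
    arr <- array(unlist(stack), c(dim(stack[[1]]), length(stack)))
    mean_sc <- apply(arr, seq_along(dim(stack[[1]])), mean, na.rm = TRUE)
    mean_sc[!is.finite(mean_sc)] <- NA_real_
    degen <- apply(is.na(arr), seq_along(dim(stack[[1]])), all)
    dimnames(mean_sc) <- dimnames(maps[[1]]$scores)
    dimnames(degen) <- dimnames(mean_sc)
    out_labels <- ids
  } else {
    stack <- lapply(maps, collapse_labels)
    arr <- array(unlist(stack), c(dim(stack[[1]]), length(stack)))
    mean_sc <- apply(arr, seq_along(dim(stack[[1]])), mean, na.rm = TRUE)
    mean_sc[!is.finite(mean_sc)] <- NA_real_
    degen <- apply(is.na(arr), seq_along(dim(stack[[1]])), all)
    dim(mean_sc) <- c(dim(stack[[1]]), 1L)
    dim(degen) <- dim(mean_sc)
    dimnames(mean_sc) <- c(lapply(g$axes, as.character), list("mean"))
    dimnames(degen) <- dimnames(mean_sc)
    out_labels <- "mean"
  }
  structure(list(grid = g, scores = mean_sc, degenerate = degen,
                 label_ids = out_labels,
                 reference_mode = maps[[1]]$reference_mode,
                 staple = NULL,
                 provenance = list(
                   aggregated_over = over,
                   constituents = lapply(maps, function(m)
                     list(segmenter_id = m$provenance$segmenter_id,
                          subject_id = m$provenance$subject_id)),
                   segmenter_id = maps[[1]]$provenance$segmenter_id,
                   subject_id = sprintf("aggregate(%d)", length(maps)),
                   center_mode = maps[[1]]$provenance$center_mode,
                   rotation_convention = maps[[1]]$provenance$rotation_convention,
                   n_points = grid_size(g))),
            class = "sensitivity_map")
}

#' Summarize a sensitivity map
#'
#' Mean and standard deviation (population convention) of the DSC over the
#' map, the maximum score with its grid coordinates, and the offset of the
#' argmax from the grid's identity point. A non-zero argmax offset in a
#' rotation map is the diagnostic for orientation sampling bias between the
#' training sample and the test data: the offset names the realignment that
#' would optimize performance. Tied maxima resolve to the point closest to
#' the identity (so a flat map reports zero bias), then to the first in
#' array order; the tie count is reported.
#'
#' @param m A `sensitivity_map` (scores are first averaged over labels,
#'   excluding degenerate cells).
#' @return List with `mean`, `sd`, `max`, `argmax` (named axis values),
#'   `argmax_offset` (argmax minus identity point), `n_ties`, `n_degenerate`.
#' @export
map_summary <- function(m) {
  stopifnot(inherits(m, "sensitivity_map"))
  sc <- collapse_labels(m)
  vals <- sc[is.finite(sc)]
  if (length(vals) == 0L) stop("map has no finite scores")
  mx <- max(vals)
  tie_idx <- which(sc == mx)
  axes <- m$grid$axes
  idp <- grid_identity_point(m$grid)
  coords <- arrayInd(tie_idx, dim2(sc))
  # normalize each axis by its value span so mixed-unit grids compare fairly
  span <- vapply(axes, function(a) max(diff(range(a)), 1), numeric(1))
  d2 <- numeric(nrow(coords))
  for (a in seq_along(axes))
    d2 <- d2 + ((axes[[a]][coords[, a]] - idp[a]) / span[a])^2
  coord <- coords[which.min(d2), ]
  argmax <- vapply(seq_along(axes), function(a) axes[[a]][coord[a]],
                   numeric(1))
  names(argmax) <- names(axes)
  list(mean = mean(vals),
       sd = sqrt(mean((vals - mean(vals))^2)),
       max = mx,
       argmax = argmax,
       argmax_offset = argmax - idp,
       n_ties = length(tie_idx),
       n_degenerate = sum(!is.finite(sc)))
}

#' Export sensitivity scores as a tidy TSV table
#'
#' One row per grid point and label: subject_id, label_id, one column per
#' grid axis, dsc, degenerate_flag.
#'
#' @param m A `sensitivity_map`.
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_scores_tsv <- function(m, path) {
  stopifnot(inherits(m, "sensitivity_map"))
  pts <- grid_points(m$grid)
  nl <- length(m$label_ids)
  df <- data.frame(
    subject_id = m$provenance$subject_id,
    label_id = rep(m$label_ids, each = nrow(pts)),
    pts[rep(seq_len(nrow(pts)), times = nl), , drop = FALSE],
    dsc = as.vector(m$scores),
    degenerate_flag = as.vector(m$degenerate),
    row.names = NULL)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write map provenance and grid as JSON
#'
#' Records the grid axes, reference mode, conventions and segmenter identity
#' so a map can be reproduced.
#' @param m A `sensitivity_map`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_map_json <- function(m, path) {
  stopifnot(inherits(m, "sensitivity_map"))
  jsonlite::write_json(
    list(grid = list(kind = m$grid$kind, axes = m$grid$axes),
         label_ids = m$label_ids,
         reference_mode = m$reference_mode,
         provenance = m$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render a 2-D sensitivity map as a heat map
#'
#' Draws the per-grid-point DSC (averaged over labels) as an image with the
#' first axis horizontal. Maps of higher dimension are computed by the
#' engine but only 2-D grids are rendered.
#'
#' @param m A `sensitivity_map` over a 2-axis grid.
#' @param file Optional PNG path; when given the plot is written there.
#' @param main Plot title.
#' @param zlim Color scale limits.
#' @return Invisibly, the plotted score matrix.
#' @export
plot_sensitivity_map <- function(m, file = NULL, main = NULL,
                                 zlim = c(0, 1)) {
  stopifnot(inherits(m, "sensitivity_map"))
  sc <- collapse_labels(m)
  if (length(dim2(sc)) != 2L)
    stop("heat-map rendering supports 2-D grids only")
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 560)
    on.exit(grDevices::dev.off())
  }
  axes <- m$grid$axes
  if (is.null(main))
    main <- sprintf("%s (%s)", m$provenance$segmenter_id,
                    m$provenance$subject_id)
  cols <- grDevices::hcl.colors(64, "viridis")
  plot_sc <- sc
  plot_sc[!is.finite(plot_sc)] <- NA
  graphics::image(x = seq_along(axes[[1]]), y = seq_along(axes[[2]]),
                  z = plot_sc, zlim = zlim, col = cols,
                  xlab = names(axes)[1], ylab = names(axes)[2],
                  main = main, axes = FALSE)
  sel1 <- unique(round(seq(1, length(axes[[1]]), length.out = 9)))
  sel2 <- unique(round(seq(1, length(axes[[2]]), length.out = 9)))
  graphics::axis(1, at = sel1, labels = signif(axes[[1]][sel1], 3))
  graphics::axis(2, at = sel2, labels = signif(axes[[2]][sel2], 3))
  graphics::box()
  invisible(sc)
}
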