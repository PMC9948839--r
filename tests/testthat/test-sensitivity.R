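test_that("parameter grids validate their axes", {
  g <- parameter_grid(list(a = 1:3, b = c(0, 1)), "custom")
  expect_equal(grid_size(g), 6L)
  pts <- grid_points(g)
  expect_equal(nrow(pts), 6L)
  expect_equal(pts$a[1:3], c(1, 2, 3))  # first axis varies fastest
  expect_error(parameter_grid(list(1:3), "custom"), "name")
  expect_error(parameter_grid(list(a = 1:3, a = 1:2), "custom"), "unique")
  expect_error(parameter_grid(list(a = numeric(0)), "custom"),
               "at least one value")
})

test_that("identity grid point is 0 per angle/offset axis, 1 for scale", {
  expect_equal(unname(grid_identity_point(rotation_grid_case2())), c(0, 0))
  expect_equal(unname(grid_identity_point(intensity_grid_case1())), c(1, 0))
})

test_that("the identity grid point reproduces the direct dice exactly", {
  v <- binary_phantom(20, seed = 31)
  thr <- make_threshold_segmenter(0.5, 1.5)
  g <- parameter_grid(list(x_angle_deg = c(-20, 0, 20),
                           y_angle_deg = c(0)), "rotation_xy")
  m <- run_sensitivity(v, thr, g, "ground_truth", label_ids = 1L)
  direct <- dice(v$labels == 1L, thr$fn(v$image) == 1L)$dsc
  expect_identical(m$scores["0", "0", "1"], direct)
})

test_that("sensitivity runs are deterministic", {
  v <- binary_phantom(20, seed = 32)
  thr <- make_threshold_segmenter(0.5, 1.5)
  g <- parameter_grid(list(x_angle_deg = c(-30, 0, 30),
                           y_angle_deg = c(-30, 0, 30)), "rotation_xy")
  m1 <- run_sensitivity(v, thr, g, "ground_truth", label_ids = 1L)
  m2 <- run_sensitivity(v, thr, g, "ground_truth", label_ids = 1L)
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$degenerate, m2$degenerate)
})

test_that("segmenter contract violations name the offending grid point", {
  v <- binary_phantom(16, seed = 33)
  bad <- segmenter(function(image, scheme = NULL)
    array(0L, dim(image)[1:3] - 1L), id = "bad-shape")
  g <- parameter_grid(list(x_angle_deg = 0, y_angle_deg = 10), "rotation_xy")
  expect_error(run_sensitivity(v, bad, g, "ground_truth", label_ids = 1L),
               "y_angle_deg=10")
})

test_that("threshold toy degrades from grid center to extremes", {
  v <- binary_phantom(20, seed = 34)
  thr <- make_threshold_segmenter(0.5, 1.5)
  g <- parameter_grid(list(scale = c(1, 5), offset = c(0, 3)),
                      "intensity_scale_offset")
  m <- run_sensitivity(v, thr, g, "ground_truth", label_ids = 1L)
  expect_gt(m$scores["1", "0", "1"], m$scores["5", "3", "1"])
})

test_that("constant-background segmenter yields a uniform 0 map", {
  v <- binary_phantom(16, seed = 35)
  g <- parameter_grid(list(x_angle_deg = c(-20, 0, 20),
                           y_angle_deg = c(-20, 0, 20)), "rotation_xy")
  m <- run_sensitivity(v, background_segmenter(), g, "ground_truth",
                       label_ids = 1L)
  expect_true(all(m$scores == 0))
  expect_false(any(m$degenerate))
})

test_that("staple reference mode scores against a back-transformed consensus", {
  v <- binary_phantom(20, seed = 36)
  thr <- make_threshold_segmenter(0.5, 1.5)
  g <- parameter_grid(list(x_angle_deg = c(-10, 0, 10),
                           y_angle_deg = c(-10, 0, 10)), "rotation_xy")
  m <- run_sensitivity(v, thr, g, reference_mode = "staple")
  expect_equal(m$reference_mode, "staple")
  expect_true(all(is.finite(m$scores)))
  # a rotation-insensitive segmenter agrees closely with its own consensus
  expect_gt(min(m$scores), 0.8)
  expect_lte(max(m$scores), 1)
  expect_gt(m$staple$valid_fraction, 0.5)
  # degenerate: nothing segmented anywhere
  expect_error(
    run_sensitivity(v, background_segmenter(), g, reference_mode = "staple"),
    "empty|degenerate")
})

test_that("map aggregation averages coordinatewise and skips degenerate cells", {
  v <- binary_phantom(16, seed = 37)
  thr <- make_threshold_segmenter(0.5, 1.5)
  g <- parameter_grid(list(x_angle_deg = c(0, 20), y_angle_deg = 0),
                      "rotation_xy")
  m <- run_sensitivity(v, thr, g, "ground_truth", label_ids = 1L)

  agg <- aggregate_maps(list(m, m, m), over = "subjects")
  expect_equal(agg$scores, m$scores, tolerance = 1e-12,
               ignore_attr = FALSE)

  m2 <- m; m2$scores[] <- 0.2
  m8 <- m; m8$scores[] <- 0.8
  expect_true(all(aggregate_maps(list(m2, m8))$scores == 0.5))

  # degenerate cell in one of three maps: mean of the remaining two
  md <- m; md$scores[1] <- 0; md$degenerate[1] <- TRUE
  a3 <- aggregate_maps(list(m2, m8, md), over = "subjects")
  expect_equal(a3$scores[1], (0.2 + 0.8) / 2)
  expect_equal(a3$scores[2], (0.2 + 0.8 + md$scores[2]) / 3)

  gg <- parameter_grid(list(x_angle_deg = c(0, 30), y_angle_deg = 0),
                       "rotation_xy")
  mg <- run_sensitivity(v, thr, gg, "ground_truth", label_ids = 1L)
  expect_error(aggregate_maps(list(m, mg)), "identical grid")
})

test_that("aggregation over labels collapses the label axis", {
  v <- small_phantom(20, seed = 38)
  tmpl <- make_template_segmenter(v, "identity_only")
  g <- parameter_grid(list(x_angle_deg = c(0, 40), y_angle_deg = 0),
                      "rotation_xy")
  m <- run_sensitivity(v, tmpl, g, "ground_truth")  # labels 1 and 2
  agg <- aggregate_maps(list(m), over = "labels")
  expect_equal(dim(agg$scores), c(2L, 1L, 1L))
  expect_equal(agg$scores[1, 1, 1], mean(m$scores[1, 1, ]))
})

test_that("map summaries report mean, sd, argmax and its offset", {
  v <- binary_phantom(16, seed = 39)
  thr <- make_threshold_segmenter(0.5, 1.5)
  g <- parameter_grid(list(x_angle_deg = c(-20, 0, 20), y_angle_deg = 0),
                      "rotation_xy")
  m <- run_sensitivity(v, thr, g, "ground_truth", label_ids = 1L)

  u <- m; u$scores[] <- 1; u$degenerate[] <- FALSE
  s <- map_summary(u)
  expect_equal(s$mean, 1); expect_equal(s$sd, 0)
  # a flat map reports zero bias: ties resolve toward the identity point
  expect_equal(unname(s$argmax_offset), c(0, 0))
  expect_equal(s$n_ties, 3L)

  one <- m; one$scores[] <- 0; one$scores["20", "0", "1"] <- 1
  expect_equal(unname(map_summary(one)$argmax_offset), c(20, 0))

  # population sd convention on an equal-count pair of values
  two <- m
  two$grid <- parameter_grid(list(x_angle_deg = c(0, 20), y_angle_deg = 0),
                             "rotation_xy")
  two$scores <- array(c(0.6, 1.0), c(2, 1, 1),
                      dimnames = list(c("0", "20"), "0", "1"))
  two$degenerate <- array(FALSE, c(2, 1, 1))
  s2 <- map_summary(two)
  expect_equal(s2$mean, 0.8)
  expect_equal(s2$sd, 0.2)
})

test_that("scores export as tidy TSV and provenance as JSON", {
  td <- withr::local_tempdir()
  v <- binary_phantom(16, seed = 40)
  thr <- make_threshold_segmenter(0.5, 1.5)
  g <- parameter_grid(list(x_angle_deg = c(0, 20), y_angle_deg = c(0, 20)),
                      "rotation_xy")
  m <- run_sensitivity(v, thr, g, "ground_truth", label_ids = 1L)
  tsv <- file.path(td, "scores.tsv")
  df <- write_scores_tsv(m, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), 4L)
  expect_equal(names(back), c("subject_id", "label_id", "x_angle_deg",
                              "y_angle_deg", "dsc", "degenerate_flag"))
  expect_equal(back$dsc, as.vector(m$scores), tolerance = 1e-12)

  js <- file.path(td, "map.json")
  write_map_json(m, js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$grid$kind, "rotation_xy")
  expect_match(meta$provenance$rotation_convention, "extrinsic")

  png <- file.path(td, "map.png")
  plot_sensitivity_map(m, png)
  expect_true(file.exists(png))
})

test_that("mirrored template on mirrored input flips the map's y-angle axis", {
  v <- small_phantom(20, seed = 41)
  ang <- c(-40, 0, 40)
  g <- parameter_grid(list(x_angle_deg = ang, y_angle_deg = ang),
                      "rotation_xy")
  m <- run_sensitivity(v, make_template_segmenter(v, "identity_only"),
                       g, "ground_truth")
  vm <- mirror_volume(v, "x")
  mm <- run_sensitivity(vm, make_template_segmenter(vm, "identity_only"),
                        g, "ground_truth")
  a <- apply(m$scores, c(1, 2), mean)
  b <- apply(mm$scores, c(1, 2), mean)
  expect_equal(a, b[, rev(seq_along(ang))], tolerance = 0.02,
               ignore_attr = TRUE)
})
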