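test_that("landmark extraction follows the quantile convention", {
  expect_length(extract_landmarks(rnorm(100)), 7L)
  expect_equal(default_landmark_fractions(), seq(0.125, 0.875, 0.125))

  # sort-and-interpolate oracle: values 1..8 once each, median = 4.5
  expect_equal(extract_landmarks(1:8, 0.5), 4.5)
  # oracle for the 25% landmark of 1..8: order statistics interpolation
  # at position 1 + 0.25*7 = 2.75 -> 2.75
  expect_equal(extract_landmarks(1:8, c(0.25, 0.5)), c(2.75, 4.5))

  # large uniform sample: landmarks converge to the fractions themselves
  set.seed(11)
  u <- stats::runif(1e6)
  lm <- extract_landmarks(u)
  expect_lt(max(abs(lm - default_landmark_fractions())), 0.01)

  expect_error(extract_landmarks(rep(1, 100)), "degenerate|constant")
  expect_error(extract_landmarks(rnorm(10), c(0.5, 0.2)), "increasing")
})

test_that("transfer-function fits are exact on polynomial-generated targets", {
  set.seed(12)
  a <- sort(rnorm(7))
  expect_equal(fit_transfer_function(a, a), c(0, 1, 0), tolerance = 1e-9)
  expect_equal(fit_transfer_function(a, 2 * a + 1), c(0, 2, 1),
               tolerance = 1e-9)
  expect_equal(fit_transfer_function(a, a^2), c(1, 0, 0), tolerance = 1e-9)
  cf <- c(0.3, -1.2, 0.7)
  expect_equal(fit_transfer_function(a, cf[1] * a^2 + cf[2] * a + cf[3]),
               cf, tolerance = 1e-9)
  expect_error(fit_transfer_function(rep(1, 7), a), "singular|identical")
  expect_error(fit_transfer_function(a, a[1:5]), "equal length")
})

test_that("transfer model pools all ordered pairs", {
  set.seed(13)
  base <- sort(rnorm(7))
  sets <- list(base, base, base)
  mod <- build_transfer_model(sets)
  expect_equal(mod$mean_c, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(mod$std_c, c(0, 0, 0))
  expect_equal(mod$n_pairs, 6L)  # 3 * 2 ordered pairs

  # invariant to the ordering of the input sets
  sets4 <- lapply(1:4, function(i) base * (1 + 0.1 * i) + 0.05 * i)
  m1 <- build_transfer_model(sets4)
  m2 <- build_transfer_model(rev(sets4))
  expect_equal(m1$mean_c, m2$mean_c, tolerance = 1e-12)
  expect_equal(m1$std_c, m2$std_c, tolerance = 1e-12)

  expect_error(build_transfer_model(list(base)), "at least 2")
})

test_that("model fitted on affine-jittered sets recovers the generator", {
  # sets are small affine distortions of one base set: every pairwise fit is
  # exactly linear, so pooled means must stay near (0, 1, 0)
  set.seed(14)
  base <- sort(rnorm(7, sd = 2))
  sets <- lapply(1:6, function(i)
    base * stats::rnorm(1, 1, 0.05) + stats::rnorm(1, 0, 0.05))
  mod <- build_transfer_model(sets)
  expect_lt(abs(mod$mean_c[1]), 0.05)
  expect_lt(abs(mod$mean_c[2] - 1), 0.2)
  expect_lt(abs(mod$mean_c[3]), 0.2)
})

test_that("model JSON serialization round trips", {
  td <- withr::local_tempdir()
  set.seed(15)
  sets <- lapply(1:3, function(i) sort(rnorm(7)) * i)
  mod <- build_transfer_model(sets)
  p <- file.path(td, "model.json")
  write_transfer_model(mod, p)
  mod2 <- read_transfer_model(p)
  expect_equal(mod2$mean_c, mod$mean_c, tolerance = 1e-12)
  expect_equal(mod2$std_c, mod$std_c, tolerance = 1e-12)
  expect_identical(mod2$n_pairs, mod$n_pairs)
})

test_that("intensity-coefficient sampler is a seeded normal draw", {
  mod <- structure(list(mean_c = c(0.1, 0.9, -0.2), std_c = c(0, 0, 0),
                        n_pairs = 2L,
                        landmark_fractions = default_landmark_fractions()),
                   class = "transfer_function_model")
  expect_identical(sample_intensity_augmentation(mod, 1), mod$mean_c)

  mod$std_c <- c(0.05, 0.2, 0.1)
  expect_identical(sample_intensity_augmentation(mod, 7),
                   sample_intensity_augmentation(mod, 7))

  # CLT bound: sample mean within 4 sigma / sqrt(n) per coefficient
  n <- 1e5
  set.seed(16)
  api_draws <- vapply(seq_len(n), function(i)
    sample_intensity_augmentation(mod), numeric(3))
  expect_lt(max(abs(rowMeans(api_draws) - mod$mean_c) /
                  (mod$std_c / sqrt(n))), 4)
})

test_that("zero-std model composed with the polynomial transform is identity", {
  set.seed(17)
  sets <- replicate(3, sort(rnorm(7)), simplify = FALSE)
  sets <- list(sets[[1]], sets[[1]], sets[[1]])
  mod <- build_transfer_model(sets)
  cf <- sample_intensity_augmentation(mod, 3)
  v <- small_phantom(16, seed = 17)
  vt <- polynomial_intensity_transform(v, cf)
  expect_equal(vt$image, v$image, tolerance = 1e-9)
})

test_that("rotation-augmentation sampler honors type and probabilities", {
  cfg1 <- rotation_aug_config("type1", mirror_probability = 0.5)
  set.seed(18)
  draws <- lapply(seq_len(1e4), function(i)
    sample_rotation_augmentation(cfg1))
  freq <- vapply(c("x", "y", "z"), function(a)
    mean(vapply(draws, function(d) a %in% d$mirror_axes, logical(1))),
    numeric(1))
  # binomial 4-sigma interval around 0.5 at n = 1e4: +/- 0.02
  expect_true(all(freq > 0.47 & freq < 0.53))
  expect_true(all(vapply(draws, function(d) d$x_angle_deg == 0, logical(1))))

  cfg2 <- rotation_aug_config("type2")
  set.seed(19)
  angles <- vapply(seq_len(500), function(i)
    sample_rotation_augmentation(cfg2)$x_angle_deg, numeric(1))
  expect_true(all(angles %in% c(0, 30, 50)))
  expect_setequal(unique(angles), c(0, 30, 50))

  cfg0 <- rotation_aug_config("type1", mirror_probability = 0)
  s <- sample_rotation_augmentation(cfg0, 20)
  expect_length(s$mirror_axes, 0L)
  expect_equal(s$x_angle_deg, 0)

  s7 <- sample_rotation_augmentation(cfg2, 7)
  expect_identical(sample_rotation_augmentation(cfg2, 7), s7)
  expect_error(rotation_aug_config("type2", discrete_x_angles_deg = numeric(0)),
               "non-empty")
})
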