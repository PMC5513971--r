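test_that("radial profile matches the analytic ridge cross-section", {
  pg <- ridge_params(6, 1, variant = "gaussian")
  expect_identical(radial_profile(6, pg), 1)
  expect_equal(radial_profile(7, pg), exp(-1 / 2), tolerance = 1e-12)
  expect_equal(radial_profile(5, pg), exp(-1 / 2), tolerance = 1e-12)

  pm <- ridge_params(6, 1, variant = "mixture", tail_floor = 0)
  expect_equal(radial_profile(6, pm), 1.12, tolerance = 1e-12)  # both peaks
  # far in the tail everything has decayed away
  expect_lt(radial_profile(6 + 8 * pm$sigma_tail, pm), 1e-10 * 1.12)

  expect_error(radial_profile(-1, pg), "non-negative")
  expect_error(radial_profile(c(1, NA), pg), "finite")
  # gaussian variant carries no tail
  expect_identical(pg$tail_amplitude, 0)
  expect_true(is.na(pg$sigma_tail))
})

test_that("tail parameterizations follow their declared readings", {
  # spread scaling: sigma (default) vs variance reading
  p_sd <- ridge_params(6, 1, variant = "mixture", tail_mode = "sd")
  p_var <- ridge_params(6, 1, variant = "mixture", tail_mode = "variance")
  expect_equal(p_sd$sigma_tail, 10)
  expect_equal(p_var$sigma_tail, sqrt(10), tolerance = 1e-12)

  # the floor keeps the pedestal flat over the workspace for small sigmas
  p_floor <- ridge_params(6, 0.3, variant = "mixture", tail_floor = 10)
  expect_equal(p_floor$sigma_tail, 10)

  # mixture-weight reading converts to the equivalent peak-height ratio
  w <- 0.12
  p_w <- ridge_params(6, 1, variant = "mixture", tail_amplitude = w,
                      amplitude_mode = "weight", tail_floor = 0)
  expect_equal(p_w$tail_amplitude, w * 1 / ((1 - w) * 10), tolerance = 1e-12)

  expect_error(ridge_params(-6, 1), "ridge_radius")
  expect_error(ridge_params(6, 0), "sigma_center")
  expect_error(ridge_params(6, 1, variant = "mixture", sigma_tail = 0.5),
               "sigma_tail")
  expect_error(ridge_params(6, 1, variant = "mixture", tail_amplitude = 0),
               "tail_amplitude")
})

test_that("central ridge dominates nearby and vanishing tails recover the gaussian", {
  pm <- ridge_params(6, 1, variant = "mixture", tail_amplitude = 0.12,
                     tail_scale = 10, tail_floor = 0)
  d <- seq(5, 7, by = 0.01)                     # |d - r| <= sigma_center
  central <- exp(-(d - 6)^2 / 2)
  expect_true(all(central / radial_profile(d, pm) >= 0.8))

  p_tiny <- ridge_params(6, 1, variant = "mixture", tail_amplitude = 1e-13,
                         tail_floor = 0)
  pg <- ridge_params(6, 1, variant = "gaussian")
  d <- seq(0, 20, by = 0.05)
  expect_lt(max(abs(radial_profile(d, p_tiny) - radial_profile(d, pg))), 1e-12)
})

test_that("ring density is rotationally symmetric, normalized, and peaks on the ridge", {
  p <- ridge_params(6, 1, variant = "gaussian")
  lm <- c(2, -1)
  g <- ring_density(lm, p, grid_spec(lm, half_width = 10.5, cell_size = 0.25))

  expect_equal(sum(g$values) * g$cell_size^2, 1, tolerance = 1e-9)

  # the grid is centred on the landmark, so quarter-turn rotations map cell
  # centres onto cell centres and must leave the map unchanged
  v <- g$values
  rot90 <- t(v)[, nrow(v):1]
  expect_lt(max(abs(v - rot90)), 1e-12)
  expect_lt(max(abs(v - v[nrow(v):1, ncol(v):1])), 1e-12)

  # the maximum sits in the cell whose centre is nearest the ridge radius
  xs <- g$origin[1] + (seq_len(g$n_cols) - 1) * g$cell_size
  ys <- g$origin[2] + (seq_len(g$n_rows) - 1) * g$cell_size
  d <- sqrt(outer((ys - lm[2])^2, (xs - lm[1])^2, `+`))
  gap <- abs(d - p$ridge_radius)
  expect_equal(min(gap[g$values == max(g$values)]), min(gap))
})

test_that("ring density validates its grid coverage", {
  p <- ridge_params(6, 1, variant = "gaussian")
  small <- grid_spec(c(0, 0), half_width = 7, cell_size = 0.25)
  expect_error(ring_density(c(0, 0), p, small), "half-width 10")
  expect_s3_class(ring_density(c(0, 0), p, small, clip = TRUE), "density_grid")
  expect_error(ring_density(c(50, 0), p, small, clip = TRUE),
               "outside the grid")
})

test_that("landmark configurations enforce their invariants", {
  expect_error(landmark_config(c(0, 0), matrix(0, 4, 2)), "1 and 3")
  expect_error(landmark_config(c(0, 0), matrix(1, 2, 2), matrix(1, 3, 2)),
               "same length")
  expect_error(landmark_config(c(0, NA), matrix(1, 1, 2)), "finite")

  cfg <- standard_config(3, radius = 6)
  d <- sqrt(rowSums(sweep(cfg$training_landmarks, 2, cfg$home)^2))
  expect_equal(d, rep(6, 3), tolerance = 1e-12)

  # relocation moves the deviant landmark radially outward on its own axis
  # (for this symmetric geometry "orthogonal to the other two" is radial)
  rc <- relocate_config(cfg, 1.5, deviant = 3)
  expect_equal(rc$training_landmarks, cfg$training_landmarks)
  moved <- rc$test_landmarks[3, ]
  expect_equal(sqrt(sum(moved^2)), 7.5, tolerance = 1e-12)
  expect_equal(moved / 7.5, cfg$training_landmarks[3, ] / 6, tolerance = 1e-12)
  others <- cfg$training_landmarks[1:2, ]
  axis <- others[2, ] - others[1, ]
  expect_equal(sum(axis * (moved - cfg$training_landmarks[3, ])), 0,
               tolerance = 1e-9)
})
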