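test_that("uniform map is the identity and combination is commutative", {
  p <- ridge_params(6, 1, variant = "gaussian")
  spec <- grid_spec(c(0, 0), 12, 0.25)
  g1 <- ring_density(c(-4, 0), p, spec, clip = TRUE)
  g2 <- ring_density(c(4, 0), p, spec, clip = TRUE)

  back <- combine_grids(list(g1, uniform_grid(spec)))
  expect_lt(max(abs(back$values - g1$values)), 1e-12)

  ab <- combine_grids(list(g1, g2))
  ba <- combine_grids(list(g2, g1))
  expect_identical(ab$values, ba$values)
  expect_equal(sum(ab$values) * ab$cell_size^2, 1, tolerance = 1e-9)

  other <- ring_density(c(0, 0), p, grid_spec(c(0, 0), 11, 0.25), clip = TRUE)
  expect_error(combine_grids(list(g1, other)), "share")

  # narrow rings far apart have no common support at all
  pn <- ridge_params(1, 0.1, variant = "gaussian")
  wide <- grid_spec(c(0, 0), 30, 0.5)
  far1 <- ring_density(c(-25, 0), pn, wide, clip = TRUE)
  far2 <- ring_density(c(25, 0), pn, wide, clip = TRUE)
  expect_error(combine_grids(list(far1, far2)), "conflict")
})

test_that("two overlapping rings peak at the circle intersections", {
  # rings of radius 6 around (-4, 0) and (4, 0) intersect at (0, +-sqrt(20))
  p <- ridge_params(6, 1, variant = "gaussian")
  spec <- grid_spec(c(0, 0), 12, 0.2)
  g <- combine_grids(list(ring_density(c(-4, 0), p, spec, clip = TRUE),
                          ring_density(c(4, 0), p, spec, clip = TRUE)))
  cfg <- landmark_config(c(0, sqrt(20)), rbind(c(-4, 0), c(4, 0)))
  pr <- ringhoming:::summarize_grid(g, cfg, p)
  expect_identical(pr$modality, "bimodal")
  ints <- rbind(c(0, sqrt(20)), c(0, -sqrt(20)))
  for (i in 1:2) {
    gaps <- sqrt(rowSums(sweep(pr$modes, 2, ints[i, ])^2))
    expect_lt(min(gaps), g$cell_size)          # within one cell
  }
})

test_that("prediction summaries equal brute-force cell summation", {
  p <- ridge_params(6, 1.2, variant = "mixture", tail_floor = 10)
  cfg <- standard_config(2)
  spec <- grid_spec(c(0, 0), 13, 0.4)          # coarse: oracle loops all cells
  pr <- predict_configuration(cfg, p, spec)

  expect_equal(pr$mle, brute_argmax(pr$grid))
  oracle <- brute_moments(pr$grid, cfg$home)
  expect_equal(pr$expected_accuracy, oracle$expected_accuracy, tolerance = 1e-9)
  expect_equal(unname(pr$covariance), oracle$cov, tolerance = 1e-9)
  expect_equal(unname(pr$mean), oracle$mean, tolerance = 1e-9)

  # the global maximum is always among the reported modes
  gaps <- sqrt(rowSums(sweep(pr$modes, 2, pr$mle)^2))
  expect_lt(min(gaps), 1e-12)
})

test_that("one, two and three landmarks give ring, bimodal and unimodal predictions", {
  for (variant in c("gaussian", "mixture")) {
    p <- ridge_params(6, 1, variant = variant, tail_floor = 10)
    spec <- default_grid_spec(standard_config(3), p)
    pr3 <- predict_configuration(standard_config(3), p, spec)
    expect_identical(pr3$modality, "unimodal")
    expect_lt(sqrt(sum(pr3$mle^2)), spec$cell_size)   # peak at home

    pr2 <- predict_configuration(standard_config(2), p, spec)
    expect_identical(pr2$modality, "bimodal")
    # modes are mirror images across the axis through the two landmarks
    lms <- pr2$config$test_landmarks
    u <- (lms[2, ] - lms[1, ]) / sqrt(sum((lms[2, ] - lms[1, ])^2))
    reflect <- function(q) {
      v <- q - lms[1, ]
      lms[1, ] + 2 * sum(v * u) * u - v
    }
    # discrete modes sit on cell centres, so mirror agreement holds to a cell
    expect_lt(sqrt(sum((reflect(pr2$modes[1, ]) - pr2$modes[2, ])^2)),
              sqrt(2) * spec$cell_size)

    pr1 <- predict_configuration(standard_config(1), p, spec)
    # a lone landmark leaves a whole ring of near-maximal cells
    expect_identical(pr1$modality, "multimodal")

    # ambiguity resolution: accuracy and variance fall with landmark count
    acc <- c(pr1$expected_accuracy, pr2$expected_accuracy, pr3$expected_accuracy)
    tv <- c(pr1$total_variance, pr2$total_variance, pr3$total_variance)
    expect_true(all(diff(acc) < 0))
    expect_true(all(diff(tv) < 0))
  }
})

test_that("single-landmark expected accuracy matches polar quadrature", {
  p <- ridge_params(6, 1, variant = "gaussian")
  cfg <- standard_config(1)
  pr <- predict_configuration(cfg, p)
  oracle <- ring_accuracy_quadrature(p, cfg$test_landmarks[1, ], cfg$home)
  expect_equal(pr$expected_accuracy, oracle, tolerance = 0.01)
})

test_that("scalar summaries are mirror symmetric", {
  p <- ridge_params(6, 1, variant = "mixture", tail_floor = 10)
  lms <- rbind(c(0, 6), c(-5.196152, -3))
  cfg <- landmark_config(c(0, 0), lms)
  mirrored <- landmark_config(c(0, 0), cbind(-lms[, 1], lms[, 2]))
  spec <- grid_spec(c(0, 0), 16, 0.2)
  a <- predict_configuration(cfg, p, spec)
  b <- predict_configuration(mirrored, p, spec)
  expect_equal(a$expected_accuracy, b$expected_accuracy, tolerance = 1e-9)
  expect_equal(a$total_variance, b$total_variance, tolerance = 1e-9)
  expect_equal(a$ellipse_area_95, b$ellipse_area_95, tolerance = 1e-9)
  # modes map onto each other under x -> -x
  ref <- cbind(-a$modes[, 1], a$modes[, 2])
  for (i in seq_len(nrow(ref))) {
    gaps <- sqrt(rowSums(sweep(b$modes, 2, ref[i, ])^2))
    expect_lt(min(gaps), 1e-9)
  }
})

test_that("a zero relocation reproduces the unperturbed prediction", {
  p <- ridge_params(6, 1, variant = "mixture", tail_floor = 10)
  spec <- default_grid_spec(standard_config(3), p)
  sw <- relocation_sweep(standard_config(3), 0, p, spec)
  base_m <- predict_configuration(standard_config(3), p, spec)
  base_g <- predict_configuration(standard_config(3),
                                  ridge_params(6, 1, variant = "gaussian"), spec)
  for (v in c("gaussian", "mixture")) {
    row <- sw[sw$variant == v, ]
    base <- if (v == "mixture") base_m else base_g
    expect_equal(row$expected_accuracy, base$expected_accuracy, tolerance = 1e-12)
    expect_equal(row$total_variance, base$total_variance, tolerance = 1e-12)
    expect_equal(c(row$mle_x, row$mle_y), unname(base$mle), tolerance = 1e-12)
  }
  expect_error(relocation_sweep(standard_config(3), 30, p, spec),
               "outside the grid")
})
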