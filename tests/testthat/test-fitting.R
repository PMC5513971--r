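test_that("polar collapse returns landmark-centred distances in order", {
  expect_equal(polar_collapse(data.frame(x = 3, y = 4), c(0, 0)), 5)
  expect_equal(polar_collapse(data.frame(x = 2, y = 0), c(2, 0)), 0)

  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  ring <- data.frame(x = 1 + 6 * cos(th), y = -2 + 6 * sin(th))
  expect_lt(max(abs(polar_collapse(ring, c(1, -2)) - 6)), 1e-12)
  # order preserved
  pts <- data.frame(x = c(10, 1, 5), y = 0)
  expect_equal(polar_collapse(pts, c(0, 0)), c(10, 1, 5))

  expect_error(polar_collapse(data.frame(x = numeric(0), y = numeric(0)),
                              c(0, 0)), "non-empty")
})

test_that("moment fit recovers the radial mean and spread, rejecting degenerate input", {
  expect_equal(fit_radial_gaussian(c(5, 6, 7)),
               c(ridge_radius = 6, sigma_center = 1))
  expect_error(fit_radial_gaussian(c(5, 7)), "at least 3")
  expect_error(fit_radial_gaussian(rep(4, 10)), "zero spread")

  set.seed(101)
  d <- rnorm(10000, mean = 6, sd = 1)
  est <- fit_radial_gaussian(d)
  se_mean <- 1 / sqrt(10000)
  se_sd <- 1 / sqrt(2 * 10000)
  expect_lt(abs(est[["ridge_radius"]] - 6), 3 * se_mean)
  expect_lt(abs(est[["sigma_center"]] - 1), 3 * se_sd)
})

test_that("maximum-likelihood ring fit recovers generating parameters", {
  # plain gaussian ring sampled from its own grid density
  pg <- ridge_params(6, 1, variant = "gaussian")
  cfg <- standard_config(1)
  spec <- default_grid_spec(cfg, pg)
  dens <- ring_density(cfg$training_landmarks[1, ], pg, spec, clip = TRUE)
  pts <- sample_from_grid(dens, 4000, seed = 7)
  fit <- ring_fit(pts, cfg$training_landmarks[1, ], variant = "gaussian")
  expect_lt(abs(coef(fit)[["ridge_radius"]] - 6), 0.1)
  expect_lt(abs(coef(fit)[["sigma_center"]] - 1), 0.1)

  # heavy-tailed data: the fixed pedestal is part of the likelihood, so the
  # central ridge parameters remain identifiable
  pm <- ridge_params(6, 1, variant = "mixture", tail_floor = 10)
  densm <- ringhoming:::condition_density(cfg, pm, spec)
  ptsm <- sample_from_grid(densm, 2000, seed = 8)
  fitm <- ring_fit(ptsm, cfg$training_landmarks[1, ], variant = "mixture")
  expect_lt(abs(coef(fitm)[["ridge_radius"]] - 6), 0.15)
  expect_lt(abs(coef(fitm)[["sigma_center"]] - 1), 0.1)

  # auditory geometry: ring at radius 2 with sd-0.2 jitter
  set.seed(9)
  th <- runif(800, 0, 2 * pi); rr <- rnorm(800, 2, 0.2)
  aud <- data.frame(x = 5 + rr * cos(th), y = 5 + rr * sin(th))
  fita <- ring_fit(aud, c(5, 5), variant = "gaussian")
  expect_lt(abs(coef(fita)[["ridge_radius"]] - 2), 0.1)
})

test_that("tail parameters are attached, never fitted", {
  set.seed(10)
  th <- runif(300, 0, 2 * pi); rr <- rnorm(300, 6, 1)
  pts <- data.frame(x = rr * cos(th), y = 6 + rr * sin(th))

  fg <- ring_fit(pts, c(0, 6), variant = "gaussian")
  expect_identical(fg$params$variant, "gaussian")
  expect_identical(fg$params$tail_amplitude, 0)

  fm <- ring_fit(pts, c(0, 6), variant = "mixture")
  expect_identical(fm$params$tail_amplitude, 0.12)
  expect_equal(fm$params$sigma_tail,
               max(10 * fm$params$sigma_center, 10))
  # residuals and fitted values are consistent with the collapsed distances
  expect_equal(residuals(fm) + fitted(fm), polar_collapse(pts, c(0, 6)))
  expect_equal(nobs(fm), 300)
})

test_that("fitting is translation equivariant and pools by concatenation", {
  set.seed(11)
  th <- runif(400, 0, 2 * pi); rr <- rnorm(400, 6, 1)
  pts <- endpoint_set(rr * cos(th), rr * sin(th),
                      participant_id = rep(c("P01", "P02"), each = 200),
                      condition_id = "L1")
  shift <- c(17, -3)
  pts2 <- pts; pts2$x <- pts$x + shift[1]; pts2$y <- pts$y + shift[2]

  for (m in c("ml", "moments")) {
    f1 <- ring_fit(pts, c(0, 0), method = m)
    f2 <- ring_fit(pts2, shift, method = m)
    # moments is exact; ml only up to optimiser termination noise
    expect_equal(coef(f1), coef(f2),
                 tolerance = if (m == "moments") 1e-12 else 1e-7)
  }

  # pooled fit equals the fit of the concatenated distance list
  pooled <- fit_radial_gaussian(polar_collapse(pts, c(0, 0)))
  split_d <- c(polar_collapse(pts[pts$participant_id == "P01", ], c(0, 0)),
               polar_collapse(pts[pts$participant_id == "P02", ], c(0, 0)))
  expect_identical(pooled, fit_radial_gaussian(split_d))

  fits <- ring_fit_by_participant(pts, c(0, 0), variant = "gaussian")
  expect_named(fits, c("P01", "P02"))
  expect_s3_class(fits$P01, "ring_fit")
})
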