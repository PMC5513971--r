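test_that("grid sampling is seeded, respects its support, and matches grid moments", {
  p <- ridge_params(6, 1, variant = "gaussian")
  cfg <- standard_config(1)
  spec <- default_grid_spec(cfg, p)
  lm <- cfg$training_landmarks[1, ]
  dens <- ring_density(lm, p, spec, clip = TRUE)

  a <- sample_from_grid(dens, 200, seed = 33)
  b <- sample_from_grid(dens, 200, seed = 33)
  expect_identical(a, b)
  expect_error(sample_from_grid(ringhoming:::new_density_grid(spec, dens$values),
                                10), "normalized")

  # degenerate support: every draw stays inside the single massive cell
  v <- matrix(0, spec$n_rows, spec$n_cols); v[40, 60] <- 1
  point_mass <- normalize_grid(ringhoming:::new_density_grid(spec, v))
  pts <- sample_from_grid(point_mass, 50, seed = 1)
  cx <- ringhoming:::grid_xs(spec)[60]; cy <- ringhoming:::grid_ys(spec)[40]
  expect_true(all(abs(pts$x - cx) <= spec$cell_size / 2))
  expect_true(all(abs(pts$y - cy) <= spec$cell_size / 2))

  # the generating radial mean is recovered within sampling error
  xs <- ringhoming:::grid_xs(dens); ys <- ringhoming:::grid_ys(dens)
  dd <- sqrt(outer((ys - lm[2])^2, (xs - lm[1])^2, `+`))
  mass <- dens$values * dens$cell_size^2
  mu_d <- sum(mass * dd)
  sd_d <- sqrt(sum(mass * (dd - mu_d)^2))
  smp <- sample_from_grid(dens, 5000, seed = 12)
  dist_s <- polar_collapse(smp, lm)
  expect_lt(abs(mean(dist_s) - mu_d), 3 * sd_d / sqrt(5000))
})

test_that("experiment-1 generator emits the full design with per-participant streams", {
  sim <- generate_experiment1("visual", seed = 5)
  e <- sim$endpoints
  expect_equal(nrow(e), 10 * 3 * 40)
  counts <- table(e$participant_id, e$condition_id)
  expect_true(all(counts == 40))
  expect_setequal(colnames(counts), c("L1", "L2", "L3"))
  expect_length(sim$metadata$participant_sigma, 10)
  expect_identical(attr(e, "provenance"), "synthetic")

  # a single participant can be regenerated bit-for-bit from the master seed
  solo <- generate_experiment1("visual", seed = 5, participants = 4)
  pid <- names(sim$metadata$participant_seed)[4]
  expect_equal(solo$endpoints, e[e$participant_id == pid, ],
               ignore_attr = TRUE)

  # ambiguity resolution shows up in the sample itself
  acc <- sapply(split(e, e$condition_id), empirical_accuracy, home = c(0, 0))
  expect_lt(acc[["L3"]], acc[["L1"]])

  # auditory geometry trains the short radius
  aud <- generate_experiment1("auditory", n_participants = 2,
                              trials_per_condition = 10, sigma_base = 0.4,
                              variant = "gaussian", seed = 6)
  expect_equal(aud$metadata$radius, 2)
  d1 <- polar_collapse(aud$endpoints[aud$endpoints$condition_id == "L1", ],
                       aud$configs$L1$training_landmarks[1, ])
  expect_lt(abs(median(d1) - 2), 1)
})

test_that("experiment-2 generator covers the sweep and breaks down at large conflict", {
  sim <- generate_experiment2(n_participants = 4, trials_per_condition = 40,
                              seed = 9)
  e <- sim$endpoints
  expect_setequal(unique(e$condition_id), c("R0", "R1.5", "R3", "R4.5", "R6"))
  expect_equal(nrow(e), 4 * 5 * 40)
  expect_equal(sim$metadata$relocations, c(0, 1.5, 3, 4.5, 6))

  # at the largest conflict the cloud sits at the stationary-pair
  # intersection (home), not at the shifted configuration centre
  e6 <- e[e$condition_id == "R6", ]
  ctr <- oracle_ls_center(sim$configs$R6$test_landmarks, 6)
  cen <- c(mean(e6$x), mean(e6$y))
  expect_lt(sqrt(sum(cen^2)), sqrt(sum((cen - ctr)^2)))
  frac_home <- mean(sqrt(e6$x^2 + e6$y^2) < 2.5)
  frac_ctr <- mean(sqrt((e6$x - ctr[1])^2 + (e6$y - ctr[2])^2) < 2.5)
  expect_gt(frac_home, frac_ctr)

  # at zero conflict the generating density is the 3-landmark density:
  # the cloud concentrates near home
  e0 <- e[e$condition_id == "R0", ]
  expect_lt(empirical_accuracy(e0, c(0, 0)), empirical_accuracy(e6, ctr))
})

test_that("sample moments converge toward the generating density moments", {
  p <- ridge_params(6, 1, variant = "mixture", tail_floor = 10)
  cfg <- standard_config(3)
  spec <- default_grid_spec(cfg, p)
  dens <- ringhoming:::condition_density(cfg, p, spec)
  pr <- ringhoming:::summarize_grid(dens, cfg, p)

  for (n in c(500, 5000)) {
    smp <- sample_from_grid(dens, n, seed = 77)
    se <- sqrt(pr$total_variance / n)
    expect_lt(abs(mean(smp$x) - pr$mean[1]), 3 * se)
    expect_lt(abs(mean(smp$y) - pr$mean[2]), 3 * se)
    expect_lt(abs(empirical_accuracy(smp, cfg$home) - pr$expected_accuracy),
              3 * se)
    tv <- empirical_precision(smp)$total_variance
    expect_lt(abs(tv - pr$total_variance) / pr$total_variance, 15 / sqrt(n))
  }
})
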