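# Independent oracles used across the suite. These re-derive quantities by
# brute force (explicit loops, quadrature, generic optimisation) so they do
# not share code paths with the package internals they check.

# argmax over all cells with lowest-row-major-index tie-breaking
brute_argmax <- function(grid) {
  best <- -Inf; best_rc <- NULL
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      if (grid$values[i, j] > best) {
        best <- grid$values[i, j]
        best_rc <- c(i, j)
      }
    }
  }
  xs <- grid$origin[1] + (seq_len(grid$n_cols) - 1) * grid$cell_size
  ys <- grid$origin[2] + (seq_len(grid$n_rows) - 1) * grid$cell_size
  c(xs[best_rc[2]], ys[best_rc[1]])
}

# expected distance to home and covariance by direct per-cell summation
brute_moments <- function(grid, home) {
  xs <- grid$origin[1] + (seq_len(grid$n_cols) - 1) * grid$cell_size
  ys <- grid$origin[2] + (seq_len(grid$n_rows) - 1) * grid$cell_size
  w <- 0; acc <- 0; mx <- 0; my <- 0
  for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
    m <- grid$values[i, j] * grid$cell_size^2
    w <- w + m
    acc <- acc + m * sqrt((xs[j] - home[1])^2 + (ys[i] - home[2])^2)
    mx <- mx + m * xs[j]; my <- my + m * ys[i]
  }
  mx <- mx / w; my <- my / w
  sxx <- sxy <- syy <- 0
  for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
    m <- grid$values[i, j] * grid$cell_size^2
    sxx <- sxx + m * (xs[j] - mx)^2
    syy <- syy + m * (ys[i] - my)^2
    sxy <- sxy + m * (xs[j] - mx) * (ys[i] - my)
  }
  list(expected_accuracy = acc / w, mean = c(mx, my),
       cov = matrix(c(sxx, sxy, sxy, syy) / w, 2))
}

# expected distance to home under a single ring likelihood, by dense polar
# quadrature around the landmark (no grid involved)
ring_accuracy_quadrature <- function(params, landmark, home,
                                     n_r = 1200, n_th = 1440) {
  dmax <- params$ridge_radius + 6 * params$sigma_center
  rr <- seq(1e-9, dmax, length.out = n_r)
  th <- seq(0, 2 * pi, length.out = n_th + 1)[-(n_th + 1)]
  f <- radial_profile(rr, params)
  px <- outer(rr, th, function(r, t) landmark[1] + r * cos(t))
  py <- outer(rr, th, function(r, t) landmark[2] + r * sin(t))
  dist_home <- sqrt((px - home[1])^2 + (py - home[2])^2)
  w <- f * rr                       # polar area element
  sum(w * dist_home) / (sum(w) * length(th))
}

# least-squares trilateration by generic optimisation (independent of the
# package's internal version: different optimiser settings and start)
oracle_ls_center <- function(landmarks, radius) {
  obj <- function(p) {
    d <- sqrt((landmarks[, 1] - p[1])^2 + (landmarks[, 2] - p[2])^2)
    sum((d - radius)^2)
  }
  stats::optim(c(mean(landmarks[, 1]) + 0.1, mean(landmarks[, 2]) - 0.1),
               obj, method = "BFGS", control = list(reltol = 1e-14))$par
}

# study geometry constants shared by several tests: landmarks at radius 6
# around home (0, 0) at angles 90, 210, 330 degrees
study_landmarks <- function() {
  ang <- c(90, 210, 330) * pi / 180
  cbind(6 * cos(ang), 6 * sin(ang))
}

# intersections of the two rings around the stationary pair (landmarks 1, 2)
# of the study geometry: home itself and its mirror across the chord
stationary_intersections <- function() {
  rbind(home = c(0, 0),
        mirror = 2 * 3 * c(cos(150 * pi / 180), sin(150 * pi / 180)))
}
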