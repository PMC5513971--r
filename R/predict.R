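# mode detection: strict-or-plateau local maxima in the 8-neighbourhood,
# keeping one cell per plateau (the lowest row-major index)
find_modes <- function(values, threshold) {
  nr <- nrow(values); nc <- ncol(values)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- values
  is_max <- matrix(TRUE, nr, nc)
  ties_earlier <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
    is_max <- is_max & (values >= nb)
    # row-major order: rows first, then columns; an equal-valued neighbour
    # earlier in that order claims the plateau
    earlier <- (di < 0) | (di == 0 & dj < 0)
    if (earlier) ties_earlier <- ties_earlier | (values == nb)
  }
  keep <- is_max & !ties_earlier & (values >= threshold)
  which(keep, arr.ind = TRUE)
}

row_major_index <- function(rc, nc) (rc[, 1] - 1L) * nc + rc[, 2]

#' Predict homing performance for a landmark configuration
#'
#' Builds one ring likelihood per landmark around its test-time position,
#' using the trained ridge radius and fitted spread (the remembered
#' home-landmark distance was learned at training, so relocated rings keep
#' the trained radius), multiplies the maps ([combine_grids()]) and
#' summarizes the resulting response-probability distribution:
#' \itemize{
#'   \item \code{mle}: the global argmax (ties broken deterministically by
#'     lowest row-major cell index) -- the maximum-likelihood home estimate;
#'   \item \code{modes}: local maxima in the 8-neighbourhood whose density is
#'     at least \code{mode_threshold} of the global maximum, and the
#'     resulting \code{modality} (unimodal / bimodal / multimodal);
#'   \item \code{expected_accuracy}: mean distance to home under the
#'     predicted distribution, and \code{mle_accuracy}, the distance of the
#'     MLE itself to home;
#'   \item precision measures from the distribution covariance:
#'     \code{total_variance} (trace), \code{sd_ellipse_area}
#'     (\eqn{\pi \sigma_{maj} \sigma_{min}}) and \code{ellipse_area_95}
#'     (\eqn{\pi \chi^2_{2,0.95} \sqrt{\det \Sigma}}).
#' }
#'
#' @param config a [landmark_config()].
#' @param params a [ridge_params()] object (typically from [ring_fit()]).
#' @param spec a [grid_spec()]; defaults to [default_grid_spec()].
#' @param mode_threshold modes must reach this fraction of the global
#'   maximum (default 0.5).
#' @return An object of class \code{"homing_prediction"}.
#' @examples
#' p <- ridge_params(6, 1, variant = "gaussian")
#' pr <- predict_configuration(standard_config(3), p)
#' pr$modality
#' @export
predict_configuration <- function(config, params, spec = NULL,
                                  mode_threshold = 0.5) {
  stopifnot(inherits(config, "landmark_config"),
            inherits(params, "ridge_params"))
  if (is.null(spec)) spec <- default_grid_spec(config, params)
  rings <- lapply(seq_len(nrow(config$test_landmarks)), function(i) {
    ring_density(config$test_landmarks[i, ], params, spec, clip = TRUE)
  })
  grid <- combine_grids(rings)
  summarize_grid(grid, config, params, mode_threshold)
}

# all scalar summaries of a normalized density grid; direct summation over
# every cell
summarize_grid <- function(grid, config, params, mode_threshold = 0.5) {
  home <- config$home
  xs <- grid_xs(grid); ys <- grid_ys(grid)
  mass <- grid$values * grid$cell_size^2           # cell probabilities
  px <- colSums(mass); py <- rowSums(mass)
  mu <- c(sum(px * xs), sum(py * ys))
  cxx <- sum(px * (xs - mu[1])^2)
  cyy <- sum(py * (ys - mu[2])^2)
  cxy <- sum(mass * outer(ys - mu[2], xs - mu[1]))
  covm <- matrix(c(cxx, cxy, cxy, cyy), 2, 2,
                 dimnames = list(c("x", "y"), c("x", "y")))
  dist_home <- sqrt(outer((ys - home[2])^2, (xs - home[1])^2, `+`))
  expected_accuracy <- sum(mass * dist_home)

  vmax <- max(grid$values)
  flat_best <- which(t(grid$values) == vmax)[1]    # lowest row-major index
  mle_rc <- c(row = (flat_best - 1L) %/% grid$n_cols + 1L,
              col = (flat_best - 1L) %% grid$n_cols + 1L)
  mle <- c(xs[mle_rc[["col"]]], ys[mle_rc[["row"]]])

  rc <- find_modes(grid$values, mode_threshold * vmax)
  ord <- order(-grid$values[rc], row_major_index(rc, grid$n_cols))
  rc <- rc[ord, , drop = FALSE]
  modes <- cbind(x = xs[rc[, 2]], y = ys[rc[, 1]])
  mode_density <- grid$values[rc]
  n_modes <- nrow(modes)

  detc <- max(det(covm), 0)
  structure(
    list(mle = mle,
         mle_accuracy = sqrt(sum((mle - home)^2)),
         modes = modes, mode_density = mode_density,
         modality = if (n_modes <= 1) "unimodal"
                    else if (n_modes == 2) "bimodal" else "multimodal",
         expected_accuracy = expected_accuracy,
         mean = mu, covariance = covm,
         total_variance = cxx + cyy,
         sd_ellipse_area = pi * sqrt(detc),
         ellipse_area_95 = pi * stats::qchisq(0.95, df = 2) * sqrt(detc),
         grid = grid, config = config, params = params,
         mode_threshold = mode_threshold),
    class = "homing_prediction"
  )
}

#' @export
print.homing_prediction <- function(x, ...) {
  cat(sprintf("Homing prediction (%s variant)%s\n", x$params$variant,
              if (nzchar(x$config$label)) paste0(" for '", x$config$label, "'") else ""))
  cat(sprintf("  MLE          : (%.4g, %.4g), distance to home %.4g\n",
              x$mle[1], x$mle[2], x$mle_accuracy))
  cat(sprintf("  modality     : %s (%d mode%s at >= %.0f%% of peak)\n",
              x$modality, nrow(x$modes), if (nrow(x$modes) > 1) "s" else "",
              100 * x$mode_threshold))
  cat(sprintf("  accuracy     : %.4g (expected distance to home)\n",
              x$expected_accuracy))
  cat(sprintf("  variance     : %.4g (trace of covariance)\n", x$total_variance))
  cat(sprintf("  95%% ellipse  : %.4g (area)\n", x$ellipse_area_95))
  invisible(x)
}

#' @export
plot.homing_prediction <- function(x, ...) {
  plot(x$grid, main = sprintf("predicted density (%s)", x$params$variant), ...)
  graphics::points(x$config$test_landmarks, pch = 19, col = "red3")
  graphics::points(x$config$home[1], x$config$home[2], pch = 3, col = "darkgreen",
                   lwd = 2)
  graphics::points(x$modes[, 1], x$modes[, 2], pch = 4, col = "blue", lwd = 2)
  invisible(x)
}

#' Predict from a fitted ring likelihood
#'
#' Applies [predict_configuration()] with the fitted parameters; multi-
#' landmark and relocation predictions are parameter-free in the sense that
#' every parameter comes from the single-landmark fit.
#'
#' @param object a \code{"ring_fit"}.
#' @param config a [landmark_config()] (or list of them).
#' @param spec optional [grid_spec()].
#' @param variant override the fitted variant (e.g. compare
#'   \code{"gaussian"} vs \code{"mixture"} predictions from one fit).
#' @param ... passed to [predict_configuration()].
#' @return A \code{"homing_prediction"}, or a list of them.
#' @export
predict.ring_fit <- function(object, config, spec = NULL, variant = NULL, ...) {
  params <- object$params
  if (!is.null(variant)) params <- switch_variant(params, variant)
  if (inherits(config, "landmark_config"))
    return(predict_configuration(config, params, spec, ...))
  stopifnot(is.list(config))
  lapply(config, predict_configuration, params = params, spec = spec, ...)
}

# same central ridge, other variant (pedestal kept or dropped)
switch_variant <- function(params, variant) {
  variant <- match.arg(variant, c("gaussian", "mixture"))
  if (variant == params$variant) return(params)
  if (variant == "gaussian") {
    ridge_params(params$ridge_radius, params$sigma_center, variant = "gaussian")
  } else {
    ridge_params(params$ridge_radius, params$sigma_center, variant = "mixture",
                 tail_floor = 10)
  }
}

# least-squares trilateration: the point minimizing the summed squared ring
# residuals; for equal-sigma plain-Gaussian rings this is the continuous
# location of the product maximum
ls_center <- function(landmarks, radius, init = colMeans(landmarks)) {
  obj <- function(p) {
    d <- sqrt((landmarks[, 1] - p[1])^2 + (landmarks[, 2] - p[2])^2)
    sum((d - radius)^2)
  }
  stats::optim(init, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))$par
}

#' Sweep a landmark relocation across conflict sizes
#'
#' For each relocation distance, moves the deviant landmark orthogonally
#' away from the other two ([relocate_config()]) and predicts the homing
#' distribution under both the plain-Gaussian and the heavy-tailed mixture
#' likelihood built from the same central ridge. The plain Gaussian always
#' compromises (its maximum tracks the shifted configuration centre), while
#' the mixture predicts a breakdown: beyond a critical conflict the maximum
#' jumps to the intersection of the two stationary rings on the deviant
#' landmark's side, with the mirror-image intersection carrying strictly
#' less density because the deviant landmark's pedestal still disambiguates
#' the two.
#'
#' @param config 3-landmark training configuration.
#' @param relocations vector of relocation distances (default the study
#'   sweep 0, 1.5, 3, 4.5, 6).
#' @param params a [ridge_params()] object carrying the central ridge.
#' @param spec a [grid_spec()] shared by the whole sweep; defaults to
#'   [default_grid_spec()] on \code{config}. Every relocated landmark must
#'   stay inside this grid.
#' @param deviant index of the relocated landmark (default 3).
#' @param variants model variants to evaluate.
#' @param mode_threshold passed to [predict_configuration()].
#' @return A data frame of class \code{"relocation_sweep"} with one row per
#'   relocation and variant (columns: relocation, variant, mle_x, mle_y,
#'   mle_accuracy, expected_accuracy, total_variance, sd_ellipse_area,
#'   ellipse_area_95, modality, n_modes, center_x, center_y,
#'   dist_mle_center, dist_mle_home). The full \code{"homing_prediction"}
#'   objects are attached as \code{attr(, "predictions")}.
#' @export
relocation_sweep <- function(config, relocations = c(0, 1.5, 3, 4.5, 6),
                             params, spec = NULL, deviant = 3L,
                             variants = c("gaussian", "mixture"),
                             mode_threshold = 0.5) {
  stopifnot(inherits(config, "landmark_config"),
            nrow(config$training_landmarks) == 3,
            all(relocations >= 0), inherits(params, "ridge_params"))
  variants <- match.arg(variants, several.ok = TRUE)
  if (is.null(spec)) spec <- default_grid_spec(config, params)
  ext <- grid_extent(spec)

  rows <- list(); preds <- list()
  for (reloc in relocations) {
    cfg <- relocate_config(config, reloc, deviant)
    lm <- cfg$test_landmarks[deviant, ]
    if (lm[1] < ext$xmin || lm[1] > ext$xmax ||
        lm[2] < ext$ymin || lm[2] > ext$ymax)
      stop(sprintf("relocation %g moves the landmark outside the grid", reloc))
    ctr <- ls_center(cfg$test_landmarks, params$ridge_radius)
    for (v in variants) {
      pr <- predict_configuration(cfg, switch_variant(params, v), spec,
                                  mode_threshold = mode_threshold)
      key <- sprintf("%s_reloc%g", v, reloc)
      preds[[key]] <- pr
      rows[[key]] <- data.frame(
        relocation = reloc, variant = v,
        mle_x = pr$mle[1], mle_y = pr$mle[2],
        mle_accuracy = pr$mle_accuracy,
        expected_accuracy = pr$expected_accuracy,
        total_variance = pr$total_variance,
        sd_ellipse_area = pr$sd_ellipse_area,
        ellipse_area_95 = pr$ellipse_area_95,
        modality = pr$modality, n_modes = nrow(pr$modes),
        center_x = ctr[1], center_y = ctr[2],
        dist_mle_center = sqrt(sum((pr$mle - ctr)^2)),
        dist_mle_home = pr$mle_accuracy,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "predictions") <- preds
  class(out) <- c("relocation_sweep", "data.frame")
  out
}

#' @export
plot.relocation_sweep <- function(x, ...) {
  sp <- split(as.data.frame(x), x$variant)
  graphics::matplot(sp[[1]]$relocation,
                    sapply(sp, `[[`, "dist_mle_home"),
                    type = "b", pch = 19, lty = 1,
                    xlab = "relocation", ylab = "MLE distance to home", ...)
  graphics::legend("topleft", legend = names(sp), col = seq_along(sp),
                   pch = 19, bty = "n")
  invisible(x)
}
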