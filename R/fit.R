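#' Construct a set of homing endpoints
#'
#' Endpoint tables are plain data frames with columns \code{participant_id},
#' \code{condition_id}, \code{x}, \code{y}; this helper builds one and tags
#' its provenance. All package functions also accept any data frame with
#' those columns.
#'
#' @param x,y endpoint coordinates.
#' @param participant_id,condition_id identifiers (recycled).
#' @param provenance \code{"empirical"} or \code{"synthetic"}.
#' @return A data frame of class \code{"endpoint_set"}.
#' @export
endpoint_set <- function(x, y, participant_id = "P01", condition_id = "C1",
                         provenance = c("synthetic", "empirical")) {
  provenance <- match.arg(provenance)
  stopifnot(length(x) == length(y), length(x) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  out <- data.frame(participant_id = as.character(participant_id),
                    condition_id = as.character(condition_id),
                    x = as.numeric(x), y = as.numeric(y),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("endpoint_set", "data.frame")
  out
}

check_endpoints <- function(endpoints) {
  if (!is.data.frame(endpoints) || nrow(endpoints) == 0)
    stop("'endpoints' must be a non-empty data frame")
  if (!all(c("x", "y") %in% names(endpoints)))
    stop("'endpoints' must have columns 'x' and 'y'")
  if (any(!is.finite(endpoints$x)) || any(!is.finite(endpoints$y)))
    stop("endpoint coordinates must be finite")
  invisible(endpoints)
}

#' Collapse endpoints onto the distance-to-landmark axis
#'
#' Converts endpoints to polar coordinates centred on the landmark and keeps
#' the radial coordinate: the Euclidean distance of each endpoint to the
#' landmark, in input order. Because a single uniform landmark is ambiguous
#' in direction, this 1D collapse preserves all the information the ring
#' model can use.
#'
#' @param endpoints data frame with columns \code{x}, \code{y}.
#' @param landmark landmark position, numeric length 2.
#' @return Numeric vector of distances.
#' @examples
#' polar_collapse(data.frame(x = 3, y = 4), c(0, 0))  # 5
#' @export
polar_collapse <- function(endpoints, landmark) {
  check_endpoints(endpoints)
  stopifnot(length(landmark) == 2, all(is.finite(landmark)))
  sqrt((endpoints$x - landmark[1])^2 + (endpoints$y - landmark[2])^2)
}

#' Moment fit of the radial Gaussian
#'
#' The literal "collapse, then fit a Gaussian" recipe: the ridge radius is
#' the sample mean of the collapsed distances and the central spread their
#' sample standard deviation (n - 1 denominator). This estimator ignores the
#' ring geometry (no area Jacobian) and any pedestal component; see
#' [ring_fit()] for the maximum-likelihood alternative used by default.
#'
#' @param distances numeric vector of radial distances (>= 3 values).
#' @return Named vector \code{c(ridge_radius, sigma_center)}.
#' @examples
#' fit_radial_gaussian(c(5, 6, 7))  # mean 6, sd 1
#' @export
fit_radial_gaussian <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) < 3)
    stop("at least 3 distances are required")
  if (any(!is.finite(distances)) || any(distances < 0))
    stop("distances must be finite and non-negative")
  s <- stats::sd(distances)
  if (s == 0)
    stop("distances have zero spread; supply a sigma floor (see ring_fit(sigma_floor = ))")
  c(ridge_radius = mean(distances), sigma_center = s)
}

# quadrature support for the 1D radial law p(d) proportional to
# w(d) * profile(d), where w(d) is the arc length of the circle of radius d
# around the landmark that lies inside the observation window (w(d) = d for
# an unbounded window). Endpoints are only ever observed inside a bounded
# workspace, so the pedestal's large-d mass is angularly clipped; ignoring
# the clipping biases the fitted central spread upward.
radial_quadrature <- function(landmark, window, d_max,
                              n_quad = 1024L, n_ang = 720L) {
  dd <- seq(d_max / n_quad, d_max, length.out = n_quad)
  if (is.null(window)) {
    w <- dd
  } else {
    th <- seq(0, 2 * pi, length.out = n_ang + 1L)[-(n_ang + 1L)]
    px <- landmark[1] + outer(dd, cos(th))
    py <- landmark[2] + outer(dd, sin(th))
    inside <- px >= window$xmin & px <= window$xmax &
      py >= window$ymin & py <= window$ymax
    w <- dd * rowMeans(inside)
  }
  list(d = dd, w = w, step = dd[2] - dd[1])
}

radial_norm_const <- function(params, quad) {
  ft <- quad$w * radial_profile(quad$d, params)
  n <- length(ft)
  sum((ft[-1] + ft[-n]) / 2) * quad$step
}

#' Fit the ring likelihood to single-landmark homing endpoints
#'
#' The central estimator of the package. Endpoints from a single-landmark
#' condition are collapsed onto the distance-to-landmark axis
#' ([polar_collapse()]) and the ridge radius and central spread are
#' estimated from the resulting 1D sample. The pedestal ("heavy tail")
#' parameters of the mixture variant are never fitted: they are attached
#' from their fixed defaults (spread ten times the central sigma, floored at
#' \code{tail_floor}; peak amplitude 12\%), so that all multi-landmark and
#' relocation predictions remain parameter-free.
#'
#' Two estimation methods are available. \code{method = "ml"} (default)
#' maximizes the likelihood of the distances under the radial law
#' \eqn{p(d) \propto d \, \mathrm{profile}(d)} implied by sampling the 2D
#' ring density -- the \eqn{d} factor accounts for ring circumference, and
#' for the mixture variant the fixed pedestal is part of the likelihood, so
#' pedestal-scattered endpoints do not inflate the central spread.
#' \code{method = "moments"} is the plain [fit_radial_gaussian()] recipe;
#' the two agree to second order in \code{sigma_center / ridge_radius} for
#' ridge-concentrated data.
#'
#' @param endpoints data frame with columns \code{x}, \code{y} (single
#'   landmark condition).
#' @param landmark landmark position, numeric length 2.
#' @param variant \code{"mixture"} (default) or \code{"gaussian"}.
#' @param method \code{"ml"} or \code{"moments"}.
#' @param tail_scale,tail_mode,tail_amplitude,amplitude_mode,tail_floor
#'   pedestal settings passed to [ridge_params()]; fixed, not fitted.
#' @param sigma_floor lower bound for the fitted central spread.
#' @param d_max upper integration limit of the radial law for
#'   \code{method = "ml"}; defaults to the largest observed distance.
#' @param window observation window for \code{method = "ml"}: a list with
#'   \code{xmin}, \code{xmax}, \code{ymin}, \code{ymax}, or a
#'   [grid_spec()] whose extent is used. Defaults to the bounding box of
#'   the endpoints. The radial likelihood weights each distance by the arc
#'   length inside this window, so that broad pedestals clipped by the
#'   workspace edge do not bias the central spread. \code{window = NA}
#'   disables the correction (full circles).
#' @return An object of class \code{"ring_fit"} with components
#'   \code{params} (a [ridge_params()] object), \code{distances},
#'   \code{landmark}, \code{n}, \code{method}, \code{logLik} (ml only).
#' @seealso [predict.ring_fit()], [simulate.ring_fit()]
#' @examples
#' p <- ridge_params(6, 1, variant = "gaussian")
#' g <- ring_density(c(0, 0), p, grid_spec(c(0, 0), 11, 0.2))
#' pts <- sample_from_grid(g, 500, seed = 1)
#' fit <- ring_fit(pts, c(0, 0), variant = "gaussian")
#' coef(fit)
#' @export
ring_fit <- function(endpoints, landmark,
                     variant = c("mixture", "gaussian"),
                     method = c("ml", "moments"),
                     tail_scale = 10, tail_mode = c("sd", "variance"),
                     tail_amplitude = 0.12,
                     amplitude_mode = c("peak", "weight"),
                     tail_floor = 10,
                     sigma_floor = 1e-6, d_max = NULL, window = NULL) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  tail_mode <- match.arg(tail_mode)
  amplitude_mode <- match.arg(amplitude_mode)
  d <- polar_collapse(endpoints, landmark)
  if (length(d) < 3) stop("at least 3 endpoints are required")
  if (stats::sd(d) == 0)
    stop("distances have zero spread; increase 'sigma_floor' data or jitter")

  make_params <- function(r, s) {
    ridge_params(r, max(s, sigma_floor), variant = variant,
                 tail_scale = tail_scale, tail_mode = tail_mode,
                 tail_amplitude = tail_amplitude,
                 amplitude_mode = amplitude_mode, tail_floor = tail_floor)
  }

  ll <- NULL
  quad <- NULL
  if (method == "moments") {
    est <- fit_radial_gaussian(d)
    params <- make_params(est[["ridge_radius"]], est[["sigma_center"]])
  } else {
    if (is.null(d_max)) d_max <- max(d)
    d_max <- max(d_max, max(d))
    if (is.null(window)) {
      window <- list(xmin = min(endpoints$x), xmax = max(endpoints$x),
                     ymin = min(endpoints$y), ymax = max(endpoints$y))
    } else if (isTRUE(is.na(window))) {
      window <- NULL
    } else if (inherits(window, "grid_spec")) {
      window <- grid_extent(window)
    }
    quad <- radial_quadrature(landmark, window, d_max)
    negll <- function(theta) {
      r <- exp(theta[1]); s <- exp(theta[2])
      if (!is.finite(r) || !is.finite(s) || s < sigma_floor / 2) return(1e10)
      p <- tryCatch(make_params(r, s), error = function(e) NULL)
      if (is.null(p)) return(1e10)
      z <- radial_norm_const(p, quad)
      if (!is.finite(z) || z <= 0) return(1e10)
      v <- d * radial_profile(d, p)
      if (any(v <= 0)) return(1e10)
      -(sum(log(v)) - length(d) * log(z))
    }
    # robust start values: the ridge dominates the sample, so median/mad of
    # the distances land close enough for Nelder-Mead
    s0 <- max(stats::mad(d), sigma_floor, 1e-3)
    init <- c(log(max(stats::median(d), 1e-3)), log(s0))
    opt <- stats::optim(init, negll, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-10))
    params <- make_params(exp(opt$par[1]), exp(opt$par[2]))
    ll <- -opt$value
  }

  structure(
    list(params = params, distances = d, landmark = as.numeric(landmark),
         n = length(d), method = method, variant = variant,
         logLik = ll, quad = quad, call = match.call()),
    class = "ring_fit"
  )
}

#' Fit the ring likelihood separately per participant
#'
#' Convenience wrapper running [ring_fit()] on each participant's endpoints.
#' The pooled fit (all participants concatenated) is the default elsewhere;
#' per-participant fits support individual-differences analyses.
#'
#' @inheritParams ring_fit
#' @param ... passed on to [ring_fit()].
#' @return Named list of \code{"ring_fit"} objects, one per participant.
#' @export
ring_fit_by_participant <- function(endpoints, landmark, ...) {
  check_endpoints(endpoints)
  if (!"participant_id" %in% names(endpoints))
    stop("'endpoints' must have a 'participant_id' column")
  lapply(split(endpoints, endpoints$participant_id),
         ring_fit, landmark = landmark, ...)
}

#' @export
coef.ring_fit <- function(object, ...) {
  p <- object$params
  c(ridge_radius = p$ridge_radius, sigma_center = p$sigma_center,
    sigma_tail = p$sigma_tail, tail_amplitude = p$tail_amplitude)
}

#' @export
logLik.ring_fit <- function(object, ...) {
  if (is.null(object$logLik)) return(NULL)
  structure(object$logLik, df = 2, nobs = object$n, class = "logLik")
}

#' @export
nobs.ring_fit <- function(object, ...) object$n

#' @export
residuals.ring_fit <- function(object, ...) {
  object$distances - object$params$ridge_radius
}

#' @export
fitted.ring_fit <- function(object, ...) {
  rep(object$params$ridge_radius, object$n)
}

#' @export
print.ring_fit <- function(x, ...) {
  cat(sprintf("Ring likelihood fit (%s variant, %s method), n = %d endpoints\n",
              x$variant, x$method, x$n))
  print(x$params)
  invisible(x)
}

#' @export
summary.ring_fit <- function(object, ...) {
  d <- object$distances
  structure(
    list(fit = object,
         distance_summary = summary(d),
         moments = c(mean = mean(d), sd = stats::sd(d)),
         n = object$n),
    class = "summary.ring_fit"
  )
}

#' @export
print.summary.ring_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCollapsed distances to the landmark:\n")
  print(x$distance_summary)
  cat(sprintf("moment estimates: mean %.4g, sd %.4g (n = %d)\n",
              x$moments[["mean"]], x$moments[["sd"]], x$n))
  invisible(x)
}

#' @export
plot.ring_fit <- function(x, breaks = 30, ...) {
  d <- x$distances
  graphics::hist(d, breaks = breaks, freq = FALSE,
                 xlab = "distance to landmark", main = "collapsed radial fit",
                 col = "grey85", border = "white", ...)
  quad <- if (is.null(x$quad)) radial_quadrature(x$landmark, NULL, max(d))
          else x$quad
  z <- radial_norm_const(x$params, quad)
  graphics::lines(quad$d, quad$w * radial_profile(quad$d, x$params) / z,
                  col = "red3", lwd = 2)
  invisible(x)
}
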