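#' Radial ridge parameters for a single-landmark likelihood
#'
#' A distance-only landmark constrains the home position to a circle of
#' radius \code{ridge_radius} (the remembered home-landmark distance). Radial
#' uncertainty turns the circle into a "donut": a circular ridge with Gaussian
#' cross-section of spread \code{sigma_center}. The \code{"mixture"} variant
#' adds a second, much broader Gaussian centred on the same radius -- a low
#' pedestal forming heavy tails -- whose peak height is \code{tail_amplitude}
#' times the central peak. The heavy tails are what allow a product of
#' widely separated likelihoods to become bimodal, i.e. they let cue
#' integration break down under large conflict instead of always averaging.
#'
#' The pedestal is deliberately crude: its spread is tied to the central
#' spread by \code{tail_scale} (default ten times the central sigma, with the
#' \code{tail_mode = "variance"} reading \code{sqrt(tail_scale)} also
#' available) and floored at \code{tail_floor} so that it stays essentially
#' flat over the workspace. Its amplitude defaults to 12% of the central peak
#' and is never re-fitted from data; predictions only require that the tails
#' carry enough mass to matter at large conflicts while the central ridge
#' dominates near the ring.
#'
#' @param ridge_radius trained home-landmark distance (length units; > 0).
#' @param sigma_center spread of the central Gaussian ridge (> 0).
#' @param variant \code{"gaussian"} (plain ridge) or \code{"mixture"}
#'   (ridge plus pedestal).
#' @param sigma_tail pedestal spread; if \code{NULL} it is derived as
#'   \code{max(scale * sigma_center, tail_floor)} where \code{scale} is
#'   \code{tail_scale} (\code{tail_mode = "sd"}) or \code{sqrt(tail_scale)}
#'   (\code{tail_mode = "variance"}).
#' @param tail_amplitude pedestal amplitude in \eqn{[0, 1]}. With
#'   \code{amplitude_mode = "peak"} (default) this is the peak-height ratio of
#'   pedestal to central ridge; with \code{"weight"} it is interpreted as the
#'   mixture probability weight of the pedestal component in the 1D radial
#'   mixture and converted to the equivalent peak-height ratio.
#' @param tail_scale,tail_mode,tail_floor see above.
#' @param amplitude_mode \code{"peak"} or \code{"weight"}.
#' @return An object of class \code{"ridge_params"}.
#' @seealso [radial_profile()], [ring_density()], [ring_fit()]
#' @examples
#' ridge_params(6, 1, variant = "gaussian")
#' ridge_params(6, 1, variant = "mixture")
#' @export
ridge_params <- function(ridge_radius, sigma_center,
                         variant = c("mixture", "gaussian"),
                         sigma_tail = NULL, tail_amplitude = 0.12,
                         tail_scale = 10,
                         tail_mode = c("sd", "variance"),
                         tail_floor = 0,
                         amplitude_mode = c("peak", "weight")) {
  variant <- match.arg(variant)
  tail_mode <- match.arg(tail_mode)
  amplitude_mode <- match.arg(amplitude_mode)
  if (!is.finite(ridge_radius) || ridge_radius <= 0)
    stop("'ridge_radius' must be finite and > 0")
  if (!is.finite(sigma_center) || sigma_center <= 0)
    stop("'sigma_center' must be finite and > 0")

  if (variant == "mixture") {
    if (is.null(sigma_tail)) {
      scale <- if (tail_mode == "sd") tail_scale else sqrt(tail_scale)
      sigma_tail <- max(scale * sigma_center, tail_floor)
    }
    if (!is.finite(sigma_tail) || sigma_tail <= sigma_center)
      stop("'sigma_tail' must be finite and larger than 'sigma_center'")
    if (!is.finite(tail_amplitude) || tail_amplitude <= 0 || tail_amplitude > 1)
      stop("'tail_amplitude' must be in (0, 1] for the mixture variant")
    if (amplitude_mode == "weight") {
      # convert a mixture probability weight w of the pedestal component
      # (1D normalized densities) into the equivalent peak-height ratio
      w <- tail_amplitude
      tail_amplitude <- w * sigma_center / ((1 - w) * sigma_tail)
    }
  } else {
    sigma_tail <- NA_real_
    tail_amplitude <- 0
  }

  structure(
    list(ridge_radius = ridge_radius, sigma_center = sigma_center,
         sigma_tail = sigma_tail, tail_amplitude = tail_amplitude,
         variant = variant),
    class = "ridge_params"
  )
}

#' @export
print.ridge_params <- function(x, ...) {
  cat("Ridge parameters (", x$variant, " variant)\n", sep = "")
  cat(sprintf("  ridge radius : %.4g\n", x$ridge_radius))
  cat(sprintf("  sigma center : %.4g\n", x$sigma_center))
  if (x$variant == "mixture") {
    cat(sprintf("  sigma tail   : %.4g\n", x$sigma_tail))
    cat(sprintf("  tail ampl.   : %.4g (peak-height ratio)\n", x$tail_amplitude))
  }
  invisible(x)
}

#' Unnormalized radial cross-section of the ring likelihood
#'
#' Evaluates the radial profile of the donut likelihood at distance \code{d}
#' from the landmark. For the \code{"gaussian"} variant this is
#' \eqn{\exp(-(d - r)^2 / (2 \sigma_c^2))}; for the \code{"mixture"} variant
#' the pedestal term \eqn{a \exp(-(d - r)^2 / (2 \sigma_t^2))} is added
#' (both components peak at \eqn{d = r}; \eqn{a} is the peak-height ratio).
#' The profile is unnormalized: its peak value is 1 (gaussian) or
#' \eqn{1 + a} (mixture).
#'
#' @param d distance(s) from the landmark; non-negative.
#' @param params a [ridge_params()] object.
#' @return Numeric vector of non-negative density values.
#' @examples
#' p <- ridge_params(6, 1, variant = "gaussian")
#' radial_profile(6, p)      # 1 at the ridge
#' radial_profile(7, p)      # exp(-1/2)
#' @export
radial_profile <- function(d, params) {
  stopifnot(inherits(params, "ridge_params"))
  if (length(d) == 0L) return(numeric(0))
  if (any(!is.finite(d))) stop("'d' must be finite")
  if (any(d < 0)) stop("'d' must be non-negative")
  v <- exp(-(d - params$ridge_radius)^2 / (2 * params$sigma_center^2))
  if (params$variant == "mixture") {
    v <- v + params$tail_amplitude *
      exp(-(d - params$ridge_radius)^2 / (2 * params$sigma_tail^2))
  }
  v
}
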