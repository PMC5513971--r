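#' Empirical homing accuracy
#'
#' Accuracy is the mean Euclidean distance of the response endpoints from
#' the home location (smaller is better; the name follows the convention of
#' reporting the error magnitude itself).
#'
#' @param endpoints data frame with columns \code{x}, \code{y}.
#' @param home home position, numeric length 2.
#' @return Mean distance to home.
#' @examples
#' empirical_accuracy(data.frame(x = c(0, 0), y = c(3, -3)), c(0, 0))  # 3
#' @export
empirical_accuracy <- function(endpoints, home) {
  check_endpoints(endpoints)
  stopifnot(length(home) == 2, all(is.finite(home)))
  mean(sqrt((endpoints$x - home[1])^2 + (endpoints$y - home[2])^2))
}

#' Empirical homing precision
#'
#' Precision summaries from the sample covariance of the endpoints:
#' \code{total_variance} is its trace, \code{sd_ellipse_area} the area of
#' the 1-SD covariance ellipse (\eqn{\pi \sigma_{maj} \sigma_{min}}) and
#' \code{ellipse_area_95} the area of the ellipse expected to contain 95\%
#' of Gaussian responses (\eqn{\pi \chi^2_{2,0.95} \sqrt{\det \Sigma}}).
#'
#' @param endpoints data frame with columns \code{x}, \code{y}
#'   (>= 3 points).
#' @return Named list with \code{total_variance}, \code{sd_ellipse_area},
#'   \code{ellipse_area_95}.
#' @export
empirical_precision <- function(endpoints) {
  check_endpoints(endpoints)
  if (nrow(endpoints) < 3)
    stop("at least 3 endpoints are required for a covariance")
  covm <- stats::cov(cbind(endpoints$x, endpoints$y))
  detc <- max(det(covm), 0)   # collinear clouds give exactly zero area
  list(total_variance = covm[1, 1] + covm[2, 2],
       sd_ellipse_area = pi * sqrt(detc),
       ellipse_area_95 = pi * stats::qchisq(0.95, df = 2) * sqrt(detc))
}

#' Per-condition empirical summaries
#'
#' Accuracy and precision per condition, in a tidy table.
#'
#' @param endpoints endpoint data frame with a \code{condition_id} column.
#' @param home home position.
#' @return Data frame with one row per condition.
#' @export
summarize_conditions <- function(endpoints, home) {
  check_endpoints(endpoints)
  sp <- split(endpoints, endpoints$condition_id)
  out <- do.call(rbind, lapply(names(sp), function(cid) {
    pr <- empirical_precision(sp[[cid]])
    data.frame(condition_id = cid, n = nrow(sp[[cid]]),
               accuracy = empirical_accuracy(sp[[cid]], home),
               total_variance = pr$total_variance,
               sd_ellipse_area = pr$sd_ellipse_area,
               ellipse_area_95 = pr$ellipse_area_95,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# landmark count encoded in the condition id ("L1" -> 1)
condition_count <- function(condition_id) {
  cnt <- suppressWarnings(as.integer(sub("^[^0-9]*", "", condition_id)))
  if (any(is.na(cnt)))
    stop("cannot parse landmark counts from condition ids; supply 'counts'")
  cnt
}

#' Per-participant slope of accuracy against landmark count
#'
#' For each participant, the mean distance to home is computed per landmark
#' count and an ordinary least-squares line is fitted through the
#' (count, mean distance) pairs. A negative slope means homing improves
#' with additional landmarks.
#'
#' @param endpoints endpoint data frame with \code{participant_id} and
#'   \code{condition_id} columns.
#' @param home home position.
#' @param counts optional named vector mapping condition ids to landmark
#'   counts; by default the count is parsed from ids like \code{"L2"}.
#' @return Data frame with columns \code{participant_id}, \code{slope},
#'   \code{intercept}.
#' @examples
#' pts <- endpoint_set(c(10, 8, 6), c(0, 0, 0), "P01", c("L1", "L2", "L3"))
#' slope_per_participant(pts, c(0, 0))  # slope -2
#' @export
slope_per_participant <- function(endpoints, home, counts = NULL) {
  check_endpoints(endpoints)
  stopifnot(all(c("participant_id", "condition_id") %in% names(endpoints)))
  if (is.null(counts)) {
    ids <- unique(endpoints$condition_id)
    counts <- stats::setNames(condition_count(ids), ids)
  }
  sp <- split(endpoints, endpoints$participant_id)
  out <- do.call(rbind, lapply(names(sp), function(pid) {
    e <- sp[[pid]]
    bycond <- split(e, e$condition_id)
    cnt <- counts[names(bycond)]
    if (!all(sort(unique(counts)) %in% cnt))
      stop(sprintf("participant %s is missing a condition", pid))
    md <- vapply(bycond, empirical_accuracy, numeric(1), home = home)
    fit <- stats::lm(md ~ cnt)
    data.frame(participant_id = pid,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# one-sample t computed explicitly so that the all-differences-zero case is
# well defined (t = 0, p = 1) instead of an error
one_sample_t <- function(x, mu = 0, alternative = c("two.sided", "less", "greater"),
                         method = "One-sample t-test") {
  alternative <- match.arg(alternative)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("at least 2 values are required")
  if (any(!is.finite(x))) stop("values must be finite")
  s <- stats::sd(x)
  m <- mean(x)
  if (s == 0) {
    if (m == mu) {
      tstat <- 0
    } else {
      stop("zero variance with nonzero mean difference: t is undefined")
    }
  } else {
    tstat <- (m - mu) / (s / sqrt(n))
  }
  df <- n - 1
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tstat), df),
              less = stats::pt(tstat, df),
              greater = stats::pt(tstat, df, lower.tail = FALSE))
  structure(
    list(statistic = c(t = tstat), parameter = c(df = df), p.value = p,
         estimate = c(`mean` = m), null.value = c(mean = mu),
         alternative = alternative, method = method,
         data.name = deparse1(substitute(x))),
    class = "htest"
  )
}

#' Test per-participant slopes against zero
#'
#' One-sample t-test (df = n - 1) of the regression slopes against the
#' no-trend null. Tail-ness is explicit because mixed one- and two-tailed
#' conventions are common in this literature.
#'
#' @param slopes numeric vector of slopes, or the output of
#'   [slope_per_participant()].
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @return An object of class \code{"htest"}.
#' @export
slope_ttest <- function(slopes, alternative = c("two.sided", "less", "greater")) {
  if (is.data.frame(slopes)) slopes <- slopes$slope
  one_sample_t(slopes, mu = 0, alternative = match.arg(alternative),
               method = "One-sample t-test of slopes against zero")
}

#' Paired comparison of model predictions and data summaries
#'
#' Paired t-test on the per-condition differences (model minus data) under
#' the null that model and data agree. With k conditions the test has
#' k - 1 degrees of freedom; all-zero differences give t = 0, p = 1.
#'
#' @param model,data numeric vectors of per-condition summaries (same
#'   length and order).
#' @param alternative tail of the test.
#' @return An object of class \code{"htest"}.
#' @export
paired_model_vs_data <- function(model, data,
                                 alternative = c("two.sided", "less", "greater")) {
  stopifnot(length(model) == length(data), length(model) >= 2)
  one_sample_t(model - data, mu = 0, alternative = match.arg(alternative),
               method = "Paired t-test, model prediction vs data")
}
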