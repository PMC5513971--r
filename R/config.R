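#' Landmark configuration for one homing condition
#'
#' Bundles the trained home position with the landmark positions at training
#' and at test. Training and test lists are index-aligned (entry i is the
#' same physical landmark); they differ only when a landmark was relocated
#' between training and test. One to three landmarks are supported.
#'
#' @param home home position, numeric length 2.
#' @param training_landmarks numeric matrix with one row per landmark and
#'   columns x, y (a single landmark may be given as a length-2 vector).
#' @param test_landmarks landmark positions at test; defaults to the
#'   training positions (no relocation).
#' @param label free-text condition label.
#' @return An object of class \code{"landmark_config"}.
#' @examples
#' standard_config(3, radius = 6)
#' @export
landmark_config <- function(home, training_landmarks,
                            test_landmarks = training_landmarks,
                            label = "") {
  as_lm <- function(m) {
    if (is.null(dim(m))) m <- matrix(m, ncol = 2, byrow = TRUE)
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    m
  }
  home <- as.numeric(home)
  training_landmarks <- as_lm(training_landmarks)
  test_landmarks <- as_lm(test_landmarks)
  if (length(home) != 2 || any(!is.finite(home)))
    stop("'home' must be two finite coordinates")
  if (any(!is.finite(training_landmarks)) || any(!is.finite(test_landmarks)))
    stop("landmark coordinates must be finite")
  n <- nrow(training_landmarks)
  if (n < 1 || n > 3)
    stop("between 1 and 3 landmarks are supported")
  if (nrow(test_landmarks) != n)
    stop("training and test landmark lists must have the same length")
  structure(
    list(home = home, training_landmarks = training_landmarks,
         test_landmarks = test_landmarks, label = as.character(label)),
    class = "landmark_config"
  )
}

#' @export
print.landmark_config <- function(x, ...) {
  n <- nrow(x$training_landmarks)
  cat(sprintf("Landmark configuration%s: %d landmark%s, home (%.4g, %.4g)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              n, if (n > 1) "s" else "", x$home[1], x$home[2]))
  for (i in seq_len(n)) {
    moved <- any(x$training_landmarks[i, ] != x$test_landmarks[i, ])
    cat(sprintf("  L%d train (%.4g, %.4g)%s\n", i,
                x$training_landmarks[i, 1], x$training_landmarks[i, 2],
                if (moved) sprintf(" -> test (%.4g, %.4g)",
                                   x$test_landmarks[i, 1],
                                   x$test_landmarks[i, 2]) else ""))
  }
  invisible(x)
}

#' Evenly spread landmarks around the home position
#'
#' Builds the standard study geometry: \code{n_landmarks} landmarks at
#' distance \code{radius} around home at angles 90, 210 and 330 degrees
#' (conditions with fewer landmarks use the first one or two of these).
#' The visual geometry uses \code{radius = 6} (virtual meters), the auditory
#' geometry \code{radius = 2} (meters); units are abstract lengths.
#'
#' @param n_landmarks 1, 2 or 3.
#' @param radius home-landmark distance.
#' @param home home position.
#' @param label condition label; defaults to \code{"L<n>"}.
#' @return A \code{"landmark_config"}.
#' @export
standard_config <- function(n_landmarks, radius = 6, home = c(0, 0),
                            label = paste0("L", n_landmarks)) {
  stopifnot(n_landmarks %in% 1:3, radius > 0)
  ang <- c(90, 210, 330)[seq_len(n_landmarks)] * pi / 180
  lm <- cbind(home[1] + radius * cos(ang), home[2] + radius * sin(ang))
  landmark_config(home, lm, label = label)
}

#' Relocate one landmark orthogonally away from the others
#'
#' Moves the designated landmark, at test time only, by \code{distance}
#' along the direction orthogonal to the line through the two remaining
#' landmarks, pointing away from them (i.e. outward through the deviant
#' landmark's trained position). This is the conflict manipulation of the
#' relocation experiment: training geometry is untouched, only the test
#' geometry changes.
#'
#' @param config a 3-landmark \code{"landmark_config"}.
#' @param distance relocation distance (>= 0).
#' @param deviant index of the landmark to relocate (default 3).
#' @return A \code{"landmark_config"} with updated test positions.
#' @export
relocate_config <- function(config, distance, deviant = 3L) {
  stopifnot(inherits(config, "landmark_config"),
            is.finite(distance), distance >= 0)
  if (nrow(config$training_landmarks) != 3)
    stop("relocation requires a 3-landmark configuration")
  deviant <- as.integer(deviant)
  stopifnot(deviant %in% 1:3)
  others <- config$training_landmarks[-deviant, , drop = FALSE]
  axis <- others[2, ] - others[1, ]
  u <- c(-axis[2], axis[1])
  u <- u / sqrt(sum(u^2))
  mid <- colMeans(others)
  if (sum(u * (config$training_landmarks[deviant, ] - mid)) < 0) u <- -u
  test <- config$training_landmarks
  test[deviant, ] <- test[deviant, ] + distance * u
  landmark_config(config$home, config$training_landmarks, test,
                  label = sprintf("%s+reloc%g", config$label, distance))
}
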