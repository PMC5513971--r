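# run code under a temporary RNG state when a seed is given, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Draw endpoints from a discretized density
#'
#' Samples cells with probability proportional to their mass and jitters
#' each draw uniformly within the cell, giving a continuous sample whose
#' distribution converges to the grid density. Reproducible for a fixed
#' seed; with \code{seed = NULL} the current RNG stream is used.
#'
#' @param grid a normalized \code{"density_grid"}.
#' @param n number of endpoints (>= 1).
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @param participant_id,condition_id labels for the returned endpoint set.
#' @return An [endpoint_set()] with \code{n} rows, provenance
#'   \code{"synthetic"}.
#' @export
sample_from_grid <- function(grid, n, seed = NULL,
                             participant_id = "P01", condition_id = "C1") {
  stopifnot(inherits(grid, "density_grid"), n >= 1)
  if (!isTRUE(grid$normalized))
    stop("'grid' must be normalized (see normalize_grid())")
  p <- as.vector(grid$values)            # column-major: index = (j-1)*nr + i
  with_seed(seed, {
    idx <- sample.int(length(p), n, replace = TRUE, prob = p)
    i <- (idx - 1L) %% grid$n_rows + 1L
    j <- (idx - 1L) %/% grid$n_rows + 1L
    half <- grid$cell_size / 2
    endpoint_set(
      x = grid_xs(grid)[j] + stats::runif(n, -half, half),
      y = grid_ys(grid)[i] + stats::runif(n, -half, half),
      participant_id = participant_id, condition_id = condition_id,
      provenance = "synthetic")
  })
}

participant_ids <- function(n) sprintf("P%02d", seq_len(n))

# deterministic per-participant seed streams so that any participant can be
# regenerated alone; offsets keep the two experiments' streams apart
participant_seed <- function(seed, k, offset) {
  (as.integer(seed) + offset * k) %% .Machine$integer.max
}

draw_participant_sigma <- function(sigma_base, sigma_dispersion) {
  sigma_base * exp(stats::rnorm(1, 0, sigma_dispersion))
}

# density of one condition for one participant-level parameter set
condition_density <- function(config, params, spec) {
  rings <- lapply(seq_len(nrow(config$test_landmarks)), function(i)
    ring_density(config$test_landmarks[i, ], params, spec, clip = TRUE))
  combine_grids(rings)
}

#' Synthetic endpoints for the landmark-number experiment
#'
#' Ideal-observer generator for the 1/2/3-landmark design: each participant
#' receives an individual central spread drawn lognormally around
#' \code{sigma_base} (meanlog \code{log(sigma_base)}, sdlog
#' \code{sigma_dispersion}), and that participant's endpoints in every
#' condition are sampled from the model's own predicted response density
#' (default: mixture variant) for the corresponding configuration --
#' landmarks at \code{radius} 6 around home for the visual geometry, 2 for
#' the auditory one. Responses are endpoints only; trajectories, release
#' points and training dynamics are not modelled.
#'
#' An optional auditory source-confusion mode (\code{p_confusion} > 0)
#' replaces that fraction of 3-landmark trials by draws from the density of
#' a randomly chosen landmark pair, scattering responses between pairs of
#' landmarks; it is off by default.
#'
#' @param geometry \code{"visual"} (radius 6) or \code{"auditory"}
#'   (radius 2).
#' @param n_participants number of participants (>= 2).
#' @param trials_per_condition endpoints per participant and condition
#'   (default 40).
#' @param sigma_base,sigma_dispersion lognormal population distribution of
#'   the per-participant central spread.
#' @param variant generating model variant (default \code{"mixture"}).
#' @param seed master seed; per-participant streams are derived from it so
#'   that single participants can be regenerated exactly.
#' @param participants optional subset of participant indices to generate.
#' @param p_confusion probability of a pair-confused response in the
#'   3-landmark condition (0 disables).
#' @return A list of class \code{"homing_sim"} with \code{endpoints} (an
#'   [endpoint_set()]; condition ids \code{"L1"}, \code{"L2"}, \code{"L3"})
#'   and \code{metadata} (all generating parameters, per-participant sigmas
#'   and seeds, and the per-condition configurations).
#' @export
generate_experiment1 <- function(geometry = c("visual", "auditory"),
                                 n_participants = 10,
                                 trials_per_condition = 40,
                                 sigma_base = 1.0, sigma_dispersion = 0.2,
                                 variant = c("mixture", "gaussian"),
                                 seed = 1, participants = NULL,
                                 p_confusion = 0) {
  geometry <- match.arg(geometry)
  variant <- match.arg(variant)
  stopifnot(n_participants >= 2, trials_per_condition >= 1,
            sigma_base > 0, sigma_dispersion >= 0,
            p_confusion >= 0, p_confusion <= 1)
  radius <- if (geometry == "visual") 6 else 2
  ids <- participant_ids(n_participants)
  if (is.null(participants)) participants <- seq_len(n_participants)
  configs <- lapply(1:3, standard_config, radius = radius)
  names(configs) <- paste0("L", 1:3)

  sets <- list(); sigmas <- c(); seeds <- c()
  for (k in participants) {
    pseed <- participant_seed(seed, k, 104729L)
    seeds[ids[k]] <- pseed
    drawn <- with_seed(pseed, {
      sigma_k <- draw_participant_sigma(sigma_base, sigma_dispersion)
      params_k <- ridge_params(radius, sigma_k, variant = variant,
                               tail_floor = 10)
      spec_k <- default_grid_spec(configs[[1]], params_k)
      per_cond <- lapply(1:3, function(m) {
        dens <- condition_density(configs[[m]], params_k, spec_k)
        pts <- sample_from_grid(dens, trials_per_condition,
                                participant_id = ids[k],
                                condition_id = paste0("L", m))
        if (m == 3 && p_confusion > 0) {
          confused <- which(stats::runif(trials_per_condition) < p_confusion)
          if (length(confused)) {
            pairs <- utils::combn(3, 2)
            pick <- sample.int(3, length(confused), replace = TRUE)
            for (ii in seq_along(confused)) {
              pr_cfg <- landmark_config(
                configs[[3]]$home,
                configs[[3]]$training_landmarks[pairs[, pick[ii]], ,
                                                drop = FALSE])
              pd <- condition_density(pr_cfg, params_k, spec_k)
              one <- sample_from_grid(pd, 1, participant_id = ids[k],
                                      condition_id = "L3")
              pts[confused[ii], c("x", "y")] <- one[, c("x", "y")]
            }
          }
        }
        pts
      })
      list(sigma = sigma_k, endpoints = do.call(rbind, per_cond))
    })
    sigmas[ids[k]] <- drawn$sigma
    sets[[ids[k]]] <- drawn$endpoints
  }
  endpoints <- do.call(rbind, sets)
  rownames(endpoints) <- NULL
  attr(endpoints, "provenance") <- "synthetic"
  class(endpoints) <- c("endpoint_set", "data.frame")

  structure(
    list(endpoints = endpoints,
         metadata = list(design = "exp1", geometry = geometry,
                         radius = radius,
                         n_participants = n_participants,
                         trials_per_condition = trials_per_condition,
                         sigma_base = sigma_base,
                         sigma_dispersion = sigma_dispersion,
                         participant_sigma = sigmas,
                         participant_seed = seeds,
                         variant = variant, tail_amplitude = 0.12,
                         tail_scale = 10, tail_floor = 10,
                         p_confusion = p_confusion, seed = seed),
         configs = configs),
    class = "homing_sim"
  )
}

#' Synthetic endpoints for the landmark-relocation experiment
#'
#' Generator for the conflict design: the 3-landmark visual configuration
#' (radius 6) is trained, and at test one landmark is relocated outward by
#' each distance in \code{relocations} (study sweep: 0 to 6 in steps of
#' 1.5). Endpoints are sampled from the heavy-tailed mixture model's
#' predicted density of each relocated test configuration, with
#' per-participant spreads as in [generate_experiment1()] -- so the
#' generated behaviour integrates small conflicts and breaks down under
#' large ones.
#'
#' @inheritParams generate_experiment1
#' @param relocations relocation distances.
#' @param deviant index of the relocated landmark.
#' @return A \code{"homing_sim"} list; condition ids are \code{"R<dist>"}
#'   (e.g. \code{"R1.5"}).
#' @export
generate_experiment2 <- function(relocations = c(0, 1.5, 3, 4.5, 6),
                                 n_participants = 10,
                                 trials_per_condition = 40,
                                 sigma_base = 1.0, sigma_dispersion = 0.2,
                                 seed = 1, participants = NULL,
                                 deviant = 3L) {
  stopifnot(n_participants >= 2, trials_per_condition >= 1,
            all(relocations >= 0))
  radius <- 6
  ids <- participant_ids(n_participants)
  if (is.null(participants)) participants <- seq_len(n_participants)
  base <- standard_config(3, radius = radius)
  configs <- lapply(relocations, function(r) relocate_config(base, r, deviant))
  names(configs) <- sprintf("R%g", relocations)

  sets <- list(); sigmas <- c(); seeds <- c()
  for (k in participants) {
    pseed <- participant_seed(seed, k, 224737L)
    seeds[ids[k]] <- pseed
    drawn <- with_seed(pseed, {
      sigma_k <- draw_participant_sigma(sigma_base, sigma_dispersion)
      params_k <- ridge_params(radius, sigma_k, variant = "mixture",
                               tail_floor = 10)
      spec_k <- default_grid_spec(base, params_k)
      per_cond <- lapply(names(configs), function(nm) {
        dens <- condition_density(configs[[nm]], params_k, spec_k)
        sample_from_grid(dens, trials_per_condition,
                         participant_id = ids[k], condition_id = nm)
      })
      list(sigma = sigma_k, endpoints = do.call(rbind, per_cond))
    })
    sigmas[ids[k]] <- drawn$sigma
    sets[[ids[k]]] <- drawn$endpoints
  }
  endpoints <- do.call(rbind, sets)
  rownames(endpoints) <- NULL
  attr(endpoints, "provenance") <- "synthetic"
  class(endpoints) <- c("endpoint_set", "data.frame")

  structure(
    list(endpoints = endpoints,
         metadata = list(design = "exp2", geometry = "visual",
                         radius = radius, relocations = relocations,
                         deviant = deviant,
                         n_participants = n_participants,
                         trials_per_condition = trials_per_condition,
                         sigma_base = sigma_base,
                         sigma_dispersion = sigma_dispersion,
                         participant_sigma = sigmas,
                         participant_seed = seeds,
                         variant = "mixture", tail_amplitude = 0.12,
                         tail_scale = 10, tail_floor = 10, seed = seed),
         configs = configs),
    class = "homing_sim"
  )
}

#' @export
print.homing_sim <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("Synthetic homing data (%s, %s geometry): %d participants x %d conditions x %d trials\n",
              md$design, md$geometry, md$n_participants, length(x$configs),
              md$trials_per_condition))
  cat(sprintf("  generating variant %s, sigma_base %.3g (dispersion %.3g), seed %d\n",
              md$variant, md$sigma_base, md$sigma_dispersion, md$seed))
  invisible(x)
}

#' Simulate endpoints from a fitted ring likelihood
#'
#' Draws endpoints from the fitted model's predicted density -- by default
#' the single-landmark density around the landmark the model was fitted to,
#' or any configuration supplied via \code{config}.
#'
#' @param object a \code{"ring_fit"}.
#' @param nsim number of endpoints to draw.
#' @param seed optional seed, as in [sample_from_grid()].
#' @param config optional [landmark_config()]; defaults to the single
#'   fitted landmark with home at the fitted ridge distance along +x.
#' @param spec optional [grid_spec()].
#' @param ... unused.
#' @return An [endpoint_set()].
#' @export
simulate.ring_fit <- function(object, nsim = 100, seed = NULL,
                              config = NULL, spec = NULL, ...) {
  if (is.null(config)) {
    home <- object$landmark + c(object$params$ridge_radius, 0)
    config <- landmark_config(home, matrix(object$landmark, 1))
  }
  if (is.null(spec)) spec <- default_grid_spec(config, object$params)
  dens <- condition_density(config, object$params, spec)
  sample_from_grid(dens, nsim, seed = seed)
}
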