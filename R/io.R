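ext_of <- function(path) tolower(tools::file_ext(path))

#' Read / write landmark configurations
#'
#' Configurations are stored as JSON or YAML (chosen by file extension) with
#' keys \code{home}, \code{training_landmarks}, \code{test_landmarks},
#' \code{label}; landmark lists are arrays of \code{[x, y]} pairs.
#'
#' @param path file path ending in \code{.json}, \code{.yaml} or
#'   \code{.yml}.
#' @param config a [landmark_config()] (for writing).
#' @return \code{read_landmark_config} returns a \code{"landmark_config"};
#'   \code{write_landmark_config} returns \code{path} invisibly.
#' @examples
#' read_landmark_config(system.file("extdata", "triangle_visual.json",
#'                                  package = "ringhoming"))
#' @export
read_landmark_config <- function(path) {
  obj <- switch(ext_of(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = , yml = yaml::read_yaml(path),
                stop("unsupported config format: ", path))
  as_lm <- function(v) {
    if (is.list(v)) do.call(rbind, lapply(v, as.numeric)) else rbind(as.numeric(v))
  }
  tl <- if (is.matrix(obj$training_landmarks)) obj$training_landmarks
        else as_lm(obj$training_landmarks)
  el <- if (is.null(obj$test_landmarks)) tl
        else if (is.matrix(obj$test_landmarks)) obj$test_landmarks
        else as_lm(obj$test_landmarks)
  landmark_config(as.numeric(obj$home), tl, el,
                  label = if (is.null(obj$label)) "" else obj$label)
}

#' @rdname read_landmark_config
#' @export
write_landmark_config <- function(config, path) {
  stopifnot(inherits(config, "landmark_config"))
  mat2list <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  obj <- list(home = config$home,
              training_landmarks = mat2list(config$training_landmarks),
              test_landmarks = mat2list(config$test_landmarks),
              label = config$label)
  switch(ext_of(path),
         json = jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA),
         yaml = , yml = yaml::write_yaml(obj, path, precision = 15),
         stop("unsupported config format: ", path))
  invisible(path)
}

#' Read / write endpoint tables
#'
#' Endpoint tables are CSV files with header
#' \code{participant_id, condition_id, x, y}.
#'
#' @param path CSV file path.
#' @param endpoints endpoint data frame (for writing).
#' @param provenance provenance tag attached on reading.
#' @return \code{read_endpoints} returns an [endpoint_set()];
#'   \code{write_endpoints} returns \code{path} invisibly.
#' @examples
#' read_endpoints(system.file("extdata", "endpoints_example.csv",
#'                            package = "ringhoming"))
#' @export
read_endpoints <- function(path, provenance = c("empirical", "synthetic")) {
  provenance <- match.arg(provenance)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "condition_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("endpoint CSV must have columns ", paste(need, collapse = ", "))
  endpoint_set(df$x, df$y, df$participant_id, df$condition_id,
               provenance = provenance)
}

#' @rdname read_endpoints
#' @export
write_endpoints <- function(endpoints, path) {
  check_endpoints(endpoints)
  cols <- c("participant_id", "condition_id", "x", "y")
  utils::write.csv(as.data.frame(endpoints)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read / write fitted ridge parameters as JSON
#'
#' @param params a [ridge_params()] object (for writing).
#' @param path JSON file path.
#' @return \code{read_ridge_params} returns a \code{"ridge_params"} object.
#' @export
write_ridge_params <- function(params, path) {
  stopifnot(inherits(params, "ridge_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_ridge_params
#' @export
read_ridge_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$variant, "gaussian"))
    ridge_params(obj$ridge_radius, obj$sigma_center, variant = "gaussian")
  else
    ridge_params(obj$ridge_radius, obj$sigma_center, variant = "mixture",
                 sigma_tail = obj$sigma_tail, tail_amplitude = obj$tail_amplitude)
}

#' Export / import a density grid
#'
#' The cell values are written as a headerless CSV matrix (rows index y,
#' columns x) together with a JSON sidecar holding origin, cell size and
#' shape.
#'
#' @param grid a \code{"density_grid"} (for writing).
#' @param path CSV path; the sidecar is \code{<path>.json}.
#' @return \code{read_density_grid} returns a \code{"density_grid"}.
#' @export
write_density_grid <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  utils::write.table(grid$values, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(origin = grid$origin, cell_size = grid$cell_size,
                            n_rows = grid$n_rows, n_cols = grid$n_cols,
                            normalized = isTRUE(grid$normalized)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_density_grid
#' @export
read_density_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(values) <- NULL
  spec <- structure(list(origin = as.numeric(meta$origin),
                         cell_size = meta$cell_size,
                         n_rows = as.integer(meta$n_rows),
                         n_cols = as.integer(meta$n_cols)),
                    class = "grid_spec")
  stopifnot(nrow(values) == spec$n_rows, ncol(values) == spec$n_cols)
  new_density_grid(spec, values, normalized = isTRUE(meta$normalized))
}

#' Serialize a homing prediction to JSON
#'
#' Writes the scalar summaries and modes of a \code{"homing_prediction"}
#' (the density grid itself is exported separately with
#' [write_density_grid()] if needed).
#'
#' @param prediction a \code{"homing_prediction"}.
#' @param path JSON file path.
#' @export
write_prediction <- function(prediction, path) {
  stopifnot(inherits(prediction, "homing_prediction"))
  obj <- list(
    label = prediction$config$label,
    variant = prediction$params$variant,
    mle = prediction$mle,
    mle_accuracy = prediction$mle_accuracy,
    modes = apply(prediction$modes, 1, function(r) unname(r), simplify = FALSE),
    mode_density = as.numeric(prediction$mode_density),
    modality = prediction$modality,
    expected_accuracy = prediction$expected_accuracy,
    mean = unname(prediction$mean),
    covariance = list(xx = prediction$covariance[1, 1],
                      xy = prediction$covariance[1, 2],
                      yy = prediction$covariance[2, 2]),
    total_variance = prediction$total_variance,
    sd_ellipse_area = prediction$sd_ellipse_area,
    ellipse_area_95 = prediction$ellipse_area_95)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
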