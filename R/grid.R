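#' Define a square-cell evaluation grid
#'
#' Probability maps are discretized on a regular grid of square cells.
#' The grid is centred on \code{center} and extends \code{half_width} in each
#' direction; an odd number of cells per side guarantees that \code{center}
#' is exactly a cell centre, which keeps mirror and rotation symmetries exact
#' at the discrete level.
#'
#' @param center grid centre, numeric length 2.
#' @param half_width half of the side length of the covered square (> 0).
#' @param cell_size side length of one cell (> 0).
#' @return An object of class \code{"grid_spec"} with elements \code{origin}
#'   (centre of the cell at row 1, column 1), \code{cell_size}, \code{n_rows},
#'   \code{n_cols}.
#' @examples
#' grid_spec(c(0, 0), half_width = 10, cell_size = 0.5)
#' @export
grid_spec <- function(center = c(0, 0), half_width, cell_size) {
  stopifnot(length(center) == 2, all(is.finite(center)),
            is.finite(half_width), half_width > 0,
            is.finite(cell_size), cell_size > 0, cell_size <= half_width)
  half_cells <- floor(half_width / cell_size)
  n <- 2L * as.integer(half_cells) + 1L
  origin <- center - half_cells * cell_size
  structure(
    list(origin = origin, cell_size = cell_size,
         n_rows = n, n_cols = n),
    class = "grid_spec"
  )
}

#' Default grid for a landmark configuration
#'
#' Square workspace centred on the home position with half-width
#' \code{ridge_radius + max(6 * sigma_center, 10)} and cell size
#' \code{sigma_center / 5}, i.e. at least five cells across the ridge width
#' so the discrete argmax is stable.
#'
#' @param config a [landmark_config()] object.
#' @param params a [ridge_params()] object.
#' @return A \code{"grid_spec"} object.
#' @export
default_grid_spec <- function(config, params) {
  stopifnot(inherits(config, "landmark_config"), inherits(params, "ridge_params"))
  grid_spec(center = config$home,
            half_width = params$ridge_radius + max(6 * params$sigma_center, 10),
            cell_size = params$sigma_center / 5)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid: %d x %d cells of size %.4g, origin (%.4g, %.4g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

# x coordinates of cell centres by column, y by row
grid_xs <- function(g) g$origin[1] + (seq_len(g$n_cols) - 1) * g$cell_size
grid_ys <- function(g) g$origin[2] + (seq_len(g$n_rows) - 1) * g$cell_size

grid_extent <- function(g) {
  half <- g$cell_size / 2
  list(xmin = g$origin[1] - half,
       xmax = g$origin[1] + (g$n_cols - 1) * g$cell_size + half,
       ymin = g$origin[2] - half,
       ymax = g$origin[2] + (g$n_rows - 1) * g$cell_size + half)
}

same_geometry <- function(a, b) {
  identical(a$n_rows, b$n_rows) && identical(a$n_cols, b$n_cols) &&
    isTRUE(all(a$origin == b$origin)) && isTRUE(a$cell_size == b$cell_size)
}

new_density_grid <- function(spec, values, normalized = FALSE) {
  structure(
    list(origin = spec$origin, cell_size = spec$cell_size,
         n_rows = spec$n_rows, n_cols = spec$n_cols,
         values = values, normalized = normalized),
    class = c("density_grid", "grid_spec")
  )
}

#' Normalize a density grid to integrate to one
#'
#' Rescales cell values so that \code{sum(values) * cell_size^2 == 1}.
#'
#' @param grid a \code{"density_grid"}.
#' @return The normalized grid.
#' @export
normalize_grid <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  total <- sum(grid$values) * grid$cell_size^2
  if (!is.finite(total) || total <= 0)
    stop("grid has zero (or non-finite) total mass; cannot normalize")
  grid$values <- grid$values / total
  grid$normalized <- TRUE
  grid
}

#' Uniform density over a grid
#'
#' The identity element under product-and-renormalize combination.
#'
#' @param spec a \code{"grid_spec"}.
#' @return A normalized \code{"density_grid"} with constant values.
#' @export
uniform_grid <- function(spec) {
  v <- matrix(1, spec$n_rows, spec$n_cols)
  normalize_grid(new_density_grid(spec, v))
}

#' Ring ("donut") likelihood map around one landmark
#'
#' Evaluates [radial_profile()] at each cell centre's distance to the
#' landmark and renormalizes the grid so it integrates to one. No area
#' Jacobian is applied: the 2D density at distance \eqn{d} is proportional to
#' the radial profile itself, which keeps the density ridge exactly at
#' \code{ridge_radius} and matches the construction of mapping a fitted 1D
#' radial Gaussian back around the landmark.
#'
#' Unless \code{clip = TRUE}, the grid must cover a square of half-width
#' \code{ridge_radius + 4 * sigma_center} around the landmark, so that the
#' whole ridge is inside the map. With \code{clip = TRUE} the grid is treated
#' as the declared workspace and the density is simply truncated at its
#' edges (the landmark must still lie inside the grid); this is how broad
#' mixture pedestals and relocated landmarks near the boundary are handled.
#'
#' @param landmark landmark position, numeric length 2.
#' @param params a [ridge_params()] object.
#' @param spec a [grid_spec()] (or an existing \code{"density_grid"} whose
#'   geometry is reused).
#' @param clip if \code{TRUE}, truncate at the workspace boundary instead of
#'   requiring full coverage of the ridge.
#' @return A normalized \code{"density_grid"}.
#' @examples
#' p <- ridge_params(6, 1, variant = "gaussian")
#' g <- ring_density(c(0, 0), p, grid_spec(c(0, 0), 11, 0.2))
#' sum(g$values) * g$cell_size^2  # 1
#' @export
ring_density <- function(landmark, params, spec, clip = FALSE) {
  stopifnot(length(landmark) == 2, all(is.finite(landmark)),
            inherits(params, "ridge_params"))
  ext <- grid_extent(spec)
  if (landmark[1] < ext$xmin || landmark[1] > ext$xmax ||
      landmark[2] < ext$ymin || landmark[2] > ext$ymax)
    stop("landmark lies outside the grid")
  if (!clip) {
    need <- params$ridge_radius + 4 * params$sigma_center
    ok <- landmark[1] - need >= ext$xmin - 1e-9 &&
      landmark[1] + need <= ext$xmax + 1e-9 &&
      landmark[2] - need >= ext$ymin - 1e-9 &&
      landmark[2] + need <= ext$ymax + 1e-9
    if (!ok)
      stop(sprintf(paste0("grid too small to contain the ridge: need the square ",
                          "of half-width %.4g around (%.4g, %.4g); ",
                          "use clip = TRUE to truncate at the workspace"),
                   need, landmark[1], landmark[2]))
  }
  dx <- grid_xs(spec) - landmark[1]
  dy <- grid_ys(spec) - landmark[2]
  # distance from each cell centre to the landmark; rows index y, cols index x
  d <- sqrt(outer(dy^2, dx^2, `+`))
  normalize_grid(new_density_grid(spec, radial_profile(d, params)))
}

#' Multiply likelihood maps and renormalize
#'
#' Pointwise product of density grids sharing one geometry, renormalized to
#' integrate to one. This is the maximum-likelihood combination rule for
#' independent landmark cues: the product concentrates mass where all rings
#' agree. Commutative and associative up to floating-point rounding.
#'
#' @param grids a list of \code{"density_grid"} objects with identical
#'   origin, cell size and shape.
#' @return A normalized \code{"density_grid"}.
#' @examples
#' p <- ridge_params(6, 1, variant = "gaussian")
#' gs <- grid_spec(c(0, 0), 12, 0.25)
#' g <- combine_grids(list(ring_density(c(-4, 0), p, gs, clip = TRUE),
#'                         ring_density(c(4, 0), p, gs, clip = TRUE)))
#' @export
combine_grids <- function(grids) {
  stopifnot(is.list(grids), length(grids) >= 1,
            all(vapply(grids, inherits, logical(1), "density_grid")))
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    if (!same_geometry(g1, g))
      stop("all grids must share origin, cell size and shape")
  }
  prod_values <- Reduce(`*`, lapply(grids, `[[`, "values"))
  if (!any(prod_values > 0))
    stop("total conflict: the likelihood maps have no common support anywhere")
  normalize_grid(new_density_grid(g1, prod_values))
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid: %d x %d cells of size %.4g%s\n",
              x$n_rows, x$n_cols, x$cell_size,
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  cat(sprintf("  extent x: [%.4g, %.4g], y: [%.4g, %.4g]\n",
              grid_extent(x)$xmin, grid_extent(x)$xmax,
              grid_extent(x)$ymin, grid_extent(x)$ymax))
  invisible(x)
}

#' @export
plot.density_grid <- function(x, ..., main = "density") {
  graphics::image(grid_xs(x), grid_ys(x), t(x$values),
                  asp = 1, xlab = "x", ylab = "y", main = main,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}
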