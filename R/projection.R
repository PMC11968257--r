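#' Projection configuration
#'
#' Parameters of the signal projection and silhouette. Radii are expressed as
#' fractions of the unit-square diagonal (`sqrt(2)`), so they are scale-free
#' with respect to the original layout units. Defaults were chosen for visual
#' plausibility on graphs of a few hundred to a few thousand vertices; the
#' proximity statistics are independent of them.
#'
#' @param grid_resolution pixels per side of the raster (>= 16, default 400).
#' @param kernel `"linear"` (triangular, `max(0, 1 - u)`) or `"gaussian"`
#'   (`exp(-u^2/2)`, truncated at `u = 3`), where `u` is Euclidean layout
#'   distance divided by `projection_radius * sqrt(2)`.
#' @param projection_radius kernel scale as a fraction of the diagonal,
#'   in `(0, 1]` (default 0.05).
#' @param silhouette_radius silhouette mask radius as a fraction of the
#'   diagonal, in `(0, 1]` (default 0.03).
#' @param aggregation `"max"` (per-pixel maximum over vertex kernels) or
#'   `"sum"` (per-pixel sum, capped at the maximum during normalization).
#' @return A `projection_config` list.
#' @export
projection_config <- function(grid_resolution = 400,
                              kernel = c("linear", "gaussian"),
                              projection_radius = 0.05,
                              silhouette_radius = 0.03,
                              aggregation = c("max", "sum")) {
  kernel <- match.arg(kernel)
  aggregation <- match.arg(aggregation)
  if (grid_resolution < 16) stop("grid_resolution must be >= 16")
  if (projection_radius <= 0 || projection_radius > 1) {
    stop("projection_radius must be in (0, 1]")
  }
  if (silhouette_radius <= 0 || silhouette_radius > 1) {
    stop("silhouette_radius must be in (0, 1]")
  }
  structure(list(grid_resolution = as.integer(grid_resolution),
                 kernel = kernel,
                 projection_radius = projection_radius,
                 silhouette_radius = silhouette_radius,
                 aggregation = aggregation),
            class = "projection_config")
}

#' Read a projection configuration from YAML
#'
#' Recognized keys: `grid_resolution`, `kernel`, `projection_radius`,
#' `silhouette_radius`, `aggregation`. Missing keys take their defaults.
#'
#' @param path YAML file path.
#' @return A [projection_config()].
#' @export
read_projection_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  allowed <- c("grid_resolution", "kernel", "projection_radius",
               "silhouette_radius", "aggregation")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown) > 0) {
    stop("unknown projection config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(projection_config, y)
}

# pixel centers along one axis: pixel j (0-based) center at (j + 0.5)/R
.pixel_centers <- function(R) (seq_len(R) - 0.5) / R

#' Circular projection of vertex signal onto a raster
#'
#' Spreads each vertex's signal over a disk around its layout position and
#' rasterizes the result: for pixel `p`,
#' `value(p) = agg_v signal[v] * K(||p - xy(v)|| / (projection_radius * sqrt(2)))`
#' with `K` the configured kernel and `agg` the configured aggregation. The
#' grid is then rescaled to `[0, 1]` by its maximum (when positive). Rows of
#' the matrix index y from the bottom (row i, column j covers the pixel whose
#' center is `((j - 0.5)/R, (i - 0.5)/R)` in unit-square coordinates).
#'
#' @param g a [pathway_graph()] with signal set (see [set_signal()]).
#' @param cfg a [projection_config()].
#' @return A `density_grid`: list with `values` (R x R matrix), `mask`
#'   (logical matrix, all `TRUE` until [silhouette_mapping()]), and `cfg`.
#' @examples
#' toy <- set_signal(toy_fig1()$graph, toy_fig1()$L1)
#' grid <- circular_projection(toy, projection_config(grid_resolution = 64))
#' range(grid$values)
#' @export
circular_projection <- function(g, cfg = projection_config()) {
  stopifnot(inherits(g, "pathway_graph"), inherits(cfg, "projection_config"))
  R <- cfg$grid_resolution
  scale <- cfg$projection_radius * sqrt(2)
  # kernel support in u units: linear hits zero at u = 1; gaussian truncated
  support <- if (cfg$kernel == "linear") 1 else 3
  vals <- matrix(0, nrow = R, ncol = R)
  centers <- .pixel_centers(R)
  active <- which(g$signal != 0)
  for (v in active) {
    vx <- g$layout[v, 1]
    vy <- g$layout[v, 2]
    r_max <- support * scale
    jx <- which(abs(centers - vx) <= r_max)
    iy <- which(abs(centers - vy) <= r_max)
    if (length(jx) == 0 || length(iy) == 0) next
    dx2 <- (centers[jx] - vx)^2
    dy2 <- (centers[iy] - vy)^2
    u <- sqrt(outer(dy2, dx2, "+")) / scale
    k <- if (cfg$kernel == "linear") {
      pmax(0, 1 - u)
    } else {
      ifelse(u <= 3, exp(-u^2 / 2), 0)
    }
    contrib <- g$signal[v] * k
    if (cfg$aggregation == "max") {
      vals[iy, jx] <- pmax(vals[iy, jx], contrib)
    } else {
      vals[iy, jx] <- vals[iy, jx] + contrib
    }
  }
  mx <- max(vals)
  if (mx > 0) vals <- vals / mx
  structure(list(values = vals,
                 mask = matrix(TRUE, nrow = R, ncol = R),
                 cfg = cfg),
            class = "density_grid")
}

#' Restrict a density grid to the graph silhouette
#'
#' Masks the raster to the neighborhood of the vertex cloud: a pixel is kept
#' iff its center lies within `silhouette_radius * sqrt(2)` of at least one
#' vertex (any vertex, regardless of signal). Values outside the silhouette
#' become `NA`; values inside are unchanged.
#'
#' @param g the [pathway_graph()] the grid was computed from.
#' @param grid a `density_grid` from [circular_projection()].
#' @param cfg a [projection_config()]; defaults to the grid's own config.
#' @return The masked `density_grid`.
#' @export
silhouette_mapping <- function(g, grid, cfg = grid$cfg) {
  stopifnot(inherits(g, "pathway_graph"), inherits(grid, "density_grid"))
  R <- nrow(grid$values)
  r <- cfg$silhouette_radius * sqrt(2)
  centers <- .pixel_centers(R)
  mask <- matrix(FALSE, nrow = R, ncol = R)
  for (v in seq_len(n_vertices(g))) {
    vx <- g$layout[v, 1]
    vy <- g$layout[v, 2]
    jx <- which(abs(centers - vx) <= r)
    iy <- which(abs(centers - vy) <= r)
    if (length(jx) == 0 || length(iy) == 0) next
    inside <- outer((centers[iy] - vy)^2, (centers[jx] - vx)^2, "+") <= r^2
    mask[iy, jx] <- mask[iy, jx] | inside
  }
  grid$values[!mask] <- NA_real_
  grid$mask <- mask
  grid
}

#' @export
print.density_grid <- function(x, ...) {
  R <- nrow(x$values)
  cat(sprintf("density_grid: %d x %d, %s kernel, %.0f%% inside silhouette\n",
              R, R, x$cfg$kernel, 100 * mean(x$mask)))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%.3g, %.3g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Write a density grid as a TSV matrix
#'
#' Rows are written top-to-bottom (highest y first) so the file reads like
#' the rendered image; masked pixels are `NA`.
#'
#' @param grid a `density_grid`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_grid_tsv <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  m <- grid$values[rev(seq_len(nrow(grid$values))), , drop = FALSE]
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
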