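#' Left-tail rejection threshold of a permutation null
#'
#' The empirical `alpha`-quantile of the null sample (type-7 linear
#' interpolation, the interpolation R uses by default; fixed here so the
#' drawn rejection region is reproducible across platforms). Observed values
#' at or below the threshold fall in the shaded rejection region of
#' [plot_path_distances()].
#'
#' @param null_sample numeric vector of null statistics.
#' @param alpha significance level in (0, 1), default 0.05.
#' @return The threshold value.
#' @examples
#' rejection_threshold(1:100, 0.05) # 5.95
#' @export
rejection_threshold <- function(null_sample, alpha = 0.05) {
  if (length(null_sample) == 0) stop("null_sample is empty")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  unname(stats::quantile(null_sample, probs = alpha, type = 7,
                         na.rm = TRUE))
}

# open a device by file extension, run plot code, close
.render <- function(path, width, height, expr) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         stop("unsupported plot extension: .", ext, " (use png/pdf/svg)"))
  on.exit(grDevices::dev.off())
  print(force(expr))
  invisible(path)
}

#' Plot the graph-space layout
#'
#' Scatter of all vertices at their layout positions with edges underneath;
#' genes in `marks` are highlighted and labeled.
#'
#' @param g a [pathway_graph()].
#' @param out_path output file (`.png`, `.pdf` or `.svg`).
#' @param marks optional [gene_list()] (or character vector) of genes to
#'   highlight; must all be vertices of `g`.
#' @param mark_color highlight color.
#' @param mark_size highlight point size.
#' @param title plot title.
#' @return Invisibly, `out_path`.
#' @export
plot_graph_space <- function(g, out_path, marks = NULL,
                             mark_color = "blue", mark_size = 2,
                             title = "Graph space") {
  stopifnot(inherits(g, "pathway_graph"))
  df <- data.frame(name = vertex_names(g), x = g$layout[, 1],
                   y = g$layout[, 2])
  el <- igraph::as_edgelist(g$graph, names = TRUE)
  ed <- data.frame(x = g$layout[el[, 1], 1], y = g$layout[el[, 1], 2],
                   xend = g$layout[el[, 2], 1], yend = g$layout[el[, 2], 2])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          color = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8, color = "grey40") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(marks)) {
    marks <- as_gene_list(marks, "marks")
    chk <- validate_membership(g, marks)
    if (!chk$ok) {
      stop("mark genes not in graph: ", paste(chk$missing, collapse = ", "))
    }
    md <- df[df$name %in% marks$ids, , drop = FALSE]
    p <- p +
      ggplot2::geom_point(data = md, color = mark_color, size = mark_size) +
      ggplot2::geom_text(data = md, ggplot2::aes(label = .data$name),
                         color = mark_color, vjust = -1, size = 3)
  }
  .render(out_path, 6, 6, p)
}

#' Plot a signal-density landscape
#'
#' Heatmap of a (silhouette-masked) density grid over the unit square, with
#' optional marked genes. `theme = "th3"` renders the dark landscape style;
#' any other tag uses a plain light theme.
#'
#' @param grid a `density_grid` from [circular_projection()] /
#'   [silhouette_mapping()].
#' @param g the [pathway_graph()] the grid came from (for mark positions).
#' @param out_path output file (`.png`, `.pdf` or `.svg`).
#' @inheritParams plot_graph_space
#' @param theme `"th3"` for the dark landscape theme, anything else for a
#'   light theme.
#' @return Invisibly, `out_path`.
#' @export
plot_pathway_space <- function(grid, g, out_path, marks = NULL,
                               mark_color = "white", mark_size = 2,
                               title = "Pathway space", theme = "th3") {
  stopifnot(inherits(grid, "density_grid"), inherits(g, "pathway_graph"))
  R <- nrow(grid$values)
  centers <- .pixel_centers(R)
  df <- expand.grid(x = centers, y = centers)
  df$value <- as.vector(t(grid$values)) # row i = y, col j = x
  dark <- identical(theme, "th3")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = if (dark) "inferno" else "viridis",
                                  na.value = if (dark) "black" else "white",
                                  limits = c(0, 1), name = "density") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    (if (dark) ggplot2::theme_void() else ggplot2::theme_minimal())
  if (!is.null(marks)) {
    marks <- as_gene_list(marks, "marks")
    chk <- validate_membership(g, marks)
    if (!chk$ok) {
      stop("mark genes not in graph: ", paste(chk$missing, collapse = ", "))
    }
    idx <- match(marks$ids, vertex_names(g))
    md <- data.frame(name = marks$ids, x = g$layout[idx, 1],
                     y = g$layout[idx, 2])
    p <- p +
      ggplot2::geom_point(data = md, ggplot2::aes(x = .data$x, y = .data$y),
                          inherit.aes = FALSE, color = mark_color,
                          size = mark_size) +
      ggplot2::geom_text(data = md,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      label = .data$name),
                         inherit.aes = FALSE, color = mark_color,
                         vjust = -1, size = 3)
  }
  .render(out_path, 6.5, 6, p)
}

#' Plot observed vs null path distances
#'
#' Histogram plus kernel-density curve (Silverman bandwidth) of the
#' permutation null, a marker at the observed statistic, the left-tail
#' rejection region shaded up to [rejection_threshold()], and the p-value and
#' z-score annotated. With `scale = "zscore"` the x-axis is relabeled in null
#' standard-deviation units, so the observed marker sits at the result's
#' z-score — useful when comparing tests with different list sizes.
#'
#' @param result a `path_distance_result` from [path_distance_test()].
#' @param out_path output file (`.png`, `.pdf` or `.svg`).
#' @param alpha significance level for the rejection region (default 0.05).
#' @param scale `"hops"` (raw statistic) or `"zscore"`.
#' @param title plot title.
#' @return Invisibly, `out_path`.
#' @export
plot_path_distances <- function(result, out_path, alpha = 0.05,
                                scale = c("hops", "zscore"),
                                title = "Path distances") {
  stopifnot(inherits(result, "path_distance_result"))
  scale <- match.arg(scale)
  null <- result$null_sample[is.finite(result$null_sample)]
  obs <- result$observed
  xlab <- "average path distance to first nearest neighbors (hops)"
  if (scale == "zscore") {
    mu <- mean(null)
    s <- stats::sd(null)
    if (is.na(s) || s == 0) stop("z-score axis undefined: degenerate null")
    null <- (null - mu) / s
    obs <- (obs - mu) / s
    xlab <- "path distance (z-score)"
  }
  thr <- rejection_threshold(null, alpha)
  dens <- stats::density(null, bw = "nrd0") # Silverman's rule
  dd <- data.frame(x = dens$x, y = dens$y)
  shade <- dd[dd$x <= thr, , drop = FALSE]
  lab <- sprintf("observed = %.3g\np = %.3g\nz = %.3g",
                 obs, result$p_value,
                 if (is.na(result$z_score)) NA else result$z_score)
  p <- ggplot2::ggplot(data.frame(x = null), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey85", color = "grey70") +
    ggplot2::geom_area(data = shade,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, fill = "black", alpha = 0.8) +
    ggplot2::geom_line(data = dd, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = obs, color = "red", linewidth = 0.8) +
    ggplot2::annotate("point", x = obs, y = 0, color = "red", shape = 17,
                      size = 3) +
    ggplot2::annotate("label", x = Inf, y = Inf, hjust = 1.05, vjust = 1.1,
                      label = lab, size = 3) +
    ggplot2::labs(title = title, x = xlab, y = "density") +
    ggplot2::theme_minimal()
  .render(out_path, 6.5, 4.5, p)
}
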