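#' Construct a pathway-space graph
#'
#' A `pathway_graph` bundles an undirected, simple gene-interaction graph with
#' a fixed 2D layout and a per-vertex signal vector. Vertices are identified
#' by unique gene symbols; the layout is normalized on construction by an
#' aspect-preserving affine map into the unit square, so that projection and
#' silhouette radii can be expressed as scale-free fractions of the unit-square
#' diagonal.
#'
#' @param graph an [igraph::igraph] object with a `name` vertex attribute.
#'   Directions, self-loops and duplicate edges are dropped (with a message
#'   reporting how many).
#' @param layout numeric matrix with one row per vertex and columns `x`, `y`,
#'   in the vertex order of `graph`, or `NULL` to use the `x`/`y` vertex
#'   attributes of `graph`.
#' @param signal numeric vector with one value per vertex (default all zero).
#' @param normalize logical; normalize the layout into the unit square
#'   (default `TRUE`).
#'
#' @return An object of class `pathway_graph` with elements `graph` (simple
#'   undirected igraph), `layout` (n x 2 matrix, rownames = vertex names) and
#'   `signal` (named numeric vector).
#'
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C)
#' pg <- pathway_graph(g, layout = cbind(x = c(0, 1, 2), y = c(0, 1, 0)))
#' n_vertices(pg)
#' @export
pathway_graph <- function(graph, layout = NULL, signal = NULL, normalize = TRUE) {
  stopifnot(igraph::is_igraph(graph))
  nm <- igraph::V(graph)$name
  if (is.null(nm)) {
    stop("graph vertices must carry a 'name' attribute (gene symbols)")
  }
  bad <- nm[is.na(nm) | !nzchar(nm)]
  if (length(bad) > 0) {
    stop("empty or missing vertex names are not allowed")
  }
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) {
    stop("duplicate vertex names: ", paste(dup, collapse = ", "))
  }
  if (igraph::is_directed(graph)) {
    graph <- igraph::as_undirected(graph, mode = "collapse")
  }
  n_loop <- sum(igraph::which_loop(graph))
  n_multi <- sum(igraph::which_multiple(graph))
  if (n_loop > 0 || n_multi > 0) {
    message(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loop, n_multi))
    graph <- igraph::simplify(graph, remove.multiple = TRUE,
                              remove.loops = TRUE)
  }
  n <- igraph::vcount(graph)
  if (is.null(layout)) {
    x <- igraph::vertex_attr(graph, "x")
    y <- igraph::vertex_attr(graph, "y")
    if (is.null(x) || is.null(y)) {
      stop("no layout supplied and graph lacks 'x'/'y' vertex attributes")
    }
    layout <- cbind(x = as.numeric(x), y = as.numeric(y))
  }
  layout <- as.matrix(layout)
  if (nrow(layout) != n || ncol(layout) != 2) {
    stop("layout must be an n x 2 matrix matching the vertex count")
  }
  if (!all(is.finite(layout))) {
    stop("layout coordinates must all be finite")
  }
  storage.mode(layout) <- "double"
  colnames(layout) <- c("x", "y")
  rownames(layout) <- nm
  if (normalize) layout <- normalize_layout(layout)
  if (is.null(signal)) {
    sig_attr <- igraph::vertex_attr(graph, "signal")
    signal <- if (is.null(sig_attr)) rep(0, n) else as.numeric(sig_attr)
  }
  if (length(signal) != n || !is.numeric(signal)) {
    stop("signal must be a numeric vector with one value per vertex")
  }
  signal <- stats::setNames(as.numeric(signal), nm)
  structure(list(graph = graph, layout = layout, signal = signal),
            class = "pathway_graph")
}

#' Normalize a 2D layout into the unit square
#'
#' Applies an aspect-preserving affine map: both axes are scaled by the same
#' factor (the reciprocal of the larger coordinate range) and the shorter axis
#' is centered, so the point cloud fills `[0, 1] x [0, 1]` without distortion.
#' A degenerate (single-point) layout maps to the center.
#'
#' @param layout numeric matrix with columns x, y.
#' @return A matrix of the same shape with coordinates in `[0, 1]`.
#' @export
normalize_layout <- function(layout) {
  layout <- as.matrix(layout)
  rx <- range(layout[, 1])
  ry <- range(layout[, 2])
  span <- max(diff(rx), diff(ry))
  if (span <= 0) {
    out <- matrix(0.5, nrow = nrow(layout), ncol = 2,
                  dimnames = dimnames(layout))
    return(out)
  }
  x <- (layout[, 1] - rx[1]) / span
  y <- (layout[, 2] - ry[1]) / span
  # center the shorter axis within the unit square
  x <- x + (1 - diff(rx) / span) / 2
  y <- y + (1 - diff(ry) / span) / 2
  out <- cbind(x = x, y = y)
  rownames(out) <- rownames(layout)
  out
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph: %d vertices, %d edges\n",
              n_vertices(x), igraph::ecount(x$graph)))
  ns <- sum(x$signal != 0)
  cat(sprintf("  signal: %d non-zero vertices\n", ns))
  cat("  layout: unit square, vertices ",
      paste(utils::head(vertex_names(x), 4), collapse = ", "),
      if (n_vertices(x) > 4) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Vertex names of a pathway graph
#' @param g a `pathway_graph`.
#' @return Character vector of gene symbols.
#' @export
vertex_names <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  igraph::V(g$graph)$name
}

#' Number of vertices of a pathway graph
#' @param g a `pathway_graph`.
#' @return Integer vertex count.
#' @export
n_vertices <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  igraph::vcount(g$graph)
}

#' Load a pathway-space graph from a file
#'
#' Reads either a GraphML file carrying `name`, `x` and `y` vertex attributes,
#' or an edge-list TSV (two columns of vertex names, with or without a header)
#' paired with a layout TSV (columns `name`, `x`, `y`). Vertices present in
#' the layout but absent from the edge list are kept as isolated vertices;
#' vertices with edges but no layout coordinates are an error. Self-loops and
#' duplicate edges are dropped with a message.
#'
#' @param path path to the GraphML file, or to the edge-list TSV.
#' @param format `"graphml"` or `"edgelist"`.
#' @param layout_path for `format = "edgelist"`, path to the layout TSV.
#' @return A [pathway_graph()].
#' @export
load_graph <- function(path, format = c("graphml", "edgelist"),
                       layout_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(pathway_graph(g))
  }
  if (is.null(layout_path)) {
    stop("edgelist format requires 'layout_path' (TSV with name, x, y)")
  }
  if (!file.exists(layout_path)) stop("file not found: ", layout_path)
  el <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character",
                          col.names = c("from", "to"))
  # tolerate a header row
  if (nrow(el) > 0 && tolower(el$from[1]) %in% c("from", "source", "v1")) {
    el <- el[-1, , drop = FALSE]
  }
  lay <- utils::read.delim(layout_path, header = TRUE, sep = "\t")
  req <- c("name", "x", "y")
  if (!all(req %in% names(lay))) {
    stop("layout TSV must have columns: name, x, y")
  }
  lay$name <- as.character(lay$name)
  edge_v <- unique(c(el$from, el$to))
  missing_layout <- setdiff(edge_v, lay$name)
  if (length(missing_layout) > 0) {
    stop("vertices in edge list without layout coordinates: ",
         paste(missing_layout, collapse = ", "))
  }
  dupn <- unique(lay$name[duplicated(lay$name)])
  if (length(dupn) > 0) {
    stop("duplicate vertex names in layout: ", paste(dupn, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = lay["name"])
  idx <- match(igraph::V(g)$name, lay$name)
  pathway_graph(g, layout = cbind(x = lay$x[idx], y = lay$y[idx]))
}

#' Write a pathway-space graph to GraphML
#'
#' Stores vertex names, the (normalized) layout and the signal as vertex
#' attributes, so that [load_graph()] round-trips the object.
#'
#' @param g a `pathway_graph`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_graph_file <- function(g, path) {
  stopifnot(inherits(g, "pathway_graph"))
  gr <- g$graph
  igraph::V(gr)$x <- g$layout[, 1]
  igraph::V(gr)$y <- g$layout[, 2]
  igraph::V(gr)$signal <- unname(g$signal)
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}

#' Top hub genes by degree centrality
#'
#' Returns the `k` vertices of highest degree as a gene list. Ties are broken
#' by lexicographic vertex name so the result is deterministic.
#'
#' @param g a `pathway_graph`.
#' @param k number of hubs, `1 <= k <= n_vertices(g)`.
#' @param label label for the returned [gene_list()] (default `"hubs"`).
#' @return A [gene_list()] of `k` gene symbols, degree non-increasing.
#' @examples
#' pg <- toy_fig1()$graph
#' top_hubs(pg, 3)
#' @export
top_hubs <- function(g, k, label = "hubs") {
  stopifnot(inherits(g, "pathway_graph"))
  n <- n_vertices(g)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n) {
    stop("k must be a single integer in [1, ", n, "]")
  }
  deg <- igraph::degree(g$graph)
  ord <- order(-deg, names(deg), method = "radix")
  gene_list(names(deg)[ord[seq_len(k)]], label = label)
}

#' Assign signal values from a gene list
#'
#' Resets every vertex to `background`, then sets `value` on the members of
#' `list`. The background reset makes repeated calls independent: signal never
#' accumulates across lists.
#'
#' @param g a `pathway_graph`.
#' @param list a [gene_list()]; every id must be a vertex of `g`.
#' @param value signal assigned to list members (default 1).
#' @param background signal assigned to all other vertices (default 0).
#' @return The updated `pathway_graph`.
#' @export
set_signal <- function(g, list, value = 1, background = 0) {
  stopifnot(inherits(g, "pathway_graph"))
  list <- as_gene_list(list)
  chk <- validate_membership(g, list)
  if (!chk$ok) {
    stop("gene list '", list$label, "' has ids not in the graph: ",
         paste(chk$missing, collapse = ", "))
  }
  sig <- stats::setNames(rep(as.numeric(background), n_vertices(g)),
                         vertex_names(g))
  sig[list$ids] <- as.numeric(value)
  g$signal <- sig
  g
}
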