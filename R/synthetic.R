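#' Schematic toy pathway space with two gene lists
#'
#' A small hand-encoded graph illustrating the proximity question: how many
#' steps does it take to walk from one gene list to the other? List `L1` has
#' four genes and `L2` has two; three of the `L1` genes sit one hop from
#' their nearest `L2` gene and the fourth sits two hops away, so the average
#' path distance to first nearest neighbors from `L1` to `L2` is
#' `(1 + 1 + 1 + 2) / 4 = 1.25`. Background vertices pad the space so the
#' layout and silhouette look like a miniature pathway landscape.
#'
#' @return A list with `graph` (a [pathway_graph()]), `L1` and `L2`
#'   ([gene_list()] objects).
#' @examples
#' toy <- toy_fig1()
#' D <- shortest_path_matrix(toy$graph)
#' nn_path_distance(D, toy$L1, toy$L2)
#' @export
toy_fig1 <- function() {
  edges <- c(
    "A", "B", "B", "C", "C", "D",    # L1 chain
    "M", "N",                         # L2 edge
    "A", "M", "B", "M", "C", "N",    # one-hop bridges
    "D", "K", "K", "N",              # two-hop route for D
    "E", "A", "F", "B", "G", "M",    # background periphery
    "H", "N", "I", "K", "J", "I"
  )
  g <- igraph::make_graph(edges, directed = FALSE)
  lay <- rbind(
    A = c(0.15, 0.70), B = c(0.20, 0.52), C = c(0.28, 0.38),
    D = c(0.22, 0.20), M = c(0.60, 0.70), N = c(0.66, 0.50),
    K = c(0.45, 0.15), E = c(0.05, 0.82), F = c(0.06, 0.45),
    G = c(0.72, 0.84), H = c(0.82, 0.45), I = c(0.55, 0.04),
    J = c(0.68, 0.06)
  )
  lay <- lay[igraph::V(g)$name, , drop = FALSE]
  colnames(lay) <- c("x", "y")
  pg <- pathway_graph(g, layout = lay)
  list(graph = pg,
       L1 = gene_list(c("A", "B", "C", "D"), label = "L1"),
       L2 = gene_list(c("M", "N"), label = "L2"))
}

# run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators are pure functions of their inputs
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Random synthetic pathway space
#'
#' Generates a connected, scale-free-like interaction graph by preferential
#' attachment (each new vertex attaches to `attach_edges` existing vertices
#' with probability proportional to degree), names the vertices
#' `G0001, G0002, ...`, and lays it out with a force-directed
#' (Fruchterman-Reingold) embedding normalized to the unit square. The
#' heavy-tailed degree distribution and hub structure mimic curated
#' pathway-interaction networks at small scale. Deterministic given `seed`.
#'
#' @param n_vertices number of vertices (>= 3).
#' @param attach_edges edges added per new vertex (>= 1).
#' @param seed integer seed.
#' @return A [pathway_graph()].
#' @examples
#' g <- random_space(50, seed = 7)
#' n_vertices(g)
#' @export
random_space <- function(n_vertices, attach_edges = 2, seed = 1) {
  if (n_vertices < 3) stop("n_vertices must be >= 3")
  if (attach_edges < 1) stop("attach_edges must be >= 1")
  .with_seed(seed, {
    g <- igraph::sample_pa(n_vertices, m = attach_edges, directed = FALSE)
    igraph::V(g)$name <- sprintf("G%04d", seq_len(n_vertices))
    lay <- igraph::layout_with_fr(g)
    pathway_graph(g, layout = lay)
  })
}

#' Sample a gene list from a pathway space
#'
#' `mode = "uniform"` draws a without-replacement uniform vertex sample — the
#' null model's notion of a random gene list. `mode = "neighborhood"` plants
#' proximity: it picks a center (random unless given), ranks all vertices by
#' hop distance from the center with random tie-breaking, and keeps the
#' nearest `size` — a BFS ball truncated to the requested size. Two
#' neighborhood samples around the same center are therefore close in the
#' graph but not identical.
#'
#' @param g a [pathway_graph()].
#' @param size list size, `1 <= size <= n_vertices(g)`.
#' @param mode `"uniform"` or `"neighborhood"`.
#' @param seed integer seed.
#' @param center optional center vertex name for neighborhood mode.
#' @param label label for the returned list.
#' @return A [gene_list()].
#' @export
sample_lists <- function(g, size, mode = c("uniform", "neighborhood"),
                         seed = 1, center = NULL, label = mode[1]) {
  stopifnot(inherits(g, "pathway_graph"))
  mode <- match.arg(mode)
  n <- n_vertices(g)
  if (size < 1 || size > n) stop("size must be in [1, ", n, "]")
  nm <- vertex_names(g)
  ids <- .with_seed(seed, {
    if (mode == "uniform") {
      sample(nm, size)
    } else {
      if (is.null(center)) center <- sample(nm, 1)
      if (!center %in% nm) stop("center '", center, "' is not a vertex")
      d <- as.numeric(igraph::distances(g$graph, v = center,
                                        algorithm = "unweighted"))
      ord <- order(d, sample.int(n), method = "radix")
      nm[ord[seq_len(size)]]
    }
  })
  gene_list(ids, label = label)
}
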