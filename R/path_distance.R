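#' All-pairs shortest-path (hop-count) distance matrix
#'
#' Computes the unweighted shortest-path distance between every pair of
#' vertices: the minimum number of edges on any connecting path (BFS
#' semantics), `Inf` across connected components. This is the vertex-wise
#' distance matrix that the proximity statistic and its permutation null
#' operate on.
#'
#' @param g a [pathway_graph()].
#' @return A symmetric numeric matrix with zero diagonal; dimnames are the
#'   vertex names.
#' @examples
#' D <- shortest_path_matrix(toy_fig1()$graph)
#' D["A", "M"]
#' @export
shortest_path_matrix <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  if (n_vertices(g) == 0) stop("graph has no vertices")
  D <- igraph::distances(g$graph, algorithm = "unweighted")
  dimnames(D) <- list(vertex_names(g), vertex_names(g))
  D
}

#' Write / read a distance matrix as TSV
#'
#' Plain-text interchange: a header row of vertex names, then one row per
#' vertex with the name in the first column. `Inf` round-trips. Generic
#' matrices produced elsewhere can be read back and handed to
#' [path_distance_test()], which only requires labeled rows/columns.
#'
#' @param D a labeled square distance matrix.
#' @param path TSV file path.
#' @return `write_distance_tsv` returns `path` invisibly;
#'   `read_distance_tsv` returns the matrix.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(name = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  D <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(D) <- "double"
  rownames(D) <- as.character(df[[1]])
  D
}

# directed mean of row minima over D[from, to]; infinite minima are excluded
# from the average (their count is reported via attribute)
.nn_directed <- function(D, fi, ti) {
  sub <- D[fi, ti, drop = FALSE]
  mins <- apply(sub, 1L, min)
  finite <- is.finite(mins)
  structure(if (any(finite)) mean(mins[finite]) else NA_real_,
            n_dropped = sum(!finite))
}

#' Nearest-neighbor path distance between two gene lists
#'
#' The proximity statistic: for each gene in `from`, take the minimum
#' hop-count distance to any gene of `to` (its first nearest neighbor in the
#' other list), then average. A gene present in both lists is its own nearest
#' neighbor and contributes 0. Genes whose nearest neighbor is unreachable
#' (`Inf`) are excluded from the average with a message; if every term is
#' infinite the statistic is undefined and an error is raised.
#'
#' `direction = "from_to"` (the default) is the directed mean of minima from
#' `from` into `to`; `"symmetric"` averages the two directed values. The two
#' directed values generally differ.
#'
#' @param D labeled square distance matrix, e.g. from
#'   [shortest_path_matrix()].
#' @param from,to [gene_list()] objects or character vectors; all ids must be
#'   row/column labels of `D`.
#' @param direction `"from_to"` or `"symmetric"`.
#' @return A single non-negative number (average hops).
#' @examples
#' toy <- toy_fig1()
#' D <- shortest_path_matrix(toy$graph)
#' nn_path_distance(D, toy$L1, toy$L2) # 1.25
#' @export
nn_path_distance <- function(D, from, to,
                             direction = c("from_to", "symmetric")) {
  direction <- match.arg(direction)
  from <- as_gene_list(from, "from")
  to <- as_gene_list(to, "to")
  labs <- rownames(D)
  missing <- setdiff(c(from$ids, to$ids), labs)
  if (length(missing) > 0) {
    stop("ids not present in distance matrix: ",
         paste(missing, collapse = ", "))
  }
  fi <- match(from$ids, labs)
  ti <- match(to$ids, labs)
  a <- .nn_directed(D, fi, ti)
  dropped <- attr(a, "n_dropped")
  if (direction == "symmetric") {
    b <- .nn_directed(D, ti, fi)
    dropped <- dropped + attr(b, "n_dropped")
    val <- mean(c(as.numeric(a), as.numeric(b)))
  } else {
    val <- as.numeric(a)
  }
  if (dropped > 0) {
    message(sprintf("excluded %d unreachable gene(s) from the average",
                    dropped))
  }
  if (is.na(val)) stop("all nearest-neighbor distances are infinite")
  val
}

# internal fast path used by the permutation loop: integer indices, no
# validation, no messages
.nn_stat_idx <- function(D, fi, ti, symmetric = FALSE) {
  a <- D[fi, ti, drop = FALSE]
  ma <- apply(a, 1L, min)
  ma <- ma[is.finite(ma)]
  va <- if (length(ma)) mean(ma) else NA_real_
  if (!symmetric) return(va)
  mb <- apply(a, 2L, min) # D symmetric: column minima = reverse direction
  mb <- mb[is.finite(mb)]
  vb <- if (length(mb)) mean(mb) else NA_real_
  mean(c(va, vb))
}

#' Permutation null distribution of the proximity statistic
#'
#' Each replicate draws two independent uniform without-replacement vertex
#' samples of sizes `from_size` and `to_size` from all rows of `D` and records
#' their nearest-neighbor path distance. The draws are not degree-matched:
#' the null asks how close two arbitrary vertex sets of these sizes typically
#' are. Reproducible given `seed`.
#'
#' @param D labeled square distance matrix.
#' @param from_size,to_size list sizes, each in `[1, nrow(D)]`.
#' @param nperm number of replicates.
#' @param seed integer seed driving the whole loop.
#' @param direction `"from_to"` or `"symmetric"`.
#' @return Numeric vector of length `nperm`.
#' @export
null_distribution <- function(D, from_size, to_size, nperm = 1000,
                              seed = 123,
                              direction = c("from_to", "symmetric")) {
  direction <- match.arg(direction)
  n <- nrow(D)
  if (from_size < 1 || to_size < 1 || from_size > n || to_size > n) {
    stop("list sizes must be in [1, ", n, "]")
  }
  if (nperm < 1) stop("nperm must be >= 1")
  symmetric <- direction == "symmetric"
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  vapply(seq_len(nperm), function(i) {
    fi <- sample.int(n, from_size)
    ti <- sample.int(n, to_size)
    .nn_stat_idx(D, fi, ti, symmetric)
  }, numeric(1))
}

#' Permutation test for gene-list proximity in pathway space
#'
#' Tests whether two gene lists are closer in the graph than random vertex
#' lists of the same sizes. The observed statistic is
#' [nn_path_distance()]; the null is [null_distribution()]. Because small
#' distances indicate proximity, the p-value is left-tailed with the add-one
#' correction: `p = (1 + #\{null <= observed\}) / (nperm + 1)`, which is never
#' zero. The z-score `(observed - mean(null)) / sd(null)` makes results
#' comparable across list-size pairs (larger lists sit closer by chance, so
#' raw hop counts are not comparable between differently sized pairs). A
#' degenerate null (zero standard deviation) yields `z_score = NA` while the
#' p-value remains valid.
#'
#' @inheritParams nn_path_distance
#' @inheritParams null_distribution
#' @return An object of class `path_distance_result`: a list with `observed`,
#'   `null_sample`, `p_value`, `z_score`, `nperm`, `seed`, `from_size`,
#'   `to_size`, `direction`, `from_label`, `to_label`.
#' @examples
#' toy <- toy_fig1()
#' D <- shortest_path_matrix(toy$graph)
#' res <- path_distance_test(D, toy$L1, toy$L2, nperm = 99, seed = 1)
#' res$p_value
#' @export
path_distance_test <- function(D, from, to, nperm = 10000, seed = 123,
                               direction = c("from_to", "symmetric")) {
  direction <- match.arg(direction)
  from <- as_gene_list(from, "from")
  to <- as_gene_list(to, "to")
  observed <- nn_path_distance(D, from, to, direction)
  null_sample <- null_distribution(D, length(from$ids), length(to$ids),
                                   nperm = nperm, seed = seed,
                                   direction = direction)
  p_value <- (1 + sum(null_sample <= observed, na.rm = TRUE)) / (nperm + 1)
  s <- stats::sd(null_sample, na.rm = TRUE)
  z_score <- if (is.na(s) || s == 0) NA_real_ else {
    (observed - mean(null_sample, na.rm = TRUE)) / s
  }
  structure(list(observed = observed, null_sample = null_sample,
                 p_value = p_value, z_score = z_score, nperm = nperm,
                 seed = seed, from_size = length(from$ids),
                 to_size = length(to$ids), direction = direction,
                 from_label = from$label, to_label = to$label),
            class = "path_distance_result")
}

#' @export
print.path_distance_result <- function(x, ...) {
  cat("path distance test (", x$direction, ")\n", sep = "")
  cat(sprintf("  %s (n=%d) -> %s (n=%d)\n", x$from_label, x$from_size,
              x$to_label, x$to_size))
  cat(sprintf("  observed: %.4g hops | null mean: %.4g | p = %.4g | z = %.4g\n",
              x$observed, mean(x$null_sample, na.rm = TRUE), x$p_value,
              if (is.na(x$z_score)) NA else x$z_score))
  cat(sprintf("  permutations: %d (seed %d)\n", x$nperm, x$seed))
  invisible(x)
}

#' Serialize a path-distance result to JSON
#'
#' @param x a `path_distance_result`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_result_json <- function(x, path) {
  stopifnot(inherits(x, "path_distance_result"))
  obj <- c(list(schema_version = 1L), unclass(x))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing an overlap strictly greater than `q` between two
#' lists drawn without replacement from a finite universe: `P(X > q)` where
#' `X` is hypergeometric with `m` white balls, `n` black balls and `k` draws.
#' This is the standard one-sided enrichment test for whether two gene lists
#' share more members than chance; a large p-value says the observed overlap
#' is unremarkable.
#'
#' @param q observed overlap count, `0 <= q <= min(m, k)`.
#' @param m size of the first list.
#' @param n universe size minus `m`.
#' @param k size of the second list, `k <= m + n`.
#' @return The upper-tail probability `P(X > q)`.
#' @examples
#' # two 50-gene lists from a 173-gene universe sharing 11 genes
#' hypergeom_upper_tail(q = 11, m = 50, n = 123, k = 50)
#' @export
hypergeom_upper_tail <- function(q, m, n, k) {
  if (m < 1 || n < 1 || k < 1) stop("m, n and k must be positive")
  if (k > m + n) stop("k cannot exceed the universe size m + n")
  if (q < 0 || q > min(m, k)) stop("q must lie in [0, min(m, k)]")
  stats::phyper(q = q, m = m, n = n, k = k, lower.tail = FALSE)
}
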