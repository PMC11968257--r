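# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately avoid the package's own code paths (igraph BFS,
# vectorized minima) so that agreement is evidence, not tautology.

# Floyd-Warshall all-pairs hop distances from the raw edge list
fw_distances <- function(pg) {
  n <- n_vertices(pg)
  nm <- vertex_names(pg)
  d <- matrix(Inf, n, n, dimnames = list(nm, nm))
  diag(d) <- 0
  el <- igraph::as_edgelist(pg$graph, names = FALSE)
  for (r in seq_len(nrow(el))) {
    d[el[r, 1], el[r, 2]] <- 1
    d[el[r, 2], el[r, 1]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# explicit double-loop mean of per-gene minima
nn_oracle <- function(D, from, to, direction = "from_to") {
  dir_mean <- function(a, b) {
    mins <- vapply(a, function(v) {
      best <- Inf
      for (w in b) if (D[v, w] < best) best <- D[v, w]
      best
    }, numeric(1))
    mean(mins[is.finite(mins)])
  }
  if (direction == "from_to") dir_mean(from, to)
  else mean(c(dir_mean(from, to), dir_mean(to, from)))
}

# Erdos-Renyi pathway graph with random layout; may be disconnected
random_pg <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
  pathway_graph(g, layout = cbind(x = runif(n), y = runif(n)))
}

# 3-vertex path A-B-C with a fixed layout
path3 <- function() {
  g <- igraph::make_graph(~ A - B, B - C)
  pathway_graph(g, layout = cbind(x = c(0, 1, 2), y = c(0, 0, 0)))
}
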