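test_that("hop-distance matrix has BFS semantics", {
  D <- shortest_path_matrix(path3())
  expect_equal(D["A", "C"], 2)
  expect_equal(D["A", "B"], 1)
  expect_equal(D["B", "C"], 1)
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))

  # disconnected pairs are infinite
  g2 <- pathway_graph(
    igraph::make_graph(~ A - B) + igraph::vertices("Z"),
    layout = cbind(x = c(0, 1, 2), y = c(0, 0, 0)))
  D2 <- shortest_path_matrix(g2)
  expect_equal(D2["A", "Z"], Inf)
  expect_equal(D2["Z", "B"], Inf)
})

test_that("distance matrix agrees with Floyd-Warshall on random graphs", {
  for (s in 1:12) {
    g <- random_pg(sample(4:12, 1), p = 0.3, seed = s)
    expect_equal(shortest_path_matrix(g), fw_distances(g))
  }
})

test_that("distance matrices are symmetric with zero diagonal and satisfy the triangle inequality", {
  g <- random_pg(10, 0.4, seed = 3)
  D <- shortest_path_matrix(g)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    if (is.finite(D[i, k]) && is.finite(D[k, j])) {
      expect_lte(D[i, j], D[i, k] + D[k, j])
    }
  }
})

test_that("distance matrices round-trip through TSV including Inf", {
  g2 <- pathway_graph(
    igraph::make_graph(~ A - B) + igraph::vertices("Z"),
    layout = cbind(x = c(0, 1, 2), y = c(0, 0, 0)))
  D <- shortest_path_matrix(g2)
  f <- tempfile(fileext = ".tsv")
  write_distance_tsv(D, f)
  expect_equal(read_distance_tsv(f), D)
})

test_that("nearest-neighbor distance matches the double-loop oracle", {
  set.seed(99)
  g <- random_pg(10, 0.35, seed = 42)
  D <- shortest_path_matrix(g)
  nm <- vertex_names(g)
  for (i in 1:25) {
    from <- sample(nm, 3)
    to <- sample(nm, 4)
    for (dir in c("from_to", "symmetric")) {
      expect_equal(
        suppressMessages(nn_path_distance(D, from, to, dir)),
        nn_oracle(D, from, to, dir),
        info = sprintf("seed-rep %d, %s", i, dir))
    }
  }
})

test_that("a list has distance zero to itself and to supersets only", {
  toy <- toy_fig1()
  D <- shortest_path_matrix(toy$graph)
  expect_equal(nn_path_distance(D, toy$L1, toy$L1), 0)
  # from within to: zero; to is superset of from
  expect_equal(nn_path_distance(D, gene_list(c("A", "B")), toy$L1), 0)
  # any from-gene outside to forces a positive statistic on a connected graph
  expect_gt(nn_path_distance(D, gene_list(c("A", "M")), toy$L2), 0)
})

test_that("symmetric direction commutes; from_to need not", {
  toy <- toy_fig1()
  D <- shortest_path_matrix(toy$graph)
  expect_equal(nn_path_distance(D, toy$L1, toy$L2, "symmetric"),
               nn_path_distance(D, toy$L2, toy$L1, "symmetric"))
  # concrete counterexample for the directed variant
  ab <- nn_path_distance(D, toy$L1, toy$L2, "from_to")
  ba <- nn_path_distance(D, toy$L2, toy$L1, "from_to")
  expect_equal(ab, 1.25)
  expect_equal(ba, 1)
  expect_false(ab == ba)
})

test_that("enlarging `to` never increases the directed statistic", {
  g <- random_pg(12, 0.3, seed = 8)
  D <- shortest_path_matrix(g)
  nm <- vertex_names(g)
  set.seed(11)
  for (i in 1:20) {
    from <- sample(nm, 4)
    to <- sample(nm, 3)
    extra <- sample(setdiff(nm, to), 1)
    d1 <- suppressMessages(nn_path_distance(D, from, to))
    d2 <- suppressMessages(nn_path_distance(D, from, c(to, extra)))
    expect_lte(d2, d1)
  }
})

test_that("unreachable genes are excluded from the average, all-unreachable errors", {
  g <- pathway_graph(
    igraph::make_graph(~ A - B, C - D) + igraph::vertices("Z"),
    layout = cbind(x = c(0, 1, 2, 3, 4), y = rep(0, 5)))
  D <- shortest_path_matrix(g)
  # A reaches B (1 hop); C is in the other component -> dropped
  expect_message(
    val <- nn_path_distance(D, gene_list(c("A", "C")), gene_list("B")),
    "unreachable")
  expect_equal(val, 1)
  expect_error(
    suppressMessages(nn_path_distance(D, gene_list("Z"), gene_list("A"))),
    "infinite")
  expect_error(nn_path_distance(D, gene_list("NOPE"), gene_list("A")),
               "NOPE")
})

test_that("null distribution is reproducible and respects size bounds", {
  g <- random_pg(15, 0.3, seed = 2)
  D <- shortest_path_matrix(g)
  a <- null_distribution(D, 3, 4, nperm = 5, seed = 77)
  b <- null_distribution(D, 3, 4, nperm = 5, seed = 77)
  expect_identical(a, b)
  expect_length(a, 5)
  expect_false(identical(a, null_distribution(D, 3, 4, nperm = 5, seed = 78)))
  # full-size lists coincide with the vertex set -> statistic 0
  expect_equal(null_distribution(D, 15, 15, nperm = 3, seed = 1),
               c(0, 0, 0))
  expect_error(null_distribution(D, 16, 3, nperm = 2, seed = 1), "sizes")
})

test_that("each null replicate equals the oracle on its own sampled lists", {
  g <- pathway_graph(
    igraph::make_full_graph(10) |>
      igraph::set_vertex_attr("name", value = sprintf("K%02d", 1:10)),
    layout = cbind(x = runif(10), y = runif(10)))
  D <- shortest_path_matrix(g)
  null <- null_distribution(D, 2, 2, nperm = 20, seed = 5)
  # replay the generator's draws and check each replicate independently
  set.seed(5)
  nm <- rownames(D)
  for (i in 1:20) {
    fi <- sample.int(10, 2)
    ti <- sample.int(10, 2)
    expect_equal(null[i], nn_oracle(D, nm[fi], nm[ti]))
  }
})

test_that("permutation test follows the add-one p-value and z-score formulas", {
  toy <- toy_fig1()
  D <- shortest_path_matrix(toy$graph)
  res <- path_distance_test(D, toy$L1, toy$L2, nperm = 199, seed = 3)
  expect_s3_class(res, "path_distance_result")
  expect_length(res$null_sample, 199)
  expect_equal(res$p_value,
               (1 + sum(res$null_sample <= res$observed)) / 200)
  expect_equal(res$z_score,
               (res$observed - mean(res$null_sample)) / sd(res$null_sample))
  expect_gte(res$p_value, 1 / 200)
  expect_lte(res$p_value, 1)
  # identical lists: observed 0, p forced by formula
  res0 <- path_distance_test(D, toy$L1, toy$L1, nperm = 99, seed = 3)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p_value, (1 + sum(res0$null_sample <= 0)) / 100)
})

test_that("degenerate null yields NA z-score but a valid p-value", {
  g <- pathway_graph(
    igraph::make_full_graph(5) |>
      igraph::set_vertex_attr("name", value = LETTERS[1:5]),
    layout = cbind(x = runif(5), y = runif(5)))
  D <- shortest_path_matrix(g)
  # full-size lists coincide with the vertex set: the null is constant zero
  all5 <- gene_list(LETTERS[1:5])
  res <- path_distance_test(D, all5, all5, nperm = 50, seed = 9)
  expect_identical(unique(res$null_sample), 0)
  expect_true(is.na(res$z_score))
  expect_equal(res$p_value, 1) # every null value <= observed = 0
})

test_that("the statistic and z-score are invariant under vertex relabeling", {
  g <- random_pg(14, 0.3, seed = 21)
  D <- shortest_path_matrix(g)
  nm <- rownames(D)
  new <- sprintf("Z_%s", nm) # strictly monotone relabeling preserves order
  D2 <- D
  dimnames(D2) <- list(new, new)
  from <- nm[2:5]
  to <- nm[7:10]
  r1 <- path_distance_test(D, from, to, nperm = 99, seed = 4)
  r2 <- path_distance_test(D2, paste0("Z_", from), paste0("Z_", to),
                           nperm = 99, seed = 4)
  expect_equal(r1$observed, r2$observed)
  expect_equal(r1$z_score, r2$z_score)
  expect_identical(r1$null_sample, r2$null_sample)
})

test_that("result JSON serializes all fields with a schema version", {
  toy <- toy_fig1()
  D <- shortest_path_matrix(toy$graph)
  res <- path_distance_test(D, toy$L1, toy$L2, nperm = 19, seed = 2)
  f <- tempfile(fileext = ".json")
  write_result_json(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$schema_version, 1)
  expect_equal(back$observed, res$observed)
  expect_equal(back$p_value, res$p_value)
  expect_length(back$null_sample, 19)
})

test_that("hypergeometric upper tail matches phyper conventions and enumeration", {
  # two 50-gene draws from a 173-gene universe overlapping in 11
  expect_equal(round(hypergeom_upper_tail(11, 50, 123, 50), 2), 0.86)
  # overlap cannot exceed min(m, k)
  expect_equal(hypergeom_upper_tail(5, 5, 10, 7), 0)
  # exhaustive enumeration: universe {w1,w2,b1,b2}, draw 2; P(X = 2) = 1/6
  combos <- combn(4, 2)
  p_two_white <- mean(apply(combos, 2, function(cc) all(cc %in% 1:2)))
  expect_equal(hypergeom_upper_tail(1, 2, 2, 2), p_two_white)
  expect_equal(p_two_white, 1 / 6)
  expect_error(hypergeom_upper_tail(-1, 2, 2, 2), "q must")
  expect_error(hypergeom_upper_tail(1, 2, 2, 5), "universe")
  expect_error(hypergeom_upper_tail(1, 0, 2, 2), "positive")
})
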