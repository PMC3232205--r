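test_that("heap distances on the worked-example fixture match the BFS trace", {
  g <- worked_example_graph()
  dm <- shortest_distances_to_target(g, "26")
  expect_equal(unname(dm$dist[c("26", "21", "18", "10", "1")]),
               c(0, 1, 2, 3, 4))
  expect_equal(unname(dm$dist["26"]), 0)
})

test_that("unreachable nodes carry the infinity sentinel", {
  g <- graph_from_lines("A\tr\tB", "C\tr\tD")
  dm <- shortest_distances_to_target(g, "A")
  expect_equal(unname(dm$dist[c("A", "B")]), c(0, 1))
  expect_true(is.infinite(dm$dist[["C"]]))
  expect_true(is.infinite(dm$dist[["D"]]))
  expect_error(shortest_distances_to_target(g, "Z"), class = "as_data_error")
})

test_that("heap-Dijkstra equals the queue-BFS oracle on random graphs", {
  for (s in 1:25) {
    g <- generate_graph(50, 0.08, seed = s)
    tgt <- g$node_ids[(s %% 50) + 1]
    dm <- shortest_distances_to_target(g, tgt)
    expect_equal(dm$dist, bfs_distances_oracle(g, tgt))
  }
})

test_that("heap-Dijkstra matches BFS in directed mode too", {
  for (s in 1:10) {
    g <- generate_graph(40, 0.08, seed = 100 + s, traversal_mode = "directed")
    tgt <- g$node_ids[5]
    dm <- shortest_distances_to_target(g, tgt)
    expect_equal(dm$dist, bfs_distances_oracle(g, tgt))
  }
})

test_that("bidirectional search returns the worked-example shortest path", {
  g <- worked_example_graph()
  p <- bidirectional_shortest_path(g, "1", "26")
  expect_equal(p$nodes, c("1", "10", "18", "21", "26"))
  expect_equal(p$length, 4L)
})

test_that("bidirectional search handles trivial and disconnected queries", {
  g <- graph_from_lines("A\tr\tB", "C\tr\tD")
  same <- bidirectional_shortest_path(g, "A", "A")
  expect_equal(same$nodes, "A")
  expect_equal(same$length, 0L)
  expect_null(bidirectional_shortest_path(g, "A", "C"))
})

test_that("bidirectional hop length always equals the distance map", {
  for (s in 1:15) {
    g <- generate_graph(40, 0.08, seed = 200 + s)
    src <- g$node_ids[1]; tgt <- g$node_ids[40]
    dm <- shortest_distances_to_target(g, tgt)
    p <- bidirectional_shortest_path(g, src, tgt)
    if (is.infinite(dm$dist[[src]])) {
      expect_null(p)
    } else {
      expect_equal(p$length, as.integer(dm$dist[[src]]))
      # path is edge-valid: every hop carries at least one predicate
      expect_true(all(lengths(p$steps) >= 1))
    }
  }
})

test_that("zero slack returns exactly the shortest-length associations", {
  g <- worked_example_graph()
  dm <- shortest_distances_to_target(g, "26")
  aset <- enumerate_near_shortest(g, "1", "26", dm,
                                  search_config(beta_slack = 0))
  expect_gt(length(aset), 0)
  expect_true(all(vapply(aset$associations, `[[`, integer(1), "length") == 4L))
  expect_equal(aset$L_min, 4L)
})

test_that("near-shortest enumeration equals the exhaustive oracle", {
  for (s in 1:12) {
    g <- generate_graph(30, 0.08, seed = 300 + s)
    src <- g$node_ids[2]; tgt <- g$node_ids[29]
    dm <- shortest_distances_to_target(g, tgt)
    for (beta in c(0, 0.5, 1.0)) {
      aset <- enumerate_near_shortest(g, src, tgt, dm,
                                      search_config(beta, max_length = 8))
      expect_identical(paths_of(aset),
                       admitted_paths_oracle(g, src, tgt, beta, 8))
    }
  }
})

test_that("enumeration contract errors and edge cases behave", {
  g <- worked_example_graph()
  dm_wrong <- shortest_distances_to_target(g, "21")
  expect_error(enumerate_near_shortest(g, "1", "26", dm_wrong,
                                       search_config()),
               class = "as_contract_error")

  dm <- shortest_distances_to_target(g, "26")
  capped <- enumerate_near_shortest(g, "1", "26", dm,
                                    search_config(beta_slack = 0,
                                                  max_length = 3))
  expect_equal(length(capped), 0)

  g2 <- graph_from_lines("A\tr\tB", "C\tr\tD")
  dmA <- shortest_distances_to_target(g2, "A")
  empty <- enumerate_near_shortest(g2, "C", "A", dmA, search_config())
  expect_equal(length(empty), 0)
  expect_true(is.infinite(empty$L_min))

  self <- enumerate_near_shortest(g2, "A", "A", dmA, search_config())
  expect_equal(length(self), 1)
  expect_equal(self$associations[[1]]$nodes, "A")
})

test_that("association sets are nested in the slack parameter", {
  for (s in 1:8) {
    g <- generate_graph(30, 0.1, seed = 400 + s)
    src <- g$node_ids[1]; tgt <- g$node_ids[30]
    dm <- shortest_distances_to_target(g, tgt)
    sets <- lapply(c(0, 0.5, 1.0), function(b)
      paths_of(enumerate_near_shortest(g, src, tgt, dm,
                                       search_config(b, max_length = 8))))
    expect_true(all(sets[[1]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[3]]))
  }
})

test_that("returned associations are simple, edge-valid and within bounds", {
  g <- generate_graph(30, 0.12, seed = 77)
  src <- g$node_ids[3]; tgt <- g$node_ids[27]
  dm <- shortest_distances_to_target(g, tgt)
  aset <- enumerate_near_shortest(g, src, tgt, dm,
                                  search_config(1.0, max_length = 8))
  for (a in aset$associations) {
    expect_false(anyDuplicated(a$nodes) > 0)
    expect_equal(a$length, length(a$nodes) - 1L)
    expect_true(all(lengths(a$steps) >= 1))
    expect_lte(a$length, 8)
  }
})

test_that("length ranking is a stable deterministic total order", {
  g <- graph_from_lines("A\tr\tB", "B\tr\tT", "A\tr\tC", "C\tr\tT",
                        "A\tr\tT")
  dm <- shortest_distances_to_target(g, "T")
  aset <- enumerate_near_shortest(g, "A", "T", dm,
                                  search_config(2, max_length = 4))
  ranked <- rank_by_length(aset)
  lens <- vapply(ranked$associations, `[[`, integer(1), "length")
  expect_equal(lens, sort(lens))
  p <- vapply(ranked$associations, format, character(1))
  expect_equal(p[1], "A~T")
  expect_equal(p[2:3], c("A~B~T", "A~C~T"))  # lexicographic tiebreak
  empty <- rank_by_length(enumerate_near_shortest(
    g, "T", "A", shortest_distances_to_target(g, "A"),
    search_config(0, max_length = 1)))
  expect_equal(length(empty), if (g$traversal_mode == "undirected") 1 else 0)
})

test_that("identical inputs give byte-identical ranked output", {
  run_once <- function() {
    g <- generate_graph(30, 0.1, seed = 11)
    dm <- shortest_distances_to_target(g, g$node_ids[30])
    aset <- rank_by_length(enumerate_near_shortest(
      g, g$node_ids[1], g$node_ids[30], dm, search_config(1, max_length = 8)))
    paste(capture.output(print(as.data.frame(aset))), collapse = "\n")
  }
  expect_identical(run_once(), run_once())
})
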