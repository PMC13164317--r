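test_that("hub graph edges require evidence at the inclusive boundary", {
  cores <- list(
    C1 = interactome("C1", c("H1", "H2"), c(2, 2)),
    C2 = interactome("C2", c("H1", "H2"), c(2, 2)),
    C3 = interactome("C3", c("H1"), 3),
    C4 = interactome("C4", c("H1"), 2)
  )
  hubs <- c("H1", "H2")
  g <- build_hub_graph(hubs, cores, evidence_min = 2)
  expect_setequal(igraph::V(g)$name, c("C1", "C2", "C3", "C4", "H1", "H2"))
  # no H1-H2 record exists: hubs are isolated from each other
  expect_false(igraph::are_adjacent(g, "H1", "H2"))
  expect_true(igraph::are_adjacent(g, "C1", "H1"))
  # evidence 1 records never create edges
  cores$C1 <- interactome("C1", c("H1", "H2"), c(1, 2))
  g2 <- build_hub_graph(hubs, cores, evidence_min = 2)
  expect_false(igraph::are_adjacent(g2, "C1", "H1"))
})

test_that("hub graph edge set matches a brute-force pair scan", {
  withr::local_seed(17)
  spec <- synthetic_spec(seed = 17, n_planted_hubs = 10, n_decoys = 30, n_cores = 6)
  gi <- gen_interactomes(spec)
  tab <- select_hubs(gi$cores, hub_params(spec$k_min, spec$evidence_min))
  g <- build_hub_graph(tab, gi$cores, evidence_min = 2)
  nodes <- igraph::V(g)$name
  want <- character()
  for (cn in names(gi$cores)) {
    i <- gi$cores[[cn]]
    keep <- i$partner %in% nodes & i$evidence >= 2 & cn %in% nodes
    want <- c(want, paste(pmin(cn, i$partner[keep]), pmax(cn, i$partner[keep])))
  }
  e <- igraph::as_data_frame(g, what = "edges")
  got <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(got, unique(want))
})

test_that("MCODE vertex weights equal hand values on canonical graphs", {
  k3 <- graph_from_pairs(named_clique("A", 3))
  expect_equal(unname(mcode_vertex_weight(k3)), rep(2, 3))
  k4 <- graph_from_pairs(named_clique("B", 4))
  expect_equal(unname(mcode_vertex_weight(k4)), rep(3, 4))
  # star S5: center weight 1 * density(star) = 2/(n+1); leaves below degree cutoff
  star <- graph_from_pairs(cbind("HUB", paste0("L", 1:5)))
  w <- mcode_vertex_weight(star)
  expect_equal(w[["HUB"]], 2 / 6)
  expect_equal(unname(w[paste0("L", 1:5)]), rep(0, 5))
  # path P5: interior closed neighborhoods are P3 (k=1, density 2/3)
  path5 <- graph_from_pairs(cbind(paste0("N", 1:4), paste0("N", 2:5)))
  wp <- mcode_vertex_weight(path5)
  expect_equal(unname(wp[c("N2", "N3", "N4")]), rep(2 / 3, 3))
  expect_equal(unname(wp[c("N1", "N5")]), c(0, 0))
  # isolated vertex
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "X"
  expect_equal(unname(mcode_vertex_weight(iso)), 0)
})

test_that("vertex weights are invariant under node relabeling", {
  withr::local_seed(4)
  g <- igraph::sample_gnp(25, 0.2)
  igraph::V(g)$name <- sprintf("V%02d", 1:25)
  w1 <- mcode_vertex_weight(g)
  perm <- sample(25)
  g2 <- igraph::permute(g, perm)
  w2 <- mcode_vertex_weight(g2)
  expect_equal(w2[names(w1)], w1)
})

test_that("the K5+K4 bridge graph resolves into exactly its two cliques", {
  el <- rbind(named_clique("A", 5), named_clique("B", 4), c("A5", "B1"))
  g <- graph_from_pairs(el)
  cx <- mcode_find_complexes(g)
  expect_equal(nrow(cx), 2L)
  expect_equal(cx$members[[1]], paste0("A", 1:5))
  expect_equal(cx$members[[2]], paste0("B", 1:4))
  expect_equal(cx$score, c(5, 4)) # density 1 x size
})

test_that("a path graph yields no complexes (2-core filter)", {
  p10 <- graph_from_pairs(cbind(paste0("N", 1:9), paste0("N", 2:10)))
  expect_equal(nrow(mcode_find_complexes(p10)), 0L)
})

test_that("empty graphs yield empty complex lists", {
  g0 <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(nrow(mcode_find_complexes(g0)), 0L)
})

test_that("well-separated planted blocks are recovered", {
  # blocks differing by >20% in MCODE weight separate cleanly
  spec <- synthetic_spec(
    seed = 3, cluster_sizes = c(20L, 10L), p_in = 1.0, p_out = 0.02
  )
  cg <- gen_cluster_graph(spec)
  cx <- mcode_find_complexes(cg$graph)
  jac <- block_jaccards(cx, cg$membership)
  expect_gte(min(jac), 0.8)
})

test_that("returned complexes satisfy their own invariants when re-verified", {
  spec <- synthetic_spec(seed = 7)
  cg <- gen_cluster_graph(spec)
  cx <- mcode_find_complexes(cg$graph)
  expect_gt(nrow(cx), 0L)
  for (i in seq_len(nrow(cx))) {
    sub <- igraph::induced_subgraph(cg$graph, cx$members[[i]])
    expect_true(igraph::is_connected(sub))
    expect_gte(max(igraph::coreness(sub)), 2L)
    expect_true(cx$seed[[i]] %in% cx$members[[i]])
    dens <- 2 * igraph::ecount(sub) /
      (igraph::vcount(sub) * (igraph::vcount(sub) - 1))
    expect_equal(cx$score[[i]], dens * cx$size[[i]])
  }
  # membership is disjoint pre-fluff
  expect_equal(anyDuplicated(unlist(cx$members)), 0L)
  # determinism: identical input, identical ordered output
  expect_identical(cx, mcode_find_complexes(cg$graph))
})

test_that("haircut and fluff post-processing honor their contracts", {
  el <- rbind(named_clique("A", 5), named_clique("B", 4), c("A5", "B1"))
  g <- graph_from_pairs(el)
  cx_h <- mcode_find_complexes(g, mcode_params(haircut = TRUE))
  for (m in cx_h$members) {
    sub <- igraph::induced_subgraph(g, m)
    expect_true(all(igraph::degree(sub) >= 2))
  }
  cx_f <- mcode_find_complexes(g, mcode_params(fluff = TRUE))
  expect_gte(nrow(cx_f), 2L)
  for (i in seq_len(nrow(cx_f))) {
    expect_true(all(cx_h$members[[i]] %in% cx_f$members[[i]]))
  }
})

test_that("topology metrics match closed forms on tiny graphs", {
  k3 <- graph_from_pairs(named_clique("A", 3))
  t3 <- topology_summary(k3, rewires = 0)
  expect_equal(t3$avg_clustering, 1)
  expect_equal(t3$char_path_length, 1)
  p3 <- graph_from_pairs(cbind(c("N1", "N2"), c("N2", "N3")))
  expect_equal(topology_summary(p3, rewires = 0)$avg_clustering, 0)
  expect_true(is.na(topology_summary(p3, rewires = 5)$sigma)) # < 4 nodes
})

test_that("small-world graphs score sigma above one against rewired nulls", {
  sigmas <- vapply(1:20, function(s) {
    g <- withr::with_seed(1000 + s, igraph::sample_smallworld(1, 50, 3, 0.1))
    igraph::V(g)$name <- sprintf("W%02d", 1:50)
    g <- igraph::simplify(g)
    topology_summary(g, rewires = 10, seed = s)$sigma
  }, numeric(1))
  expect_gt(mean(sigmas, na.rm = TRUE), 1)
  expect_gte(mean(sigmas > 1, na.rm = TRUE), 0.9)
})
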