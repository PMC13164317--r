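small_spec <- function(seed = 5) {
  synthetic_spec(
    seed = seed, n_planted_hubs = 10, n_decoys = 40, n_cores = 6,
    n_terms = 20, query_size = 15, n_library_genes = 120,
    track_length_range = c(60L, 120L)
  )
}

test_that("generators are pure functions of (spec, seed)", {
  spec <- small_spec()
  expect_equal(gen_interactomes(spec), gen_interactomes(spec))
  g1 <- gen_cluster_graph(spec)
  g2 <- gen_cluster_graph(spec)
  expect_true(igraph::identical_graphs(g1$graph, g2$graph))
  expect_equal(
    gen_tracks_and_scores(spec, c("P1", "P2")),
    gen_tracks_and_scores(spec, c("P1", "P2"))
  )
  # and they do not disturb the caller's RNG stream
  set.seed(1)
  before <- stats::runif(1)
  set.seed(1)
  invisible(gen_interactomes(spec))
  expect_equal(stats::runif(1), before)
})

test_that("simulated input bundles are byte-identical across reruns", {
  spec <- small_spec()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(simulate_inputs(spec, d1))
  suppressMessages(simulate_inputs(spec, d2))
  expect_identical(file_digests(d1), file_digests(d2))
})

test_that("planted hubs qualify and decoys violate the rule they are labeled with", {
  spec <- small_spec(seed = 23)
  gi <- gen_interactomes(spec)
  filtered <- lapply(gi$cores, filter_by_evidence, spec$evidence_min)
  qual_count <- function(p) {
    sum(vapply(filtered, function(f) p %in% members(f), logical(1)))
  }
  for (h in gi$ledger$planted_hubs) {
    expect_gte(qual_count(h), spec$k_min)
  }
  for (i in seq_len(nrow(gi$ledger$decoys))) {
    expect_lt(qual_count(gi$ledger$decoys$protein[[i]]), spec$k_min)
  }
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(k_min = 8, n_cores = 4), class = "nbhub_config_error")
  expect_error(synthetic_spec(evidence_max = 1, evidence_min = 2),
    class = "nbhub_config_error"
  )
})

test_that("a fully planted term attains the minimum possible p-value", {
  spec <- synthetic_spec(seed = 40, effect_size = 1, query_size = 12)
  gl <- gen_geneset_library(spec)
  res <- enrich(gl$query, gl$library, top = Inf)
  planted <- res[res$term == gl$planted_term, ]
  expect_equal(planted$k, planted$n) # query fully contained
  expect_equal(res$term[[1]], gl$planted_term)
})

test_that("null library specs plant nothing", {
  spec <- synthetic_spec(seed = 41, effect_size = 0)
  gl <- gen_geneset_library(spec)
  expect_true(is.na(gl$planted_term))
  expect_false("T_PLANTED" %in% names(gl$library$terms))
})

test_that("degenerate cluster specs are handled without crashing", {
  # p_in == p_out: no structure; just a valid (possibly empty) result
  flat <- synthetic_spec(seed = 2, cluster_sizes = c(8L, 8L), p_in = 0.1, p_out = 0.1)
  expect_no_error(mcode_find_complexes(gen_cluster_graph(flat)$graph))
  # a perfect triangle block is recovered exactly
  tri <- synthetic_spec(seed = 2, cluster_sizes = 3L, p_in = 1, p_out = 0)
  cg <- gen_cluster_graph(tri)
  cx <- mcode_find_complexes(cg$graph)
  expect_equal(nrow(cx), 1L)
  expect_setequal(cx$members[[1]], cg$membership$node)
})

test_that("ledger labels can be re-derived from the emitted files", {
  spec <- small_spec(seed = 29)
  dir <- withr::local_tempdir()
  sim <- suppressMessages(simulate_inputs(spec, dir))
  scores <- read_score_table(sim$paths$scores)
  tracks <- read_residue_tracks(sim$paths$tracks)
  ptm <- read_ptm_table(sim$paths$ptm)
  seqs <- read_fasta(sim$paths$sequences)
  ann <- annotate_hubs(
    sim$ledger$planted_hubs,
    scores = scores, tracks = tracks, ptm = ptm, sequences = seqs,
    min_region_length = spec$min_region_length
  )
  led <- sim$ledger$annotation_labels
  led <- led[match(ann$protein, led$protein), ]
  expect_equal(ann$combined_label, led$combined_label)
  expect_equal(ann$role_label, led$role_label)
  expect_equal(ann$disorder_class, led$disorder_class)
  expect_identical(ann$sumo, led$sumo)
  expect_identical(ann$ubiquitin, led$ubiquitin)
  # hub rule re-derived from the files reproduces the planted set
  cores <- purrr::imap(
    sim$paths$cores, function(p, nm) read_interaction_table(p, nm)
  )
  tab <- select_hubs(cores, hub_params(spec$k_min, spec$evidence_min))
  expect_setequal(hub_proteins(tab), sim$ledger$planted_hubs)
})
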