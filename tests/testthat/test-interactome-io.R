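test_that("evidence counts distinct (publication, system) records per pair", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_tab3(
    path,
    a = c("USP7", "MDM2", "USP7"),
    b = c("MDM2", "USP7", "MDM2"),
    system = c("Two-hybrid", "AP-MS", "Two-hybrid"),
    publication = c("pub1", "pub2", "pub1")
  )
  i <- read_interaction_table(path, "USP7")
  expect_equal(i$partner, "MDM2")
  expect_equal(i$evidence, 2L) # duplicate (pub1, Two-hybrid) not recounted
})

test_that("header-only tables and absent focal proteins yield empty interactomes", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_tab3(path, character(), character(), character(), character())
  expect_warning(i <- read_interaction_table(path, "USP7"), "absent")
  expect_equal(nrow(i), 0L)
  expect_s3_class(i, "nb_interactome")
})

test_that("self-interactions are dropped", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_tab3(path, "USP7", "USP7", "Two-hybrid", "pub1")
  i <- read_interaction_table(path, "USP7")
  expect_equal(nrow(i), 0L)
  expect_s3_class(i, "nb_interactome")
})

test_that("missing required columns raise a format error naming the column", {
  path <- withr::local_tempfile(fileext = ".txt")
  readr::write_tsv(
    tibble::tibble(`Official Symbol Interactor A` = "USP7", x = "y"),
    path, progress = FALSE
  )
  expect_error(
    read_interaction_table(path, "USP7"),
    "experimental system", class = "nbhub_format_error"
  )
})

test_that("taxon filtering drops rows with either organism outside the filter", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_tab3(
    path,
    a = c("USP7", "USP7"), b = c("MDM2", "TP53"),
    system = c("AP-MS", "AP-MS"), publication = c("p1", "p2"),
    org_a = c("9606", "9606"), org_b = c("9606", "10090")
  )
  i <- read_interaction_table(path, "USP7", taxon_filter = 9606)
  expect_equal(i$partner, "MDM2")
  i_all <- read_interaction_table(path, "USP7")
  expect_equal(i_all$partner, c("MDM2", "TP53"))
})

test_that("evidence counting is invariant to row order", {
  withr::local_seed(11)
  a <- rep("USP7", 30)
  b <- sample(c("MDM2", "TP53", "DAXX"), 30, replace = TRUE)
  sys <- sample(c("Y2H", "AP-MS"), 30, replace = TRUE)
  pub <- sample(paste0("pub", 1:6), 30, replace = TRUE)
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_tab3(p1, a, b, sys, pub)
  perm <- sample(30)
  write_tab3(p2, a[perm], b[perm], sys[perm], pub[perm])
  expect_equal(
    read_interaction_table(p1, "USP7"),
    read_interaction_table(p2, "USP7")
  )
})

test_that("interactome snapshots round-trip through the TAB3 dialect", {
  i <- interactome("PML", c("SUMO1", "DAXX", "UBC9"), c(3, 1, 2))
  path <- withr::local_tempfile(fileext = ".txt")
  write_interaction_table(i, path)
  expect_equal(read_interaction_table(path, "PML"), i)
})

test_that("gene lists normalize case, deduplicate and skip comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#comment", "tp53", "TP53", "PML"), path)
  ps <- suppressMessages(read_protein_list(path))
  expect_setequal(members(ps), c("TP53", "PML"))
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), empty)
  expect_warning(suppressMessages(read_protein_list(empty)), "empty")
})

test_that("GMT parsing builds terms and a union universe", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "T1\tdesc\tA\tB",
    "T2\tdesc\tB\tC\tD",
    "T3\tdesc\tE\tF\tG\tH"
  ), path)
  lib <- read_gmt(path)
  expect_equal(lib$terms$T1, c("A", "B"))
  expect_equal(length(lib$universe), 8L) # B shared between T1 and T2
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tA", "T2\tonlydesc"), bad)
  expect_error(read_gmt(bad), "line 2", class = "nbhub_format_error")
})

test_that("score and track readers enforce the [0,1] range", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein\tpredictor\tscore", "P1\tfuzdrop\t0.7"), p)
  st <- read_score_table(p)
  expect_equal(st$score, 0.7)
  writeLines(c("protein\tpredictor\tscore", "P1\tfuzdrop\t1.2"), p)
  expect_error(read_score_table(p), "P1.*fuzdrop", class = "nbhub_range_error")
  writeLines(c("protein\tpredictor\tscore", "P1\tfuzdrop\t-0.1"), p)
  expect_error(read_score_table(p), class = "nbhub_range_error")

  tr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein\tpredictor\tscores", "P1\tdisorder\t0.1,0.9"), tr)
  tt <- read_residue_tracks(tr)
  expect_length(tt$scores[[1]], 2L)
  writeLines(c("protein\tpredictor\tscores", "P1\tdisorder\t0.1,1.9"), tr)
  expect_error(read_residue_tracks(tr), class = "nbhub_range_error")
})

test_that("PTM flags are tri-state and unknown is preserved", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protein\tsumo\tubiquitin",
    "P1\ttrue\tfalse",
    "P2\tunknown\ttrue"
  ), p)
  ptm <- read_ptm_table(p)
  expect_identical(ptm$sumo, c(TRUE, NA))
  expect_identical(ptm$ubiquitin, c(FALSE, TRUE))
})

test_that("FASTA sequences round-trip", {
  df <- tibble::tibble(protein = c("P1", "P2"), sequence = c("ACDE", "GGGG"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(df, path)
  expect_equal(read_fasta(path), df)
})

test_that("GraphML output re-reads to identical node and edge sets", {
  el <- rbind(named_clique("A", 4), c("A1", "B1"))
  g <- graph_from_pairs(el)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graph_outputs(g, graphml_path = path)
  g2 <- read_graphml(path)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  edge_key <- function(gr) {
    e <- igraph::as_data_frame(gr, what = "edges")
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  expect_equal(edge_key(g2), edge_key(g))
})
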