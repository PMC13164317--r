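# Independent oracles and small fixture builders used across the suite.

# Hypergeometric upper tail by direct closed-form summation of
# C(K,i) C(N-K, n-i) / C(N, n) over i = k..min(n,K). Independent of the
# log-space implementation under test.
hyper_tail_oracle <- function(k, n, K, N) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Hand step-up BH: sort ascending, multiply by m/rank, enforce
# monotonicity from the largest down, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Tab-delimited interaction snapshot from explicit records.
write_tab3 <- function(path, a, b, system, publication,
                       org_a = NULL, org_b = NULL) {
  df <- tibble::tibble(
    `Official Symbol Interactor A` = a,
    `Official Symbol Interactor B` = b,
    `Experimental System` = system,
    `Publication Source` = publication
  )
  if (!is.null(org_a)) df$`Organism ID Interactor A` <- org_a
  if (!is.null(org_b)) df$`Organism ID Interactor B` <- org_b
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Named clique graph helpers for MCODE tests.
named_clique <- function(prefix, n) {
  t(utils::combn(paste0(prefix, seq_len(n)), 2))
}

graph_from_pairs <- function(el) {
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# Best Jaccard between each planted block and any found complex.
block_jaccards <- function(complexes, membership) {
  blocks <- split(membership$node, membership$block)
  vapply(blocks, function(bl) {
    if (nrow(complexes) == 0L) return(0)
    max(vapply(complexes$members, function(m) {
      length(intersect(m, bl)) / length(union(m, bl))
    }, numeric(1)))
  }, numeric(1))
}

random_symbols <- function(n, pool = 200) {
  sample(sprintf("P%04d", seq_len(pool)), n)
}

file_digests <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  digests <- unname(tools::md5sum(files))
  stats::setNames(digests, basename(files))
}
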