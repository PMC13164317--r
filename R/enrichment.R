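# Over-representation statistics: hypergeometric upper tail, BH
# adjustment, odds ratio with Haldane-Anscombe correction, and a combined
# score (-ln(p) times the standardized overlap count).

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` marked items in `n` draws without replacement from
#' a universe of `N` items of which `K` are marked. Evaluated in log space
#' for numerical stability at small p.
#'
#' @param k observed overlap count
#' @param n query size (within the universe)
#' @param K term (marked-set) size
#' @param N universe size
#' @return the upper-tail p-value, in `(0, 1]`
#' @export
#' @examples
#' hypergeom_tail(4, 4, 5, 10) # 5/210
hypergeom_tail <- function(k, n, K, N) {
  args <- vctrs_recycle(k, n, K, N)
  k <- args[[1]]; n <- args[[2]]; K <- args[[3]]; N <- args[[4]]
  if (any(k < 0 | n < 0 | K < 0 | N < 0)) {
    abort_range("hypergeom_tail: all arguments must be non-negative")
  }
  if (any(k > pmin(n, K)) || any(n > N) || any(K > N)) {
    abort_range("hypergeom_tail: need k <= min(n, K) and n, K <= N")
  }
  out <- ifelse(
    k <= 0, 1,
    exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  )
  pmin(pmax(out, 0), 1)
}

vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  lapply(args, rep_len, length.out = len)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment; outputs are returned
#' in input order, are never below the raw p-values, and are capped at 1.
#'
#' @param p numeric vector of p-values in `(0, 1]`
#' @return adjusted p-values in input order
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    abort_range("bh_adjust: p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Odds ratio of a 2x2 overlap table
#'
#' Computes `(a*d)/(b*c)` on the table `a = k`, `b = n - k`, `c = K - k`,
#' `d = N - n - K + k`. The Haldane-Anscombe 0.5 correction is applied to
#' every cell iff any cell is zero, so the ratio is always finite.
#'
#' @inheritParams hypergeom_tail
#' @return the (possibly corrected) odds ratio
#' @export
odds_ratio <- function(k, n, K, N) {
  args <- vctrs_recycle(k, n, K, N)
  k <- args[[1]]; n <- args[[2]]; K <- args[[3]]; N <- args[[4]]
  a <- k; b <- n - k; c <- K - k; d <- N - n - K + k
  if (any(b < 0 | c < 0 | d < 0)) {
    abort_range("odds_ratio: inconsistent 2x2 table")
  }
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c <- c + 0.5 * zero; d <- d + 0.5 * zero
  (a * d) / (b * c)
}

#' Combined enrichment score
#'
#' `-ln(p) * z`, where `z = (k - mu) / sigma` standardizes the overlap
#' count against its hypergeometric mean `mu = nK/N` and standard
#' deviation; `z` is defined as 0 when `sigma = 0`.
#'
#' @param p_value the term's p-value, in `(0, 1]`
#' @inheritParams hypergeom_tail
#' @return the combined score
#' @export
combined_score <- function(p_value, k, n, K, N) {
  args <- vctrs_recycle(p_value, k, n, K, N)
  p_value <- args[[1]]; k <- args[[2]]; n <- args[[3]]
  K <- args[[4]]; N <- args[[5]]
  if (any(p_value <= 0 | p_value > 1)) {
    abort_range("combined_score: p_value must lie in (0, 1]")
  }
  mu <- n * K / N
  sigma2 <- ifelse(
    N > 1,
    n * (K / N) * (1 - K / N) * (N - n) / (N - 1),
    0
  )
  sigma <- sqrt(pmax(sigma2, 0))
  z <- ifelse(sigma == 0, 0, (k - mu) / sigma)
  -log(p_value) * z
}

#' Over-representation analysis of a protein set
#'
#' Tests the query against every term of a gene-set library with the
#' hypergeometric upper-tail test, adjusts across all terms with
#' Benjamini-Hochberg, and reports odds ratio, combined score and the
#' overlapping members. Query symbols outside the universe are dropped
#' (and counted in the `n_dropped` attribute), never added to `N`.
#'
#' @param query interactome, protein set or character vector of symbols
#' @param library a `nb_geneset_library` (see [read_gmt()])
#' @param top number of top terms to return (default 10; `Inf` for all)
#' @param order_by rank by raw `"p_value"` (default) or `"adjusted_p"`
#' @return tibble of class `nb_enrichment`, sorted ascending by the
#'   ordering statistic with ties broken by term label; columns `term`,
#'   `k`, `n`, `K`, `N`, `p_value`, `adjusted_p`, `odds_ratio`,
#'   `combined_score`, `overlap_members` (list-column)
#' @export
enrich <- function(query, library, top = 10,
                   order_by = c("p_value", "adjusted_p")) {
  stopifnot(inherits(library, "nb_geneset_library"))
  order_by <- match.arg(order_by)
  q_all <- members(query)
  q <- intersect(q_all, library$universe)
  if (length(q) == 0L) {
    rlang::abort(
      "no testable genes: query does not intersect the library universe",
      class = "nbhub_no_testable_genes"
    )
  }
  N <- length(library$universe)
  n <- length(q)
  res <- purrr::imap_dfr(library$terms, function(mem, tm) {
    ov <- intersect(q, mem)
    tibble::tibble(
      term = tm, k = length(ov), n = n, K = length(mem), N = N,
      overlap_members = list(ov)
    )
  })
  res$p_value <- hypergeom_tail(res$k, res$n, res$K, res$N)
  res$adjusted_p <- bh_adjust(res$p_value)
  res$odds_ratio <- odds_ratio(res$k, res$n, res$K, res$N)
  res$combined_score <- combined_score(res$p_value, res$k, res$n, res$K, res$N)
  key <- if (order_by == "p_value") res$p_value else res$adjusted_p
  res <- res[order(key, res$term), , drop = FALSE]
  res <- utils::head(res, n = top)
  res <- res[, c(
    "term", "k", "n", "K", "N", "p_value", "adjusted_p", "odds_ratio",
    "combined_score", "overlap_members"
  )]
  tibble::new_tibble(
    res,
    n_dropped = length(q_all) - length(q),
    library = library$name,
    class = "nb_enrichment"
  )
}

#' @rdname enrich
#' @param x an `nb_enrichment`
#' @param ... unused
#' @return `glance()`: one-row tibble (n_terms, n_significant at BH 0.05,
#'   n_query, n_dropped)
#' @method glance nb_enrichment
#' @export
glance.nb_enrichment <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x),
    n_significant = sum(x$adjusted_p < 0.05),
    n_query = if (nrow(x)) x$n[[1]] else NA_integer_,
    n_dropped = attr(x, "n_dropped")
  )
}

#' Bar chart of top enriched terms
#'
#' @param object an `nb_enrichment`
#' @param ... unused
#' @return horizontal bar chart of `-log10(p)` for the returned terms
#' @method autoplot nb_enrichment
#' @export
autoplot.nb_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = expression(-log[10] * "(p-value)"), y = NULL,
      title = attr(object, "library")
    ) +
    ggplot2::theme_minimal()
}

#' Write enrichment results as TSV
#' @param x an `nb_enrichment`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_enrichment <- function(x, path) {
  out <- tibble::as_tibble(x)
  out$overlap_members <- vapply(
    out$overlap_members, paste, character(1), collapse = ","
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
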