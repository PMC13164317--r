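# Set algebra over interactomes and proteome lists. Overlaps are computed
# on partner-symbol sets only; evidence filtering belongs to hub selection.

#' Intersection of two protein sets
#'
#' @param a,b interactomes, protein sets or character vectors
#' @param name optional label for the result
#' @return a [protein_set()] holding the intersection
#' @export
#' @examples
#' overlap(c("A", "B", "C"), c("B", "C", "D"))
overlap <- function(a, b, name = NULL) {
  protein_set(intersect(members(a), members(b)), name = name)
}

#' Three-way Venn partition
#'
#' Partitions the union of three sets into the seven disjoint membership
#' regions (only-A, only-B, only-C, the three pairwise-only regions and the
#' triple intersection).
#'
#' @param a,b,c interactomes, protein sets or character vectors
#' @param names length-3 character vector of set labels
#' @return tibble of class `nb_venn` with columns `region`, `size`,
#'   `members` (list-column); regions are disjoint and their union is
#'   `a + b + c`
#' @export
venn3 <- function(a, b, c, names = c("A", "B", "C")) {
  stopifnot(length(names) == 3L, !anyDuplicated(names))
  sets <- list(members(a), members(b), members(c))
  u <- sort(unique(unlist(sets)))
  inset <- matrix(
    unlist(lapply(sets, function(s) u %in% s)),
    nrow = length(u), ncol = 3
  )
  combos <- expand.grid(A = c(TRUE, FALSE), B = c(TRUE, FALSE), C = c(TRUE, FALSE))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  rows <- purrr::pmap_dfr(combos, function(A, B, C) {
    want <- c(A, B, C)
    sel <- inset[, 1] == want[1] & inset[, 2] == want[2] & inset[, 3] == want[3]
    tibble::tibble(
      region = paste(names[want], collapse = "&"),
      size = sum(sel),
      members = list(u[sel])
    )
  })
  tibble::new_tibble(rows, class = "nb_venn")
}

#' Pairwise overlap matrix
#'
#' Square matrix of pairwise intersection sizes across a collection of
#' protein sets; the diagonal holds set sizes. This is the tabular form of
#' the shared-protein heatmap across interactomes and proteome lists.
#'
#' @param sets named list of interactomes, protein sets or character
#'   vectors; at least two, with distinct names
#' @return integer matrix of class `nb_overlap_matrix` with the set names
#'   as dimnames
#' @export
overlap_matrix <- function(sets) {
  if (length(sets) < 2L) {
    abort_config("overlap_matrix needs at least two sets")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort_config("overlap_matrix needs a named list of sets")
  }
  if (anyDuplicated(names(sets))) {
    abort_config("duplicate set names in overlap_matrix input")
  }
  mem <- lapply(sets, members)
  n <- length(mem)
  m <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- length(intersect(mem[[i]], mem[[j]]))
    }
  }
  structure(m, class = c("nb_overlap_matrix", class(m)))
}

#' @rdname overlap_matrix
#' @param x an `nb_overlap_matrix`
#' @param ... unused
#' @return `tidy()`: long tibble (set_a, set_b, shared)
#' @method tidy nb_overlap_matrix
#' @export
tidy.nb_overlap_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    set_a = rep(rownames(m), times = ncol(m)),
    set_b = rep(colnames(m), each = nrow(m)),
    shared = as.integer(m)
  )
}

#' Heatmap of an overlap matrix
#'
#' @param object an `nb_overlap_matrix`
#' @param ... unused
#' @return a ggplot tile plot of pairwise shared-protein counts
#' @method autoplot nb_overlap_matrix
#' @export
autoplot.nb_overlap_matrix <- function(object, ...) {
  df <- generics::tidy(object)
  df$set_a <- factor(df$set_a, levels = rownames(object))
  df$set_b <- factor(df$set_b, levels = rev(colnames(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_a, y = .data$set_b, fill = .data$shared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$shared), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "shared\nproteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write an overlap matrix as TSV
#' @param x an `nb_overlap_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_overlap_matrix <- function(x, path) {
  df <- tibble::as_tibble(unclass(x), rownames = "set")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a Venn partition as TSV
#' @param x an `nb_venn`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_venn <- function(x, path) {
  out <- tibble::tibble(
    region = x$region,
    size = x$size,
    members = vapply(x$members, paste, character(1), collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
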