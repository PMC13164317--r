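#' Construct an interactome
#'
#' An interactome is the partner set of one focal protein, with a per-pair
#' evidence count: the number of independent records (distinct publication
#' x experimental-system combinations) supporting the interaction.
#' Self-loops are removed and evidence counts must be positive.
#'
#' @param focal focal gene symbol (normalized to uppercase)
#' @param partners character vector of partner symbols, or a data frame with
#'   columns `partner` and `evidence`
#' @param evidence integer vector of evidence counts, recycled if length 1;
#'   ignored when `partners` is a data frame
#' @return a tibble of class `nb_interactome` with columns `partner` and
#'   `evidence`, sorted by partner, carrying the focal symbol as an attribute
#' @export
#' @examples
#' interactome("USP7", c("MDM2", "TP53"), c(3, 2))
interactome <- function(focal, partners = character(), evidence = 1L) {
  focal <- norm_symbol(focal)
  if (length(focal) != 1L || !nzchar(focal)) {
    abort_format("`focal` must be a single non-empty gene symbol.")
  }
  if (is.data.frame(partners)) {
    tbl <- tibble::as_tibble(partners)[, c("partner", "evidence")]
  } else {
    tbl <- tibble::tibble(
      partner = as.character(partners),
      evidence = rep_len(as.integer(evidence), length(partners))
    )
  }
  tbl$partner <- norm_symbol(tbl$partner)
  tbl$evidence <- as.integer(tbl$evidence)
  tbl <- tbl[nzchar(tbl$partner) & tbl$partner != focal, , drop = FALSE]
  if (anyDuplicated(tbl$partner)) {
    abort_format("duplicate partner symbols in interactome construction")
  }
  if (any(tbl$evidence < 1L)) {
    abort_range("every evidence count must be >= 1")
  }
  tbl <- tbl[order(tbl$partner), , drop = FALSE]
  structure(
    tibble::new_tibble(tbl, focal = focal, class = "nb_interactome"),
    focal = focal
  )
}

#' @export
print.nb_interactome <- function(x, ...) {
  cat(sprintf(
    "<nb_interactome> focal = %s, %d partners\n",
    attr(x, "focal"), nrow(x)
  ))
  NextMethod()
}

#' Focal protein of an interactome
#' @param x an `nb_interactome`
#' @return the focal gene symbol
#' @export
focal_protein <- function(x) {
  attr(x, "focal")
}

#' Partner symbols of an interactome or members of a protein set
#'
#' Coerces the common carriers of "a set of proteins" to a normalized,
#' deduplicated character vector: an interactome contributes its partner
#' symbols (evidence ignored), a protein set its members, and a plain
#' character vector is normalized.
#'
#' @param x an `nb_interactome`, `nb_protein_set`, or character vector
#' @return sorted character vector of normalized symbols
#' @export
members <- function(x) {
  if (inherits(x, "nb_interactome")) {
    return(sort(unique(x$partner)))
  }
  if (inherits(x, "nb_protein_set")) {
    return(sort(unique(unclass(x))))
  }
  if (is.character(x)) {
    m <- norm_symbol(x)
    return(sort(unique(m[nzchar(m)])))
  }
  rlang::abort("cannot extract protein members from this object")
}

#' Construct a named protein set
#'
#' @param x character vector of gene symbols (normalized, deduplicated)
#' @param name optional set label
#' @return character vector of class `nb_protein_set`
#' @export
protein_set <- function(x, name = NULL) {
  m <- members(x)
  structure(m, name = name, class = "nb_protein_set")
}

#' @export
print.nb_protein_set <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf(
    "<nb_protein_set>%s %d proteins\n",
    if (is.null(nm)) "" else paste0(" ", nm, ":"), length(x)
  ))
  print(unclass(x), ...)
  invisible(x)
}
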