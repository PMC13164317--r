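# Readers and writers for the pipeline's tab-delimited dialects:
# BioGRID TAB3-style interaction snapshots, plain-text gene lists, GMT
# gene-set libraries, predictor score tables, per-residue score tracks,
# and PTM annotation tables.

# Header matching is case-insensitive and tolerant of punctuation so minor
# column-name drift between export flavors does not break parsing.
match_column <- function(headers, what) {
  h <- tolower(gsub("[^a-z0-9 ]", " ", tolower(headers)))
  h <- gsub("\\s+", " ", trimws(h))
  hit <- switch(what,
    symbol_a = grepl("official symbol", h) & grepl("(interactor )?a$", h),
    symbol_b = grepl("official symbol", h) & grepl("(interactor )?b$", h),
    system   = grepl("experimental system", h) & !grepl("type", h),
    publication = grepl("publication", h),
    organism_a = grepl("organism", h) & grepl("(interactor )?a$", h),
    organism_b = grepl("organism", h) & grepl("(interactor )?b$", h)
  )
  which(hit)[1]
}

#' Read a BioGRID TAB3-style interaction snapshot
#'
#' Parses a tab-delimited interaction table and collapses it to the focal
#' protein's partner set with per-pair evidence counts. The evidence count
#' of a pair is the number of distinct (publication, experimental system)
#' records supporting it, so duplicated rows never inflate it. Rows not
#' involving the focal protein are ignored; self-interactions are dropped.
#'
#' @param path path to a tab-delimited file whose header names at least the
#'   interactor A/B official-symbol columns, an experimental-system column
#'   and a publication column (matched case-insensitively)
#' @param focal focal gene symbol
#' @param taxon_filter optional taxon id (or vector of ids); when given,
#'   rows whose organism columns fall outside it are dropped
#' @return an [interactome()] for `focal`
#' @export
read_interaction_table <- function(path, focal, taxon_filter = NULL) {
  focal <- norm_symbol(focal)
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  headers <- names(tbl)
  required <- c(
    symbol_a = "official symbol interactor A",
    symbol_b = "official symbol interactor B",
    system = "experimental system",
    publication = "publication"
  )
  idx <- vapply(names(required), function(w) match_column(headers, w), 1L)
  if (anyNA(idx)) {
    missing <- required[is.na(idx)]
    abort_format(sprintf(
      "interaction table %s lacks required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  rec <- tibble::tibble(
    symbol_a = norm_symbol(tbl[[idx[["symbol_a"]]]]),
    symbol_b = norm_symbol(tbl[[idx[["symbol_b"]]]]),
    system = as.character(tbl[[idx[["system"]]]]),
    publication = as.character(tbl[[idx[["publication"]]]])
  )
  if (!is.null(taxon_filter)) {
    ia <- match_column(headers, "organism_a")
    ib <- match_column(headers, "organism_b")
    if (is.na(ia) || is.na(ib)) {
      abort_format(sprintf(
        "taxon_filter given but %s has no organism interactor A/B columns", path
      ))
    }
    keep <- suppressWarnings(as.integer(tbl[[ia]])) %in% taxon_filter &
      suppressWarnings(as.integer(tbl[[ib]])) %in% taxon_filter
    rec <- rec[keep, , drop = FALSE]
  }
  rec <- rec[rec$symbol_a == focal | rec$symbol_b == focal, , drop = FALSE]
  if (nrow(rec) == 0L) {
    rlang::warn(sprintf("focal protein %s absent from %s", focal, path))
    return(interactome(focal))
  }
  rec$partner <- ifelse(rec$symbol_a == focal, rec$symbol_b, rec$symbol_a)
  rec <- rec[rec$partner != focal & nzchar(rec$partner), , drop = FALSE]
  counts <- rec |>
    dplyr::distinct(.data$partner, .data$publication, .data$system) |>
    dplyr::count(.data$partner, name = "evidence")
  interactome(focal, counts)
}

#' Write an interactome as a TAB3-style snapshot
#'
#' Expands each partner's evidence count into that many rows with distinct
#' synthetic publication identifiers, so [read_interaction_table()] on the
#' output reproduces the interactome exactly (round trip).
#'
#' @param x an [interactome()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_interaction_table <- function(x, path) {
  stopifnot(inherits(x, "nb_interactome"))
  focal <- focal_protein(x)
  rows <- purrr::map2_dfr(x$partner, x$evidence, function(p, e) {
    tibble::tibble(
      `Official Symbol Interactor A` = focal,
      `Official Symbol Interactor B` = p,
      `Experimental System` = "Synthetic Assay",
      `Publication Source` = sprintf("PUB:%s:%s:%d", focal, p, seq_len(e)),
      `Organism ID Interactor A` = "9606",
      `Organism ID Interactor B` = "9606"
    )
  })
  if (nrow(rows) == 0L) {
    rows <- tibble::tibble(
      `Official Symbol Interactor A` = character(),
      `Official Symbol Interactor B` = character(),
      `Experimental System` = character(),
      `Publication Source` = character(),
      `Organism ID Interactor A` = character(),
      `Organism ID Interactor B` = character()
    )
  }
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; lines starting with `#` are comments; symbols are
#' normalized and deduplicated.
#'
#' @param path path to the list file
#' @param name optional set label (defaults to the file name)
#' @return a [protein_set()]
#' @export
read_protein_list <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  syms <- unique(norm_symbol(lines))
  syms <- syms[nzchar(syms)]
  if (length(syms) == 0L) {
    rlang::warn(sprintf("gene list %s is empty", path))
  }
  rlang::inform(sprintf(
    "read_protein_list: %d lines read, %d symbols kept", length(lines),
    length(syms)
  ))
  protein_set(syms, name = name %||% basename(path))
}

#' Write a plain-text gene list
#' @param x a [protein_set()] or character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_protein_list <- function(x, path) {
  writeLines(members(x), path)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Each line holds a term label, a description, and tab-separated member
#' symbols. The universe defaults to the union of all term members.
#'
#' @param path path to a GMT file
#' @param universe optional background universe overriding the union
#' @param name library label (defaults to the file name)
#' @return a `nb_geneset_library`: list with `name`, `terms` (named list of
#'   member vectors) and `universe`
#' @export
read_gmt <- function(path, universe = NULL, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  terms <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      abort_format(sprintf(
        "GMT line %d of %s has %d field(s); need term, description, members",
        i, path, length(fields)
      ))
    }
    mem <- members(fields[-(1:2)])
    if (length(mem) == 0L) {
      abort_format(sprintf("GMT line %d of %s defines an empty term", i, path))
    }
    terms[[fields[[1]]]] <- mem
  }
  geneset_library(terms, universe = universe, name = name %||% basename(path))
}

#' Construct a gene-set library
#'
#' @param terms named list of member-symbol vectors
#' @param universe optional background universe; defaults to the union of
#'   all terms. Term members outside a supplied universe are dropped.
#' @param name library label
#' @return a `nb_geneset_library`
#' @export
geneset_library <- function(terms, universe = NULL, name = "library") {
  if (length(terms) == 0L || is.null(names(terms)) || any(!nzchar(names(terms)))) {
    abort_format("`terms` must be a non-empty named list")
  }
  terms <- lapply(terms, members)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(terms, use.names = FALSE)))
  } else {
    universe <- members(universe)
    terms <- lapply(terms, function(m) m[m %in% universe])
  }
  if (any(lengths(terms) == 0L)) {
    abort_format("library contains an empty term (after universe restriction)")
  }
  structure(
    list(name = name, terms = terms, universe = universe),
    class = "nb_geneset_library"
  )
}

#' @export
print.nb_geneset_library <- function(x, ...) {
  cat(sprintf(
    "<nb_geneset_library> %s: %d terms, universe of %d genes\n",
    x$name, length(x$terms), length(x$universe)
  ))
  invisible(x)
}

#' Write a gene-set library in GMT format
#' @param x a `nb_geneset_library`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "nb_geneset_library"))
  lines <- vapply(names(x$terms), function(tm) {
    paste(c(tm, "na", x$terms[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

check_score_range <- function(score, protein, predictor, path) {
  bad <- which(!is.na(score) & (score < 0 | score > 1))
  if (length(bad)) {
    i <- bad[[1]]
    abort_range(sprintf(
      "score %g out of [0,1] for protein %s, predictor %s in %s",
      score[i], protein[i], predictor[i], path
    ))
  }
}

#' Read a per-protein predictor score table
#'
#' Tab-delimited with columns `protein`, `predictor`, `score`. Scores must
#' lie in [0,1]; a value outside that range is a hard error (it would
#' silently invalidate every downstream classifier). Missing combinations
#' are explicit absences, never zeros.
#'
#' @param path path to the table
#' @return tibble of class `nb_score_table` (protein, predictor, score)
#' @export
read_score_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein = readr::col_character(),
      predictor = readr::col_character(),
      score = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(c("protein", "predictor", "score") %in% names(tbl))) {
    abort_format(sprintf(
      "score table %s needs columns protein, predictor, score", path
    ))
  }
  tbl$protein <- norm_symbol(tbl$protein)
  check_score_range(tbl$score, tbl$protein, tbl$predictor, path)
  score_table(tbl)
}

#' Construct a score table
#' @param tbl data frame with columns protein, predictor, score
#' @return tibble of class `nb_score_table`
#' @export
score_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)[, c("protein", "predictor", "score")]
  tbl$protein <- norm_symbol(tbl$protein)
  check_score_range(tbl$score, tbl$protein, tbl$predictor, "<in-memory>")
  if (anyDuplicated(tbl[, c("protein", "predictor")])) {
    abort_format("duplicate (protein, predictor) rows in score table")
  }
  tibble::new_tibble(tbl, class = "nb_score_table")
}

# Look up one predictor score; NA when absent.
get_score <- function(scores, protein, predictor) {
  hit <- scores$score[scores$protein == protein & scores$predictor == predictor]
  if (length(hit) == 0L) NA_real_ else hit[[1]]
}

#' Read per-residue score tracks
#'
#' Tab-delimited with columns `protein`, `predictor`, `scores`, the latter
#' a comma-separated list of per-residue values in [0,1].
#'
#' @param path path to the track table
#' @return tibble of class `nb_track_table` with a list-column `scores`
#' @export
read_residue_tracks <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(c("protein", "predictor", "scores") %in% names(tbl))) {
    abort_format(sprintf(
      "track table %s needs columns protein, predictor, scores", path
    ))
  }
  tbl$protein <- norm_symbol(tbl$protein)
  tracks <- lapply(strsplit(tbl$scores, ",", fixed = TRUE), as.numeric)
  for (i in seq_along(tracks)) {
    v <- tracks[[i]]
    if (length(v) < 1L || anyNA(v)) {
      abort_format(sprintf(
        "track for %s/%s in %s is empty or non-numeric",
        tbl$protein[i], tbl$predictor[i], path
      ))
    }
    if (any(v < 0 | v > 1)) {
      abort_range(sprintf(
        "residue score out of [0,1] for protein %s, predictor %s in %s",
        tbl$protein[i], tbl$predictor[i], path
      ))
    }
  }
  tibble::new_tibble(
    tibble::tibble(
      protein = tbl$protein, predictor = tbl$predictor, scores = tracks
    ),
    class = "nb_track_table"
  )
}

#' Write per-residue score tracks
#' @param x track tibble (protein, predictor, scores list-column)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_residue_tracks <- function(x, path) {
  out <- tibble::tibble(
    protein = x$protein,
    predictor = x$predictor,
    scores = vapply(
      x$scores, function(v) paste(format(v, trim = TRUE), collapse = ","),
      character(1)
    )
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Fetch one protein's track for a predictor; NULL when absent.
get_track <- function(tracks, protein, predictor) {
  hit <- which(tracks$protein == protein & tracks$predictor == predictor)
  if (length(hit) == 0L) NULL else tracks$scores[[hit[[1]]]]
}

#' Read a PTM annotation table
#'
#' Tab-delimited with columns `protein`, `sumo`, `ubiquitin`; flag values
#' are `true`/`false`/`unknown` (case-insensitive). Unknown is stored as
#' `NA` and is never coerced to `FALSE` in summaries.
#'
#' @param path path to the table
#' @return tibble (protein, sumo, ubiquitin) with logical NA-able flags
#' @export
read_ptm_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(c("protein", "sumo", "ubiquitin") %in% names(tbl))) {
    abort_format(sprintf(
      "PTM table %s needs columns protein, sumo, ubiquitin", path
    ))
  }
  parse_flag <- function(x) {
    x <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[x %in% c("true", "t", "1", "yes")] <- TRUE
    out[x %in% c("false", "f", "0", "no")] <- FALSE
    bad <- !is.na(x) & !(x %in% c(
      "true", "t", "1", "yes", "false", "f", "0", "no", "unknown", "na", ""
    ))
    if (any(bad)) {
      abort_format(sprintf(
        "unrecognized PTM flag value '%s' in %s", x[which(bad)[1]], path
      ))
    }
    out
  }
  tibble::tibble(
    protein = norm_symbol(tbl$protein),
    sumo = parse_flag(tbl$sumo),
    ubiquitin = parse_flag(tbl$ubiquitin)
  )
}

#' Read protein sequences from a FASTA file
#'
#' Minimal single-letter amino-acid FASTA reader; header word after `>` is
#' taken as the protein symbol.
#'
#' @param path path to a FASTA file
#' @return tibble (protein, sequence)
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1]) {
    abort_format(sprintf("%s does not start with a FASTA header", path))
  }
  idx <- cumsum(hdr)
  names <- norm_symbol(sub("^>\\s*(\\S+).*$", "\\1", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1), collapse = "")
  tibble::tibble(protein = names, sequence = unname(toupper(seqs[as.character(seq_along(names))])))
}

#' Write protein sequences to a FASTA file
#' @param x tibble (protein, sequence)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path) {
  writeLines(
    as.vector(rbind(paste0(">", x$protein), x$sequence)),
    path
  )
  invisible(path)
}
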