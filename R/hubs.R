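# Hub discovery: evidence-filter each core interactome, count qualifying
# cores per candidate protein, call hubs at a configurable threshold.
# Defaults mirror the organelle-restricted hub rule: a protein is a hub
# when it appears in >= 4 core interactomes with evidence count >= 2.

#' Hub-selection parameters
#'
#' @param k_min minimum number of qualifying core interactomes for a hub
#'   call (default 4)
#' @param evidence_min minimum per-pair evidence count for an interaction
#'   to qualify (default 2)
#' @param exclude_cores_as_candidates should the core proteins themselves
#'   be excluded from the candidate universe? (default TRUE: hubs are
#'   partners of cores, not the cores)
#' @return list of class `nb_hub_params`
#' @export
hub_params <- function(k_min = 4L, evidence_min = 2L,
                       exclude_cores_as_candidates = TRUE) {
  k_min <- as.integer(k_min)
  evidence_min <- as.integer(evidence_min)
  if (k_min < 1L) abort_config("k_min must be >= 1")
  if (evidence_min < 1L) abort_config("evidence_min must be >= 1")
  structure(
    list(
      k_min = k_min, evidence_min = evidence_min,
      exclude_cores_as_candidates = isTRUE(exclude_cores_as_candidates)
    ),
    class = "nb_hub_params"
  )
}

#' Filter an interactome by evidence count
#'
#' Removes partners supported by fewer than `evidence_min` independent
#' records; surviving evidence counts are unchanged.
#'
#' @param x an [interactome()]
#' @param evidence_min minimum evidence count (>= 1)
#' @return the filtered interactome
#' @export
filter_by_evidence <- function(x, evidence_min = 2L) {
  stopifnot(inherits(x, "nb_interactome"))
  evidence_min <- as.integer(evidence_min)
  if (evidence_min < 1L) abort_config("evidence_min must be >= 1")
  interactome(focal_protein(x), x[x$evidence >= evidence_min, , drop = FALSE])
}

#' Select hub proteins across core interactomes
#'
#' Evidence-filters each core interactome, counts for each candidate
#' protein the number of cores whose filtered partner set contains it, and
#' flags candidates reaching `k_min` cores as hubs. The candidate universe
#' is the union of all filtered partner sets, excluding the core proteins
#' themselves unless `exclude_cores_as_candidates` is FALSE.
#'
#' @param cores named list of [interactome()] objects, one per core protein
#' @param params a [hub_params()] object
#' @return tibble of class `nb_hub_table` with columns `protein`,
#'   `core_count`, `qualifying_cores` (list-column of core names) and
#'   `is_hub`, ordered by descending `core_count` then symbol
#' @export
select_hubs <- function(cores, params = hub_params()) {
  stopifnot(inherits(params, "nb_hub_params"))
  if (is.null(names(cores)) || any(!nzchar(names(cores)))) {
    abort_config("`cores` must be a named list of interactomes")
  }
  if (params$k_min > length(cores)) {
    abort_config(sprintf(
      "k_min (%d) exceeds the number of cores supplied (%d)",
      params$k_min, length(cores)
    ))
  }
  filtered <- lapply(cores, filter_by_evidence, evidence_min = params$evidence_min)
  core_symbols <- norm_symbol(c(
    names(cores), vapply(cores, focal_protein, character(1))
  ))
  hits <- purrr::imap_dfr(filtered, function(i, nm) {
    tibble::tibble(core = nm, protein = members(i))
  })
  if (params$exclude_cores_as_candidates) {
    hits <- hits[!(hits$protein %in% core_symbols), , drop = FALSE]
  }
  if (nrow(hits) == 0L) {
    tab <- tibble::tibble(
      protein = character(), core_count = integer(),
      qualifying_cores = list(), is_hub = logical()
    )
  } else {
    tab <- hits |>
      dplyr::group_by(.data$protein) |>
      dplyr::summarise(
        core_count = dplyr::n_distinct(.data$core),
        qualifying_cores = list(sort(unique(.data$core))),
        .groups = "drop"
      ) |>
      dplyr::mutate(is_hub = .data$core_count >= params$k_min) |>
      dplyr::arrange(dplyr::desc(.data$core_count), .data$protein)
  }
  tibble::new_tibble(tab, params = params, n_cores = length(cores),
                     class = "nb_hub_table")
}

#' Hub proteins from a hub table
#' @param x an `nb_hub_table`
#' @return character vector of hub symbols
#' @export
hub_proteins <- function(x) {
  stopifnot(inherits(x, "nb_hub_table"))
  sort(x$protein[x$is_hub])
}

#' @rdname select_hubs
#' @param x an `nb_hub_table`
#' @param ... unused
#' @return `glance()`: one-row tibble with candidate and hub counts and the
#'   thresholds used
#' @method glance nb_hub_table
#' @export
glance.nb_hub_table <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_candidates = nrow(x),
    n_hubs = sum(x$is_hub),
    n_cores = attr(x, "n_cores"),
    k_min = p$k_min,
    evidence_min = p$evidence_min
  )
}

#' Hub-count sensitivity to both thresholds
#'
#' Re-runs hub selection over a grid of `k_min` and `evidence_min` values;
#' hub counts are weakly decreasing in both thresholds.
#'
#' @param cores named list of [interactome()] objects
#' @param k_range integer vector of `k_min` values
#' @param evidence_range integer vector of `evidence_min` values
#' @param exclude_cores_as_candidates passed to [hub_params()]
#' @return tibble (k_min, evidence_min, n_hubs)
#' @export
hub_sensitivity <- function(cores, k_range = 1:6, evidence_range = 1:3,
                            exclude_cores_as_candidates = TRUE) {
  if (length(k_range) == 0L || length(evidence_range) == 0L) {
    abort_config("k_range and evidence_range must be nonempty")
  }
  grid <- tidyr::expand_grid(
    k_min = sort(as.integer(k_range)),
    evidence_min = sort(as.integer(evidence_range))
  )
  grid$n_hubs <- purrr::map2_int(grid$k_min, grid$evidence_min, function(k, e) {
    tab <- select_hubs(cores, hub_params(
      k_min = k, evidence_min = e,
      exclude_cores_as_candidates = exclude_cores_as_candidates
    ))
    sum(tab$is_hub)
  })
  grid
}

#' Write a hub table as TSV
#' @param x an `nb_hub_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hub_table <- function(x, path) {
  out <- tibble::tibble(
    protein = x$protein,
    core_count = x$core_count,
    qualifying_cores = vapply(x$qualifying_cores, paste, character(1), collapse = ","),
    is_hub = x$is_hub
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
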