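# End-to-end orchestration: overlaps -> Venn/aging overlap -> hub
# selection -> hub network + MCODE + topology -> enrichment (global and
# per-cluster) -> annotation, with a structured JSON run report. Given
# identical inputs, configuration and seed, every output file is
# byte-identical across reruns.

#' Pipeline run configuration
#'
#' @param cores named character vector of interaction-snapshot paths, one
#'   per core protein (names are the core labels)
#' @param aging_lists character vector of up to two gene-list paths (e.g.
#'   senescence and aging databases) for the three-way overlap stage
#' @param proteome_lists named character vector of additional proteome
#'   list paths entering the overlap matrix (optional)
#' @param gmt path to the enrichment library (optional; enrichment stages
#'   are skipped when absent)
#' @param scores,tracks,ptm,sequences paths to the annotation inputs
#'   (optional; missing inputs yield unknown labels)
#' @param overlap_pair names of the two interactomes compared in the
#'   headline pairwise overlap (default: the first two cores)
#' @param k_min,evidence_min hub rule thresholds
#' @param mcode an [mcode_params()] object
#' @param top number of enrichment terms reported per query
#' @param min_region_length droplet-promoting region length for client
#'   calls
#' @param pH pH for the net-charge annotation
#' @param rewires rewired null graphs for the topology summary
#' @param seed seed recorded in the report and used for the topology null
#' @param out_dir output directory (created if missing)
#' @return list of class `nb_run_config`
#' @export
run_config <- function(cores, aging_lists = character(),
                       proteome_lists = character(), gmt = NULL,
                       scores = NULL, tracks = NULL, ptm = NULL,
                       sequences = NULL, overlap_pair = NULL,
                       k_min = 4L, evidence_min = 2L,
                       mcode = mcode_params(), top = 10L,
                       min_region_length = 10L, pH = 7.0, rewires = 20L,
                       seed = 1L, out_dir = tempfile("nbhub_run_")) {
  if (is.null(names(cores)) || any(!nzchar(names(cores)))) {
    abort_config("`cores` must be a named vector of file paths")
  }
  cfg <- list(
    cores = cores, aging_lists = aging_lists,
    proteome_lists = proteome_lists, gmt = gmt, scores = scores,
    tracks = tracks, ptm = ptm, sequences = sequences,
    overlap_pair = overlap_pair %||% names(cores)[1:2],
    k_min = as.integer(k_min), evidence_min = as.integer(evidence_min),
    mcode = mcode, top = top,
    min_region_length = as.integer(min_region_length), pH = pH,
    rewires = as.integer(rewires), seed = as.integer(seed),
    out_dir = out_dir
  )
  all_paths <- c(
    cores, aging_lists, proteome_lists,
    unlist(cfg[c("gmt", "scores", "tracks", "ptm", "sequences")])
  )
  missing <- all_paths[!file.exists(all_paths)]
  if (length(missing)) {
    abort_config(sprintf(
      "input file(s) not found: %s", paste(missing, collapse = ", ")
    ))
  }
  structure(cfg, class = "nb_run_config")
}

#' Configuration for a fully synthetic run
#'
#' Generates a complete input bundle with [simulate_inputs()] and wires it
#' into a [run_config()]: the one-call way to exercise the whole pipeline
#' against planted ground truth.
#'
#' @param spec a [synthetic_spec()]
#' @param dir directory receiving the synthetic inputs
#' @param out_dir pipeline output directory
#' @param ... further arguments passed to [run_config()]
#' @return list with `config` (an `nb_run_config`) and `ledger` (planted
#'   ground truth)
#' @export
synthetic_run_config <- function(spec = synthetic_spec(),
                                 dir = tempfile("nbhub_inputs_"),
                                 out_dir = tempfile("nbhub_run_"), ...) {
  sim <- simulate_inputs(spec, dir)
  p <- sim$paths
  cfg <- run_config(
    cores = p$cores,
    aging_lists = c(cellage = p$cellage, genage = p$genage),
    proteome_lists = c(nb_proteome = p$nb_proteome),
    gmt = p$gmt, scores = p$scores, tracks = p$tracks, ptm = p$ptm,
    sequences = p$sequences,
    k_min = spec$k_min, evidence_min = spec$evidence_min,
    min_region_length = spec$min_region_length,
    seed = spec$seed, out_dir = out_dir, ...
  )
  list(config = cfg, ledger = sim$ledger)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = "nbhub_stage_error", parent = e
    )
  })
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes all outputs plus a JSON run
#' report listing the headline counts: pairwise overlap size, three-way
#' aging-overlap sizes, hub count, MCODE complex count and the annotation
#' category counts. Any stage error aborts with the stage name.
#'
#' @param config an [run_config()] object, or a path to a YAML file whose
#'   keys mirror the [run_config()] arguments
#' @return invisibly, a list with all stage results and the `report`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg_list <- yaml::read_yaml(config)
    cfg_list$mcode <- do.call(mcode_params, as.list(cfg_list$mcode %||% list()))
    cfg_list$cores <- unlist(cfg_list$cores)
    config <- do.call(run_config, cfg_list)
  }
  stopifnot(inherits(config, "nb_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  cores <- run_stage("read_cores", {
    purrr::imap(config$cores, function(path, nm) {
      read_interaction_table(path, focal = nm)
    })
  })
  lists <- run_stage("read_lists", {
    c(
      lapply(config$aging_lists, read_protein_list),
      purrr::imap(
        config$proteome_lists,
        function(p, nm) read_protein_list(p, name = nm)
      )
    )
  })

  # --- overlap stage -------------------------------------------------
  pair <- config$overlap_pair
  ov <- run_stage("overlap", {
    if (!all(pair %in% names(cores))) {
      abort_config(sprintf(
        "overlap_pair (%s) not among the core names",
        paste(pair, collapse = ", ")
      ))
    }
    overlap(cores[[pair[1]]], cores[[pair[2]]],
            name = paste(pair, collapse = "&"))
  })
  om <- run_stage("overlap_matrix", {
    overlap_matrix(c(cores, lists))
  })
  write_overlap_matrix(om, out("overlap_matrix.tsv"))

  venn <- NULL
  if (length(config$aging_lists) >= 2L) {
    venn <- run_stage("aging_overlap", {
      venn3(
        lists[[1]], lists[[2]], ov,
        names = c(
          names(config$aging_lists)[1:2] %||% c("aging1", "aging2"),
          paste(pair, collapse = "&")
        )
      )
    })
    write_venn(venn, out("venn.tsv"))
  }

  # --- hub stage -----------------------------------------------------
  hubs <- run_stage("hub_selection", {
    select_hubs(cores, hub_params(
      k_min = config$k_min, evidence_min = config$evidence_min
    ))
  })
  write_hub_table(hubs, out("hubs.tsv"))
  sens <- run_stage("hub_sensitivity", {
    hub_sensitivity(
      cores,
      k_range = seq_len(min(length(cores), max(config$k_min + 2L, 6L))),
      evidence_range = seq_len(max(config$evidence_min, 3L))
    )
  })
  readr::write_tsv(sens, out("hub_sensitivity.tsv"), progress = FALSE)

  # --- network stage -------------------------------------------------
  graph <- run_stage("hub_network", {
    build_hub_graph(hubs, cores, evidence_min = config$evidence_min)
  })
  write_graph_outputs(graph, out("network.graphml"), out("edges.tsv"))
  complexes <- run_stage("mcode", {
    mcode_find_complexes(graph, config$mcode)
  })
  write_complexes(complexes, out("complexes.tsv"))
  topo <- run_stage("topology", {
    topology_summary(graph, rewires = config$rewires, seed = config$seed)
  })
  readr::write_tsv(topo, out("topology.tsv"), progress = FALSE)

  # --- enrichment stage ----------------------------------------------
  enr <- NULL
  cluster_enr <- NULL
  library <- NULL
  if (!is.null(config$gmt)) {
    library <- run_stage("read_gmt", read_gmt(config$gmt))
    enr <- run_stage("enrichment", {
      tryCatch(
        enrich(hub_proteins(hubs), library, top = config$top),
        nbhub_no_testable_genes = function(e) NULL
      )
    })
    if (!is.null(enr)) write_enrichment(enr, out("enrichment.tsv"))
    cluster_enr <- run_stage("cluster_enrichment", {
      per_cluster_enrichment(complexes, library, top = config$top)
    })
    readr::write_tsv(cluster_enr, out("enrichment_clusters.tsv"),
                     progress = FALSE)
  }

  # --- annotation stage ----------------------------------------------
  annot <- NULL
  if (sum(hubs$is_hub) > 0L) {
    annot <- run_stage("annotation", {
      annotate_hubs(
        hubs,
        scores = if (is.null(config$scores)) NULL else read_score_table(config$scores),
        tracks = if (is.null(config$tracks)) NULL else read_residue_tracks(config$tracks),
        ptm = if (is.null(config$ptm)) NULL else read_ptm_table(config$ptm),
        sequences = if (is.null(config$sequences)) NULL else read_fasta(config$sequences),
        min_region_length = config$min_region_length, pH = config$pH
      )
    })
    write_annotation(annot, out("annotations.tsv"))
  }

  report <- list(
    package_version = as.character(utils::packageVersion("nbhub")),
    seed = config$seed,
    parameters = list(
      k_min = config$k_min, evidence_min = config$evidence_min,
      mcode = unclass(config$mcode), top = config$top,
      min_region_length = config$min_region_length, pH = config$pH,
      evidence_definition = paste(
        "number of distinct (publication, experimental system) records",
        "supporting a pair"
      ),
      hub_graph_edge_evidence = paste(
        "union of all loaded snapshots; duplicate pairs keep the maximum",
        "per-snapshot evidence count"
      )
    ),
    inputs = list(
      cores = as.list(config$cores),
      aging_lists = as.list(config$aging_lists),
      proteome_lists = as.list(config$proteome_lists),
      gmt = config$gmt
    ),
    counts = list(
      interactome_sizes = lapply(cores, nrow),
      overlap_pair = paste(pair, collapse = "&"),
      overlap_size = length(ov),
      venn_region_sizes = if (is.null(venn)) NULL else {
        stats::setNames(as.list(venn$size), venn$region)
      },
      n_candidates = nrow(hubs),
      n_hubs = sum(hubs$is_hub),
      network_nodes = igraph::vcount(graph),
      network_edges = igraph::ecount(graph),
      n_complexes = nrow(complexes),
      top_term = if (is.null(enr) || nrow(enr) == 0L) NULL else enr$term[[1]],
      annotation = if (is.null(annot)) NULL else as.list(generics::glance(annot))
    )
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = 10, null = "null")
  invisible(list(
    cores = cores, lists = lists, overlap = ov, overlap_matrix = om,
    venn = venn, hubs = hubs, sensitivity = sens, graph = graph,
    complexes = complexes, topology = topo, enrichment = enr,
    cluster_enrichment = cluster_enr, annotation = annot, report = report,
    out_dir = config$out_dir
  ))
}

#' Per-complex enrichment
#'
#' Runs [enrich()] on the member set of every MCODE complex and attaches
#' the top terms as functional labels. A complex disjoint from the
#' library universe is recorded as having no testable genes, not an
#' error.
#'
#' @param complexes an `nb_mcode` result
#' @param library a `nb_geneset_library`
#' @param top top terms kept per complex
#' @return tibble (rank, term, k, K, p_value, adjusted_p, note) with one
#'   row per complex x term, or a single `no testable genes` row per
#'   untestable complex
#' @export
per_cluster_enrichment <- function(complexes, library, top = 3L) {
  stopifnot(inherits(complexes, "nb_mcode"))
  if (nrow(complexes) == 0L) {
    return(tibble::tibble(
      rank = integer(), term = character(), k = integer(), K = integer(),
      p_value = numeric(), adjusted_p = numeric(), note = character()
    ))
  }
  purrr::map_dfr(seq_len(nrow(complexes)), function(i) {
    res <- tryCatch(
      enrich(complexes$members[[i]], library, top = top),
      nbhub_no_testable_genes = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(
        rank = complexes$rank[[i]], term = NA_character_, k = NA_integer_,
        K = NA_integer_, p_value = NA_real_, adjusted_p = NA_real_,
        note = "no testable genes"
      )
    } else {
      tibble::tibble(
        rank = complexes$rank[[i]], term = res$term, k = res$k, K = res$K,
        p_value = res$p_value, adjusted_p = res$adjusted_p, note = ""
      )
    }
  })
}
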