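# Hub interaction graph, MCODE clustering and topology metrics.
#
# The MCODE algorithm is implemented here in full: vertex weighting by the
# density of the highest k-core of each closed neighborhood, greedy seeded
# complex expansion with a node-score cutoff and depth limit, and the
# k-core / haircut / fluff post-processing steps. igraph supplies the
# graph container and the standard primitives (coreness, components,
# transitivity, distances, degree-preserving rewiring).

#' MCODE parameters
#'
#' Defaults match the standard parameterization used for hub-network
#' clustering: degree cutoff 2, node score cutoff 0.2, k-core 2, max depth
#' 100, haircut and fluff off.
#'
#' @param degree_cutoff minimum vertex degree to receive a nonzero weight
#' @param node_score_cutoff fraction of the seed weight a neighbor may fall
#'   below and still join (in `[0,1]`)
#' @param k_core complexes lacking a k-core of this order are discarded
#' @param max_depth maximum expansion distance from the seed
#' @param haircut remove degree-1 members from each complex
#' @param fluff add boundary neighbors whose closed-neighborhood density
#'   exceeds `fluff_density_cutoff`
#' @param fluff_density_cutoff density threshold used only when `fluff`
#' @return list of class `nb_mcode_params`
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, max_depth = 100L, haircut = FALSE,
                         fluff = FALSE, fluff_density_cutoff = 0.5) {
  if (node_score_cutoff < 0 || node_score_cutoff > 1) {
    abort_config("node_score_cutoff must lie in [0,1]")
  }
  if (degree_cutoff < 1L) abort_config("degree_cutoff must be >= 1")
  if (k_core < 2L) abort_config("k_core must be >= 2")
  structure(
    list(
      degree_cutoff = as.integer(degree_cutoff),
      node_score_cutoff = node_score_cutoff,
      k_core = as.integer(k_core),
      max_depth = as.integer(max_depth),
      haircut = isTRUE(haircut),
      fluff = isTRUE(fluff),
      fluff_density_cutoff = fluff_density_cutoff
    ),
    class = "nb_mcode_params"
  )
}

#' Build the hub interaction graph
#'
#' Nodes are the hub proteins plus the core proteins; an edge is drawn
#' between two nodes whenever the pair co-occurs in the supplied
#' interaction data with evidence count at least `evidence_min`
#' (boundary inclusive). When the same pair occurs in several snapshots
#' the edge keeps the maximum evidence count.
#'
#' @param hubs an `nb_hub_table` (hubs taken from `is_hub`) or character
#'   vector of hub symbols
#' @param cores named list of core [interactome()] objects
#' @param all_interactions optional list of additional interactomes whose
#'   records may contribute edges (defaults to `cores`)
#' @param evidence_min minimum evidence for an edge
#' @return an undirected simple `igraph` with vertex attributes
#'   `core_count` (hub-table counts, NA for cores) and `is_core`
#' @export
build_hub_graph <- function(hubs, cores, all_interactions = NULL,
                            evidence_min = 2L) {
  hub_syms <- if (inherits(hubs, "nb_hub_table")) hub_proteins(hubs) else members(hubs)
  core_syms <- sort(unique(vapply(cores, focal_protein, character(1))))
  nodes <- sort(unique(c(hub_syms, core_syms)))
  interactions <- all_interactions %||% cores
  edges <- purrr::map_dfr(interactions, function(i) {
    tibble::tibble(
      a = rep(focal_protein(i), nrow(i)), b = i$partner, evidence = i$evidence
    )
  })
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(a = character(), b = character(), evidence = integer())
  }
  if (nrow(edges)) {
    edges <- edges[edges$evidence >= evidence_min &
                     edges$a %in% nodes & edges$b %in% nodes, , drop = FALSE]
  }
  if (nrow(edges)) {
    lo <- pmin(edges$a, edges$b)
    hi <- pmax(edges$a, edges$b)
    edges <- tibble::tibble(a = lo, b = hi, evidence = edges$evidence) |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(evidence = max(.data$evidence), .groups = "drop") |>
      dplyr::arrange(.data$a, .data$b)
  }
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edges[, c("a", "b", "evidence")]),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  counts <- rep(NA_integer_, length(nodes))
  if (inherits(hubs, "nb_hub_table")) {
    hit <- hubs$protein %in% nodes
    counts[match(hubs$protein[hit], nodes)] <- hubs$core_count[hit]
  }
  igraph::V(g)$core_count <- counts
  igraph::V(g)$is_core <- nodes %in% core_syms
  g
}

graph_density <- function(g) {
  v <- igraph::vcount(g)
  if (v < 2L) return(0)
  2 * igraph::ecount(g) / (v * (v - 1))
}

#' MCODE vertex weights
#'
#' The weight of a vertex is `k * density` of the highest k-core of the
#' subgraph induced by its closed neighborhood, where density is
#' `2E / (V(V-1))` (0 for fewer than two vertices). Vertices with degree
#' below `degree_cutoff` get weight 0.
#'
#' @param g an undirected `igraph`
#' @param v vertices to weight (default: all)
#' @param degree_cutoff minimum degree for a nonzero weight
#' @return named numeric vector of weights
#' @export
mcode_vertex_weight <- function(g, v = igraph::V(g), degree_cutoff = 2L) {
  names <- if (is.character(v)) v else igraph::V(g)$name[as.integer(v)]
  deg <- igraph::degree(g, v)
  w <- vapply(seq_along(names), function(i) {
    if (deg[[i]] < degree_cutoff) return(0)
    nb <- igraph::ego(g, order = 1, nodes = names[[i]])[[1]]
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax < 1L) return(0)
    core_sub <- igraph::induced_subgraph(sub, which(core >= kmax))
    kmax * graph_density(core_sub)
  }, numeric(1))
  stats::setNames(w, names)
}

#' Find MCODE complexes
#'
#' Seeds are taken in order of decreasing vertex weight (ties broken
#' lexicographically by symbol, for determinism). From each unvisited
#' seed, a complex grows breadth-first: a neighbor joins iff its weight
#' exceeds `(1 - node_score_cutoff)` times the seed weight and it lies
#' within `max_depth` of the seed. Each vertex belongs to at most one
#' complex before fluffing. Complexes lacking a `k_core`-core are
#' discarded; optional haircut removes degree-1 members and optional fluff
#' adds boundary neighbors with dense closed neighborhoods. Complexes are
#' scored `density * size` and ranked by descending score.
#'
#' @param g an undirected `igraph`
#' @param params an [mcode_params()] object
#' @return tibble of class `nb_mcode` with columns `rank`, `seed`,
#'   `score`, `size`, `members` (list-column of symbol vectors)
#' @export
mcode_find_complexes <- function(g, params = mcode_params()) {
  stopifnot(inherits(params, "nb_mcode_params"))
  n <- igraph::vcount(g)
  empty <- tibble::new_tibble(
    tibble::tibble(
      rank = integer(), seed = character(), score = numeric(),
      size = integer(), members = list()
    ),
    params = params, class = "nb_mcode"
  )
  if (n == 0L) return(empty)
  names <- igraph::V(g)$name
  w <- mcode_vertex_weight(g, degree_cutoff = params$degree_cutoff)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, function(a) names[as.integer(a)])
  names(adj) <- names
  order_idx <- order(-w, names)
  visited <- stats::setNames(rep(FALSE, n), names)
  complexes <- list()
  for (i in order_idx) {
    seed <- names[[i]]
    if (visited[[seed]] || w[[seed]] <= 0) next
    threshold <- (1 - params$node_score_cutoff) * w[[seed]]
    comp <- seed
    visited[[seed]] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      cand <- unique(unlist(adj[frontier], use.names = FALSE))
      cand <- cand[!visited[cand] & w[cand] > threshold]
      if (!length(cand)) break
      visited[cand] <- TRUE
      comp <- c(comp, cand)
      frontier <- cand
      depth <- depth + 1L
    }
    complexes[[length(complexes) + 1L]] <- list(seed = seed, members = sort(comp))
  }
  # post-processing
  keep <- list()
  for (cx in complexes) {
    sub <- igraph::induced_subgraph(g, cx$members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    mem <- cx$members
    if (params$haircut) {
      deg <- igraph::degree(sub)
      mem <- sort(igraph::V(sub)$name[deg >= 2])
      if (!length(mem)) next
    }
    if (params$fluff) {
      boundary <- setdiff(
        unique(unlist(adj[mem], use.names = FALSE)), mem
      )
      dense <- vapply(boundary, function(b) {
        nb <- igraph::ego(g, order = 1, nodes = b)[[1]]
        graph_density(igraph::induced_subgraph(g, nb))
      }, numeric(1))
      mem <- sort(c(mem, boundary[dense > params$fluff_density_cutoff]))
    }
    sub <- igraph::induced_subgraph(g, mem)
    score <- graph_density(sub) * length(mem)
    keep[[length(keep) + 1L]] <- tibble::tibble(
      seed = cx$seed, score = score, size = length(mem), members = list(mem)
    )
  }
  if (!length(keep)) return(empty)
  out <- dplyr::bind_rows(keep) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$size), .data$seed) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  tibble::new_tibble(out, params = params, class = "nb_mcode")
}

#' @rdname mcode_find_complexes
#' @param x an `nb_mcode` result
#' @param ... unused
#' @return `tidy()`: long tibble (rank, protein) of complex membership
#' @method tidy nb_mcode
#' @export
tidy.nb_mcode <- function(x, ...) {
  if (nrow(x) == 0L) return(tibble::tibble(rank = integer(), protein = character()))
  tidyr::unnest(
    tibble::tibble(rank = x$rank, protein = x$members),
    "protein"
  )
}

#' @rdname mcode_find_complexes
#' @return `glance()`: one-row tibble (n_complexes, top_score, n_clustered)
#' @method glance nb_mcode
#' @export
glance.nb_mcode <- function(x, ...) {
  tibble::tibble(
    n_complexes = nrow(x),
    top_score = if (nrow(x)) max(x$score) else NA_real_,
    n_clustered = length(unique(unlist(x$members)))
  )
}

#' Topology summary with small-world coefficient
#'
#' Computes node/edge counts, the average local clustering coefficient
#' (isolated and degree-1 vertices contribute 0), the characteristic path
#' length of the largest connected component, and the small-world sigma
#' `(C/C_rand) / (L/L_rand)` against a degree-preserving rewired ensemble.
#' Sigma is `NA` when the graph has fewer than 4 nodes or rewiring is
#' impossible.
#'
#' @param g an undirected `igraph`
#' @param rewires number of rewired null graphs (default 20)
#' @param seed RNG seed for the rewiring ensemble
#' @return one-row tibble (n_nodes, n_edges, avg_clustering,
#'   char_path_length, sigma)
#' @export
topology_summary <- function(g, rewires = 20L, seed = 1L) {
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  cc <- if (n == 0L) NA_real_ else {
    mean(igraph::transitivity(g, type = "local", isolates = "zero"), na.rm = TRUE)
  }
  comps <- if (n) igraph::components(g) else NULL
  cpl <- NA_real_
  if (n >= 2L && !is.null(comps) && max(comps$csize) >= 2L) {
    big <- which(comps$membership == which.max(comps$csize))
    sub <- igraph::induced_subgraph(g, big)
    cpl <- igraph::mean_distance(sub, directed = FALSE)
  }
  sigma <- NA_real_
  if (n >= 4L && e >= 2L && rewires > 0L) {
    sigma <- with_seed(seed, {
      vals <- purrr::map_dbl(seq_len(rewires), function(r) {
        gr <- igraph::rewire(g, igraph::keeping_degseq(niter = max(100L, 10L * e)))
        cr <- mean(igraph::transitivity(gr, type = "local", isolates = "zero"), na.rm = TRUE)
        compr <- igraph::components(gr)
        bigr <- which(compr$membership == which.max(compr$csize))
        lr <- igraph::mean_distance(
          igraph::induced_subgraph(gr, bigr), directed = FALSE
        )
        if (is.na(cr) || cr <= 0 || is.na(lr) || lr <= 0) return(NA_real_)
        (cc / cr) / (cpl / lr)
      })
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    })
  }
  tibble::tibble(
    n_nodes = n, n_edges = e, avg_clustering = cc,
    char_path_length = cpl, sigma = sigma
  )
}

#' Write a graph as GraphML and as an edge-list TSV
#'
#' @param g an `igraph`
#' @param graphml_path output GraphML path (skipped if NULL)
#' @param edges_path output edge-list TSV path (skipped if NULL)
#' @return invisibly, the paths written
#' @export
write_graph_outputs <- function(g, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    el <- el[order(el$from, el$to), , drop = FALSE]
    readr::write_tsv(tibble::as_tibble(el), edges_path, progress = FALSE)
  }
  invisible(c(graphml_path, edges_path))
}

#' Read a GraphML graph
#' @param path path to a GraphML file
#' @return an `igraph`
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write MCODE complexes as TSV
#' @param x an `nb_mcode` result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_complexes <- function(x, path) {
  out <- tibble::tibble(
    rank = x$rank, seed = x$seed, score = x$score, size = x$size,
    members = vapply(x$members, paste, character(1), collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
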