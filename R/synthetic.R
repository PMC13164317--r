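# Seeded synthetic-data generators. Every pipeline input can be produced
# with planted, recorded ground truth: planted hubs and decoys across core
# interactomes, planted dense blocks for the clustering benchmark, a
# planted enriched term, and per-protein labels realized by sampling
# predictor scores on the correct side of each documented threshold.
# All generators are pure functions of (spec, seed): the ground-truth
# ledger can always be re-derived from the emitted files.

#' Synthetic-data specification
#'
#' Collects every knob of the synthetic generators. The defaults emulate
#' the shape of the study the pipeline targets: 10 core interactomes, 61
#' planted hubs against 500 decoys with evidence noise, a four-block
#' clustered hub network (sizes 20/16/14/11), and label frequencies in the
#' range reported for nuclear-body hub proteins.
#'
#' @param seed RNG seed; planted structure is reproducible from
#'   `(spec, seed)` alone
#' @param n_cores number of core interactomes
#' @param n_planted_hubs proteins planted to satisfy the hub rule
#' @param n_decoys proteins planted to violate it
#' @param k_min,evidence_min the hub rule the generator plants against
#' @param evidence_geom_prob geometric-tail parameter of the evidence
#'   count distribution (most pairs have 1-2 records, long tail)
#' @param evidence_max ceiling on evidence counts
#' @param cluster_sizes sizes of the planted dense blocks
#' @param p_in,p_out within- and between-block edge probabilities
#' @param n_terms number of gene-set terms in the synthetic library
#' @param term_size_range min/max term size
#' @param effect_size fraction of the planted query contained in the
#'   planted term (0 disables planting; the library is then a null)
#' @param query_size size of the planted query set
#' @param n_library_genes universe size for a standalone library
#' @param track_length_range min/max per-residue track length (also used
#'   as sequence length)
#' @param min_region_length droplet-promoting region length planted for
#'   clients
#' @param p_role sampling probabilities for driver/client/neither
#' @param p_pspredictor_pass probability the PSPredictor score passes 0.5
#' @param p_catgranule_llps probability of a planted catGRANULE LLPS label
#' @param p_psphunter sampling probabilities for likely/unlikely/non-LLPS
#' @param p_disorder sampling probabilities for highly/moderately/ordered
#' @param p_sumo,p_ubiquitin probability of a TRUE PTM flag
#' @param p_ptm_unknown probability a PTM flag is recorded as unknown
#' @return list of class `nb_synthetic_spec`
#' @export
synthetic_spec <- function(
    seed = 42L, n_cores = 10L, n_planted_hubs = 61L, n_decoys = 500L,
    k_min = 4L, evidence_min = 2L, evidence_geom_prob = 0.6,
    evidence_max = 6L, cluster_sizes = c(20L, 16L, 14L, 11L),
    p_in = 0.9, p_out = 0.02, n_terms = 50L, term_size_range = c(10L, 40L),
    effect_size = 0.9, query_size = 30L, n_library_genes = 300L,
    track_length_range = c(80L, 300L), min_region_length = 10L,
    p_role = c(driver = 0.50, client = 0.45, neither = 0.05),
    p_pspredictor_pass = 0.75,
    p_catgranule_llps = 0.6,
    p_psphunter = c(likely = 0.5, unlikely = 0.3, `non-LLPS` = 0.2),
    p_disorder = c(
      `highly disordered` = 0.80, `moderately disordered` = 0.13,
      `highly ordered` = 0.07
    ),
    p_sumo = 0.70, p_ubiquitin = 0.23, p_ptm_unknown = 0.05) {
  spec <- list(
    seed = as.integer(seed), n_cores = as.integer(n_cores),
    n_planted_hubs = as.integer(n_planted_hubs),
    n_decoys = as.integer(n_decoys),
    k_min = as.integer(k_min), evidence_min = as.integer(evidence_min),
    evidence_geom_prob = evidence_geom_prob,
    evidence_max = as.integer(evidence_max),
    cluster_sizes = as.integer(cluster_sizes), p_in = p_in, p_out = p_out,
    n_terms = as.integer(n_terms),
    term_size_range = as.integer(term_size_range),
    effect_size = effect_size, query_size = as.integer(query_size),
    n_library_genes = as.integer(n_library_genes),
    track_length_range = as.integer(track_length_range),
    min_region_length = as.integer(min_region_length),
    p_role = p_role, p_pspredictor_pass = p_pspredictor_pass,
    p_catgranule_llps = p_catgranule_llps, p_psphunter = p_psphunter,
    p_disorder = p_disorder, p_sumo = p_sumo, p_ubiquitin = p_ubiquitin,
    p_ptm_unknown = p_ptm_unknown
  )
  counts <- c(
    spec$n_cores, spec$n_planted_hubs, spec$n_decoys, spec$cluster_sizes,
    spec$n_terms, spec$query_size
  )
  if (any(counts < 0)) abort_config("all synthetic counts must be >= 0")
  if (spec$k_min > spec$n_cores) {
    abort_config("infeasible spec: k_min exceeds n_cores")
  }
  if (spec$evidence_max < spec$evidence_min) {
    abort_config("infeasible spec: evidence_max < evidence_min")
  }
  structure(spec, class = "nb_synthetic_spec")
}

# Truncated geometric evidence count at or above `lo`.
sample_evidence <- function(n, lo, spec) {
  lo + pmin(stats::rgeom(n, spec$evidence_geom_prob), spec$evidence_max - lo)
}

# sample one element of a vector (safe for length-1 vectors)
pick <- function(v) v[sample.int(length(v), 1L)]

#' Generate core interactomes with planted hubs and decoys
#'
#' Each planted hub appears in at least `k_min` cores with evidence count
#' at least `evidence_min`; each decoy violates at least one of the two
#' conditions (which one is recorded). Hub-hub and hub-core edges are
#' added so the downstream hub network is connected.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `cores` (named list of [interactome()]), and `ledger`
#'   (planted hub symbols, decoy table with violation types, core names)
#' @export
gen_interactomes <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "nb_synthetic_spec"))
  with_seed(spec$seed + 1L, {
    core_names <- sprintf("CORE%02d", seq_len(spec$n_cores))
    hubs <- sprintf("P%04d", seq_len(spec$n_planted_hubs))
    decoys <- sprintf("P%04d", spec$n_planted_hubs + seq_len(spec$n_decoys))
    rows <- list()
    add_rows <- function(cores, partner, evidence) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        core = cores, partner = partner, evidence = as.integer(evidence)
      )
    }
    for (h in hubs) {
      n_qual <- pick(spec$k_min:spec$n_cores)
      qual <- sample(core_names, n_qual)
      add_rows(qual, h, sample_evidence(n_qual, spec$evidence_min, spec))
      rest <- setdiff(core_names, qual)
      if (spec$evidence_min > 1L && length(rest)) {
        n_low <- stats::rbinom(1L, length(rest), 0.3)
        if (n_low > 0L) {
          low <- sample(rest, n_low)
          add_rows(low, h, sample(seq_len(spec$evidence_min - 1L), n_low, replace = TRUE))
        }
      }
    }
    decoy_type <- character(length(decoys))
    for (i in seq_along(decoys)) {
      d <- decoys[[i]]
      if (spec$evidence_min > 1L && i %% 2L == 0L) {
        # present in >= k_min cores, but too few with qualifying evidence
        decoy_type[[i]] <- "low_evidence"
        n_present <- pick(spec$k_min:spec$n_cores)
        present <- sample(core_names, n_present)
        n_qual <- pick(0:(spec$k_min - 1L))
        if (n_qual > 0L) {
          add_rows(present[seq_len(n_qual)], d,
                   sample_evidence(n_qual, spec$evidence_min, spec))
        }
        lowc <- present[setdiff(seq_len(n_present), seq_len(n_qual))]
        add_rows(lowc, d,
                 sample(seq_len(spec$evidence_min - 1L), length(lowc), replace = TRUE))
      } else {
        # well-supported, but in too few cores
        decoy_type[[i]] <- "few_cores"
        n_qual <- pick(seq_len(spec$k_min - 1L))
        qual <- sample(core_names, n_qual)
        add_rows(qual, d, sample_evidence(n_qual, spec$evidence_min, spec))
      }
    }
    # core-core interactions, so the downstream hub network is connected
    # and has density for clustering (cores interact with one another)
    if (spec$n_cores >= 2L) {
      for (i in seq_len(spec$n_cores - 1L)) {
        for (j in (i + 1L):spec$n_cores) {
          if (stats::runif(1) < 0.6) {
            add_rows(core_names[[i]], core_names[[j]],
                     sample_evidence(1L, spec$evidence_min, spec))
          }
        }
      }
    }
    tbl <- dplyr::bind_rows(rows) |>
      dplyr::group_by(.data$core, .data$partner) |>
      dplyr::summarise(evidence = max(.data$evidence), .groups = "drop")
    cores <- lapply(core_names, function(cn) {
      sub <- tbl[tbl$core == cn, c("partner", "evidence")]
      interactome(cn, sub)
    })
    names(cores) <- core_names
    list(
      cores = cores,
      ledger = list(
        planted_hubs = hubs,
        decoys = tibble::tibble(protein = decoys, type = decoy_type),
        core_names = core_names
      )
    )
  })
}

#' Generate a planted-partition benchmark graph
#'
#' Dense near-clique blocks (within-block edge probability `p_in`) on a
#' sparse background (between-block probability `p_out`), the standard
#' benchmark for density-based graph clustering.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `graph` (igraph) and `membership`
#'   (tibble node, block)
#' @export
gen_cluster_graph <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "nb_synthetic_spec"))
  with_seed(spec$seed + 2L, {
    sizes <- spec$cluster_sizes
    n <- sum(sizes)
    nodes <- sprintf("C%03d", seq_len(n))
    block <- rep(seq_along(sizes), sizes)
    edges <- list()
    for (i in seq_len(n - 1L)) {
      js <- (i + 1L):n
      p <- ifelse(block[js] == block[i], spec$p_in, spec$p_out)
      hit <- js[stats::runif(length(js)) < p]
      if (length(hit)) {
        edges[[length(edges) + 1L]] <- cbind(nodes[i], nodes[hit])
      }
    }
    em <- do.call(rbind, edges)
    g <- igraph::graph_from_data_frame(
      as.data.frame(em, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
    )
    list(
      graph = g,
      membership = tibble::tibble(node = nodes, block = block)
    )
  })
}

#' Generate a gene-set library with one planted enriched term
#'
#' @param spec a [synthetic_spec()]
#' @param universe optional symbol universe (default: synthetic gene ids)
#' @param query optional planted query set (default: sampled from the
#'   universe at `query_size`)
#' @return list with `library` (`nb_geneset_library`), `query`
#'   ([protein_set()]) and `planted_term` (NA when `effect_size` is 0)
#' @export
gen_geneset_library <- function(spec = synthetic_spec(), universe = NULL,
                                query = NULL) {
  stopifnot(inherits(spec, "nb_synthetic_spec"))
  with_seed(spec$seed + 3L, {
    universe <- if (is.null(universe)) {
      sprintf("G%04d", seq_len(spec$n_library_genes))
    } else {
      members(universe)
    }
    query <- if (is.null(query)) {
      sample(universe, min(spec$query_size, length(universe)))
    } else {
      intersect(members(query), universe)
    }
    terms <- list()
    for (t in seq_len(spec$n_terms)) {
      sz <- sample(spec$term_size_range[1]:spec$term_size_range[2], 1L)
      terms[[sprintf("T%03d", t)]] <- sample(universe, min(sz, length(universe)))
    }
    planted_term <- NA_character_
    if (spec$effect_size > 0 && length(query) > 0L) {
      planted_term <- "T_PLANTED"
      n_in <- max(1L, round(spec$effect_size * length(query)))
      mem <- sample(query, n_in)
      sz <- sample(spec$term_size_range[1]:spec$term_size_range[2], 1L)
      filler <- setdiff(universe, query)
      extra <- max(0L, sz - n_in)
      mem <- c(mem, sample(filler, min(extra, length(filler))))
      terms[[planted_term]] <- mem
    }
    list(
      library = geneset_library(terms, universe = universe, name = "synthetic"),
      query = protein_set(query, name = "planted_query"),
      planted_term = planted_term
    )
  })
}

sample_label <- function(probs) {
  sample(names(probs), 1L, prob = probs)
}

runif1 <- function(lo, hi) stats::runif(1L, lo, hi)

#' Generate predictor scores, residue tracks, PTM flags and sequences
#'
#' For each protein a label tuple is sampled (LLPS role, PSPredictor
#' pass/fail, catGRANULE and PSPHunter classes, disorder class, PTM
#' flags), then scores and tracks are drawn on the correct side of every
#' documented threshold so the labels are realized exactly. The FuzDrop
#' score doubles as the combined-scheme input and the pLLPS role input, so
#' role and combined labels are sampled jointly and are always mutually
#' consistent. The ledger records the intended labels.
#'
#' @param spec a [synthetic_spec()]
#' @param proteins character vector of proteins to annotate
#' @return list with `scores` (`nb_score_table`), `tracks`
#'   (`nb_track_table`: predictors `disorder` and `pdp`), `ptm`,
#'   `sequences` (tibble protein/sequence) and `ledger` (intended labels)
#' @export
gen_tracks_and_scores <- function(spec = synthetic_spec(), proteins) {
  stopifnot(inherits(spec, "nb_synthetic_spec"))
  proteins <- members(proteins)
  with_seed(spec$seed + 4L, {
    aa <- names(kyte_doolittle)
    score_rows <- list()
    track_rows <- list()
    ledger_rows <- list()
    ptm_rows <- list()
    seq_rows <- list()
    for (p in proteins) {
      L <- sample(spec$track_length_range[1]:spec$track_length_range[2], 1L)
      role <- sample_label(spec$p_role)
      psp_pass <- stats::runif(1) < spec$p_pspredictor_pass
      # FuzDrop pLLPS drives both the role and the combined call
      fuzdrop <- if (role == "driver") runif1(0.65, 1) else runif1(0.05, 0.55)
      fd_pass <- fuzdrop > 0.6
      combined <- if (psp_pass && fd_pass) {
        "LLPS"
      } else if (!psp_pass && !fd_pass) "non-LLPS" else "controversial"
      pspredictor <- if (psp_pass) runif1(0.55, 1) else runif1(0, 0.45)
      cat_llps <- stats::runif(1) < spec$p_catgranule_llps
      catgranule <- if (cat_llps) runif1(0.55, 1) else runif1(0, 0.45)
      psph_label <- sample_label(spec$p_psphunter)
      psphunter <- switch(psph_label,
        likely = runif1(0.63, 1),
        unlikely = runif1(0.38, 0.59),
        `non-LLPS` = runif1(0, 0.34)
      )
      # pDP track: clients get one planted droplet-promoting region
      pdp <- runif1(0, 0.55) * stats::runif(L)
      pdp <- pmin(pdp, 0.55)
      if (role == "client") {
        run_len <- spec$min_region_length +
          sample(0:spec$min_region_length, 1L)
        run_len <- min(run_len, L)
        start <- sample(seq_len(L - run_len + 1L), 1L)
        pdp[start:(start + run_len - 1L)] <- stats::runif(run_len, 0.62, 1)
      } else if (role == "driver" && stats::runif(1) < 0.5) {
        # drivers may also carry regions; the role call short-circuits
        run_len <- min(spec$min_region_length + 2L, L)
        start <- sample(seq_len(L - run_len + 1L), 1L)
        pdp[start:(start + run_len - 1L)] <- stats::runif(run_len, 0.62, 1)
      }
      dis_class <- sample_label(spec$p_disorder)
      n_dis <- switch(dis_class,
        `highly disordered` = sample(ceiling(0.31 * L):floor(0.9 * L), 1L),
        `moderately disordered` = sample(ceiling(0.101 * L):floor(0.30 * L), 1L),
        `highly ordered` = sample(0:max(0L, ceiling(0.099 * L) - 1L), 1L)
      )
      disorder <- stats::runif(L, 0, 0.45)
      if (n_dis > 0L) {
        disorder[sample(L, n_dis)] <- stats::runif(n_dis, 0.55, 1)
      }
      sumo <- if (stats::runif(1) < spec$p_ptm_unknown) {
        NA
      } else {
        stats::runif(1) < spec$p_sumo
      }
      ubi <- if (stats::runif(1) < spec$p_ptm_unknown) {
        NA
      } else {
        stats::runif(1) < spec$p_ubiquitin
      }
      seqchars <- sample(aa, L, replace = TRUE)
      score_rows[[p]] <- tibble::tibble(
        protein = p,
        predictor = c("catgranule", "psphunter", "pspredictor", "fuzdrop"),
        score = c(catgranule, psphunter, pspredictor, fuzdrop)
      )
      track_rows[[p]] <- tibble::tibble(
        protein = p, predictor = c("disorder", "pdp"),
        scores = list(round(disorder, 4), round(pdp, 4))
      )
      ptm_rows[[p]] <- tibble::tibble(protein = p, sumo = sumo, ubiquitin = ubi)
      seq_rows[[p]] <- tibble::tibble(
        protein = p, sequence = paste(seqchars, collapse = "")
      )
      ledger_rows[[p]] <- tibble::tibble(
        protein = p,
        catgranule_label = if (cat_llps) "LLPS" else "non-LLPS",
        psphunter_label = psph_label,
        combined_label = combined,
        role_label = role,
        disorder_class = dis_class,
        sumo = sumo, ubiquitin = ubi
      )
    }
    list(
      scores = score_table(dplyr::bind_rows(score_rows)),
      tracks = tibble::new_tibble(
        dplyr::bind_rows(track_rows), class = "nb_track_table"
      ),
      ptm = dplyr::bind_rows(ptm_rows),
      sequences = dplyr::bind_rows(seq_rows),
      ledger = dplyr::bind_rows(ledger_rows)
    )
  })
}

#' Write a complete synthetic input bundle
#'
#' Emits every file the pipeline consumes, plus `ledger.json` recording
#' the planted ground truth: TAB3-style interaction snapshots (with
#' deliberate duplicate records, to exercise evidence counting), aging /
#' proteome gene lists, a GMT library with a planted term over the protein
#' universe, predictor score and track tables, PTM flags and FASTA
#' sequences. Byte-identical across reruns with the same spec.
#'
#' @param spec a [synthetic_spec()]
#' @param dir output directory (created if missing)
#' @return invisibly, a list with all file `paths` and the `ledger`
#' @export
simulate_inputs <- function(spec = synthetic_spec(), dir) {
  stopifnot(inherits(spec, "nb_synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gi <- gen_interactomes(spec)
  hubs <- gi$ledger$planted_hubs
  decoys <- gi$ledger$decoys$protein
  universe <- sort(unique(c(hubs, decoys)))
  core_paths <- character()
  with_seed(spec$seed + 5L, {
    for (cn in names(gi$cores)) {
      path <- file.path(dir, paste0(cn, ".tab3.txt"))
      write_interaction_table(gi$cores[[cn]], path)
      # duplicate a few records verbatim: evidence counts must not inflate
      lines <- readLines(path)
      if (length(lines) > 3L) {
        dup <- sample(2:length(lines), min(5L, length(lines) - 1L))
        writeLines(c(lines, lines[dup]), path)
      }
      core_paths[[cn]] <- path
    }
    cellage <- sort(c(
      hubs[stats::runif(length(hubs)) < 0.45],
      decoys[stats::runif(length(decoys)) < 0.10]
    ))
    genage <- sort(c(
      hubs[stats::runif(length(hubs)) < 0.35],
      decoys[stats::runif(length(decoys)) < 0.08]
    ))
    nb_proteome <- sort(c(
      names(gi$cores), hubs[stats::runif(length(hubs)) < 0.5]
    ))
    writeLines(cellage, file.path(dir, "cellage.txt"))
    writeLines(genage, file.path(dir, "genage.txt"))
    writeLines(nb_proteome, file.path(dir, "nb_proteome.txt"))
  })
  gl <- gen_geneset_library(spec, universe = universe, query = hubs)
  write_gmt(gl$library, file.path(dir, "library.gmt"))
  ts <- gen_tracks_and_scores(spec, hubs)
  readr::write_tsv(tibble::as_tibble(ts$scores), file.path(dir, "scores.tsv"),
                   progress = FALSE)
  write_residue_tracks(ts$tracks, file.path(dir, "tracks.tsv"))
  ptm_out <- tibble::tibble(
    protein = ts$ptm$protein,
    sumo = ifelse(is.na(ts$ptm$sumo), "unknown", tolower(ts$ptm$sumo)),
    ubiquitin = ifelse(is.na(ts$ptm$ubiquitin), "unknown", tolower(ts$ptm$ubiquitin))
  )
  readr::write_tsv(ptm_out, file.path(dir, "ptm.tsv"), progress = FALSE)
  write_fasta(ts$sequences, file.path(dir, "sequences.fasta"))
  ledger <- list(
    seed = spec$seed,
    planted_hubs = hubs,
    n_planted_hubs = length(hubs),
    decoy_types = as.list(table(gi$ledger$decoys$type)),
    core_names = gi$ledger$core_names,
    planted_term = gl$planted_term,
    label_counts = as.list(
      generics::glance(
        structure(ts$ledger, class = c("nb_annotation", class(ts$ledger)))
      )[c(
        "n_llps_combined", "n_llps_catgranule", "n_driver", "n_client",
        "n_driver_or_client", "n_highly_disordered",
        "n_moderately_disordered", "n_disordered_any", "n_sumo",
        "n_ubiquitin"
      )]
    ),
    annotation_labels = ts$ledger
  )
  ledger_path <- file.path(dir, "ledger.json")
  jsonlite::write_json(
    ledger[setdiff(names(ledger), "annotation_labels")],
    ledger_path, auto_unbox = TRUE, pretty = TRUE
  )
  readr::write_tsv(ts$ledger, file.path(dir, "ledger_labels.tsv"),
                   progress = FALSE)
  invisible(list(
    paths = list(
      cores = core_paths,
      cellage = file.path(dir, "cellage.txt"),
      genage = file.path(dir, "genage.txt"),
      nb_proteome = file.path(dir, "nb_proteome.txt"),
      gmt = file.path(dir, "library.gmt"),
      scores = file.path(dir, "scores.tsv"),
      tracks = file.path(dir, "tracks.tsv"),
      ptm = file.path(dir, "ptm.tsv"),
      sequences = file.path(dir, "sequences.fasta"),
      ledger = ledger_path
    ),
    ledger = ledger
  ))
}
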