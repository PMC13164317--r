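# Per-protein consensus annotation: LLPS calls from predictor scores,
# driver/client assignment from FuzDrop-style profiles, PPIDR disorder
# class, GRAVY hydropathy and Henderson-Hasselbalch charge at pH.
#
# Threshold conventions (strict vs inclusive) follow the predictors'
# published usage exactly:
#   catGRANULE:  LLPS iff score  > 0.5
#   PSPHunter:   likely iff      > 0.61; non-LLPS iff < 0.36; else unlikely
#   combined:    LLPS iff PSPredictor > 0.5 AND FuzDrop > 0.6;
#                non-LLPS iff both fail; controversial iff exactly one passes
#   driver:      pLLPS >= 0.60 (inclusive)
#   client:      a run of >= min_region_length residues with pDP >= 0.60
#   PPIDR:       fraction of residues with disorder score strictly > 0.5;
#                < 10 ordered, 10-30 moderate (bounds in the middle class),
#                > 30 highly disordered

#' Kyte-Doolittle hydropathy scale
#'
#' Named vector of hydropathy values for the 20 standard amino acids
#' (one-letter codes), from the Kyte & Doolittle scale.
#' @export
kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' pKa table for charge calculations
#'
#' Bjellqvist-style pKa values (as used by common isoelectric-point
#' calculators) for the protein termini and the ionizable side chains.
#' `positive` groups gain a proton below their pKa; `negative` groups lose
#' one above it.
#' @export
pka_table <- list(
  positive = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
  negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
)

check_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    abort_format("sequence must be a single non-empty string")
  }
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!(aa %in% names(kyte_doolittle)))
  if (length(bad)) {
    abort_format(sprintf(
      "non-standard residue '%s' at position %d", aa[bad[1]], bad[1]
    ))
  }
  aa
}

#' GRAVY hydropathy index
#'
#' Mean Kyte-Doolittle hydropathy over all residues of a sequence of the
#' 20 standard amino acids. A non-standard residue is an error naming its
#' position, never silently skipped.
#'
#' @param sequence amino-acid string (one-letter codes)
#' @return the grand average of hydropathicity, in `[-4.5, 4.5]`
#' @export
#' @examples
#' gravy("ACDE") # (1.8 + 2.5 - 3.5 - 3.5) / 4
gravy <- function(sequence) {
  aa <- check_sequence(sequence)
  mean(kyte_doolittle[aa])
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R), using the shipped
#' [pka_table]. Each positive group contributes
#' `1 / (1 + 10^(pH - pKa))`, each negative group
#' `-1 / (1 + 10^(pKa - pH))`; the total is monotonically non-increasing
#' in pH.
#'
#' @param sequence amino-acid string (one-letter codes)
#' @param pH pH value in `[0, 14]` (default 7.0)
#' @return net charge in elementary charge units
#' @export
charge_at_ph <- function(sequence, pH = 7.0) {
  aa <- check_sequence(sequence)
  if (pH < 0 || pH > 14) abort_range("pH must lie in [0, 14]")
  pos <- 0
  for (grp in names(pka_table$positive)) {
    cnt <- if (grp == "Nterm") 1 else sum(aa == grp)
    if (cnt) pos <- pos + cnt / (1 + 10^(pH - pka_table$positive[[grp]]))
  }
  neg <- 0
  for (grp in names(pka_table$negative)) {
    cnt <- if (grp == "Cterm") 1 else sum(aa == grp)
    if (cnt) neg <- neg + cnt / (1 + 10^(pka_table$negative[[grp]] - pH))
  }
  pos - neg
}

#' Isoelectric point
#'
#' pH at which [charge_at_ph()] crosses zero, found by bisection.
#'
#' @param sequence amino-acid string
#' @param tol root tolerance on pH
#' @return the isoelectric pH
#' @export
isoelectric_point <- function(sequence, tol = 1e-8) {
  stats::uniroot(
    function(ph) charge_at_ph(sequence, ph),
    interval = c(0, 14), tol = tol
  )$root
}

#' Percentage of predicted intrinsically disordered residues
#'
#' PPIDR is `100 * (# residues with disorder score strictly > 0.5) /
#' length`. Classes: below 10% highly ordered, 10-30% (inclusive)
#' moderately disordered, above 30% highly disordered.
#'
#' @param scores numeric vector of per-residue disorder scores in `[0, 1]`
#' @return one-row tibble (ppidr, disorder_class)
#' @export
ppidr <- function(scores) {
  if (length(scores) < 1L) abort_format("ppidr: residue track is empty")
  if (any(is.na(scores)) || any(scores < 0 | scores > 1)) {
    abort_range("ppidr: residue scores must lie in [0, 1]")
  }
  val <- 100 * sum(scores > 0.5) / length(scores)
  tibble::tibble(ppidr = val, disorder_class = disorder_class(val))
}

disorder_class <- function(ppidr) {
  dplyr::case_when(
    is.na(ppidr) ~ "unknown",
    ppidr < 10 ~ "highly ordered",
    ppidr <= 30 ~ "moderately disordered",
    TRUE ~ "highly disordered"
  )
}

#' Consensus LLPS calls from predictor scores
#'
#' Applies the three labeling schemes to whatever scores are present;
#' any missing required score yields `"unknown"` for that scheme, never a
#' default label.
#'
#' @param catgranule catGRANULE score in `[0,1]` (NA if absent)
#' @param psphunter PSPHunter score (NA if absent)
#' @param pspredictor PSPredictor score (NA if absent)
#' @param fuzdrop FuzDrop pLLPS score (NA if absent)
#' @return one-row tibble (catgranule_label, psphunter_label,
#'   combined_label)
#' @export
llps_consensus <- function(catgranule = NA_real_, psphunter = NA_real_,
                           pspredictor = NA_real_, fuzdrop = NA_real_) {
  cat_label <- if (is.na(catgranule)) {
    "unknown"
  } else if (catgranule > 0.5) "LLPS" else "non-LLPS"
  psp_label <- if (is.na(psphunter)) {
    "unknown"
  } else if (psphunter > 0.61) {
    "likely"
  } else if (psphunter < 0.36) "non-LLPS" else "unlikely"
  comb_label <- if (is.na(pspredictor) || is.na(fuzdrop)) {
    "unknown"
  } else {
    pass_psp <- pspredictor > 0.5
    pass_fd <- fuzdrop > 0.6
    if (pass_psp && pass_fd) {
      "LLPS"
    } else if (!pass_psp && !pass_fd) "non-LLPS" else "controversial"
  }
  tibble::tibble(
    catgranule_label = cat_label,
    psphunter_label = psp_label,
    combined_label = comb_label
  )
}

#' Driver/client role from FuzDrop-style profiles
#'
#' A protein drives phase separation when its overall droplet-promoting
#' probability `pLLPS >= 0.60` (inclusive); otherwise it is a client when
#' it contains a droplet-promoting region, i.e. a run of at least
#' `min_region_length` consecutive residues with `pDP >= 0.60`; otherwise
#' neither. Missing inputs yield `"unknown"`.
#'
#' @param pllps protein-level pLLPS score (NA if absent)
#' @param pdp_track numeric vector of per-residue pDP scores (NULL if
#'   absent; only needed when `pllps < 0.60`)
#' @param min_region_length minimum droplet-promoting region length
#'   (default 10 residues)
#' @return one of `"driver"`, `"client"`, `"neither"`, `"unknown"`
#' @export
llps_role <- function(pllps = NA_real_, pdp_track = NULL,
                      min_region_length = 10L) {
  if (min_region_length < 1L) abort_config("min_region_length must be >= 1")
  if (is.na(pllps)) return("unknown")
  if (pllps >= 0.60) return("driver")
  if (is.null(pdp_track)) return("unknown")
  if (any(is.na(pdp_track)) || any(pdp_track < 0 | pdp_track > 1)) {
    abort_range("llps_role: pDP scores must lie in [0, 1]")
  }
  runs <- rle(pdp_track >= 0.60)
  has_region <- any(runs$values & runs$lengths >= min_region_length)
  if (has_region) "client" else "neither"
}

#' Annotate hub proteins
#'
#' Joins every per-protein call into one row per hub: the three LLPS
#' labels, driver/client role, PPIDR and disorder class, SUMO/ubiquitin
#' flags, GRAVY and net charge. Any missing input yields `"unknown"` (or
#' NA for numeric columns); unknowns are excluded from the summary counts
#' reported by `glance()`.
#'
#' @param hubs an `nb_hub_table` or character vector of proteins
#' @param scores a `nb_score_table` with predictors `catgranule`,
#'   `psphunter`, `pspredictor`, `fuzdrop` (any subset)
#' @param tracks a track table (see [read_residue_tracks()]) holding the
#'   disorder and pDP profiles
#' @param ptm PTM table (protein, sumo, ubiquitin) or NULL
#' @param sequences tibble (protein, sequence) or NULL
#' @param min_region_length droplet-promoting region length for the client
#'   call (default 10)
#' @param ppidr_predictor name of the track predictor feeding PPIDR
#'   (default "disorder"; VSL2-style per-residue disorder scores)
#' @param pdp_predictor name of the pDP track predictor (default "pdp")
#' @param pH pH for the net-charge column (default 7.0)
#' @return tibble of class `nb_annotation`, one row per protein
#' @export
annotate_hubs <- function(hubs, scores = NULL, tracks = NULL, ptm = NULL,
                          sequences = NULL, min_region_length = 10L,
                          ppidr_predictor = "disorder",
                          pdp_predictor = "pdp", pH = 7.0) {
  proteins <- if (inherits(hubs, "nb_hub_table")) hub_proteins(hubs) else members(hubs)
  if (length(proteins) == 0L) {
    abort_config("annotate_hubs: hub set is empty")
  }
  rows <- purrr::map_dfr(proteins, function(p) {
    cat_s <- if (is.null(scores)) NA_real_ else get_score(scores, p, "catgranule")
    psph_s <- if (is.null(scores)) NA_real_ else get_score(scores, p, "psphunter")
    pspr_s <- if (is.null(scores)) NA_real_ else get_score(scores, p, "pspredictor")
    fd_s <- if (is.null(scores)) NA_real_ else get_score(scores, p, "fuzdrop")
    cons <- llps_consensus(cat_s, psph_s, pspr_s, fd_s)
    pdp_tr <- if (is.null(tracks)) NULL else get_track(tracks, p, pdp_predictor)
    role <- llps_role(fd_s, pdp_tr, min_region_length)
    dis_tr <- if (is.null(tracks)) NULL else get_track(tracks, p, ppidr_predictor)
    dis <- if (is.null(dis_tr)) {
      tibble::tibble(ppidr = NA_real_, disorder_class = "unknown")
    } else {
      ppidr(dis_tr)
    }
    ptm_row <- if (is.null(ptm)) NULL else ptm[ptm$protein == p, , drop = FALSE]
    sumo <- if (is.null(ptm_row) || nrow(ptm_row) == 0L) NA else ptm_row$sumo[[1]]
    ubi <- if (is.null(ptm_row) || nrow(ptm_row) == 0L) NA else ptm_row$ubiquitin[[1]]
    seq_row <- if (is.null(sequences)) NULL else sequences$sequence[sequences$protein == p]
    grav <- if (is.null(seq_row) || length(seq_row) == 0L) NA_real_ else gravy(seq_row[[1]])
    chg <- if (is.null(seq_row) || length(seq_row) == 0L) NA_real_ else charge_at_ph(seq_row[[1]], pH)
    tibble::tibble(
      protein = p,
      catgranule_label = cons$catgranule_label,
      psphunter_label = cons$psphunter_label,
      combined_label = cons$combined_label,
      role_label = role,
      ppidr = dis$ppidr,
      disorder_class = dis$disorder_class,
      sumo = sumo,
      ubiquitin = ubi,
      gravy = grav,
      net_charge = chg
    )
  })
  tibble::new_tibble(
    rows,
    min_region_length = as.integer(min_region_length), pH = pH,
    class = "nb_annotation"
  )
}

#' @rdname annotate_hubs
#' @param x an `nb_annotation`
#' @param ... unused
#' @return `glance()`: one-row tibble of category counts across the
#'   annotated proteins (unknowns excluded, never coerced)
#' @method glance nb_annotation
#' @export
glance.nb_annotation <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_llps_combined = sum(x$combined_label == "LLPS"),
    n_llps_catgranule = sum(x$catgranule_label == "LLPS"),
    n_llps_psphunter_likely = sum(x$psphunter_label == "likely"),
    n_controversial = sum(x$combined_label == "controversial"),
    n_driver = sum(x$role_label == "driver"),
    n_client = sum(x$role_label == "client"),
    n_driver_or_client = sum(x$role_label %in% c("driver", "client")),
    n_highly_disordered = sum(x$disorder_class == "highly disordered"),
    n_moderately_disordered = sum(x$disorder_class == "moderately disordered"),
    n_disordered_any = sum(
      x$disorder_class %in% c("highly disordered", "moderately disordered")
    ),
    n_sumo = sum(x$sumo, na.rm = TRUE),
    n_ubiquitin = sum(x$ubiquitin, na.rm = TRUE),
    n_ptm_unknown = sum(is.na(x$sumo) | is.na(x$ubiquitin))
  )
}

#' Bar chart of annotation category counts
#'
#' @param object an `nb_annotation`
#' @param ... unused
#' @return ggplot bar chart of the main category counts
#' @method autoplot nb_annotation
#' @export
autoplot.nb_annotation <- function(object, ...) {
  g <- generics::glance(object)
  df <- tibble::tibble(
    category = c(
      "LLPS (combined)", "driver or client", "disordered (any)",
      "SUMO", "ubiquitin"
    ),
    count = c(
      g$n_llps_combined, g$n_driver_or_client, g$n_disordered_any,
      g$n_sumo, g$n_ubiquitin
    )
  )
  df$category <- factor(df$category, levels = rev(df$category))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$category)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = sprintf("proteins (of %d)", g$n_proteins), y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Write an annotation table as TSV
#' @param x an `nb_annotation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotation <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
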