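#' Target-prediction configuration
#'
#' Defaults reproduce the prediction filters used for the branchial-arch
#' interactome: marginal site classes (6mer, off-6mer) are discarded, sites
#' weaker than -7 kcal/mol (i.e. energy greater than -7; -7.0 itself is
#' retained) are discarded, and any 3'UTR with fewer than two retained
#' binding sites in total is dropped.
#'
#' @param energy_max Retain sites with hybridisation energy `<= energy_max`
#'   (kcal/mol).
#' @param min_sites_per_utr Minimum retained sites a 3'UTR must carry.
#' @param per_mirna_site_count If `TRUE`, the site-count filter applies per
#'   (miRNA, UTR) pair instead of per UTR across all miRNAs (the default,
#'   matching the literal reading of the rule).
#' @param drop_classes Site classes removed outright.
#' @param flank_up Upstream (target 5') context, in nt, included in the
#'   duplex-energy calculation for each site.
#' @param seed_only Score only the seed helix (miRNA positions 1-8 against
#'   the 8-nt window) instead of the full miRNA over the flanked region.
#' @param energy_params Nearest-neighbour parameter set
#'   (see [turner_2004_params()]).
#' @return A list of class `mirarch_prediction_config`.
#' @export
prediction_config <- function(energy_max = -7,
                              min_sites_per_utr = 2L,
                              per_mirna_site_count = FALSE,
                              drop_classes = c("6mer", "off-6mer"),
                              flank_up = 30L,
                              seed_only = FALSE,
                              energy_params = turner_2004_params()) {
  stopifnot(min_sites_per_utr >= 1, all(drop_classes %in% SITE_CLASSES))
  structure(
    list(
      energy_max = energy_max,
      min_sites_per_utr = as.integer(min_sites_per_utr),
      per_mirna_site_count = per_mirna_site_count,
      drop_classes = drop_classes,
      flank_up = as.integer(flank_up),
      seed_only = seed_only,
      energy_params = energy_params
    ),
    class = "mirarch_prediction_config"
  )
}

#' Filter predicted sites and aggregate to miRNA-gene interactions
#'
#' Applies the three retention filters in order: drop sites of the discarded
#' classes; drop sites with hybridisation energy above `energy_max`
#' (weaker than the cutoff); then drop every gene whose 3'UTR retains fewer
#' than `min_sites_per_utr` sites (counted across all miRNAs by default).
#' Remaining sites are aggregated to one row per (miRNA, gene).
#'
#' @param sites Site tibble from [scan_utr()]/[scan_targets()] with columns
#'   `gene_id`, `mirna_id`, `site_class`, `energy`.
#' @param config A [prediction_config()].
#' @return Tibble of class `mirarch_interactions`: `mirna_id`, `gene_id`,
#'   `n_sites`, `best_class` (most specific retained class), `min_energy`.
#' @export
filter_interactions <- function(sites, config = prediction_config()) {
  kept <- retained_sites(sites, config)
  if (nrow(kept) == 0) {
    out <- tibble(mirna_id = character(0), gene_id = character(0),
                  n_sites = integer(0), best_class = character(0),
                  min_energy = numeric(0))
    class(out) <- c("mirarch_interactions", class(out))
    return(out)
  }
  out <- dplyr::summarise(
    dplyr::group_by(kept, .data$mirna_id, .data$gene_id),
    n_sites = dplyr::n(),
    best_class = SITE_CLASSES[min(match(.data$site_class, SITE_CLASSES))],
    min_energy = min(.data$energy),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$mirna_id, .data$gene_id)
  class(out) <- c("mirarch_interactions", class(out))
  out
}

#' @rdname filter_interactions
#' @details `retained_sites()` returns the individual site rows surviving
#'   the filters; `filter_interactions()` is its aggregation. The site-level
#'   filter is idempotent: re-filtering retained sites changes nothing.
#' @export
retained_sites <- function(sites, config = prediction_config()) {
  assert_columns(sites, c("gene_id", "mirna_id", "site_class", "energy"),
                 "site table")
  kept <- sites[!sites$site_class %in% config$drop_classes &
                  sites$energy <= config$energy_max, , drop = FALSE]
  if (nrow(kept) == 0) return(kept)
  group_cols <- if (config$per_mirna_site_count) {
    c("gene_id", "mirna_id")
  } else {
    "gene_id"
  }
  kept <- dplyr::group_by(kept, dplyr::across(dplyr::all_of(group_cols)))
  kept <- dplyr::filter(kept, dplyr::n() >= config$min_sites_per_utr)
  dplyr::ungroup(kept)
}
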