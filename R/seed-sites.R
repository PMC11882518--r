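SITE_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer", "off-6mer")

# Target-side match strings for a miRNA, read 5'->3' on the UTR. With the
# 8-nt window written w1..w8 (5'->3'), target position t1 (opposite miRNA
# position 1) is w8, t8 is w1.
seed_patterns <- function(mirna_sequence) {
  if (nchar(mirna_sequence) < 8) abort("miRNA must be at least 8 nt.")
  m <- strsplit(substr(mirna_sequence, 1, 8), NULL)[[1]]
  list(
    match_m2_m8 = rc_rna(substr(mirna_sequence, 2, 8)), # w1..w7 of 7/8mer sites
    match_m2_m7 = rc_rna(substr(mirna_sequence, 2, 7)), # w2..w7 of 6mer sites
    match_m3_m8 = rc_rna(substr(mirna_sequence, 3, 8)), # w1..w6 of off-6mer sites
    comp_m8 = comp_rna(m[[8]]),
    comp_m2 = comp_rna(m[[2]])
  )
}

#' Classify one 8-nt target window against a miRNA seed
#'
#' Implements the canonical seed-match taxonomy. Writing the window 5'->3'
#' as `w1..w8`, target position t1 (the base opposite miRNA position 1) is
#' `w8` and t2-t8 run from `w7` back to `w1`:
#'
#' * **8mer**: t2-t8 Watson-Crick complement miRNA 2-8 and t1 is an A.
#' * **7mer-m8**: t2-t8 complement miRNA 2-8, t1 not A.
#' * **7mer-A1**: t2-t7 complement miRNA 2-7, position 8 unpaired, t1 is A.
#' * **6mer**: t2-t7 complement miRNA 2-7 only.
#' * **off-6mer**: t3-t8 complement miRNA 3-8 only (offset seed).
#'
#' Only Watson-Crick pairs count for seed matching (no G:U). When a window
#' satisfies several definitions the most specific class wins, in the order
#' listed above.
#'
#' @param mirna_sequence Mature miRNA sequence, 5'->3' RNA.
#' @param window 8-nt UTR substring, 5'->3'.
#' @return One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`,
#'   `"off-6mer"`, or `NA_character_` when no class matches.
#' @export
classify_seed_site <- function(mirna_sequence, window) {
  if (nchar(window) != 8) abort("Seed-site windows must be exactly 8 nt.")
  p <- seed_patterns(mirna_sequence)
  w17 <- substr(window, 1, 7)
  w16 <- substr(window, 1, 6)
  w27 <- substr(window, 2, 7)
  w1 <- substr(window, 1, 1)
  w7 <- substr(window, 7, 7)
  t1 <- substr(window, 8, 8)
  if (w17 == p$match_m2_m8) {
    return(if (t1 == "A") "8mer" else "7mer-m8")
  }
  if (w27 == p$match_m2_m7 && w1 != p$comp_m8) {
    return(if (t1 == "A") "7mer-A1" else "6mer")
  }
  if (w16 == p$match_m3_m8 && w7 != p$comp_m2) {
    return("off-6mer")
  }
  NA_character_
}

#' Scan a 3'UTR for seed-match sites of one miRNA
#'
#' Every 8-nt window of the UTR is classified (see [classify_seed_site()]);
#' overlapping sites are each reported. Optionally, each site's duplex
#' hybridisation energy against the full miRNA is computed over the site
#' plus `flank_up` nt of upstream (target 5') context.
#'
#' @param mirna One-row tibble or list with `id` and `sequence` (mature
#'   miRNA, 5'->3' RNA).
#' @param utr One-row tibble or list with `gene_id` and `sequence`
#'   (3'UTR, 5'->3' RNA).
#' @param energy Compute per-site duplex energies (default `TRUE`).
#' @param config A [prediction_config()]; supplies the energy model and
#'   flank length.
#' @return Tibble of sites: `gene_id`, `mirna_id`, `position` (0-based
#'   window start), `site_class`, and `energy` when requested.
#' @export
scan_utr <- function(mirna, utr, energy = TRUE, config = prediction_config()) {
  n <- nchar(utr$sequence)
  empty <- tibble(
    gene_id = character(0), mirna_id = character(0),
    position = integer(0), site_class = character(0), energy = numeric(0)
  )
  if (n < 8) return(if (energy) empty else empty[, 1:4])
  p <- seed_patterns(mirna$sequence)
  starts <- seq_len(n - 7L)
  win <- substring(utr$sequence, starts, starts + 7L)

  w17 <- substr(win, 1, 7)
  w16 <- substr(win, 1, 6)
  w27 <- substr(win, 2, 7)
  w1 <- substr(win, 1, 1)
  w7 <- substr(win, 7, 7)
  t1 <- substr(win, 8, 8)

  cls <- rep(NA_character_, length(win))
  core7 <- w17 == p$match_m2_m8
  cls[core7 & t1 == "A"] <- "8mer"
  cls[core7 & t1 != "A"] <- "7mer-m8"
  core6 <- !core7 & w27 == p$match_m2_m7 & w1 != p$comp_m8
  cls[core6 & t1 == "A"] <- "7mer-A1"
  cls[core6 & t1 != "A"] <- "6mer"
  off6 <- is.na(cls) & w16 == p$match_m3_m8 & w7 != p$comp_m2
  cls[off6] <- "off-6mer"

  hit <- which(!is.na(cls))
  out <- tibble(
    gene_id = rep(utr$gene_id, length(hit)),
    mirna_id = rep(mirna$id, length(hit)),
    position = starts[hit] - 1L, # 0-based
    site_class = cls[hit]
  )
  if (energy) {
    out$energy <- vapply(
      out$position,
      function(pos) site_energy(mirna$sequence, utr$sequence, pos, config),
      numeric(1)
    )
  }
  out
}

#' Predict seed-match sites for all miRNA-UTR pairs
#'
#' @param mirnas Tibble of mature miRNAs (`id`, `sequence`).
#' @param utrs Tibble of 3'UTRs (`gene_id`, `sequence`), one row per gene.
#' @inheritParams scan_utr
#' @return Combined site tibble across all pairs (see [scan_utr()]).
#' @export
scan_targets <- function(mirnas, utrs, energy = TRUE,
                         config = prediction_config()) {
  assert_columns(mirnas, c("id", "sequence"), "miRNA table")
  assert_columns(utrs, c("gene_id", "sequence"), "UTR table")
  purrr::map_dfr(seq_len(nrow(mirnas)), function(i) {
    purrr::map_dfr(seq_len(nrow(utrs)), function(j) {
      scan_utr(mirnas[i, ], utrs[j, ], energy = energy, config = config)
    })
  })
}
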