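#' Specification for a simulated pre-miRNA hairpin candidate
#'
#' Describes a hairpin locus and its read stack so that every criterion of
#' the high-confidence filter is forced to a known pass/fail state by
#' construction. Counts are multiplicity-weighted (collapsed) reads.
#'
#' @param stem_length Paired stem length, nt.
#' @param loop_length Terminal loop length, nt.
#' @param mature_reads_0mm Weighted 0-mismatch read count on the mature arm.
#' @param star_reads_0mm Weighted 0-mismatch read count on the star arm.
#' @param mature_reads_1mm,star_reads_1mm Additional 1-mismatch reads; they
#'   enter the homogeneity denominator but not the support counts.
#' @param homogeneity_target Fraction of each arm's reads placed on the
#'   modal 5' start; the rest are spread over starts +1..+3 nt.
#' @param overhang_3p 3'-arm overhang in nt; negative values build a
#'   recessed 3' end (supported down to -3).
#' @param n_subhairpins Number of hairpin loops in the structure (>= 1).
#' @param mfe_per_nt_target Folding energy density, kcal/mol/nt.
#' @param mature_arm Which duplex strand carries the mature sequence.
#' @param rng_seed Seed; the generator is a pure function of this spec.
#' @return A list of class `mirarch_hairpin_sim_spec`.
#' @export
hairpin_sim_spec <- function(stem_length = 30L,
                             loop_length = 8L,
                             mature_reads_0mm = 40,
                             star_reads_0mm = 15,
                             mature_reads_1mm = 0,
                             star_reads_1mm = 0,
                             homogeneity_target = 1.0,
                             overhang_3p = 2L,
                             n_subhairpins = 1L,
                             mfe_per_nt_target = -0.35,
                             mature_arm = c("5p", "3p"),
                             rng_seed = 1L) {
  mature_arm <- match.arg(mature_arm)
  if (homogeneity_target <= 0 || homogeneity_target > 1) {
    abort("`homogeneity_target` must lie in (0, 1].")
  }
  if (any(c(mature_reads_0mm, star_reads_0mm,
            mature_reads_1mm, star_reads_1mm) < 0)) {
    abort("Read counts must be non-negative.")
  }
  if (n_subhairpins < 1) abort("`n_subhairpins` must be >= 1.")
  if (overhang_3p < -3) abort("Recessed 3' ends are supported down to -3 nt.")
  if (stem_length < 24) abort("`stem_length` must be at least 24 nt.")
  structure(
    list(
      stem_length = as.integer(stem_length),
      loop_length = as.integer(loop_length),
      mature_reads_0mm = mature_reads_0mm,
      star_reads_0mm = star_reads_0mm,
      mature_reads_1mm = mature_reads_1mm,
      star_reads_1mm = star_reads_1mm,
      homogeneity_target = homogeneity_target,
      overhang_3p = as.integer(overhang_3p),
      n_subhairpins = as.integer(n_subhairpins),
      mfe_per_nt_target = mfe_per_nt_target,
      mature_arm = mature_arm,
      rng_seed = as.integer(rng_seed)
    ),
    class = "mirarch_hairpin_sim_spec"
  )
}

# Arm start histogram realising a homogeneity target: `modal` reads on the
# arm 5' start, the remainder spread over starts +1..+3. Errors when the
# target is unreachable (a spread position would out-count the modal one).
arm_start_histogram <- function(total, homogeneity_target) {
  if (total == 0) return(integer(0))
  modal <- round(homogeneity_target * total)
  if (modal < 1) abort("`homogeneity_target` unreachable: modal count rounds to zero.")
  rest <- total - modal
  alt <- rep(rest %/% 3, 3) + c(rep(1, rest %% 3), rep(0, 3 - rest %% 3))
  if (any(alt > modal)) {
    abort("`homogeneity_target` unreachable: spread reads would exceed the modal start.")
  }
  counts <- c(modal, alt)
  names(counts) <- as.character(0:3)
  counts[counts > 0]
}

# Reads for one arm: starts offset from `arm_start`, 0-mismatch quota filled
# from the modal start outward, remaining reads labelled 1-mismatch.
arm_reads <- function(arm_start, precursor_length, n0, n1, homogeneity_target) {
  hist <- arm_start_histogram(n0 + n1, homogeneity_target)
  if (length(hist) == 0) {
    return(tibble(start = integer(0), end = integer(0),
                  mismatches = integer(0), count = numeric(0)))
  }
  rows <- list()
  left0 <- n0
  for (i in seq_along(hist)) {
    start <- arm_start + as.integer(names(hist)[[i]])
    end <- min(start + 22L, precursor_length)
    take0 <- min(left0, hist[[i]])
    left0 <- left0 - take0
    if (take0 > 0) rows[[length(rows) + 1]] <-
      tibble(start = start, end = end, mismatches = 0L, count = take0)
    if (hist[[i]] - take0 > 0) rows[[length(rows) + 1]] <-
      tibble(start = start, end = end, mismatches = 1L, count = hist[[i]] - take0)
  }
  dplyr::bind_rows(rows)
}

# Dot-bracket string for the requested architecture. A single sub-hairpin is
# a plain stem-loop; more sub-hairpins nest a multiloop of small stem-loops
# inside the outer stem, each contributing one hairpin loop.
hairpin_dot_bracket <- function(spec) {
  S <- spec$stem_length
  k <- spec$overhang_3p
  inner <- if (spec$n_subhairpins == 1) {
    strrep(".", spec$loop_length)
  } else {
    paste(rep(paste0("((((", strrep(".", 4), "))))"), spec$n_subhairpins),
          collapse = ".")
  }
  if (k >= 0) {
    paste0(strrep("(", S), inner, strrep(")", S), strrep(".", k))
  } else {
    d <- -k
    paste0(strrep(".", d), strrep("(", S - d), inner, strrep(")", S - d))
  }
}

# Random sequence consistent with a pair table: unpaired and 5'-side bases
# are drawn uniformly, partners are Watson-Crick complements.
sequence_from_pairs <- function(pt) {
  n <- length(pt)
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  for (i in seq_len(n)) {
    j <- pt[[i]]
    if (!is.na(j) && j + 1 > i) bases[[j + 1]] <- comp_rna(bases[[i]])
  }
  paste(bases, collapse = "")
}

#' Simulate a pre-miRNA hairpin candidate with ground truth
#'
#' Builds a hairpin structure, a consistent random sequence, annotated
#' mature/star arm intervals and a collapsed read stack realising the
#' spec's support and 5'-homogeneity targets. Truth labels for each filter
#' criterion are computed from the spec's arithmetic alone, never by running
#' the filter, so they can serve as an independent oracle for
#' [evaluate_candidates()].
#'
#' @param spec A [hairpin_sim_spec()].
#' @param id Candidate id used in all emitted tables.
#' @param criteria Thresholds the truth labels refer to
#'   (default [filter_criteria()]).
#' @return List with `candidate` (one-row tibble: sequence, dot-bracket,
#'   MFE, arm intervals), `reads` (read-stack tibble with `precursor_id`)
#'   and `truth` (one-row tibble of per-criterion booleans and
#'   `overall_pass`).
#' @export
simulate_hairpin_candidate <- function(spec, id = "hairpin_1",
                                       criteria = filter_criteria()) {
  stopifnot(inherits(spec, "mirarch_hairpin_sim_spec"))
  with_seed(spec$rng_seed, {
    db <- hairpin_dot_bracket(spec)
    pt <- pair_table(db)
    len <- nchar(db)
    seq <- sequence_from_pairs(pt)

    arm_len <- 22L
    fivep <- c(0L, arm_len)
    threep <- c(len - arm_len, len)
    if (threep[[1]] - fivep[[2]] < 4) {
      abort("Infeasible spec: arms would overlap; increase stem or loop length.")
    }
    if (spec$mature_arm == "5p") {
      mature <- fivep; star <- threep
    } else {
      mature <- threep; star <- fivep
    }

    reads <- dplyr::bind_rows(
      arm_reads(mature[[1]], len, spec$mature_reads_0mm, spec$mature_reads_1mm,
                spec$homogeneity_target),
      arm_reads(star[[1]], len, spec$star_reads_0mm, spec$star_reads_1mm,
                spec$homogeneity_target)
    )
    reads <- dplyr::bind_cols(tibble(precursor_id = rep(id, nrow(reads))), reads)

    candidate <- tibble(
      id = id,
      sequence = seq,
      dot_bracket = db,
      mfe_kcal_mol = spec$mfe_per_nt_target * len,
      mature_start = mature[[1]], mature_end = mature[[2]],
      star_start = star[[1]], star_end = star[[2]]
    )

    # Truth from spec arithmetic only (same rounding as the construction).
    realised_homog <- function(total) {
      if (total == 0) return(0)
      hist <- arm_start_histogram(total, spec$homogeneity_target)
      max(hist) / total
    }
    mature_total <- spec$mature_reads_0mm + spec$mature_reads_1mm
    star_total <- spec$star_reads_0mm + spec$star_reads_1mm
    truth <- tibble(
      id = id,
      mature_support_pass = spec$mature_reads_0mm >= criteria$mature_min_reads,
      star_support_pass = spec$star_reads_0mm >= criteria$star_min_reads,
      homogeneity_pass =
        realised_homog(mature_total) >= criteria$homogeneity_min &&
        realised_homog(star_total) >= criteria$homogeneity_min,
      overhang_pass = spec$overhang_3p >= criteria$overhang_range[1] &&
        spec$overhang_3p <= criteria$overhang_range[2],
      # same arithmetic as the emitted MFE so the float boundary agrees
      mfe_pass = (spec$mfe_per_nt_target * len) / len <= criteria$mfe_per_nt_max,
      loops_pass = spec$n_subhairpins <= criteria$max_hairpin_loops
    )
    truth$overall_pass <- truth$mature_support_pass & truth$star_support_pass &
      truth$homogeneity_pass & truth$overhang_pass & truth$mfe_pass &
      truth$loops_pass

    list(candidate = candidate, reads = reads, truth = truth)
  })
}

#' Specification for a simulated 3'UTR with planted seed sites
#'
#' @param utr_length UTR length, nt.
#' @param planted_sites Tibble with columns `site_class` (one of 8mer,
#'   7mer-m8, 7mer-A1, 6mer, off-6mer) and `position` (0-based window
#'   start); windows must fit in the UTR and must not overlap.
#' @param background_gc Background GC fraction.
#' @param rng_seed Seed.
#' @return A list of class `mirarch_utr_sim_spec`.
#' @export
utr_sim_spec <- function(utr_length = 300L,
                         planted_sites = tibble(site_class = character(0),
                                                position = integer(0)),
                         background_gc = 0.4,
                         rng_seed = 1L) {
  assert_columns(planted_sites, c("site_class", "position"), "planted_sites")
  if (!all(planted_sites$site_class %in% SITE_CLASSES)) {
    abort("Unknown site class in `planted_sites`.")
  }
  if (nrow(planted_sites) > 0) {
    if (any(planted_sites$position < 0) ||
        any(planted_sites$position + 8 > utr_length)) {
      abort("Planted sites must fit inside the UTR.")
    }
    pos <- sort(planted_sites$position)
    if (any(diff(pos) < 8)) abort("Planted sites must not overlap.")
  }
  structure(
    list(utr_length = as.integer(utr_length),
         planted_sites = planted_sites,
         background_gc = background_gc,
         rng_seed = as.integer(rng_seed)),
    class = "mirarch_utr_sim_spec"
  )
}

# Window content realising one site class for `mirna_sequence`, with free
# positions drawn at random under the class-exclusion constraints.
planted_window <- function(mirna_sequence, site_class) {
  p <- seed_patterns(mirna_sequence)
  not_a <- sample(c("C", "G", "U"), 1)
  free <- function(exclude) sample(setdiff(c("A", "C", "G", "U"), exclude), 1)
  switch(site_class,
    "8mer" = paste0(p$match_m2_m8, "A"),
    "7mer-m8" = paste0(p$match_m2_m8, not_a),
    "7mer-A1" = paste0(free(p$comp_m8), p$match_m2_m7, "A"),
    "6mer" = paste0(free(p$comp_m8), p$match_m2_m7, free("A")),
    "off-6mer" = paste0(p$match_m3_m8, free(p$comp_m2),
                        sample(c("A", "C", "G", "U"), 1))
  )
}

# Vectorised window classification, restated independently of scan_utr so
# that generator truth does not depend on the scanner under test.
classify_windows <- function(mirna_sequence, utr_sequence) {
  n <- nchar(utr_sequence)
  if (n < 8) return(tibble(position = integer(0), site_class = character(0)))
  p <- seed_patterns(mirna_sequence)
  starts <- seq_len(n - 7L)
  win <- substring(utr_sequence, starts, starts + 7L)
  cls <- rep(NA_character_, length(win))
  core7 <- substr(win, 1, 7) == p$match_m2_m8
  cls[core7] <- ifelse(substr(win[core7], 8, 8) == "A", "8mer", "7mer-m8")
  core6 <- is.na(cls) & substr(win, 2, 7) == p$match_m2_m7 &
    substr(win, 1, 1) != p$comp_m8
  cls[core6] <- ifelse(substr(win[core6], 8, 8) == "A", "7mer-A1", "6mer")
  off6 <- is.na(cls) & substr(win, 1, 6) == p$match_m3_m8 &
    substr(win, 7, 7) != p$comp_m2
  cls[off6] <- "off-6mer"
  hit <- which(!is.na(cls))
  tibble(position = starts[hit] - 1L, site_class = cls[hit])
}

#' Simulate a 3'UTR with planted seed-match sites
#'
#' Each planted window carries the exact target-side pattern of its class
#' for the given miRNA. The background is resampled (up to `max_attempts`
#' times, then an error) whenever any window outside the planted set is
#' classifiable, so the planted truth is exactly the set of sites present.
#'
#' @param mirna One-row tibble or list with `id`, `sequence` (>= 8 nt).
#' @param spec A [utr_sim_spec()].
#' @param utr_id Gene id given to the emitted UTR.
#' @param max_attempts Background resampling budget.
#' @return List with `utr` (one-row tibble `gene_id`, `sequence`) and
#'   `truth` (tibble `gene_id`, `mirna_id`, `position`, `site_class`).
#' @export
simulate_utr_with_sites <- function(mirna, spec, utr_id = "utr_1",
                                    max_attempts = 100L) {
  stopifnot(inherits(spec, "mirarch_utr_sim_spec"))
  if (nchar(mirna$sequence) < 8) abort("miRNA must be at least 8 nt.")
  with_seed(spec$rng_seed, {
    planted <- spec$planted_sites
    probs <- c(A = (1 - spec$background_gc) / 2, C = spec$background_gc / 2,
               G = spec$background_gc / 2, U = (1 - spec$background_gc) / 2)

    for (attempt in seq_len(max_attempts)) {
      # free window characters are redrawn along with the background: for
      # low-complexity seeds some free-character choices force a spurious
      # site in the planted window's shadow, others do not
      windows <- vapply(planted$site_class,
                        function(cl) planted_window(mirna$sequence, cl),
                        character(1))
      chars <- sample(names(probs), spec$utr_length, replace = TRUE, prob = probs)
      for (i in seq_len(nrow(planted))) {
        pos <- planted$position[[i]]
        chars[(pos + 1):(pos + 8)] <- strsplit(windows[[i]], NULL)[[1]]
      }
      seq <- paste(chars, collapse = "")
      found <- classify_windows(mirna$sequence, seq)
      expected <- planted[order(planted$position), , drop = FALSE]
      same <- nrow(found) == nrow(expected) &&
        all(found$position == expected$position) &&
        all(found$site_class == expected$site_class)
      if (same) {
        truth <- tibble(
          gene_id = rep(utr_id, nrow(expected)),
          mirna_id = rep(mirna$id, nrow(expected)),
          position = expected$position,
          site_class = expected$site_class
        )
        return(list(utr = tibble(gene_id = utr_id, sequence = seq),
                    truth = truth))
      }
    }
    abort(sprintf(
      "Could not realise a site-free background in %d attempts (degenerate seed?).",
      max_attempts
    ))
  })
}

#' Specification for a simulated count matrix
#'
#' The design mirrors the branchial-arch study layout: three tissue domains
#' (BA1, BA2, PBA_OFT) at two embryonic stages (E10.5, E11.5) with two
#' replicate libraries each. Differentially expressed genes change between
#' the posterior domain (PBA_OFT) and both anterior domains.
#'
#' @param n_genes Number of genes.
#' @param de_fraction Fraction of genes with a planted fold change.
#' @param log2fc_magnitude Absolute planted log2 fold change (sign random).
#' @param nb_dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param library_size_mean Approximate expected library size.
#' @param rng_seed Seed.
#' @return A list of class `mirarch_count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = 2000L,
                           de_fraction = 0.1,
                           log2fc_magnitude = 2,
                           nb_dispersion = 0.05,
                           library_size_mean = 1e6,
                           rng_seed = 1L) {
  if (de_fraction < 0 || de_fraction > 1) abort("`de_fraction` must be in [0, 1].")
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be positive.")
  structure(
    list(n_genes = as.integer(n_genes), de_fraction = de_fraction,
         log2fc_magnitude = log2fc_magnitude, nb_dispersion = nb_dispersion,
         library_size_mean = library_size_mean, rng_seed = as.integer(rng_seed)),
    class = "mirarch_count_sim_spec"
  )
}

#' Simulate a gene-by-library count matrix with planted fold changes
#'
#' Counts are negative-binomial around lognormal gene means scaled to the
#' target library size. DE genes multiply their mean by
#' `2^(+/- log2fc_magnitude)` in the PBA_OFT libraries (both stages).
#'
#' @param spec A [count_sim_spec()].
#' @return List with `counts` (tibble: `gene_id` + 12 libraries), `meta`
#'   (tibble: `library_id`, `domain`, `stage`, `replicate`) and `truth`
#'   (tibble: `gene_id`, `is_de`, `true_log2fc` signed PBA_OFT-vs-anterior).
#' @export
simulate_count_matrix <- function(spec) {
  stopifnot(inherits(spec, "mirarch_count_sim_spec"))
  with_seed(spec$rng_seed, {
    meta <- tidyr::expand_grid(
      domain = c("BA1", "BA2", "PBA_OFT"),
      stage = c("E10.5", "E11.5"),
      replicate = 1:2
    )
    meta$library_id <- sprintf("%s_%s_rep%d", meta$domain, meta$stage,
                               meta$replicate)
    meta <- meta[, c("library_id", "domain", "stage", "replicate")]

    genes <- sprintf("gene_%04d", seq_len(spec$n_genes))
    base <- stats::rlnorm(spec$n_genes, meanlog = log(50), sdlog = 1.2)
    base <- base / sum(base) * spec$library_size_mean

    n_de <- round(spec$de_fraction * spec$n_genes)
    de_idx <- if (n_de > 0) sample(spec$n_genes, n_de) else integer(0)
    direction <- rep(0, spec$n_genes)
    direction[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE)
    true_log2fc <- direction * spec$log2fc_magnitude

    mu <- matrix(base, nrow = spec$n_genes, ncol = nrow(meta))
    posterior <- meta$domain == "PBA_OFT"
    mu[, posterior] <- mu[, posterior] * 2^true_log2fc

    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / spec$nb_dispersion),
      nrow = spec$n_genes
    )
    rownames(counts) <- genes
    colnames(counts) <- meta$library_id

    list(
      counts = matrix_to_tibble(counts),
      meta = meta,
      truth = tibble(gene_id = genes, is_de = direction != 0,
                     true_log2fc = true_log2fc)
    )
  })
}

#' Specification for a simulated miRNA-gene interactome
#'
#' @param n_mirnas,n_genes Population dimensions.
#' @param set_size Size of the focal gene set (drawn at random from the
#'   genes).
#' @param baseline_target_prob Probability that any (miRNA, gene) pair is a
#'   predicted interaction.
#' @param enrichment_factor Multiplier on the in-set targeting probability
#'   of the planted miRNA; `1` plants nothing (null model).
#' @param enriched_mirna_id Id of the planted miRNA.
#' @param rng_seed Seed.
#' @return A list of class `mirarch_interactome_sim_spec`.
#' @export
interactome_sim_spec <- function(n_mirnas = 50L,
                                 n_genes = 2000L,
                                 set_size = 300L,
                                 baseline_target_prob = 0.05,
                                 enrichment_factor = 3,
                                 enriched_mirna_id = "mirna_01",
                                 rng_seed = 1L) {
  if (set_size > n_genes) abort("`set_size` cannot exceed `n_genes`.")
  if (enrichment_factor < 1) abort("`enrichment_factor` must be >= 1.")
  if (baseline_target_prob <= 0 || baseline_target_prob > 1) {
    abort("`baseline_target_prob` must be in (0, 1].")
  }
  structure(
    list(n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
         set_size = as.integer(set_size),
         baseline_target_prob = baseline_target_prob,
         enrichment_factor = enrichment_factor,
         enriched_mirna_id = enriched_mirna_id,
         rng_seed = as.integer(rng_seed)),
    class = "mirarch_interactome_sim_spec"
  )
}

#' Simulate a miRNA-gene interactome with one planted-enriched miRNA
#'
#' Every (miRNA, gene) pair becomes a predicted interaction independently
#' with the baseline probability; for the planted miRNA, pairs whose gene
#' belongs to the focal set use `min(1, enrichment_factor * baseline)`
#' instead. With `enrichment_factor = 1` no miRNA is planted and the truth
#' id is `NA`.
#'
#' @param spec An [interactome_sim_spec()].
#' @return List with `interactions` (tibble: `mirna_id`, `gene_id`,
#'   `n_sites`, `best_class`, `min_energy`), `gene_set` (character) and
#'   `truth` (planted miRNA id or `NA`).
#' @export
simulate_interactome <- function(spec) {
  stopifnot(inherits(spec, "mirarch_interactome_sim_spec"))
  with_seed(spec$rng_seed, {
    mirnas <- sprintf("mirna_%02d", seq_len(spec$n_mirnas))
    if (!spec$enriched_mirna_id %in% mirnas) {
      abort("`enriched_mirna_id` must be one of the simulated miRNA ids.")
    }
    genes <- sprintf("gene_%04d", seq_len(spec$n_genes))
    gene_set <- sort(sample(genes, spec$set_size))

    prob <- matrix(spec$baseline_target_prob,
                   nrow = spec$n_mirnas, ncol = spec$n_genes)
    planted <- spec$enrichment_factor > 1
    if (planted) {
      prob[match(spec$enriched_mirna_id, mirnas), genes %in% gene_set] <-
        min(1, spec$enrichment_factor * spec$baseline_target_prob)
    }
    hits <- matrix(stats::runif(length(prob)) < prob,
                   nrow = spec$n_mirnas, ncol = spec$n_genes)
    idx <- which(hits, arr.ind = TRUE)
    interactions <- tibble(
      mirna_id = mirnas[idx[, 1]],
      gene_id = genes[idx[, 2]],
      n_sites = 2L,
      best_class = "7mer-m8",
      min_energy = -8
    )
    interactions <- dplyr::arrange(interactions, .data$mirna_id, .data$gene_id)
    list(
      interactions = interactions,
      gene_set = gene_set,
      truth = if (planted) spec$enriched_mirna_id else NA_character_
    )
  })
}
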