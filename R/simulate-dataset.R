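# Random mature miRNA sequences with strong (G/C-only) seeds. A G/C seed
# guarantees every 7-nt seed helix scores below the -7 kcal/mol retention
# threshold under the nearest-neighbour model, so planted sites survive the
# energy filter by construction. Seeds are drawn distinct.
dataset_mirnas <- function(n, length = 21L) {
  seeds <- character(0)
  while (length(seeds) < n) {
    cand <- paste(sample(c("G", "C"), 7, replace = TRUE), collapse = "")
    if (!cand %in% seeds) seeds <- c(seeds, cand)
  }
  seqs <- vapply(seeds, function(seed) {
    tail_len <- length - 8L
    paste0(
      sample(c("A", "C", "G", "U"), 1), seed,
      paste(sample(c("A", "C", "G", "U"), tail_len, replace = TRUE),
            collapse = "")
    )
  }, character(1))
  tibble(id = sprintf("mirna_%02d", seq_len(n)), sequence = unname(seqs))
}

#' Write a complete simulated toy dataset directory
#'
#' Emits every input the end-to-end pipeline consumes, with a planted
#' ground truth: a small miRNA complement with one miRNA enriched for
#' predicted interactions with a focal gene set, 3'UTRs carrying two strong
#' seed sites per planted interaction, count matrices for the expression
#' filters (including one miRNA constructed to fail them), DE and
#' annotation-term tables that reproduce the focal gene set, and a set of
#' hairpin candidates spanning pass and fail states of the novel pre-miRNA
#' filter. Planted sites use 8mer windows with G/C seeds so they always
#' clear the energy cutoff; accidental cross-miRNA seed matches are left in
#' place as background noise, so the dataset-level truth is the planted
#' enrichment, not a per-site census.
#'
#' @param dir Output directory (created if needed).
#' @param rng_seed Seed; the dataset is a pure function of it.
#' @param n_mirnas,n_genes,set_size,baseline_target_prob,enrichment_factor
#'   Interactome dimensions (see [interactome_sim_spec()]).
#' @param utr_length Length of every simulated 3'UTR.
#' @return Invisibly, a list with the dataset `truth` (planted miRNA id,
#'   gene set) and the paths written.
#' @export
simulate_dataset <- function(dir, rng_seed = 1L,
                             n_mirnas = 8L, n_genes = 40L, set_size = 10L,
                             baseline_target_prob = 0.12,
                             enrichment_factor = 6,
                             utr_length = 150L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "hairpins"), showWarnings = FALSE)
  paths <- list(
    mirna_fasta = file.path(dir, "mirnas.fa"),
    utr_fasta = file.path(dir, "utrs.fa"),
    counts_small_rna = file.path(dir, "counts_small_rna.tsv"),
    counts_rna = file.path(dir, "counts_rna.tsv"),
    library_meta = file.path(dir, "library_meta.tsv"),
    de_vs_ba1 = file.path(dir, "de_pba_vs_ba1.tsv"),
    de_vs_ba2 = file.path(dir, "de_pba_vs_ba2.tsv"),
    go_terms = file.path(dir, "go_terms.tsv"),
    go_annotation = file.path(dir, "go_annotation.tsv"),
    hairpin_structures = file.path(dir, "hairpins", "structures.str"),
    hairpin_arms = file.path(dir, "hairpins", "arms.tsv"),
    hairpin_reads = file.path(dir, "hairpins", "read_stacks.tsv"),
    truth = file.path(dir, "truth.json")
  )

  with_seed(rng_seed, {
    inter_spec <- interactome_sim_spec(
      n_mirnas = n_mirnas, n_genes = n_genes, set_size = set_size,
      baseline_target_prob = baseline_target_prob,
      enrichment_factor = enrichment_factor,
      enriched_mirna_id = "mirna_01",
      rng_seed = sample.int(1e6, 1)
    )
    interactome <- simulate_interactome(inter_spec)
    mirnas <- dataset_mirnas(n_mirnas)
    genes <- sprintf("gene_%04d", seq_len(n_genes))

    # 3'UTRs: two 8mer sites per planted interaction, on a fixed slot grid.
    slots <- seq(2L, utr_length - 10L, by = 14L)
    utrs <- purrr::map_chr(genes, function(g) {
      partners <- interactome$interactions$mirna_id[
        interactome$interactions$gene_id == g
      ]
      chars <- sample(c("A", "U", "G", "C"), utr_length, replace = TRUE,
                      prob = c(0.3, 0.3, 0.2, 0.2))
      needed <- rep(partners, each = 2)
      if (length(needed) > length(slots)) {
        abort("Too many planted interactions for the UTR slot grid.")
      }
      for (i in seq_along(needed)) {
        m <- mirnas$sequence[[match(needed[[i]], mirnas$id)]]
        win <- strsplit(paste0(rc_rna(substr(m, 2, 8)), "A"), NULL)[[1]]
        chars[(slots[[i]] + 1):(slots[[i]] + 8)] <- win
      }
      paste(chars, collapse = "")
    })
    write_rna_fasta(tibble(id = genes, sequence = utrs), paths$utr_fasta)

    # The mature miRNA complement, plus one miRNA whose counts fail the
    # expression filter (a single library above threshold).
    mirna_fasta <- dplyr::bind_rows(
      mirnas,
      tibble(id = "mirna_low",
             sequence = paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
                              collapse = ""))
    )
    write_rna_fasta(mirna_fasta, paths$mirna_fasta)

    count_spec <- count_sim_spec(
      n_genes = n_genes, de_fraction = 0, nb_dispersion = 0.05,
      library_size_mean = 5e5, rng_seed = sample.int(1e6, 1)
    )
    rna_counts <- simulate_count_matrix(count_spec)
    write_tsv_table(rna_counts$counts, paths$counts_rna)
    write_tsv_table(rna_counts$meta, paths$library_meta)

    sm <- matrix(stats::rpois(n_mirnas * 12, lambda = 1200), nrow = n_mirnas)
    sm <- rbind(sm, c(5L, rep(0L, 11)))
    rownames(sm) <- c(mirnas$id, "mirna_low")
    colnames(sm) <- rna_counts$meta$library_id
    write_tsv_table(matrix_to_tibble(sm), paths$counts_small_rna)

    # DE and annotation-term tables that reproduce the focal gene set.
    in_set <- genes %in% interactome$gene_set
    de_tbl <- function() {
      tibble(
        gene_id = genes,
        log2fc = ifelse(in_set, 1.2, round(stats::rnorm(n_genes, 0, 0.2), 4)),
        padj = ifelse(in_set, 0.001, round(stats::runif(n_genes, 0.2, 0.9), 4))
      )
    }
    write_tsv_table(de_tbl(), paths$de_vs_ba1)
    write_tsv_table(de_tbl(), paths$de_vs_ba2)
    write_tsv_table(
      tibble(term_id = c("TERM:MUSCLE", "TERM:WEAK", "TERM:NS"),
             fold_enrichment = c(3.5, 1.3, 2.5),
             fdr = c(0.001, 0.04, 0.2)),
      paths$go_terms
    )
    write_tsv_table(
      dplyr::bind_rows(
        tibble(gene_id = interactome$gene_set, term_id = "TERM:MUSCLE"),
        tibble(gene_id = utils::head(genes[!in_set], 5), term_id = "TERM:WEAK"),
        tibble(gene_id = utils::tail(genes[!in_set], 3), term_id = "TERM:NS")
      ),
      paths$go_annotation
    )

    # Hairpin candidates spanning each pass/fail state of the novel filter.
    hp_specs <- list(
      all_pass = hairpin_sim_spec(rng_seed = sample.int(1e6, 1)),
      star_fail = hairpin_sim_spec(star_reads_0mm = 9,
                                   rng_seed = sample.int(1e6, 1)),
      homogeneity_fail = hairpin_sim_spec(homogeneity_target = 0.4,
                                          rng_seed = sample.int(1e6, 1)),
      overhang_fail = hairpin_sim_spec(overhang_3p = 6,
                                       rng_seed = sample.int(1e6, 1)),
      mfe_fail = hairpin_sim_spec(mfe_per_nt_target = -0.1,
                                  rng_seed = sample.int(1e6, 1)),
      subhairpin_fail = hairpin_sim_spec(n_subhairpins = 2,
                                         rng_seed = sample.int(1e6, 1))
    )
    hp <- purrr::imap(hp_specs, function(s, nm) {
      simulate_hairpin_candidate(s, id = nm)
    })
    cands <- dplyr::bind_rows(purrr::map(hp, "candidate"))
    write_structures(
      cands[, c("id", "sequence", "dot_bracket", "mfe_kcal_mol")],
      paths$hairpin_structures
    )
    write_tsv_table(
      cands[, c("id", "mature_start", "mature_end", "star_start", "star_end")],
      paths$hairpin_arms
    )
    write_tsv_table(dplyr::bind_rows(purrr::map(hp, "reads")), paths$hairpin_reads)

    truth <- list(
      enriched_mirna = interactome$truth,
      gene_set = interactome$gene_set,
      filtered_mirna = "mirna_low",
      hairpin_truth = dplyr::bind_rows(purrr::map(hp, "truth"))
    )
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    invisible(list(truth = truth, paths = paths))
  })
}
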