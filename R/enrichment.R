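#' Domain gene-set construction configuration
#'
#' @param up_fold_min Minimum linear up-regulation fold change required in
#'   both pairwise comparisons (inclusive).
#' @param up_padj_max Maximum adjusted p-value for those comparisons.
#' @param go_fold_min Minimum fold enrichment of an annotation term.
#' @param go_fdr_max Maximum FDR of an annotation term.
#' @return A list of class `mirarch_gene_set_config`.
#' @export
gene_set_config <- function(up_fold_min = 1.5, up_padj_max = 0.05,
                            go_fold_min = 2, go_fdr_max = 0.05) {
  stopifnot(up_fold_min > 0, up_padj_max > 0, go_fold_min > 0, go_fdr_max > 0)
  structure(
    list(up_fold_min = up_fold_min, up_padj_max = up_padj_max,
         go_fold_min = go_fold_min, go_fdr_max = go_fdr_max),
    class = "mirarch_gene_set_config"
  )
}

#' Build the domain-specific gene set
#'
#' The set contains genes up-regulated at least `up_fold_min`-fold (adjusted
#' p <= `up_padj_max`) in the focal domain relative to *both* reference
#' domains, intersected with genes annotated under any enrichment term
#' passing the term-level fold and FDR cutoffs. The term table itself comes
#' from an external GO analysis; this function only consumes it.
#'
#' @param de_vs_a,de_vs_b DE tibbles (`gene_id`, `log2fc`, `padj`) for the
#'   focal domain versus each reference domain, with positive `log2fc`
#'   meaning higher expression in the focal domain.
#' @param go_terms Tibble of enriched terms: `term_id`, `fold_enrichment`,
#'   `fdr`.
#' @param go_annotation Tibble mapping `gene_id` to `term_id`.
#' @param config A [gene_set_config()].
#' @return Sorted character vector of gene ids.
#' @export
build_domain_gene_set <- function(de_vs_a, de_vs_b, go_terms, go_annotation,
                                  config = gene_set_config()) {
  assert_columns(go_terms, c("term_id", "fold_enrichment", "fdr"), "term table")
  assert_columns(go_annotation, c("gene_id", "term_id"), "annotation table")
  up <- function(de) {
    assert_columns(de, c("gene_id", "log2fc", "padj"), "DE table")
    de$gene_id[!is.na(de$padj) &
                 de$log2fc >= log2(config$up_fold_min) &
                 de$padj <= config$up_padj_max]
  }
  up_both <- intersect(up(de_vs_a), up(de_vs_b))
  passing_terms <- go_terms$term_id[
    go_terms$fold_enrichment >= config$go_fold_min &
      go_terms$fdr <= config$go_fdr_max
  ]
  if (length(passing_terms) == 0) {
    warn("No annotation terms pass the cutoffs; the gene set is empty.")
    return(character(0))
  }
  annotated <- unique(go_annotation$gene_id[
    go_annotation$term_id %in% passing_terms
  ])
  sort(intersect(up_both, annotated))
}

# Upper-tail hypergeometric probability P(X >= k) for X ~ Hypergeom(N, K, n),
# inclusive of the observed k, computed with log-space binomial coefficients
# so that population sizes of ~1e5 interactions do not overflow.
hyper_tail_p <- function(k, K, n, N) {
  if (k <= 0) return(1)
  upper <- min(n, K)
  if (k > upper) return(0)
  i <- k:upper
  logs <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, sum(exp(logs)))
}

#' Rank miRNAs by hypergeometric enrichment of predicted set interactions
#'
#' The urn is the predicted interaction table: with `N` the total number of
#' (miRNA, gene) interaction rows, `K` those whose gene belongs to the gene
#' set, `n` the interactions of one miRNA and `k` its interactions with set
#' genes, the enrichment p-value is the upper-tail hypergeometric
#' probability `P(X >= k)` (inclusive) and the fold enrichment is
#' `(k/n) / (K/N)`. A gene-universe variant (`universe = "gene"`) instead
#' uses all distinct genes as `N` and the set size as `K`. Results are
#' sorted by ascending p, ties broken by descending fold then miRNA id.
#' No multiple-testing correction is applied to the ranking; a
#' Benjamini-Hochberg column is emitted alongside for transparency.
#'
#' @param interactions Interaction tibble (`mirna_id`, `gene_id`), one row
#'   per (miRNA, gene) pair, e.g. from [filter_interactions()].
#' @param gene_set Character vector of gene ids.
#' @param universe `"interaction"` (default) or `"gene"`.
#' @return Tibble of class `mirarch_enrichment`: `mirna_id`, `k`, `n`, `K`,
#'   `N`, `p_hyper`, `fold_enrichment`, `bh_fdr`.
#' @export
mirna_set_enrichment <- function(interactions, gene_set,
                                 universe = c("interaction", "gene")) {
  universe <- match.arg(universe)
  assert_columns(interactions, c("mirna_id", "gene_id"), "interaction table")
  if (nrow(interactions) == 0) abort("The interaction table is empty.")
  in_set <- interactions$gene_id %in% gene_set
  per <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(interactions, .in_set = in_set),
      .data$mirna_id
    ),
    n = dplyr::n(),
    k = sum(.data$.in_set),
    .groups = "drop"
  )
  if (universe == "interaction") {
    N <- nrow(interactions)
    K <- sum(in_set)
  } else {
    genes <- unique(interactions$gene_id)
    N <- length(genes)
    K <- length(intersect(gene_set, genes))
  }
  per$K <- K
  per$N <- N
  per$p_hyper <- vapply(seq_len(nrow(per)),
                        function(i) hyper_tail_p(per$k[i], K, per$n[i], N),
                        numeric(1))
  per$fold_enrichment <- ifelse(per$n > 0 & K > 0,
                                (per$k / per$n) / (K / N), NA_real_)
  per$bh_fdr <- stats::p.adjust(per$p_hyper, method = "BH")
  out <- dplyr::arrange(per, .data$p_hyper,
                        dplyr::desc(.data$fold_enrichment), .data$mirna_id)
  out <- out[, c("mirna_id", "k", "n", "K", "N", "p_hyper",
                 "fold_enrichment", "bh_fdr")]
  class(out) <- c("mirarch_enrichment", class(out))
  out
}
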