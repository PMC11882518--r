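#' Expression filtering configuration
#'
#' Defaults hold the study-calibrated thresholds: 4.2 CPM (about 100 reads in
#' these libraries) for small RNA-seq and 0.38 CPM (about 10 reads) for
#' RNA-seq, required in at least two libraries; differential expression is a
#' fold change of at least 1.5 at an adjusted p-value of at most 0.05.
#'
#' @param cpm_threshold_small_rna CPM threshold for small RNA libraries.
#' @param cpm_threshold_rna CPM threshold for RNA-seq libraries.
#' @param min_libraries Minimum number of libraries above threshold.
#' @param strict_above Treat the CPM threshold as a strict inequality
#'   ("above", the default) rather than inclusive.
#' @param fold_change_min Minimum linear fold change (applied symmetrically
#'   in both directions).
#' @param padj_max Maximum adjusted p-value.
#' @return A list of class `mirarch_expression_config`.
#' @export
expression_config <- function(cpm_threshold_small_rna = 4.2,
                              cpm_threshold_rna = 0.38,
                              min_libraries = 2L,
                              strict_above = TRUE,
                              fold_change_min = 1.5,
                              padj_max = 0.05) {
  stopifnot(
    cpm_threshold_small_rna > 0, cpm_threshold_rna > 0,
    min_libraries >= 1, fold_change_min > 0, padj_max > 0
  )
  structure(
    list(
      cpm_threshold_small_rna = cpm_threshold_small_rna,
      cpm_threshold_rna = cpm_threshold_rna,
      min_libraries = as.integer(min_libraries),
      strict_above = strict_above,
      fold_change_min = fold_change_min,
      padj_max = padj_max
    ),
    class = "mirarch_expression_config"
  )
}

counts_to_matrix <- function(counts) {
  assert_columns(counts, "gene_id", "count matrix")
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_to_tibble <- function(m) {
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

#' Counts per million
#'
#' Scales every library (column) so its counts sum to one million.
#'
#' @param counts Tibble with a `gene_id` column and one numeric column per
#'   library.
#' @return Tibble of the same shape with CPM values.
#' @export
cpm <- function(counts) {
  m <- counts_to_matrix(counts)
  totals <- colSums(m)
  if (any(totals <= 0)) abort("Every library must have a positive total count.")
  matrix_to_tibble(sweep(m, 2, totals, "/") * 1e6)
}

#' Genes passing the expression threshold
#'
#' A gene is called expressed when its CPM exceeds the assay-specific
#' threshold in at least `min_libraries` libraries. "Above" is a strict
#' inequality by default, so a CPM exactly at the threshold does not count.
#'
#' @inheritParams cpm
#' @param config An [expression_config()].
#' @param assay `"small_rna"` (4.2 CPM default threshold) or `"rna"`
#'   (0.38 CPM).
#' @return Character vector of expressed gene ids, in input order.
#' @export
expressed_genes <- function(counts, config = expression_config(),
                            assay = c("small_rna", "rna")) {
  assay <- match.arg(assay)
  threshold <- switch(assay,
    small_rna = config$cpm_threshold_small_rna,
    rna = config$cpm_threshold_rna
  )
  m <- counts_to_matrix(cpm(counts))
  hits <- if (config$strict_above) m > threshold else m >= threshold
  rownames(m)[rowSums(hits) >= config$min_libraries]
}

#' Filter a differential-expression table
#'
#' Keeps records with an absolute fold change of at least
#' `fold_change_min` (i.e. `|log2fc| >= log2(fold_change_min)`) and
#' `padj <= padj_max`; both bounds are inclusive. Records with a missing
#' adjusted p-value are dropped with a message.
#'
#' @param de Tibble with columns `gene_id`, `log2fc`, `padj`.
#' @param config An [expression_config()].
#' @return The filtered tibble.
#' @export
filter_de <- function(de, config = expression_config()) {
  assert_columns(de, c("gene_id", "log2fc", "padj"), "DE table")
  na_p <- is.na(de$padj)
  if (any(na_p)) {
    rlang::inform(sprintf("Dropping %d DE record(s) with missing padj.", sum(na_p)))
    de <- de[!na_p, , drop = FALSE]
  }
  keep <- abs(de$log2fc) >= log2(config$fold_change_min) &
    de$padj <= config$padj_max
  de[keep, , drop = FALSE]
}

#' Exclusive membership-pattern counts across gene sets
#'
#' UpSet-style decomposition: every element of the union is attributed to
#' exactly one membership pattern (the sets it belongs to), so pattern
#' counts sum to the union size.
#'
#' @param sets Named list of character vectors (at least two).
#' @return Tibble with columns `pattern` (set names joined by `&`),
#'   `degree` and `count`, sorted by degree then pattern.
#' @export
overlap_counts <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list of at least two sets.")
  }
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(
    universe,
    function(x) paste(names(sets)[vapply(sets, function(s) x %in% s, logical(1))],
                      collapse = "&"),
    character(1)
  )
  counts <- table(membership)
  out <- tibble(
    pattern = names(counts),
    degree = stringr::str_count(names(counts), stringr::fixed("&")) + 1L,
    count = as.integer(counts)
  )
  dplyr::arrange(out, .data$degree, .data$pattern)
}

#' Row-wise z-score normalisation
#'
#' Each row is centred and scaled by its population (divide-by-n) standard
#' deviation, the convention used for expression heatmaps. Zero-variance
#' rows become all-zero with a warning.
#'
#' @inheritParams cpm
#' @return Tibble of the same shape with z-scores.
#' @export
row_zscore <- function(counts) {
  m <- counts_to_matrix(counts)
  mu <- rowMeans(m)
  centred <- m - mu
  sd_pop <- sqrt(rowMeans(centred^2))
  flat <- sd_pop == 0
  if (any(flat)) {
    warn(sprintf("%d constant row(s) set to zero in z-score transform.", sum(flat)))
    sd_pop[flat] <- 1
    centred[flat, ] <- 0
  }
  matrix_to_tibble(centred / sd_pop)
}

#' Library-by-library Spearman correlation
#'
#' Rank correlation (midranks for ties) between all pairs of libraries,
#' typically applied to the CPM matrix to assess similarity of expression
#' profiles.
#'
#' @inheritParams cpm
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(counts) {
  m <- counts_to_matrix(counts)
  if (ncol(m) < 2 || nrow(m) < 3) {
    abort("Need at least 2 libraries and 3 genes for a correlation matrix.")
  }
  stats::cor(m, method = "spearman")
}

#' Relative quantification by the 2^-ddCt method
#'
#' Fold change of a target transcript in a case sample relative to a control
#' sample, each first normalised to a reference transcript:
#' `2^-((Ct_target_case - Ct_ref_case) - (Ct_target_ctrl - Ct_ref_ctrl))`.
#'
#' @param ct_target_case,ct_ref_case Ct values in the case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control sample.
#' @return Linear fold change (vectorised).
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
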