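#' Extract the longest 3'UTR per gene from annotation and genome sequence
#'
#' For every transcript, the spliced 3'UTR length is the sum of its
#' `three_prime_utr` interval widths; per gene, the transcript with the
#' maximal spliced length is chosen (ties broken by the lexicographically
#' smallest transcript id, for determinism). The emitted sequence is the
#' concatenation of the genomic slices in ascending genomic order,
#' reverse-complemented for minus-strand transcripts, so it always reads
#' 5'->3' in the RNA alphabet.
#'
#' @param features Feature tibble from [read_gtf_features()] (0-based
#'   half-open coordinates) containing `three_prime_utr` rows.
#' @param genome Tibble of chromosome sequences (`id`, `sequence`), e.g.
#'   from [read_rna_fasta()].
#' @return Tibble of class tbl: `gene_id`, `transcript_id`, `sequence`,
#'   `length`, one row per gene.
#' @export
extract_longest_3utrs <- function(features, genome) {
  assert_columns(
    features,
    c("gene_id", "transcript_id", "feature", "chrom", "start", "end", "strand"),
    "feature table"
  )
  assert_columns(genome, c("id", "sequence"), "genome table")
  utr <- features[features$feature == "three_prime_utr", , drop = FALSE]
  if (nrow(utr) == 0) {
    warn("No three_prime_utr features found; returning an empty UTR table.")
    return(tibble(gene_id = character(0), transcript_id = character(0),
                  sequence = character(0), length = integer(0)))
  }
  chrom_seq <- stats::setNames(genome$sequence, genome$id)
  missing_chrom <- setdiff(unique(utr$chrom), names(chrom_seq))
  if (length(missing_chrom) > 0) {
    abort(sprintf("Genome lacks sequence for: %s",
                  paste(missing_chrom, collapse = ", ")))
  }

  lengths <- dplyr::summarise(
    dplyr::group_by(utr, .data$gene_id, .data$transcript_id),
    length = sum(.data$end - .data$start),
    .groups = "drop"
  )
  chosen <- dplyr::slice(
    dplyr::group_by(dplyr::arrange(lengths, .data$transcript_id), .data$gene_id),
    which.max(.data$length)
  )
  chosen <- dplyr::ungroup(chosen)

  seqs <- purrr::map_chr(chosen$transcript_id, function(tx) {
    rows <- utr[utr$transcript_id == tx, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    pieces <- substring(chrom_seq[[rows$chrom[[1]]]], rows$start + 1, rows$end)
    joined <- paste(pieces, collapse = "")
    if (rows$strand[[1]] == "-") rc_rna(joined) else joined
  })
  tibble(
    gene_id = chosen$gene_id,
    transcript_id = chosen$transcript_id,
    sequence = unname(seqs),
    length = chosen$length
  )
}
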