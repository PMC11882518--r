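#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Sequences are upper-cased and DNA thymine is transcribed to uracil, so all
#' downstream code works in a single RNA alphabet. Record ids are taken as the
#' first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param validate_alphabet If `TRUE` (default), error when a sequence
#'   contains characters outside A/C/G/U after normalisation. Genome FASTA
#'   files with ambiguity codes can be read with `validate_alphabet = FALSE`.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_rna_fasta <- function(path, validate_alphabet = TRUE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(sprintf("FASTA file '%s' contains no records.", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "FASTA file '%s' contains duplicate ids: %s",
      path, paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- normalise_rna(as.character(set))
  if (any(nchar(seqs) == 0)) abort("FASTA records must be non-empty.")
  if (validate_alphabet) assert_rna_alphabet(seqs, sprintf("FASTA '%s'", path))
  tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(seqs, path) {
  assert_columns(seqs, c("id", "sequence"), "sequence table")
  writeLines(paste0(">", seqs$id, "\n", seqs$sequence), path)
  invisible(path)
}

#' Read an RNAfold-style secondary structure file
#'
#' Parses the common three-line dialect: a `>id` header, the sequence, and a
#' dot-bracket line with the minimum free energy appended in parentheses,
#' e.g. `(((...))) (-1.20)`. Brackets are checked for balance and the
#' dot-bracket string must match the sequence length.
#'
#' @param path Path to a structure file.
#' @return A tibble with columns `id`, `sequence`, `dot_bracket`,
#'   `mfe_kcal_mol`.
#' @export
read_structures <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("Structure file '%s' is empty.", path))
  if (length(lines) %% 3 != 0) {
    abort(sprintf("Structure file '%s' is not in >id/sequence/structure triplets.", path))
  }
  idx <- seq(1, length(lines), by = 3)
  recs <- purrr::map(idx, function(i) {
    header <- lines[[i]]
    if (!startsWith(header, ">")) {
      abort(sprintf("Expected '>' header at line %d of '%s'.", i, path))
    }
    id <- sub("\\s.*$", "", sub("^>", "", header))
    seq <- normalise_rna(trimws(lines[[i + 1]]))
    assert_rna_alphabet(seq, sprintf("structure record '%s'", id))
    struct_line <- trimws(lines[[i + 2]])
    m <- regmatches(struct_line, regexec("^([.()]+)\\s*\\((\\s*-?[0-9.]+)\\)$", struct_line))[[1]]
    if (length(m) != 3) {
      abort(sprintf(
        "Record '%s': structure line must be dot-bracket followed by '(mfe)'.", id
      ))
    }
    db <- m[[2]]
    mfe <- as.numeric(m[[3]])
    if (nchar(db) != nchar(seq)) {
      abort(sprintf(
        "Record '%s': dot-bracket length (%d) differs from sequence length (%d).",
        id, nchar(db), nchar(seq)
      ))
    }
    pair_table(db) # errors on unbalanced brackets
    tibble(id = id, sequence = seq, dot_bracket = db, mfe_kcal_mol = mfe)
  })
  out <- dplyr::bind_rows(recs)
  if (anyDuplicated(out$id)) {
    abort(sprintf("Structure file '%s' contains duplicate ids.", path))
  }
  out
}

#' Write an RNAfold-style secondary structure file
#'
#' @param structures Tibble with columns `id`, `sequence`, `dot_bracket`,
#'   `mfe_kcal_mol`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(structures, path) {
  assert_columns(structures, c("id", "sequence", "dot_bracket", "mfe_kcal_mol"),
                 "structure table")
  writeLines(sprintf(
    ">%s\n%s\n%s (%.2f)",
    structures$id, structures$sequence, structures$dot_bracket,
    structures$mfe_kcal_mol
  ), path)
  invisible(path)
}

#' Read gene/transcript features from a GTF file
#'
#' GTF coordinates are 1-based inclusive; they are converted to the package's
#' internal 0-based half-open convention at this boundary. Rows whose
#' `gene_id` or `transcript_id` attribute is missing are skipped with a
#' warning. Strand is recorded as metadata; sequences are only
#' reverse-complemented at extraction time (see [extract_longest_3utrs()]).
#'
#' @param path Path to a GTF file.
#' @param feature_types Character vector of feature types to keep
#'   (e.g. `"three_prime_utr"`). Other rows are dropped.
#' @return A tibble with columns `gene_id`, `transcript_id`, `feature`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`.
#' @export
read_gtf_features <- function(path, feature_types = "three_prime_utr") {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[df$type %in% feature_types, , drop = FALSE]
  if (!all(c("gene_id", "transcript_id") %in% names(df))) {
    abort(sprintf("GTF '%s' lacks gene_id/transcript_id attributes entirely.", path))
  }
  bad <- is.na(df$gene_id) | is.na(df$transcript_id)
  if (any(bad)) {
    warn(sprintf(
      "Skipping %d GTF row(s) with missing gene_id/transcript_id.", sum(bad)
    ))
    df <- df[!bad, , drop = FALSE]
  }
  tibble(
    gene_id = df$gene_id,
    transcript_id = df$transcript_id,
    feature = as.character(df$type),
    chrom = as.character(df$seqnames),
    start = df$start - 1L, # GTF 1-based inclusive -> 0-based half-open
    end = df$end,
    strand = as.character(df$strand)
  )
}

#' Read and write the pipeline's tab-separated tables
#'
#' All tabular interchange uses UTF-8 TSV with a header row; lines starting
#' with `#` are comments. `read_tsv_table()` and `write_tsv_table()` are thin
#' [readr] wrappers enforcing that dialect; the convenience readers check the
#' columns each stage requires.
#'
#' @param path File path.
#' @param required_columns Columns that must be present.
#' @return A tibble.
#' @export
read_tsv_table <- function(path, required_columns = NULL) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!is.null(required_columns)) assert_columns(out, required_columns, path)
  out
}

#' @rdname read_tsv_table
#' @param x Data frame to write.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_tsv_table
#' @export
read_counts <- function(path) {
  out <- read_tsv_table(path, "gene_id")
  if (anyDuplicated(out$gene_id)) abort("Count matrix has duplicate gene ids.")
  out
}

#' @rdname read_tsv_table
#' @export
read_de_table <- function(path) {
  read_tsv_table(path, c("gene_id", "log2fc", "padj"))
}

#' @rdname read_tsv_table
#' @export
read_read_stacks <- function(path) {
  read_tsv_table(path, c("precursor_id", "start", "end", "mismatches", "count"))
}

#' @rdname read_tsv_table
#' @export
read_interactions <- function(path) {
  read_tsv_table(path, c("mirna_id", "gene_id", "n_sites", "best_class", "min_energy"))
}
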