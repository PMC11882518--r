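#' Thresholds for the high-confidence novel pre-miRNA filter
#'
#' Defaults reproduce the post-hoc criteria used to retain high-confidence
#' novel pre-miRNA candidates from read-stack evidence: at least 30
#' zero-mismatch reads supporting the mature arm and 10 for the star arm, at
#' least 50% 5' homogeneity on each arm, a 0-4 nt 3' overhang of the arm
#' duplex, a hairpin folding energy of at most -0.2 kcal/mol per nucleotide,
#' and a single hairpin loop (no internal sub-hairpins). All comparisons are
#' inclusive, as the thresholds are stated.
#'
#' @param mature_min_reads Minimum weighted 0-mismatch read count, mature arm.
#' @param star_min_reads Minimum weighted 0-mismatch read count, star arm.
#' @param homogeneity_min Minimum fraction of arm reads sharing the modal 5'
#'   start.
#' @param homogeneity_zero_mismatch_only If `TRUE`, the homogeneity
#'   denominator uses only 0-mismatch reads. The default (`FALSE`) counts all
#'   arm reads: the read-support criteria are the only ones stated in terms
#'   of 0-mismatch reads.
#' @param overhang_range Inclusive `[low, high]` range of allowed 3'-arm
#'   overhangs, in nucleotides.
#' @param mfe_per_nt_max Maximum (i.e. least negative) folding energy per
#'   nucleotide, kcal/mol/nt.
#' @param max_hairpin_loops Maximum number of hairpin loops.
#' @param arm_window Reads are assigned to an arm when their 5' end lies
#'   within this many nt of the arm's annotated 5' end.
#' @return A list of class `mirarch_filter_criteria`.
#' @export
filter_criteria <- function(mature_min_reads = 30,
                            star_min_reads = 10,
                            homogeneity_min = 0.5,
                            homogeneity_zero_mismatch_only = FALSE,
                            overhang_range = c(0L, 4L),
                            mfe_per_nt_max = -0.2,
                            max_hairpin_loops = 1L,
                            arm_window = 3L) {
  stopifnot(
    is_scalar_number(mature_min_reads), is_scalar_number(star_min_reads),
    is_scalar_number(homogeneity_min), is_scalar_number(mfe_per_nt_max),
    length(overhang_range) == 2, overhang_range[1] <= overhang_range[2],
    is_scalar_number(max_hairpin_loops), is_scalar_number(arm_window)
  )
  structure(
    list(
      mature_min_reads = mature_min_reads,
      star_min_reads = star_min_reads,
      homogeneity_min = homogeneity_min,
      homogeneity_zero_mismatch_only = homogeneity_zero_mismatch_only,
      overhang_range = as.integer(overhang_range),
      mfe_per_nt_max = mfe_per_nt_max,
      max_hairpin_loops = as.integer(max_hairpin_loops),
      arm_window = as.integer(arm_window)
    ),
    class = "mirarch_filter_criteria"
  )
}

#' Assign aligned reads to precursor arms
#'
#' A read joins an arm when its 5' end (alignment start) lies within
#' `arm_window` nt of that arm's annotated 5' end, a tolerance that absorbs
#' Drosha/Dicer processing heterogeneity while keeping the two arms
#' unambiguous (annotated arms are far apart relative to the window).
#'
#' @param reads Tibble of collapsed read alignments against one precursor:
#'   columns `start`, `end` (0-based half-open precursor coordinates),
#'   `mismatches`, `count`.
#' @param candidate One-row tibble or list with `sequence`, `mature_start`,
#'   `mature_end`, `star_start`, `star_end`.
#' @param arm_window Assignment window in nt (default 3).
#' @return `reads` with an added `arm` column:
#'   `"mature"`, `"star"` or `"unassigned"`.
#' @export
assign_reads_to_arms <- function(reads, candidate, arm_window = 3L) {
  assert_columns(reads, c("start", "end", "mismatches", "count"), "read stack")
  len <- nchar(candidate$sequence)
  if (nrow(reads) > 0 && (any(reads$start < 0) || any(reads$end > len))) {
    abort("Read alignment lies outside the precursor.")
  }
  arm <- rep("unassigned", nrow(reads))
  arm[abs(reads$start - candidate$mature_start) <= arm_window] <- "mature"
  arm[abs(reads$start - candidate$star_start) <= arm_window] <- "star"
  dplyr::mutate(reads, arm = arm)
}

#' Weighted 0-mismatch read support of an arm
#'
#' @param arm_reads Tibble of reads assigned to one arm (`mismatches`,
#'   `count`).
#' @return Sum of `count` over perfectly matching reads.
#' @export
arm_support <- function(arm_reads) {
  if (nrow(arm_reads) == 0) return(0)
  sum(arm_reads$count[arm_reads$mismatches == 0])
}

#' 5' homogeneity of an arm's read stack
#'
#' Fraction of the arm's (multiplicity-weighted) reads that share the modal
#' 5' start position — the hallmark of precise Drosha/Dicer processing. All
#' arm reads count by default, regardless of mismatches.
#'
#' @inheritParams arm_support
#' @param zero_mismatch_only Restrict the numerator and denominator to
#'   0-mismatch reads.
#' @return Fraction in (0, 1], or 0 for an empty arm (which fails the
#'   criterion).
#' @export
five_prime_homogeneity <- function(arm_reads, zero_mismatch_only = FALSE) {
  if (zero_mismatch_only) {
    arm_reads <- arm_reads[arm_reads$mismatches == 0, , drop = FALSE]
  }
  if (nrow(arm_reads) == 0 || sum(arm_reads$count) == 0) return(0)
  by_start <- tapply(arm_reads$count, arm_reads$start, sum)
  max(by_start) / sum(by_start)
}

#' 3' overhang of the precursor arm duplex
#'
#' Measures how far the 3'-arm strand's 3' terminus protrudes past the base
#' paired with the 5'-arm strand's 5' terminus — the signature two-nucleotide
#' 3' overhang left by RNase III cleavage. If the 5'-arm terminus itself is
#' unpaired, the nearest paired position within 3 nt towards the loop is
#' used and the offset subtracted, which extrapolates the duplex end;
#' negative values indicate a recessed 3' end. If no paired position is
#' found within the search window the overhang is undefined (`NA`) and the
#' criterion fails.
#'
#' @param candidate One-row tibble or list with `dot_bracket`,
#'   `mature_start`, `mature_end`, `star_start`, `star_end`.
#' @return Integer overhang in nt, or `NA` when undefined.
#' @export
three_prime_overhang <- function(candidate) {
  pt <- pair_table(candidate$dot_bracket)
  arms <- rbind(
    c(candidate$mature_start, candidate$mature_end),
    c(candidate$star_start, candidate$star_end)
  )
  fivep <- arms[which.min(arms[, 1]), ]
  threep <- arms[which.max(arms[, 1]), ]
  i5 <- fivep[[1]] # 5'-arm strand 5' terminus, 0-based
  for (d in 0:3) {
    partner <- pt[[i5 + d + 1L]]
    if (!is.na(partner)) {
      return(as.integer((threep[[2]] - 1L) - partner - d))
    }
  }
  NA_integer_
}

#' Folding energy per nucleotide
#'
#' @param mfe_kcal_mol Minimum free energy of the hairpin, kcal/mol.
#' @param precursor_length Precursor length in nt.
#' @return Energy density in kcal/mol/nt.
#' @export
mfe_per_nucleotide <- function(mfe_kcal_mol, precursor_length) {
  if (any(precursor_length <= 0)) abort("Precursor length must be positive.")
  mfe_kcal_mol / precursor_length
}

#' Evaluate novel pre-miRNA candidates against the high-confidence filter
#'
#' Applies all six criteria — mature-arm support, star-arm support, 5'
#' homogeneity (both arms), 3' overhang, folding-energy density, and
#' single-hairpin structure — and reports the measured value and a boolean
#' per criterion. `overall_pass` is their conjunction. An optional exclusion
#' list drops candidates matching known non-miRNA ncRNAs identified
#' externally.
#'
#' @param candidates Tibble with columns `id`, `sequence`, `dot_bracket`,
#'   `mfe_kcal_mol`, `mature_start`, `mature_end`, `star_start`, `star_end`.
#' @param reads Tibble of collapsed read alignments with a `precursor_id`
#'   column plus `start`, `end`, `mismatches`, `count`.
#' @param criteria A [filter_criteria()] object.
#' @param exclude Character vector of candidate ids to drop before
#'   evaluation (known-ncRNA exclusion hook).
#' @return A tibble of class `mirarch_filter_report`, one row per candidate,
#'   with measured values, per-criterion booleans and `overall_pass`.
#' @export
evaluate_candidates <- function(candidates, reads, criteria = filter_criteria(),
                                exclude = NULL) {
  assert_columns(
    candidates,
    c("id", "sequence", "dot_bracket", "mfe_kcal_mol",
      "mature_start", "mature_end", "star_start", "star_end"),
    "candidate table"
  )
  assert_columns(reads, c("precursor_id", "start", "end", "mismatches", "count"),
                 "read stack")
  if (!is.null(exclude)) {
    candidates <- candidates[!candidates$id %in% exclude, , drop = FALSE]
  }
  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    cand_reads <- reads[reads$precursor_id == cand$id, , drop = FALSE]
    assigned <- assign_reads_to_arms(cand_reads, cand, criteria$arm_window)
    mature <- assigned[assigned$arm == "mature", , drop = FALSE]
    star <- assigned[assigned$arm == "star", , drop = FALSE]

    mature_support <- arm_support(mature)
    star_support <- arm_support(star)
    homog_mature <- five_prime_homogeneity(
      mature, criteria$homogeneity_zero_mismatch_only)
    homog_star <- five_prime_homogeneity(
      star, criteria$homogeneity_zero_mismatch_only)
    overhang <- tryCatch(three_prime_overhang(cand), error = function(e) NA_integer_)
    mfe_nt <- mfe_per_nucleotide(cand$mfe_kcal_mol, nchar(cand$sequence))
    loops <- tryCatch(count_hairpin_loops(cand$dot_bracket),
                      error = function(e) NA_integer_)

    tibble(
      id = cand$id,
      mature_support = mature_support,
      mature_support_pass = mature_support >= criteria$mature_min_reads,
      star_support = star_support,
      star_support_pass = star_support >= criteria$star_min_reads,
      homogeneity = min(homog_mature, homog_star),
      homogeneity_pass = homog_mature >= criteria$homogeneity_min &&
        homog_star >= criteria$homogeneity_min,
      overhang = overhang,
      overhang_pass = !is.na(overhang) &&
        overhang >= criteria$overhang_range[1] &&
        overhang <= criteria$overhang_range[2],
      mfe_per_nt = mfe_nt,
      mfe_pass = mfe_nt <= criteria$mfe_per_nt_max,
      n_hairpin_loops = loops,
      loops_pass = !is.na(loops) && loops <= criteria$max_hairpin_loops
    )
  })
  out <- dplyr::bind_rows(rows)
  pass_cols <- grep("_pass$", names(out), value = TRUE)
  out$overall_pass <- Reduce(`&`, out[pass_cols])
  class(out) <- c("mirarch_filter_report", class(out))
  out
}

#' Pair novel mature miRNAs with known miRNAs sharing their seed
#'
#' Two mature sequences belong to the same seed family when nucleotides 2-8
#' (5' to 3') are identical.
#'
#' @param novel_matures,reference_matures Tibbles with `id` and `sequence`
#'   (mature sequences, at least 8 nt).
#' @return Tibble of matches: `novel_id`, `reference_id`, `seed`.
#' @export
seed_family_match <- function(novel_matures, reference_matures) {
  assert_columns(novel_matures, c("id", "sequence"), "novel mature table")
  assert_columns(reference_matures, c("id", "sequence"), "reference mature table")
  if (any(nchar(c(novel_matures$sequence, reference_matures$sequence)) < 8)) {
    abort("Mature sequences must be at least 8 nt for seed comparison.")
  }
  novel <- dplyr::mutate(novel_matures, seed = substr(.data$sequence, 2, 8))
  ref <- dplyr::mutate(reference_matures, seed = substr(.data$sequence, 2, 8))
  dplyr::inner_join(
    dplyr::select(novel, novel_id = "id", "seed"),
    dplyr::select(ref, reference_id = "id", "seed"),
    by = "seed",
    relationship = "many-to-many"
  )[, c("novel_id", "reference_id", "seed")]
}
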