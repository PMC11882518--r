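#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a hairpin filter report
#'
#' Pivots the per-candidate report to one row per (candidate, criterion)
#' with the measured value and its pass/fail decision.
#'
#' @param x A `mirarch_filter_report` from [evaluate_candidates()].
#' @param ... Unused.
#' @return A long tibble: `id`, `criterion`, `value`, `pass`.
#' @export
tidy.mirarch_filter_report <- function(x, ...) {
  measures <- c(
    mature_support = "mature_support", star_support = "star_support",
    homogeneity = "homogeneity", overhang = "overhang",
    mfe_per_nt = "mfe_per_nt", hairpin_loops = "n_hairpin_loops"
  )
  passes <- c(
    mature_support = "mature_support_pass", star_support = "star_support_pass",
    homogeneity = "homogeneity_pass", overhang = "overhang_pass",
    mfe_per_nt = "mfe_pass", hairpin_loops = "loops_pass"
  )
  purrr::map_dfr(names(measures), function(cr) {
    tibble(
      id = x$id,
      criterion = cr,
      value = as.numeric(x[[measures[[cr]]]]),
      pass = x[[passes[[cr]]]]
    )
  })
}

#' @rdname tidy.mirarch_filter_report
#' @return For `glance()`: a one-row summary with candidate and pass counts.
#' @export
glance.mirarch_filter_report <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    n_pass = sum(x$overall_pass),
    pass_rate = if (nrow(x) > 0) mean(x$overall_pass) else NA_real_
  )
}

#' Tidy an enrichment ranking
#'
#' @param x A `mirarch_enrichment` from [mirna_set_enrichment()].
#' @param ... Unused.
#' @return The ranking as a plain tibble with a `rank` column.
#' @export
tidy.mirarch_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  out$rank <- seq_len(nrow(out))
  out[, c("rank", setdiff(names(out), "rank"))]
}

#' @rdname tidy.mirarch_enrichment
#' @return For `glance()`: a one-row summary of the ranking.
#' @export
glance.mirarch_enrichment <- function(x, ...) {
  tibble(
    n_mirnas = nrow(x),
    top_mirna = if (nrow(x) > 0) x$mirna_id[[1]] else NA_character_,
    top_p = if (nrow(x) > 0) x$p_hyper[[1]] else NA_real_,
    n_significant = sum(x$p_hyper <= 0.05)
  )
}
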