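#' Base-pair table of a dot-bracket structure
#'
#' @param dot_bracket Dot-bracket string using `(`, `)` and `.`.
#' @return Integer vector the length of the structure; element `i` is the
#'   0-based position paired with position `i - 1`, or `NA` if unpaired.
#' @export
pair_table <- function(dot_bracket) {
  if (!is.character(dot_bracket) || length(dot_bracket) != 1) {
    abort("`dot_bracket` must be a single string.")
  }
  ch <- strsplit(dot_bracket, NULL)[[1]]
  if (any(!ch %in% c("(", ")", "."))) {
    abort("Dot-bracket may only contain '(', ')' and '.'.")
  }
  n <- length(ch)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[[i]] == "(") {
      stack <- c(stack, i)
    } else if (ch[[i]] == ")") {
      if (length(stack) == 0) abort("Unbalanced dot-bracket: unmatched ')'.")
      j <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      pt[[i]] <- j - 1L
      pt[[j]] <- i - 1L
    }
  }
  if (length(stack) > 0) abort("Unbalanced dot-bracket: unmatched '('.")
  pt
}

#' Count hairpin loops in a dot-bracket structure
#'
#' A hairpin loop is a maximal unpaired run directly closed by a base pair,
#' i.e. a `(` and `)` with no pairs between them. A genuine single stem-loop
#' precursor has exactly one; any bifurcation or internal sub-hairpin yields
#' two or more, which fails the single-hairpin criterion of the novel
#' pre-miRNA filter.
#'
#' @inheritParams pair_table
#' @return Integer number of hairpin loops.
#' @export
count_hairpin_loops <- function(dot_bracket) {
  pair_table(dot_bracket) # validates characters and balance
  hits <- gregexpr("\\(\\.*\\)", dot_bracket)[[1]]
  sum(hits > 0)
}
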