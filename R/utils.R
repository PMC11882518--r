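#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Reverse-complement an RNA string (A/C/G/U, Watson-Crick only).
rc_rna <- function(x) {
  chartr("ACGU", "UGCA", vapply(
    strsplit(x, NULL),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  ))
}

# Watson-Crick complement of single RNA bases (vectorised over characters).
comp_rna <- function(x) chartr("ACGU", "UGCA", x)

normalise_rna <- function(x) {
  x <- chartr("t", "u", chartr("T", "U", x))
  toupper(x)
}

assert_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside the RNA alphabet (A/C/G/U): %s",
      what, paste(utils::head(x[bad], 3), collapse = ", ")
    ))
  }
  invisible(x)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators have no hidden global side effects.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`rng_seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
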