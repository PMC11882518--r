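# Pair codes used by the energy model: top-strand base then bottom-strand
# base, with the top strand written 5'->3'.
DUPLEX_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Nearest-neighbour parameters for RNA duplex energies
#'
#' Turner 2004 free-energy parameters at 37 degrees C, as tabulated in the
#' ViennaRNA `rna_turner2004.par` distribution: the 6x6 Watson-Crick + G:U
#' stack table, the intermolecular duplex initiation term (+4.10 kcal/mol)
#' and the terminal AU/GU penalty (+0.50 kcal/mol per helix end). The stack
#' entry `stack[p1, p2]` is the free energy of the dinucleotide step
#' 5'-ab-3' / 3'-a'b'-5' with `p1 = aa'` and `p2 = bb'`.
#'
#' @return List with elements `stack` (matrix), `init`, `terminal_au`.
#' @export
turner_2004_params <- function() {
  stack <- matrix(
    c( #  AU     UA     CG     GC     GU     UG
      -0.90, -1.10, -2.20, -2.10, -0.60, -1.40, # AU
      -1.30, -0.90, -2.40, -2.10, -1.00, -1.30, # UA
      -2.10, -2.10, -3.30, -2.40, -1.40, -2.10, # CG
      -2.40, -2.20, -3.40, -3.30, -1.50, -2.50, # GC
      -1.30, -1.40, -2.50, -2.10, -0.50,  1.30, # GU
      -1.00, -0.60, -1.50, -1.40,  0.30, -0.50  # UG
    ),
    nrow = 6, byrow = TRUE, dimnames = list(DUPLEX_PAIRS, DUPLEX_PAIRS)
  )
  list(stack = stack, init = 4.10, terminal_au = 0.50)
}

#' Hybridisation energy of the best intermolecular helix
#'
#' Free energy (kcal/mol) of the most stable contiguous intermolecular helix
#' between two RNA strands, by nearest-neighbour stack summation: every
#' gapless antiparallel alignment is considered, contiguous runs of
#' Watson-Crick or G:U pairs are scored as the sum of their stack energies
#' plus the duplex initiation term and terminal AU/GU penalties, and the
#' minimum over all runs is returned. Intramolecular structure is ignored.
#' By convention the value is never positive: if no helix scores below zero
#' (including the no-pair case) the energy is 0.
#'
#' @param strand_a,strand_b RNA sequences, both written 5'->3'.
#' @param params Energy parameters, see [turner_2004_params()].
#' @return Free energy in kcal/mol (<= 0).
#' @export
duplex_energy <- function(strand_a, strand_b, params = turner_2004_params()) {
  a <- strsplit(normalise_rna(strand_a), NULL)[[1]]
  b <- strsplit(normalise_rna(strand_b), NULL)[[1]]
  n <- length(a)
  m <- length(b)
  if (n == 0 || m == 0) return(0)

  # b reversed: an antiparallel gapless alignment pairs a[i] with rev_b[j]
  # along a diagonal (i - j constant).
  rev_b <- rev(b)
  pair_code <- outer(a, rev_b, paste0)
  pairable <- matrix(pair_code %in% DUPLEX_PAIRS, n, m)

  au_like <- c("AU", "UA", "GU", "UG")
  best <- 0
  for (off in (-(m - 1)):(n - 1)) {
    i <- max(1, 1 + off):min(n, m + off)
    j <- i - off
    ok <- pairable[cbind(i, j)]
    codes <- pair_code[cbind(i, j)]
    len <- length(ok)
    run_start <- 1
    k <- 1
    while (k <= len) {
      if (!ok[k]) {
        k <- k + 1
        next
      }
      run_start <- k
      while (k < len && ok[k + 1]) k <- k + 1
      run <- run_start:k
      steps <- if (length(run) >= 2) {
        params$stack[cbind(codes[run[-length(run)]], codes[run[-1]])]
      } else {
        numeric(0)
      }
      best <- min(best, helix_best(steps, codes[run], au_like, params))
      k <- k + 1
    }
  }
  min(0, best)
}

# Best (lowest) energy over all contiguous sub-helices of a maximal paired
# run: segment stack sum + initiation + terminal AU/GU penalties at the two
# closing pairs of the segment.
helix_best <- function(steps, codes, au_like, params) {
  L <- length(codes)
  end_pen <- ifelse(codes %in% au_like, params$terminal_au, 0)
  best <- Inf
  for (s in 1:L) {
    acc <- 0
    best <- min(best, params$init + 2 * end_pen[s]) # single-pair segment
    if (s < L) {
      for (t in (s + 1):L) {
        acc <- acc + steps[t - 1]
        best <- min(best, acc + params$init + end_pen[s] + end_pen[t])
      }
    }
  }
  best
}

#' Duplex energy of one predicted site in its UTR context
#'
#' Extracts the 8-nt site window plus `flank_up` nt of upstream (target 5')
#' context from the UTR and scores it against the full miRNA with
#' [duplex_energy()]. With `seed_only = TRUE` the miRNA is truncated to its
#' first 8 nt and no flank is added, scoring the seed helix alone.
#'
#' @param mirna_sequence Mature miRNA, 5'->3' RNA.
#' @param utr_sequence 3'UTR, 5'->3' RNA.
#' @param position 0-based start of the 8-nt site window in the UTR.
#' @param config A [prediction_config()] carrying `flank_up`, `seed_only`
#'   and the parameter table.
#' @return Free energy in kcal/mol (<= 0).
#' @export
site_energy <- function(mirna_sequence, utr_sequence, position,
                        config = prediction_config()) {
  n <- nchar(utr_sequence)
  if (position < 0 || position + 8 > n) {
    abort("Site window lies outside the UTR.")
  }
  if (isTRUE(config$seed_only)) {
    region <- substr(utr_sequence, position + 1, position + 8)
    return(duplex_energy(substr(mirna_sequence, 1, 8), region, config$energy_params))
  }
  from <- max(0, position - config$flank_up)
  region <- substr(utr_sequence, from + 1, position + 8)
  duplex_energy(mirna_sequence, region, config$energy_params)
}
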