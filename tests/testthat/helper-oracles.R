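# Independent oracles, deliberately implemented with different machinery
# than the package code they check.

# Per-position Watson-Crick pairing check between miRNA position i and its
# opposite target position t_i (t1 is the 3'-most window base).
oracle_classify <- function(mirna, window) {
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  m <- strsplit(mirna, NULL)[[1]]
  t <- rev(strsplit(window, NULL)[[1]]) # t[1] = t1, ..., t[8] = t8
  paired <- vapply(1:8, function(i) identical(wc[[m[[i]]]], t[[i]]), logical(1))
  t1_a <- t[[1]] == "A"
  if (all(paired[2:8])) {
    if (t1_a) "8mer" else "7mer-m8"
  } else if (all(paired[2:7])) {
    if (t1_a) "7mer-A1" else "6mer"
  } else if (all(paired[3:8])) {
    "off-6mer"
  } else {
    NA_character_
  }
}

# Regex scan of a whole UTR: classify every 8-nt window with oracle_classify.
oracle_scan <- function(mirna, utr) {
  n <- nchar(utr)
  if (n < 8) {
    return(data.frame(position = integer(0), site_class = character(0)))
  }
  starts <- seq_len(n - 7L)
  cls <- vapply(starts, function(s) {
    oracle_classify(mirna, substr(utr, s, s + 7L))
  }, character(1))
  keep <- !is.na(cls)
  data.frame(position = starts[keep] - 1L, site_class = cls[keep],
             stringsAsFactors = FALSE)
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of an urn
# with K successes and count those with >= k successes.
oracle_hyper <- function(k, K, n, N) {
  urn <- c(rep(1, K), rep(0, N - K))
  subsets <- utils::combn(N, n)
  hits <- colSums(matrix(urn[subsets], nrow = n))
  mean(hits >= k)
}

# Pair-table hairpin-loop count: pairs enclosing no other pair.
oracle_loop_count <- function(db) {
  ch <- strsplit(db, NULL)[[1]]
  open <- integer(0)
  pairs <- list()
  for (i in seq_along(ch)) {
    if (ch[[i]] == "(") open <- c(open, i)
    if (ch[[i]] == ")") {
      pairs[[length(pairs) + 1]] <- c(open[length(open)], i)
      open <- open[-length(open)]
    }
  }
  if (length(pairs) == 0) return(0L)
  sum(vapply(pairs, function(p) {
    !any(vapply(pairs, function(q) p[1] < q[1] && q[2] < p[2], logical(1)))
  }, logical(1)))
}

# Random balanced dot-bracket structures for property tests.
random_dot_bracket <- function(max_depth = 4) {
  # wrap random inner content in matched stems, recursively
  build <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.35) {
      return(strrep(".", sample(1:5, 1)))
    }
    k <- sample(1:3, 1)
    inner <- paste(vapply(seq_len(sample(1:2, 1)), function(i) build(depth + 1),
                          character(1)), collapse = strrep(".", sample(0:2, 1)))
    paste0(strrep("(", k), inner, strrep(")", k))
  }
  paste0(strrep(".", sample(0:2, 1)), build(1), strrep(".", sample(0:2, 1)))
}

# Brute-force duplex energy: enumerate all antiparallel gapless alignments
# and all contiguous sub-helices, scoring each with direct table lookups.
oracle_duplex <- function(a, b, params = turner_2004_params()) {
  pairs_ok <- c("AU", "UA", "CG", "GC", "GU", "UG")
  av <- strsplit(a, NULL)[[1]]
  bv <- strsplit(b, NULL)[[1]]
  n <- length(av); m <- length(bv)
  best <- 0
  au_like <- c("AU", "UA", "GU", "UG")
  for (i in 1:n) {
    for (j in 1:m) {
      # helix starting with a[i] paired to b[j], extending i+1 vs j-1, ...
      codes <- character(0)
      ii <- i; jj <- j
      while (ii <= n && jj >= 1) {
        code <- paste0(av[[ii]], bv[[jj]])
        if (!code %in% pairs_ok) break
        codes <- c(codes, code)
        L <- length(codes)
        e <- params$init
        if (L >= 2) {
          e <- e + sum(params$stack[cbind(codes[-L], codes[-1])])
        }
        e <- e + (codes[[1]] %in% au_like) * params$terminal_au +
          (codes[[L]] %in% au_like) * params$terminal_au
        best <- min(best, e)
        ii <- ii + 1; jj <- jj - 1
      }
    }
  }
  min(0, best)
}

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "U", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_mirna <- function(len = 21) {
  tibble::tibble(id = "mir_rand", sequence = random_rna(len))
}

# Draw a miRNA + planted-site spec and realise the UTR; on the rare
# infeasible draw (a doubly periodic seed whose planted window forces a
# spurious neighbour site for every free-character choice) redraw the
# miRNA. The redraw count is returned so tests can assert it stays rare.
simulate_utr_redraw <- function(spec_seed, utr_length = 300,
                                max_redraws = 25) {
  for (r in seq_len(max_redraws)) {
    mir <- random_mirna()
    n_sites <- sample(0:4, 1)
    classes <- sample(c("8mer", "7mer-m8", "7mer-A1", "6mer", "off-6mer"),
                      n_sites, replace = TRUE)
    positions <- sort(sample(seq(0, utr_length - 20, by = 10), n_sites))
    spec <- utr_sim_spec(
      utr_length = utr_length,
      planted_sites = tibble::tibble(site_class = classes,
                                     position = positions),
      background_gc = sample(c(0.3, 0.4, 0.5), 1),
      rng_seed = spec_seed + r - 1
    )
    sim <- tryCatch(simulate_utr_with_sites(mir, spec),
                    error = function(e) NULL)
    if (!is.null(sim)) {
      return(list(mirna = mir, sim = sim, redraws = r - 1))
    }
  }
  stop("UTR simulation kept drawing infeasible miRNA seeds.")
}
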