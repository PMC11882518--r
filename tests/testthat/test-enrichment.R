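interactions_for <- function(k, K, n, N) {
  # one focal miRNA with n interactions (k in-set); filler miRNAs supply the
  # remaining N - n interactions, K - k of them with set genes
  set_genes <- paste0("s", seq_len(K))
  bg_genes <- paste0("b", seq_len(N))
  focal <- tibble::tibble(
    mirna_id = "focal",
    gene_id = c(set_genes[seq_len(k)], bg_genes[seq_len(n - k)])
  )
  filler <- tibble::tibble(
    mirna_id = "filler",
    gene_id = c(
      if (K - k > 0) set_genes[(k + 1):K] else character(0),
      bg_genes[(n - k + 1):(n - k + (N - n - (K - k)))]
    )
  )
  list(interactions = dplyr::bind_rows(focal, filler),
       gene_set = set_genes)
}

test_that("the worked hypergeometric example reproduces exactly", {
  x <- interactions_for(k = 3, K = 4, n = 5, N = 10)
  res <- mirna_set_enrichment(x$interactions, x$gene_set)
  focal <- res[res$mirna_id == "focal", ]
  expect_equal(focal$p_hyper, 66 / 252, tolerance = 1e-12)
  expect_equal(focal$fold_enrichment, 1.5)
  expect_equal(focal[, c("k", "n", "K", "N")],
               tibble::tibble(k = 3L, n = 5L, K = 4L, N = 10L),
               ignore_attr = TRUE)
})

test_that("tail probabilities match exhaustive enumeration at small N", {
  for (N in c(6, 9, 11)) {
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 2, N - 1)) {
        for (k in 0:min(n, K)) {
          expect_equal(
            mirarch:::hyper_tail_p(k, K, n, N),
            oracle_hyper(k, K, n, N),
            tolerance = 1e-9,
            info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k)
          )
        }
      }
    }
  }
})

test_that("degenerate configurations behave as certain events", {
  x <- interactions_for(k = 2, K = 6, n = 4, N = 12)
  # gene_set covering every gene: k = n, p = 1, fold = 1 for every miRNA
  all_genes <- unique(x$interactions$gene_id)
  res <- mirna_set_enrichment(x$interactions, all_genes)
  expect_true(all(res$p_hyper == 1))
  expect_true(all(res$fold_enrichment == 1))
  # k = 0 is a certain event under the inclusive upper tail
  res0 <- mirna_set_enrichment(x$interactions, "not_a_gene")
  expect_true(all(res0$p_hyper == 1))
  expect_error(mirna_set_enrichment(x$interactions[0, ], "s1"), "empty")
})

test_that("the tail is non-increasing in k and the pmf sums to one", {
  for (params in list(c(40, 12, 9), c(200, 50, 30), c(100000, 20000, 150))) {
    N <- params[1]; K <- params[2]; n <- params[3]
    tails <- vapply(0:min(n, K), function(k) mirarch:::hyper_tail_p(k, K, n, N),
                    numeric(1))
    expect_true(all(diff(tails) <= 1e-12))
    # pmf mass from the log-space coefficients
    i <- max(0, n - (N - K)):min(n, K)
    pmf <- exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
})

test_that("results are ranked by p, then fold, then id, and BH is emitted", {
  set.seed(5)
  sim <- simulate_interactome(interactome_sim_spec(
    n_mirnas = 12, n_genes = 300, set_size = 60,
    enrichment_factor = 4, rng_seed = 9
  ))
  res <- mirna_set_enrichment(sim$interactions, sim$gene_set)
  expect_equal(res$mirna_id[[1]], sim$truth)
  expect_true(!is.unsorted(res$p_hyper))
  expect_equal(res$bh_fdr, p.adjust(res$p_hyper, "BH"))
  # agreement with the reference distribution function
  expect_equal(res$p_hyper,
               phyper(res$k - 1, res$K, res$N - res$K, res$n,
                      lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("the gene-universe variant uses genes as the urn", {
  x <- interactions_for(k = 3, K = 4, n = 5, N = 10)
  res <- mirna_set_enrichment(x$interactions, x$gene_set, universe = "gene")
  focal <- res[res$mirna_id == "focal", ]
  expect_equal(focal$N, length(unique(x$interactions$gene_id)))
  expect_equal(focal$K, 4L)
})

test_that("the domain gene set matches a hand enumeration on a toy fixture", {
  genes <- paste0("g", 1:20)
  de_a <- tibble::tibble(
    gene_id = genes,
    log2fc = c(rep(1, 8), rep(0.2, 12)), # g1-g8 up vs A
    padj = rep(0.01, 20)
  )
  de_b <- tibble::tibble(
    gene_id = genes,
    log2fc = c(rep(0.2, 4), rep(1, 8), rep(0.2, 8)), # g5-g12 up vs B
    padj = rep(0.01, 20)
  )
  terms <- tibble::tibble(
    term_id = c("T_strong", "T_weak_fold", "T_weak_fdr"),
    fold_enrichment = c(3, 1.5, 4),
    fdr = c(0.01, 0.01, 0.5)
  )
  annot <- tibble::tibble(
    gene_id = c("g5", "g6", "g15", "g7", "g8"),
    term_id = c("T_strong", "T_strong", "T_strong", "T_weak_fold", "T_weak_fdr")
  )
  # up in both: g5-g8; annotated to a passing term: g5, g6, g15
  expect_equal(build_domain_gene_set(de_a, de_b, terms, annot),
               c("g5", "g6"))
  # gene up in only one comparison is excluded even when annotated
  expect_false("g15" %in% build_domain_gene_set(de_a, de_b, terms, annot))
  expect_warning(
    empty <- build_domain_gene_set(de_a, de_b, terms[terms$fdr > 0.2, ], annot),
    "empty"
  )
  expect_equal(empty, character(0))
})
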