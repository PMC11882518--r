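toy_counts <- function(m) {
  tibble::as_tibble(cbind(
    tibble::tibble(gene_id = paste0("g", seq_len(nrow(m)))),
    as.data.frame(m)
  ))
}

test_that("CPM scales every library to one million", {
  counts <- toy_counts(matrix(c(10, 90, 25, 75), ncol = 2,
                              dimnames = list(NULL, c("L1", "L2"))))
  out <- cpm(counts)
  expect_equal(out$L1, c(1e5, 9e5))
  expect_equal(out$L2, c(25e4, 75e4))
  m <- as.matrix(out[, -1])
  expect_true(all(abs(colSums(m) - 1e6) < 1e-6))
  # rank order within a library is preserved
  expect_equal(order(counts$L1), order(out$L1))
  zero <- toy_counts(matrix(c(0, 0, 1, 2), ncol = 2,
                            dimnames = list(NULL, c("L1", "L2"))))
  expect_error(cpm(zero), "positive total")
})

test_that("expression threshold is strict and needs two libraries", {
  # gene above threshold in exactly 2 of 4 libraries is kept, 1 of 4 is not,
  # and CPM exactly at the threshold never counts as above
  cfg <- expression_config(cpm_threshold_small_rna = 1e5)
  counts <- toy_counts(matrix(c(
    2, 8, # L1: g1 cpm 2e5 (>), g2 8e5
    2, 8, # L2: g1 2e5 (>)
    1, 9, # L3: g1 1e5 (== threshold, not above)
    1, 9  # L4
  ), ncol = 4, dimnames = list(NULL, paste0("L", 1:4))))
  kept <- expressed_genes(counts, cfg, assay = "small_rna")
  expect_true("g1" %in% kept) # above in exactly two libraries
  one_lib <- toy_counts(matrix(c(2, 8, 1, 9, 1, 9, 1, 9), ncol = 4,
                               dimnames = list(NULL, paste0("L", 1:4))))
  expect_false("g1" %in% expressed_genes(one_lib, cfg, assay = "small_rna"))
  at_threshold <- toy_counts(matrix(rep(c(1, 9), 4), ncol = 4,
                                    dimnames = list(NULL, paste0("L", 1:4))))
  expect_false("g1" %in% expressed_genes(at_threshold, cfg, assay = "small_rna"))
  # inclusive variant is available behind the configuration switch
  incl <- expression_config(cpm_threshold_small_rna = 1e5, strict_above = FALSE)
  expect_true("g1" %in% expressed_genes(at_threshold, incl, assay = "small_rna"))
})

test_that("expression filter is monotone in the threshold", {
  set.seed(1)
  counts <- toy_counts(matrix(rpois(200, 30), ncol = 4,
                              dimnames = list(NULL, paste0("L", 1:4))))
  strict <- expressed_genes(counts, expression_config(), "small_rna")
  lax <- expressed_genes(counts, expression_config(cpm_threshold_small_rna = 1),
                         "small_rna")
  expect_true(all(strict %in% lax))
})

test_that("DE filtering keeps both boundaries inclusively", {
  de <- tibble::tibble(
    gene_id = c("at_boundary", "below_fc", "bad_p", "down", "na_p"),
    log2fc = c(log2(1.5), 0.5, 2, -1, 3),
    padj = c(0.05, 0.01, 0.2, 0.01, NA)
  )
  expect_message(kept <- filter_de(de), "missing padj")
  expect_setequal(kept$gene_id, c("at_boundary", "down"))
})

test_that("overlap counts partition the union into exclusive patterns", {
  out <- overlap_counts(list(A = c("x", "y"), B = c("y", "z")))
  expect_setequal(out$pattern, c("A", "B", "A&B"))
  expect_equal(out$count[match(c("A", "B", "A&B"), out$pattern)], c(1L, 1L, 1L))
  expect_equal(sum(out$count), 3) # |union|

  same <- overlap_counts(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$pattern, "A&B")
  expect_equal(same$count, 2L)

  disjoint <- overlap_counts(list(A = "x", B = "y"))
  expect_false("A&B" %in% disjoint$pattern)
  expect_error(overlap_counts(list(c("x"))), "at least two")
})

test_that("row z-scores have mean 0, population sd 1, and are affine-invariant", {
  counts <- toy_counts(matrix(c(1, 10, 2, 20, 3, 30), ncol = 3,
                              dimnames = list(NULL, paste0("L", 1:3))))
  z <- as.matrix(row_zscore(counts)[, -1])
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(unname(sqrt(rowMeans(z^2))), c(1, 1))
  # location/scale invariance
  shifted <- counts
  shifted[, -1] <- shifted[, -1] * 3.7 + 11
  expect_equal(row_zscore(shifted)[, -1], row_zscore(counts)[, -1])
  # constant rows collapse to zero with a warning
  flat <- toy_counts(matrix(c(5, 5, 5), ncol = 3,
                            dimnames = list(NULL, paste0("L", 1:3))))
  expect_warning(zf <- row_zscore(flat), "constant")
  expect_equal(unlist(zf[, -1], use.names = FALSE), c(0, 0, 0))
})

test_that("Spearman matrix is symmetric with unit diagonal and midrank ties", {
  counts <- toy_counts(matrix(c(1, 2, 3, 4, 1, 3, 2, 4, 4, 3, 2, 1), ncol = 3,
                              dimnames = list(NULL, c("L1", "L2", "L3"))))
  s <- spearman_matrix(counts)
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, 3))
  expect_equal(s["L1", "L2"], 0.8) # hand-computed midrank value
  expect_equal(s["L1", "L3"], -1) # exactly reversed ranks
  dup <- toy_counts(matrix(c(1, 2, 3, 1, 2, 3), ncol = 2,
                           dimnames = list(NULL, c("L1", "L2"))))
  expect_equal(spearman_matrix(dup)["L1", "L2"], 1)
})

test_that("ddCt fold change follows 2^-ddCt", {
  expect_equal(ddct_fold_change(20, 20, 20, 20), 1)
  expect_equal(ddct_fold_change(21, 20, 20, 20), 0.5) # ddCt = 1
  expect_equal(ddct_fold_change(18, 20, 20, 20), 4) # ddCt = -2
  # normalising identical targets to identical references is always 1
  expect_equal(ddct_fold_change(15.3, 15.3, 28.1, 28.1), 1)
})
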