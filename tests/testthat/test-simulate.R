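test_that("every generator is a pure function of its spec", {
  h1 <- simulate_hairpin_candidate(hairpin_sim_spec(rng_seed = 5))
  h2 <- simulate_hairpin_candidate(hairpin_sim_spec(rng_seed = 5))
  expect_identical(h1, h2)
  h3 <- simulate_hairpin_candidate(hairpin_sim_spec(rng_seed = 6))
  expect_false(identical(h1$candidate$sequence, h3$candidate$sequence))

  mir <- tibble::tibble(id = "m", sequence = "AGCAUUAACGGUCAAGCUUU")
  us <- utr_sim_spec(utr_length = 120,
                     planted_sites = tibble::tibble(site_class = "8mer",
                                                    position = 50L),
                     rng_seed = 3)
  expect_identical(simulate_utr_with_sites(mir, us),
                   simulate_utr_with_sites(mir, us))

  cs <- count_sim_spec(n_genes = 100, rng_seed = 4)
  expect_identical(simulate_count_matrix(cs), simulate_count_matrix(cs))

  is <- interactome_sim_spec(n_mirnas = 10, n_genes = 100, set_size = 20,
                             rng_seed = 8)
  expect_identical(simulate_interactome(is), simulate_interactome(is))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(runif(0))
  invisible(simulate_hairpin_candidate(hairpin_sim_spec(rng_seed = 99)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("hairpin specs force each criterion's truth value", {
  all_pass <- simulate_hairpin_candidate(hairpin_sim_spec(rng_seed = 1))
  expect_true(all_pass$truth$overall_pass)
  star9 <- simulate_hairpin_candidate(hairpin_sim_spec(star_reads_0mm = 9,
                                                       rng_seed = 1))
  expect_false(star9$truth$star_support_pass)
  expect_true(star9$truth$mature_support_pass)
  expect_true(star9$truth$homogeneity_pass)
  sub2 <- simulate_hairpin_candidate(hairpin_sim_spec(n_subhairpins = 2,
                                                      rng_seed = 1))
  expect_false(sub2$truth$loops_pass)
  expect_equal(count_hairpin_loops(sub2$candidate$dot_bracket), 2)
})

test_that("generated hairpins realise the requested read stack exactly", {
  spec <- hairpin_sim_spec(mature_reads_0mm = 37, star_reads_0mm = 12,
                           mature_reads_1mm = 6, homogeneity_target = 0.7,
                           rng_seed = 17)
  sim <- simulate_hairpin_candidate(spec)
  assigned <- assign_reads_to_arms(sim$reads, sim$candidate)
  mature <- assigned[assigned$arm == "mature", ]
  expect_equal(sum(mature$count[mature$mismatches == 0]), 37)
  expect_equal(sum(mature$count), 43)
  expect_equal(sum(assigned$count[assigned$arm == "star"]), 12)
  # read lengths respect the upstream 18-25 nt filter
  expect_true(all(sim$reads$end - sim$reads$start >= 18))
  expect_true(all(sim$reads$end - sim$reads$start <= 25))
})

test_that("infeasible hairpin specs are rejected", {
  expect_error(hairpin_sim_spec(homogeneity_target = 0), "in \\(0, 1\\]")
  expect_error(hairpin_sim_spec(mature_reads_0mm = -1), "non-negative")
  spread_too_thin <- hairpin_sim_spec(homogeneity_target = 0.1, rng_seed = 1)
  expect_error(simulate_hairpin_candidate(spread_too_thin), "unreachable")
})

test_that("UTR specs reject overlapping or out-of-range sites", {
  expect_error(
    utr_sim_spec(utr_length = 100,
                 planted_sites = tibble::tibble(
                   site_class = c("8mer", "6mer"), position = c(10L, 14L))),
    "overlap"
  )
  expect_error(
    utr_sim_spec(utr_length = 50,
                 planted_sites = tibble::tibble(site_class = "8mer",
                                                position = 47L)),
    "fit inside"
  )
  mir <- tibble::tibble(id = "m", sequence = "ACGUACG") # 7 nt
  expect_error(
    simulate_utr_with_sites(mir, utr_sim_spec(utr_length = 50, rng_seed = 1)),
    "at least 8 nt"
  )
})

test_that("a siteless spec yields a UTR with no sites at all", {
  mir <- tibble::tibble(id = "m", sequence = "AGCAUUAACGGUCAAGCUUU")
  sim <- simulate_utr_with_sites(mir, utr_sim_spec(utr_length = 250,
                                                   rng_seed = 10))
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nrow(oracle_scan(mir$sequence, sim$utr$sequence)), 0)
})

test_that("planted count-matrix fold changes are realised on average", {
  spec <- count_sim_spec(n_genes = 2000, de_fraction = 0.1,
                         log2fc_magnitude = 2, nb_dispersion = 0.02,
                         rng_seed = 12)
  sim <- simulate_count_matrix(spec)
  m <- as.matrix(sim$counts[, -1])
  post <- sim$meta$domain == "PBA_OFT"
  up <- sim$truth$true_log2fc > 0
  ratio <- rowMeans(m[up, post]) / rowMeans(m[up, !post])
  expect_equal(mean(ratio), 2^2, tolerance = 0.1)
  down <- sim$truth$true_log2fc < 0
  ratio_down <- rowMeans(m[down, post]) / rowMeans(m[down, !post])
  expect_equal(mean(ratio_down), 2^-2, tolerance = 0.1)
})

test_that("a zero DE fraction plants no fold changes", {
  sim <- simulate_count_matrix(count_sim_spec(n_genes = 50, de_fraction = 0,
                                              rng_seed = 2))
  expect_false(any(sim$truth$is_de))
  expect_true(all(sim$truth$true_log2fc == 0))
})

test_that("strong planted DE is exactly recoverable from true fold changes", {
  # applying the DE rule to the per-gene true log2 fold changes (with a
  # nominal p-value) recovers exactly the planted DE set
  sim <- simulate_count_matrix(count_sim_spec(n_genes = 500, de_fraction = 0.2,
                                              log2fc_magnitude = 2,
                                              rng_seed = 3))
  de_tbl <- tibble::tibble(gene_id = sim$truth$gene_id,
                           log2fc = sim$truth$true_log2fc,
                           padj = ifelse(sim$truth$is_de, 0.001, 1))
  kept <- filter_de(de_tbl)
  expect_setequal(kept$gene_id, sim$truth$gene_id[sim$truth$is_de])
})

test_that("the interactome planting matches its probability model", {
  spec <- interactome_sim_spec(n_mirnas = 30, n_genes = 1500, set_size = 300,
                               baseline_target_prob = 0.05,
                               enrichment_factor = 4, rng_seed = 77)
  sim <- simulate_interactome(spec)
  planted <- sim$interactions[sim$interactions$mirna_id == sim$truth, ]
  in_set_rate <- mean(sim$gene_set %in% planted$gene_id)
  expect_gt(in_set_rate, 0.12) # nominal 0.20 vs baseline 0.05
  others <- sim$interactions[sim$interactions$mirna_id != sim$truth, ]
  expect_equal(nrow(others) / (29 * 1500), 0.05, tolerance = 0.15)
  # no planted miRNA under the null
  null_sim <- simulate_interactome(interactome_sim_spec(
    n_mirnas = 10, n_genes = 200, set_size = 50,
    enrichment_factor = 1, rng_seed = 5
  ))
  expect_true(is.na(null_sim$truth))
})
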