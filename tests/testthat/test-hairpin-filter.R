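toy_candidate <- function(db = paste0(strrep("(", 30), strrep(".", 8),
                                      strrep(")", 30), ".."),
                          mfe = -20) {
  len <- nchar(db)
  tibble::tibble(
    id = "cand", sequence = strrep("A", len), dot_bracket = db,
    mfe_kcal_mol = mfe,
    mature_start = 0L, mature_end = 22L,
    star_start = len - 22L, star_end = len
  )
}

test_that("reads join an arm only within the 5'-end window", {
  cand <- toy_candidate()
  reads <- tibble::tibble(
    start = c(0L, 3L, 4L, 46L, 30L),
    end = c(22L, 25L, 26L, 68L, 52L),
    mismatches = 0L, count = 1
  )
  assigned <- assign_reads_to_arms(reads, cand)
  expect_equal(assigned$arm,
               c("mature", "mature", "unassigned", "star", "unassigned"))
  bad <- tibble::tibble(start = -1L, end = 20L, mismatches = 0L, count = 1)
  expect_error(assign_reads_to_arms(bad, cand), "outside the precursor")
})

test_that("arm support is the weighted 0-mismatch read count", {
  reads <- tibble::tibble(start = c(0L, 1L, 0L), end = 22L,
                          mismatches = c(0L, 0L, 1L), count = c(20, 15, 100))
  expect_equal(arm_support(reads), 35)
  expect_equal(arm_support(reads[0, ]), 0)
})

test_that("5' homogeneity is the weighted modal-start fraction", {
  reads <- tibble::tibble(start = c(10L, 11L), end = 32L,
                          mismatches = 0L, count = c(30, 10))
  expect_equal(five_prime_homogeneity(reads), 0.75)
  # a tie still yields the shared maximum fraction
  tie <- tibble::tibble(start = c(10L, 11L), end = 32L,
                        mismatches = 0L, count = c(20, 20))
  expect_equal(five_prime_homogeneity(tie), 0.5)
  # all reads share one start
  one <- tibble::tibble(start = 10L, end = 32L, mismatches = 1L, count = 7)
  expect_equal(five_prime_homogeneity(one), 1)
  expect_equal(five_prime_homogeneity(one, zero_mismatch_only = TRUE), 0)
  expect_equal(five_prime_homogeneity(one[0, ]), 0)
})

test_that("3' overhang measures protrusion past the duplex end", {
  # blunt duplex: 24-bp stem, no unpaired 3' tail
  blunt <- toy_candidate(paste0(strrep("(", 30), strrep(".", 8), strrep(")", 30)))
  expect_equal(three_prime_overhang(blunt), 0L)
  # canonical 2-nt 3' overhang
  dicer <- toy_candidate(paste0(strrep("(", 30), strrep(".", 8), strrep(")", 30),
                                ".."))
  expect_equal(three_prime_overhang(dicer), 2L)
  # recessed 3' end: the 5'-arm terminus is unpaired, partner extrapolated
  recessed <- toy_candidate(paste0(".", strrep("(", 29), strrep(".", 8),
                                   strrep(")", 29)))
  expect_equal(three_prime_overhang(recessed), -1L)
  # wholly unpaired terminus region: overhang undefined
  open_end <- toy_candidate(paste0(strrep(".", 5), strrep("(", 25),
                                   strrep(".", 8), strrep(")", 25),
                                   strrep(".", 5)))
  expect_true(is.na(three_prime_overhang(open_end)))
})

test_that("folding energy density uses the stated inclusive boundary", {
  expect_equal(mfe_per_nucleotide(-30, 60), -0.5)
  expect_equal(mfe_per_nucleotide(-10, 100), -0.1)
  crit <- filter_criteria()
  expect_true(mfe_per_nucleotide(-12, 60) <= crit$mfe_per_nt_max) # exactly -0.2
  expect_error(mfe_per_nucleotide(-10, 0), "positive")
})

test_that("candidate evaluation matches generator truth across random specs", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:60) {
    spec <- hairpin_sim_spec(
      mature_reads_0mm = sample(25:45, 1),
      star_reads_0mm = sample(5:15, 1),
      mature_reads_1mm = sample(c(0, 5), 1),
      star_reads_1mm = sample(c(0, 3), 1),
      homogeneity_target = sample(c(0.35, 0.45, 0.5, 0.7, 1), 1),
      overhang_3p = sample(-2:6, 1),
      n_subhairpins = sample(1:3, 1),
      mfe_per_nt_target = sample(c(-0.4, -0.25, -0.2, -0.15), 1),
      mature_arm = sample(c("5p", "3p"), 1),
      rng_seed = i
    )
    sim <- simulate_hairpin_candidate(spec, id = paste0("c", i))
    report <- evaluate_candidates(sim$candidate, sim$reads)
    expect_equal(report$mature_support_pass, sim$truth$mature_support_pass)
    expect_equal(report$star_support_pass, sim$truth$star_support_pass)
    expect_equal(report$homogeneity_pass, sim$truth$homogeneity_pass)
    expect_equal(report$overhang_pass, sim$truth$overhang_pass)
    expect_equal(report$mfe_pass, sim$truth$mfe_pass)
    expect_equal(report$loops_pass, sim$truth$loops_pass)
    expect_equal(report$overall_pass, sim$truth$overall_pass)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 60)
})

test_that("single criterion failures are isolated", {
  sim <- simulate_hairpin_candidate(hairpin_sim_spec(star_reads_0mm = 9,
                                                     rng_seed = 1))
  report <- evaluate_candidates(sim$candidate, sim$reads)
  expect_false(report$star_support_pass)
  expect_true(all(unlist(report[c("mature_support_pass", "homogeneity_pass",
                                  "overhang_pass", "mfe_pass", "loops_pass")])))
  expect_false(report$overall_pass)
})

test_that("relaxing any single threshold never flips pass to fail", {
  set.seed(7)
  relaxed <- list(
    filter_criteria(mature_min_reads = 10),
    filter_criteria(star_min_reads = 2),
    filter_criteria(homogeneity_min = 0.2),
    filter_criteria(overhang_range = c(-2L, 8L)),
    filter_criteria(mfe_per_nt_max = -0.05),
    filter_criteria(max_hairpin_loops = 4L)
  )
  for (i in 1:20) {
    spec <- hairpin_sim_spec(
      mature_reads_0mm = sample(20:40, 1), star_reads_0mm = sample(5:15, 1),
      homogeneity_target = sample(c(0.4, 0.6, 1), 1),
      overhang_3p = sample(-1:6, 1), n_subhairpins = sample(1:2, 1),
      mfe_per_nt_target = sample(c(-0.3, -0.15), 1), rng_seed = 1000 + i
    )
    sim <- simulate_hairpin_candidate(spec)
    base <- evaluate_candidates(sim$candidate, sim$reads)
    for (crit in relaxed) {
      rel <- evaluate_candidates(sim$candidate, sim$reads, crit)
      expect_false(base$overall_pass && !rel$overall_pass)
    }
  }
})

test_that("exclusion list drops candidates before evaluation", {
  sim <- simulate_hairpin_candidate(hairpin_sim_spec(rng_seed = 2), id = "novel_1")
  report <- evaluate_candidates(sim$candidate, sim$reads, exclude = "novel_1")
  expect_equal(nrow(report), 0)
})

test_that("seed family matching compares nucleotides 2-8 exactly", {
  novel <- tibble::tibble(id = c("n1", "n2"),
                          sequence = c("AGCAUUAACGGUCAAGCUUU",
                                       "GAGCAUUAACGGUCAAGCUU"))
  ref <- tibble::tibble(
    id = c("r1", "r2", "n1_self"),
    sequence = c("UGCAUUAACGAAAAAAAAAA", # same 2-8 as n1
                 "CAUUAACGAAAAAAAAAAAA", # n1 seed shifted by 1: no match
                 "AGCAUUAACGGUCAAGCUUU")
  )
  hits <- seed_family_match(novel, ref)
  expect_setequal(paste(hits$novel_id, hits$reference_id),
                  c("n1 r1", "n1 n1_self"))
  expect_error(seed_family_match(tibble::tibble(id = "x", sequence = "ACGU"), ref),
               "at least 8 nt")
})
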