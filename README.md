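# mirarch

Candidate microRNA regulators from small RNA-seq of embryonic branchial
arches — and the building blocks to validate every step of finding them.

## The problem

Mouse branchial arches (BA1, BA2, and the posterior arches plus cardiac
outflow tract, PBA/OFT) are transient embryonic domains whose correct
differentiation depends on tightly buffered gene regulatory networks.
Small RNA-seq of these domains raises three bespoke computational
questions that generic RNA-seq tooling does not answer:

1. **Which predicted novel pre-miRNA hairpins are trustworthy?** Discovery
   tools over-call; a post-hoc filter on read-stack evidence is needed:
   ≥ 30 zero-mismatch reads on the mature arm and ≥ 10 on the star arm,
   ≥ 50% 5′ homogeneity, a 0–4 nt 3′ overhang, folding energy
   ≤ −0.2 kcal/mol/nt, and no internal sub-hairpins.
2. **Which genes does each expressed miRNA plausibly target?** Seed-match
   scanning of each gene's longest 3′UTR with the five-class taxonomy
   (8mer, 7mer-m8, 7mer-A1, 6mer, off-6mer), a nearest-neighbour duplex
   hybridisation energy (Turner 2004 parameters), and retention filters:
   drop marginal classes (6mer, off-6mer), drop sites weaker than
   −7 kcal/mol, drop UTRs with fewer than two retained sites.
3. **Which miRNA is most enriched for targets in a domain gene set?**
   With the predicted interactome as the urn — N interactions overall, K
   touching the gene set, n for one miRNA, k of them in the set — rank
   miRNAs by the inclusive upper-tail hypergeometric probability

   p = Σ<sub>i=k</sub><sup>min(n,K)</sup> C(K,i)·C(N−K,n−i) / C(N,n),

   with fold enrichment (k/n)/(K/N).

`mirarch` implements all three, plus the supporting expression layer (CPM
thresholds of 4.2 / 0.38 in ≥ 2 libraries, DE filtering at ≥ 1.5-fold and
adjusted p ≤ 0.05, z-scores, Spearman library correlation, 2^−ΔΔCt), an
end-to-end pipeline with a provenance manifest, and seed-controlled
synthetic-data generators that plant ground truth for every stage.

## Worked example

Filter a simulated novel hairpin candidate whose star arm has only 9
supporting reads:

```r
library(mirarch)

sim <- simulate_hairpin_candidate(
  hairpin_sim_spec(star_reads_0mm = 9, rng_seed = 7), id = "novel_14")
report <- evaluate_candidates(sim$candidate, sim$reads)
tidy(report)
#> # A tibble: 6 × 4
#>   id       criterion      value pass
#>   <chr>    <chr>          <dbl> <lgl>
#> 1 novel_14 mature_support 40    TRUE
#> 2 novel_14 star_support    9    FALSE
#> 3 novel_14 homogeneity     1    TRUE
#> 4 novel_14 overhang        2    TRUE
#> 5 novel_14 mfe_per_nt     -0.35 TRUE
#> 6 novel_14 hairpin_loops   1    TRUE
```

The star-arm criterion (≥ 10 zero-mismatch reads) fails, so
`report$overall_pass` is `FALSE`; every other criterion is measured and
passes. Next, rank miRNAs of a simulated interactome (20 miRNAs × 500
genes, one miRNA planted with 4-fold enriched targeting of an 80-gene
set):

```r
it <- simulate_interactome(interactome_sim_spec(
  n_mirnas = 20, n_genes = 500, set_size = 80,
  enrichment_factor = 4, rng_seed = 4))
rank <- mirna_set_enrichment(it$interactions, it$gene_set)
tidy(rank)
#> # A tibble: 20 × 9
#>    rank mirna_id     k     n     K     N p_hyper fold_enrichment bh_fdr
#>   <int> <chr>    <int> <int> <int> <int>   <dbl>           <dbl>  <dbl>
#> 1     1 mirna_01    12    31    83   529 0.00115            2.47 0.0231
#> 2     2 mirna_03     6    23    83   529 0.135              1.66 1
#> 3     3 mirna_13     6    25    83   529 0.183              1.53 1
#> # ℹ 17 more rows
```

The planted miRNA (`it$truth`, here `mirna_01`) ranks first: 12 of its 31
predicted interactions hit the set where 31 × 83/529 ≈ 4.9 were expected
by chance — a 2.47-fold enrichment at p = 0.0012. `autoplot(rank)` draws
the ranking; `glance(rank)` summarises it. `simulate_dataset()` +
`run_pipeline()` exercise the same flow end to end from files on disk.

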