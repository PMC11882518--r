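---
title: "Methods: hairpin filtering, seed target prediction and target-set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hairpin filtering, seed target prediction and target-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirarch)
```

## Scope and overall design

`mirarch` re-implements, as tested reusable components, the bespoke
computations of a small RNA-seq study design in embryonic branchial-arch
tissue: three dissected domains (first arch BA1, second arch BA2, and the
posterior arches plus outflow tract, PBA/OFT) at two embryonic stages
(E10.5, E11.5) with two replicate libraries each. The pipeline asks which
microRNAs are plausible regulators of the posterior domain's developmental
programme, in four steps:

1. **Expression filtering** — counts-per-million thresholds decide which
   miRNAs and genes are expressed at all.
2. **Target prediction** — seed-match scanning of each gene's longest
   3'UTR, followed by site-class, hybridisation-energy and site-count
   filters, yields a predicted miRNA–gene interactome.
3. **Domain gene set** — genes up-regulated in the focal domain against
   both reference domains, intersected with genes annotated under strongly
   enriched ontology terms from an external GO analysis.
4. **Enrichment ranking** — a hypergeometric test per miRNA asks whether
   its predicted interactions hit the domain gene set more often than
   expected from the full interactome.

A separate component, the novel pre-miRNA filter, post-processes hairpin
candidates proposed by an upstream discovery tool using read-stack
evidence. Upstream read mapping, DESeq2 model fitting, GO term computation
and any wet-lab validation are out of scope: their outputs are consumed as
plain tables.

All user-facing functions take data frames and return tibbles, so stages
compose with the pipe; `run_pipeline()` wires them together and writes a
provenance manifest (stage thresholds plus content checksums) so a rerun
on identical inputs is bit-identical.

## The novel pre-miRNA filter

A trustworthy novel miRNA annotation must look like a Drosha/Dicer product,
not like degradation debris. Six criteria are measured per candidate from
its hairpin structure and collapsed read alignments (`evaluate_candidates()`):

| criterion | default | rationale |
|---|---|---|
| mature-arm support | ≥ 30 weighted 0-mismatch reads | real mature miRNAs are abundantly and exactly processed |
| star-arm support | ≥ 10 weighted 0-mismatch reads | the passenger strand must also be observed |
| 5' homogeneity | ≥ 50% of arm reads on the modal 5' start | precise 5' ends are the hallmark of enzymatic processing |
| 3' overhang | 0–4 nt | RNase III cleavage leaves short 3' protrusions (canonically 2 nt) |
| folding energy | ≤ −0.2 kcal/mol per nt | genuine hairpins are thermodynamically stable for their length |
| structure | exactly 1 hairpin loop | internal sub-hairpins indicate a non-canonical fold |

All comparisons are inclusive, as the thresholds are stated. Several rules
the upstream literature leaves unstated had to be fixed here:

* **Read-to-arm assignment** is not defined by the criteria themselves; a
  read joins an arm when its 5' end lies within ±3 nt of the annotated arm
  5' end. The window tolerates processing heterogeneity while the two arms
  (≥16 nt apart) stay unambiguous.
* **Homogeneity denominator**: all arm reads count, not only 0-mismatch
  reads — only the support criteria are stated in terms of perfect reads.
  The alternative is available via
  `filter_criteria(homogeneity_zero_mismatch_only = TRUE)`. The criterion
  is applied to both arms; the synthetic generator plants the same
  homogeneity on both, so either reading yields the same truth labels.
* **Overhang** is measured on the 3'-arm strand only, as the number of
  nucleotides its 3' terminus protrudes past the base paired with the
  5'-arm strand's 5' terminus. If that terminus is unpaired, the nearest
  paired position within 3 nt (towards the loop) is used and the offset
  subtracted, extrapolating the duplex end; a recessed end is negative and
  fails the 0–4 range. If no anchor pairs within the window the overhang
  is undefined and the criterion fails.
* **"No internal sub-hairpins"** is operationalised as *exactly one
  hairpin loop* in the dot-bracket (a maximal unpaired run closed by a
  pair); any second loop implies an internal sub-hairpin or bifurcation.

An exclusion-list hook (`evaluate_candidates(exclude = ...)`) drops
candidates matching externally identified non-miRNA ncRNAs, standing in
for a covariance-model database search, which needs external tooling.

## Expression and differential-expression filtering

CPM scales each library to one million assigned counts (the denominator is
the total assigned count of that library). A feature is expressed when its
CPM is strictly **above** the assay threshold — 4.2 CPM for small RNA
libraries and 0.38 CPM for RNA-seq, each corresponding to roughly 100 and
10 reads at the library sizes these defaults were calibrated for — in at
least two libraries. Strictness follows the word "above"; the inclusive
variant is a configuration switch. Differential expression keeps records
with |log2 fold change| ≥ log2(1.5) and adjusted p ≤ 0.05, both inclusive
and two-sided — the fold-change rule is symmetric on the linear scale.

Supporting descriptive statistics mirror standard practice: row z-scores
use the population (divide-by-n) standard deviation, with constant rows
set to zero under a warning; library similarity uses Spearman correlation
with midranks; qPCR fold changes use 2^−ΔΔCt. Exclusive set-overlap
patterns (`overlap_counts()`) partition the union so pattern counts sum to
the union size.

## Seed-site taxonomy and duplex energies

Writing an 8-nt UTR window 5'→3' as w1…w8, target position t1 (opposite
miRNA position 1) is w8. With Watson–Crick pairing only (no G:U in seed
matching):

* **8mer** — t2–t8 pair miRNA 2–8 and t1 is an A;
* **7mer-m8** — t2–t8 pair miRNA 2–8, t1 not A;
* **7mer-A1** — t2–t7 pair miRNA 2–7, position 8 unpaired, t1 is A;
* **6mer** — t2–t7 pair miRNA 2–7 only;
* **off-6mer** — t3–t8 pair miRNA 3–8 only (offset seed).

When a window satisfies several definitions the most specific class wins
(the order above). Overlapping sites are reported separately — the
site-count filter needs a deterministic count of occurrences, and
occurrence-level reporting matches how seed-match predictors emit results.

Each site's **hybridisation energy** is the free energy of the best
contiguous intermolecular helix between the full miRNA and the site window
extended 30 nt upstream (target 5'), under nearest-neighbour stack
summation with the Turner 2004 parameters as tabulated in the ViennaRNA
`rna_turner2004.par` set: Watson–Crick and G:U stacks, a duplex initiation
term of +4.10 kcal/mol and a +0.50 kcal/mol penalty per AU/GU helix end.
Intramolecular structure is ignored. Every gapless antiparallel alignment
is scanned and every contiguous run of pairable positions contributes all
its sub-helices; the reported value is the minimum, clamped at 0 (a
no-pair duplex has no negative energy). The model is deliberately simple
and fully declared: the upstream predictor this step replaces does not
document its energy model, so the parameter table, the 30-nt extension and
a seed-only scoring mode are all exposed through `prediction_config()` for
calibration against external reference values. The published calibration
point for this configuration (a −7.2 kcal/mol site in a cardiac
transcription factor 3'UTR) requires genome-derived sequence that is not
bundled; the calibration test therefore reports as unverified rather than
being silently skipped.

Retention filters then drop 6mer and off-6mer sites, sites weaker than
−7 kcal/mol (a site at exactly −7.0 is retained: the rule removes only
energies *greater than* −7), and finally every UTR retaining fewer than
two sites. The site-count rule pools sites across miRNAs per UTR — the
literal reading of "3'UTRs with <2 predicted microRNAs binding sites" —
with a per-(miRNA, UTR) variant behind
`prediction_config(per_mirna_site_count = TRUE)`.

`extract_longest_3utrs()` supplies the scan targets: per gene, the
transcript with the maximal spliced 3'UTR length, ties broken by the
lexicographically smallest transcript id for determinism; minus-strand
UTRs are reverse-complemented so sequences always read 5'→3'. GTF input
(1-based, inclusive) is converted to 0-based half-open coordinates at the
parsing boundary, and every internal coordinate uses that single
convention.

## Hypergeometric target-set enrichment

The urn is the interaction table itself: N = all (miRNA, gene) interaction
rows, K = rows whose gene belongs to the domain set, n = one miRNA's rows,
k = its rows hitting the set. The p-value is the inclusive upper tail

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

computed with log-space binomial coefficients so interactomes of ~10^5
rows do not overflow, and fold enrichment is (k/n)/(K/N). The inclusive
tail is the standard over-representation convention (the exclusive variant
would make k = 0 ill-behaved). Because the parameterisation of the urn is
a genuine modelling choice, a gene-level variant (N = distinct genes,
K = set size) is available via `universe = "gene"`. Rankings use raw
p-values — the study design ranks candidates rather than testing a family —
but a Benjamini–Hochberg column is emitted alongside for transparency.
Ties sort by descending fold enrichment, then id, for determinism.

## What the synthetic data emulate — and what they do not

Each generator is a pure function of its spec (same seed, byte-identical
output; the caller's RNG stream is untouched), and truth labels are
computed from the spec's arithmetic, never by running the component under
test.

* `simulate_hairpin_candidate()` builds a hairpin dot-bracket with a
  configurable stem, loop, sub-hairpin count and 3' overhang (recessed
  ends down to −3 nt), a random sequence consistent with the pair table,
  and a read stack realising exact 0-/1-mismatch counts with the requested
  modal-start fraction (remainder spread over starts +1…+3). Infeasible
  homogeneity targets error rather than silently degrade. It does not
  model sequencing error, cross-mapping or expression-dependent sampling
  noise.
* `simulate_utr_with_sites()` plants exact class-defining windows into a
  GC-controlled background and resamples the background (up to 100
  attempts, then an error) until no window outside the planted set is
  classifiable, so planted truth is exactly the set of sites present. Free
  window characters are redrawn each attempt: for low-complexity seeds a
  fixed draw can force a spurious neighbouring site. Degenerate periodic
  seeds for which no assignment exists error out by design.
* `simulate_count_matrix()` draws negative-binomial counts
  (mean–dispersion form) around lognormal gene means scaled to the target
  library size, with planted ±log2 fold changes between the posterior
  domain and both anterior domains — matching the overdispersed count
  structure the DE layer assumes without re-implementing inference.
  Library totals vary around the target rather than being renormalised, so
  planted fold changes stay unbiased.
* `simulate_interactome()` plants one miRNA whose in-set targeting
  probability is `enrichment_factor × baseline` (others at baseline);
  `enrichment_factor = 1` is the null model and plants nothing.
* `simulate_dataset()` wires these into a complete toy input directory
  (miRNA/UTR FASTA, count matrices, DE and GO tables, hairpin candidates).
  Dataset miRNAs carry G/C-only seeds so planted sites always clear the
  −7 kcal/mol cutoff; accidental cross-miRNA matches are left in as
  realistic background noise, so the dataset truth is the planted
  enrichment and gene set, not a per-site census.

Passing these tests therefore demonstrates algorithmic correctness against
planted structure — it does not demonstrate that the thresholds generalise
to other tissues, library depths or annotation versions, and it cannot
validate the energy model against wet-lab binding data.

## Numerical choices and problem sizes

* Threshold boundaries are inclusive exactly as stated; boundary behaviour
  is covered by dedicated tests (energy −7.0 retained, fold change
  log2(1.5) kept, CPM at threshold dropped).
* The hypergeometric tail is validated against exact integer
  (Pascal-triangle) enumeration for every (N, K, n, k) with N ≤ 25, and
  against the reference distribution function at large N.
* The test and acceptance workloads use 500 hairpin candidates, 1000
  simulated UTRs, 10,000 random classification windows and 200 interactome
  replicates (50 miRNAs × 2000 genes, set 300, baseline 0.05) — sizes
  chosen to exercise every boundary combination while keeping the default
  check fast on a laptop.
* Degenerate inputs are defined errors, not silent results: zero-sum
  libraries, empty interaction tables, unbalanced dot-brackets, overlapping
  planted sites, unreachable homogeneity targets.

## Known limitations

* The duplex energy model scores single contiguous helices; bulged or
  interior-loop duplexes score as their best helix, which underestimates
  some real affinities. This is acceptable for a retention threshold but
  is not a folding algorithm.
* The overhang criterion reads the rule literally (3'-arm end only); if
  the intent was both duplex ends, candidates with an aberrant 5' overhang
  but canonical 3' overhang would pass this criterion.
* The gene-set builder treats the external GO table as authoritative; no
  term redundancy handling is attempted.
* Enrichment treats interactions as exchangeable draws; miRNAs with very
  few predicted targets have coarse, conservative p-values.
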