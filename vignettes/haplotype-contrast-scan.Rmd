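---
title: "Methods: the strain-contrast haplotype scan and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the strain-contrast haplotype scan and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploscan)
```

## The model

Classical inbred mouse strains are mosaics of a small number of ancestral
founder haplotypes: across most of the genome, the variation segregating
among them reduces to fewer than ten distinct haplotypes per locus. A
haplotype resource therefore describes each strain as a track of labeled
blocks — intervals over which the strain's chromosome derives from one
founder. The vector of labels across a panel of strains at a locus is its
*strain distribution pattern* (SDP).

When a phenotype splits a strain panel — here, the tumor spectrum of
*Trp53*-deficient mice, where some backgrounds are refractive and others
prone — loci that modify the phenotype are expected to show an SDP that
mirrors the split. `haploscan` encodes that expectation as a predicate on
the SDP, the `contrast_design`: a *shared group* of strains must carry one
identical label `h0`, and each *distinct strain* must carry a label other
than `h0`. The canonical design has four refractive strains shared and two
susceptible strains distinct.

## The scan

`segment_joint()` cuts each chromosome at the union of every strain's block
boundaries. Within a resulting segment each strain's label (or its absence)
is constant, so the predicate is constant too; evaluating it per segment is
exactly equivalent to evaluating it per base, which the test suite verifies
against a literal per-base brute-force oracle on randomized toy panels.
`scan_contrast()` then merges runs of qualifying segments into maximal
candidate regions and reports the qualifying genome fraction.

Three decisions here were genuinely open and are worth recording:

* **Missing calls disqualify.** A base where any designated strain lacks a
  haplotype call never qualifies. This is the conservative reading of a
  presence-requiring pattern match; `missing_as_wildcard = TRUE` exposes
  the permissive alternative (a missing call is compatible with any
  requirement, but the shared group still needs one non-missing witness).
* **Distinct strains are pairwise distinct by default.** With two
  susceptible strains the phrase "a second distinct haplotype in one, a
  third in the other" reads most naturally as three mutually different
  labels; `require_pairwise_distinct = FALSE` gives the weaker reading
  where the susceptible strains may share a haplotype as long as it differs
  from the shared group's.
* **Merging is book-ended.** Only qualifying segments with zero gap merge;
  `merge_gap` (bp) lets a user bridge short non-qualifying or uncovered
  gaps, but the default is 0 because no merging tolerance is implied by the
  design. Merged regions may span witness-label changes: the requirement is
  on each base, not on a constant witness.

Strains present in the panel but named in neither design list are ignored,
matching a design drawn from a subset of a larger panel. Coordinates are
0-based half-open everywhere in memory and in BED output; GFF3 input is
converted on read, and that conversion is pinned by fixed fixtures because
it is the only place an off-by-one can enter.

## Annotation and categories

Candidate regions are intersected with gene annotations (1 bp of half-open
overlap suffices; strand ignored; an optional `flank` extends regions
symmetrically, default 0 since no promoter rule is part of the method).
Regions are classified into six categories: a region with no genes is a
*gene desert*; otherwise it takes the highest-precedence category among its
genes, with precedence `cancer > dna_repair > immune > non_neoplastic >
unknown_function`. The precedence resolves multi-category regions in favor
of presumed relevance to a tumor phenotype and is overridable. Genes absent
from the category map default to `unknown_function`, so a partially curated
map degrades gracefully. `summarize_categories(drop_uninformative = TRUE)`
removes `unknown_function` and `gene_desert` before renormalizing — by
construction the dropped variant is the restriction-and-renormalization of
the full one, and a property test holds that over random inputs.

## Cohort statistics

`km_estimate()` is the standard product-limit estimator: at each distinct
event time with `d` events among `n` at risk, survival multiplies by
`1 - d/n`; animals censored at an event time leave the risk set after the
events. `km_median()` is the smallest observed time at which the estimate
reaches 0.5 or less, `NA` if it never does within the window.
`logrank_test()` accumulates observed-minus-expected events over the pooled
distinct event times with the hypergeometric variance for ties and refers
`(O − E)² / V` to chi-square with 1 df; when the variance is zero (as for
two identical groups) the statistic is 0 and p is 1, and a comparison with
no events at all is an explicit error rather than a silent 0. Both
functions are checked to 1e-10 against the `survival` package on random
cohorts, and against hand-computed worked examples frozen before
implementation.

Animals found dead without a visible tumor are events with diagnosis
`"none"` — they belong on the survival curve and in the spectrum — while
tumor-free survivors are censored at the 35-week study horizon.
`mendelian_test()` is a plain chi-square goodness of fit (via
`chisq.test`) against a caller-supplied segregation ratio; the default is
1:2:1 for a heterozygote intercross, and the ratio is a parameter precisely
because published expectations sometimes disagree with that default.

## Allele arithmetic

`amplicon_length()` is the dropout identity (wild-type product minus
deletion), erroring when the deletion reaches the primer sites.
`predict_truncation()` models the allele as a clean dropout between two
points: it removes the interval from the CDS, translates from the original
ATG with the standard genetic code, and reports the residues before the
first stop, a frameshift flag (deletion length not divisible by 3), a
runs-through flag when no stop is reached, and an explicit start-lost
result when the deletion invades the start codon. No microhomology or
indel-repair modelling is attempted — the exact endpoints are an input.
`protein_mass()` sums average (not monoisotopic) residue masses plus one
water, the convention of common protein MW calculators; the table is pinned
in the source and cross-checked in tests against an independent
free-amino-acid table. The empty chain weighs one water (18.02 Da) so the
additivity identity `mass(AB) = mass(A) + mass(B) − 18.02` holds exactly.

## The simulator and what it does (not) show

`simulate_panel()` is a block-process generator, not a coalescent: each
chromosome is partitioned once into geometric-length blocks (mean
`mean_block_bp`), a hidden template draws one of `n_founders` labels per
block, and each designated shared strain copies the template per block with
probability `shared_prob`, everyone else drawing independently. The default
of 8 founders respects the fewer-than-ten-haplotypes regime; the default
200 kb block length matches the scale of classical-strain haplotype blocks.
Because the analysis consumes only block labels, ancestral realism
(recombination maps, phylogeny, SNP-level data) is deliberately out of
scope — so passing tests demonstrate correctness of the interval logic and
the predicate, not robustness to haplotype-calling error or to real linkage
structure.

`plant_regions()` overwrites labels inside chosen windows so every base
qualifies, and scrubs a flank on each side to a single label shared by all
strains — a pattern that can never qualify — so recovery tests are bp-exact
by construction. With independent labels and `H = 4` founders, the
per-block qualifying probability for the four-shared/two-distinct design is
`4·3·2 / 4⁶ = 0.586%` by exhaustive enumeration, and the Monte-Carlo
qualifying fraction of a simulated panel (one 10 Mb chromosome, 200 bp mean
blocks, about 50,000 blocks) is required to match it within three standard
errors; block lengths being geometric roughly doubles the variance of the
bp-weighted fraction relative to the per-block binomial, which the
tolerance accounts for.

`simulate_cohort()` draws, per animal, an outcome from its genotype's
diagnosis distribution (the remainder are tumor-free survivors), then an
event time from a log-normal parameterized by its median; times past the
35-week horizon censor there. The log-normal-by-median choice reflects that
a median and a horizon are the natural published summaries of such a
cohort; dispersion defaults to σ = 0.3 on the log scale, giving a
realistic spread (80% of null event times between roughly 8 and 18 weeks)
without mass beyond the horizon. Cohort defaults emulate the study design
the package accompanies: 6 wild-type, 14 heterozygous and 5 null animals;
null outcomes 40% thymic lymphoma, 40% testicular teratoma, 20% death
without visible tumor at a 12-week median; heterozygotes 15% sarcoma and 7%
tumor-free death, with a 20-week median for those that die — the published
design gives no heterozygote median, so this value was fixed once to place
heterozygote deaths late but inside the window. A single user seed derives
a named substream per generator, so adding a generator never perturbs
another's draws.

## Numerical and scale choices

Everything is exact interval arithmetic on integers except the survival and
mass computations, which are plain double precision; `km_median()` uses a
1e-12 slack on the 0.5 threshold to absorb product rounding. Test problem
sizes were chosen to make the suite fast while keeping the oracles honest:
the per-base oracle runs on 200 panels of ≤ 2.5 kb toy genomes (the
brute-force cost is per base, the scan's is per block boundary — the
equivalence is scale-free), planted-recovery runs 100 trials on 200 kb
genomes, the Monte-Carlo enumeration check uses ~50,000 blocks, and the
parameter-recovery cohort uses n = 200 (KM-median simulation error ≈ 0.4
weeks at that size, against a ±1 week acceptance band).

## Known limitations

* Haplotype labels are trusted as given; there is no inference of blocks
  from genotype matrices and no modelling of label error.
* Build consistency between haplotype tracks and gene annotations is the
  user's responsibility; chromosome names are matched verbatim.
* The scan attaches no significance measure to the qualifying fraction —
  the method is descriptive, and none is defined for it.
* Heterozygote tumor biology (loss of heterozygosity, dose effects) is not
  modelled; heterozygous cohorts are simulated with the same machinery as
  nulls, only with different parameters.
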