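---
title: "fecoduo: methods and design notes"
author: "fecoduo maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fecoduo: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fecoduo` implements an integrated analysis of stool small RNA sequencing
(sRNA-Seq) together with shotgun-metagenomic taxonomic profiles of the same
samples. The biological setting is a three-group colorectal cohort (healthy,
adenoma, carcinoma): stool total RNA yields a mixture of human small RNAs
(miRNAs and other sncRNAs), fragments of other human transcripts or genomic
DNA, traces of dietary miRNAs, and a large pool of microbial small RNAs
(bsRNAs); stool DNA yields species-level relative abundances. The package
covers the computational chain only — read triage, quantification, taxonomic
classification, statistics, DNA–RNA integration and classification — and
ships a synthetic-data module so every stage can be verified against known
ground truth without any external downloads.

# The analysis model, stage by stage

## Preprocessing

Reads are 3'-adapter trimmed with a semi-global edit-distance model
(mismatches, insertions and deletions all count): the best occurrence of the
adapter, or of an adapter prefix flush with the read's 3' end, is removed
when its edit distance is at most `floor(0.15 * aligned adapter length)`.
The error rate is measured against the aligned adapter length; among
qualifying occurrences the lowest error rate wins and ties go to the
leftmost start, i.e. the longer trim. The default minimum overlap is 3 nt, a
common trimmer default. Reads shorter than 14 nt are then discarded.
Trimming precedes the length filter by default: trimming only shortens
reads, so filtering post-trim is the conservative superset; the opposite
order is available via `preprocessReads(trim_first = FALSE)`.

## Hierarchical triage

Each read is assigned to the first reference class it maps to, in fixed
order: (1) human small RNA annotations (miRNA precursor hairpins plus
sncRNAs), (2) a host genome decoy, (3) dietary miRNAs, with the remainder
forming the candidate-microbial pool. Alignment is ungapped and end-to-end:
a read is placed at every offset of every reference and all placements
achieving the per-read minimal mismatch count are reported, up to a default
cap of 2 mismatches for reads of 50 bp or less. Annotation references are
searched on their annotated strand only; the genome pass searches both
strands. Candidate placements come from `max_mismatches + 1` disjoint exact
seeds per read; by pigeonhole any qualifying placement leaves at least one
seed intact, so the seeded search is exactly equivalent to the brute-force
scan (the test suite asserts this against an independent exhaustive-scan
oracle).

## Mature miRNA quantification

Two rules are merged into one mature count matrix. For hairpins with
annotated arm intervals (knowledge-based), a read increments the arm whose
interval overlaps the placement by the most nucleotides; overlap ties go to
the 5p arm. For hairpins without annotations (position-based), the placement
midpoint decides: midpoint in the 5' half increments `<id>_5p-Novel`,
otherwise `<id>_3p-Novel` (ASCII renderings of the 5'/3' "Novel" suffixes;
the exact strings are configuration-exposed). Multi-mapping reads count
exactly once — best hit first, then the lexicographically smallest feature
name — which keeps counting deterministic and conservation-preserving. The
same one-read-one-count contract drives sncRNA, diet-miRNA and bsRNA
counting.

## k-mer LCA classification and mpa profiles

Candidate-microbial reads of at least 31 nt are classified with a minimal
Kraken-style engine: every canonical 31-mer of the species genomes maps to
the lowest common ancestor of the species containing it; a read's k-mers
vote, and the read is assigned to the leaf of the root-to-leaf path with the
maximal summed votes. Equal-weight paths resolve conservatively to the LCA
of the tied leaves. `k = 31` is the classification tool's long-standing
default and matches the read-length rule; canonical (strand-minimal) k-mers
make classification strand-insensitive. Clade counts (reads at a taxon or
below) are converted to rank-level relative abundances with the total
classified read count as denominator; unclassified reads are excluded. Note
that with this denominator a rank's abundances sum to 100% only when every
read is classified at or below that rank — reads stopping at, say, a genus
leave the species level short, which is the intended clade-count arithmetic.
Profiles serialize to mpa text lines (`k__...|s__...<TAB>abundance` with 5
decimals).

## Nonredundant bsRNA sets and transcription rates

Bacterial sRNA annotations are filtered to species whose mean DNA-derived
abundance across the cohort exceeds 0.01% (unweighted mean over all
samples), restricted to sequences strictly shorter than 80 nt, and identical
sequences — the same sRNA annotated to different species or strains — are
merged into single entries with full member bookkeeping. Entry identifiers
are FNV-1a 64-bit hashes of the sequence, so the set is independent of input
order. Expression is quantified by aligning the candidate-microbial pool
against entry sequences under the standard counting contract.

Per species and sample, the transcription-rate ratio divides the
sRNA-derived relative abundance by the DNA-derived one; ratios with zero or
missing DNA abundance are flagged undefined and dropped from medians. The
cohort report keeps species whose per-sample median ratio exceeds 1
(per-sample ratios, then the median — matching a per-sample heat-map
reading of the results rather than a ratio of cohort means).

## Statistics

*Differential expression* uses a negative-binomial likelihood-ratio test per
feature: full model `~ group + age + gender` versus reduced
`~ age + gender`, log link, median-of-ratios size factors as offsets, the
statistic referred to a chi-square with 1 df. Dispersion is estimated per
feature by maximizing the Cox–Reid adjusted profile likelihood under the
full model (method-of-moments bracket, floor 1e-8) and shared between the
two fits. No empirical-Bayes shrinkage is applied — a deliberate
simplification of the larger DE frameworks; instead, calibration is enforced
by simulation: the acceptance suite requires empirical type-I error within
[0.03, 0.07] at nominal 0.05 (n = 15/15) and ≥ 90% BH-power for 4-fold
effects (mean 100, dispersion 0.1, n = 20/20). Age is standardized before
fitting, which improves conditioning without changing the LRT. Non-converged
features are flagged and reported with p = 1, keeping them in the BH family
conservatively. Differentially expressed features must additionally pass
BH-adjusted p < 0.05 and a raw median count > 20 in at least one group, both
strict.

Note that median-of-ratios factors absorb any shift common to most features;
a power simulation must therefore embed effect features among nulls (as the
acceptance suite does), and the rescaling invariance of the LRT holds only
approximately (the NB likelihood is not scale-equivariant; the property test
allows |Δp| < 0.02).

*Differential abundance* uses two-sided Wilcoxon rank-sum tests on species
passing a mean-abundance filter (> 0.1% in at least one group), with the
exact null when both groups have ≤ 10 samples and no ties and the
tie-corrected normal approximation otherwise. *Correlation screens* (DNA–RNA
concordance per rank; miRNA expression against a target species' abundance)
use the Pearson product-moment coefficient with the two-sided t-transform
p-value, BH-adjusted per screen; concordant species must pass r > 0.6,
BH-adjusted p < 0.05 and the 0.1% abundance filter, all strict. The Fisher
overlap test is the exact two-sided hypergeometric test; the background
universe (the "neither" cell) must be supplied by the caller, since no
default background is defensible.

## Classification protocol

Feature tables combine up to four profile types — bDNA and bsRNA species
abundances (percent, untransformed) and miRNA/sncRNA counts (log10(1 + CPM)
after size-factor normalization) — with provenance-prefixed feature names.
Each experiment is a stratified 10-fold cross-validation iterated 20 times
(200 test AUCs) of a 500-tree Random Forest with sqrt(p) feature
subsampling; AUC is the rank-based (Mann–Whitney) probability with ties at
one half, computed from held-out positive-class probabilities. Per-iteration
seeds derive as `seed + iteration` for reproducibility. When estimating the
protocol's permutation null, a fresh label permutation is drawn for every
iteration rather than fixing one permutation per experiment: at 50 samples a
single permutation can chance-align with the informative features, an
alignment every fold inherits, so the one-permutation estimate of the null
mean AUC has standard error near 0.06 while re-permuting per iteration
brings it close to 0.01. Feature importances
(mean impurity decrease) and the rankings driving the feature-count sweep
are computed on training folds only; `featureSweep(assert_no_leakage =
TRUE)` re-derives every ranking after zeroing the test rows and stops if
anything changes. The experiment grid crosses data categories with the three
group comparisons; carcinoma is the positive class when present, adenoma
otherwise. Because four profile types give 15 nonempty subsets while the
canonical protocol counts 14 categories without naming the excluded one, the
default preset is the full 15 and a 14-category preset (`"paper14"`,
dropping the miRNA+sncRNA pair) is provided; neither guesses further.

# The synthetic-data generator

The generator defines the study conditions for all tests. A reference bundle
holds 60 precursor hairpins (70% with both arms annotated, 22-nt arms), 40
sncRNAs under 80 nt with biotypes, a 100-kb host contig in which every
precursor and sncRNA is embedded (so triage order is genuinely exercised),
30 dietary miRNAs, six divergent 30-kb species genomes under a seven-rank
taxonomy with paired genera, and 8 bsRNA annotations per species, at least
two of which are annotated identically to two species. A sibling-species
mode creates genome 2 as a copy of genome 1 with a substitution every
`31 / (1 - shared)` bases, giving a controlled shared-31-mer fraction.

Cohorts default to the acceptance conditions: provenance fractions
0.4 / 0.2 / 0.0 / 0.3 / 0.1 (human sRNA / human genome / diet / bacterial /
junk), 50-bp reads assembled as insert + 21-nt small-RNA 3' adapter + random
filler, miRNA-arm inserts of 20–24 nt, 85% of bacterial inserts ≥ 31 nt,
35% of bacterial inserts drawn from bsRNA annotation footprints
(transcript-like; the rest uniform over the genome), and host-genome inserts
drawn outside the embedded sRNA loci. All insert lengths stay ≥ 20 nt:
shorter inserts would chance-map against a 100-kb decoy at 2 mismatches with
non-negligible probability and provenance classes would stop being well
defined. Per-feature counts are negative-binomial (log-normal baseline
means, dispersion 0.2) with multiplicative group effects on selected
features, matching the DE model's assumptions; species proportions are
Dirichlet-perturbed group compositions with log-normal multiplicative DNA
noise (σ = 0.3 by default, 0 giving exact profiles). Quality strings are
constant "I" since the QC stage is report-only. Effect sizes are
placeholders for recovery tests, not estimates of biology.

What the generator does not emulate — sequencing errors, PCR duplicates,
isomiR variation, real genome repeat structure and homology, uneven genome
coverage — bounds what green tests mean: they demonstrate that the
implementation recovers known truth under its own model assumptions, not
that the pipeline is robust to every artifact of real stool sRNA-Seq data.

# Numerical choices and degenerate inputs

Alignment ties are broken deterministically (fewest mismatches, then
lexicographic feature id, then leftmost placement). Empty inputs are legal
everywhere: empty read sets, zero classified reads (empty profile, no
division by zero), all-zero count features (LRT statistic 0, p = 1), empty
annotation sets after filtering. Size factors fall back to library-size
ratios with a warning when no feature is positive in all samples, and
zero-count samples receive the average depth. The problem sizes used by the
test and acceptance suites (24 samples × 100k reads for triage recovery,
2,000 null features for calibration, 200-test cross-validations) were chosen
as the smallest cohorts at which the statistical properties under test are
stable.

# Known limitations

* The NB dispersion estimator is per-feature; with very few samples its
  variance is high and the LRT is only asymptotically calibrated (the
  simulation suite bounds this at the tested sizes).
* The k-mer engine stores the full k-mer map in memory and targets
  reduced-scale genomes; no minimizer compression or disk-backed database.
* Ungapped alignment cannot place reads across indels; the paper-level
  contract (entire-read evaluation, mismatches only) makes this explicit.
* Wilcoxon p-values switch between exact and approximate paths at the
  documented rule; near the switchover the two differ by up to ~0.02.
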