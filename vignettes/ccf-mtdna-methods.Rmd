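---
title: "Methods: NUMT-aware CCF-mtDNA analysis, heteroplasmy calling and metabolomic impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NUMT-aware CCF-mtDNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and conventions behind `cfmtdna`: what
each stage computes, which parameters matter and why their defaults are
what they are, what the synthetic-data generators emulate, and the
numerical and design choices made where more than one convention exists.

## The NUMT problem and the Hamming scan

Nuclear-mitochondrial segments (NUMTs) are copies of mitochondrial sequence
embedded in the nuclear genome. A PCR amplicon or a sequencing read that
matches a NUMT as well as it matches mtDNA cannot attribute its signal to
circulating cell-free mtDNA. The scan quantifies this risk per position:
the circular mitochondrial genome of length $L$ is cut into $L$ windows of
odd width $W$ (default 101 bp), one per position, the central nucleotide
indexing the window; windows crossing the origin are formed by
concatenation, which is what makes the count exactly $L$ rather than
$L - W + 1$. For each window the scan reports

$$d_{\min}(i) \;=\; \min_{\text{offsets } o,\ \text{strands}} \#\{\,k : w_i[k] \neq N[o+k]\,\}$$

the smallest ungapped mismatch count of the window *or its reverse
complement* anywhere in the nuclear sequence. The implementation is exact:
a sliding mismatch sum along every diagonal of the window-by-offset
comparison grid, $O(L \cdot |N|)$ character operations in C++. We
deliberately replace the heuristic seeded search a BLAST-style tool would
use with an exhaustive contract — the unit tests compare the production
scan against an independent brute-force oracle at every position on small
genomes, and the two must agree exactly.

Conventions: all coordinates are 0-based half-open; any comparison
involving an `N` counts as a mismatch (including `N` vs `N`), which is the
conservative choice for primer design; ties between equally good nuclear
matches are irrelevant because only the minimum is reported.
`select_target_regions(profile, min_distance, min_length)` then returns
maximal runs with $d_{\min} \ge$ `min_distance` of at least `min_length`
bp, the candidate ddPCR targets. Runs are taken in linear position order; a
run spanning the circular origin is reported as two regions.

## Fragment sizes

The paired-end fragment length is defined as the distance (+1) between the
first and last aligned bases of the pair. Fragments whose *primary*
alignment is nuclear are removed before any mitochondrial statistic —
secondary nuclear hits do not disqualify a fragment, since NUMT-derived
ambiguity is expressed through the primary assignment. `fraction_below(t)`
uses strict `<` (matching the convention "fragments less than 100 bp");
`fraction_in(lo, hi)` is closed on both ends.

The record reader accepts a minimal SAM dialect (all-match CIGARs) or an
equivalent TSV. Mates are paired by query name; unpaired reads are dropped
and counted in a message. The package's own writer serialises each
simulated fragment as two abutting mates (first half / second half), so
that re-pairing reconstructs the full span and base calls with no overlap
to double-count. Real library preparations produce overlapping or gapped
mates; how such pairs should be resolved is a declared convention here
(span = min first aligned to max last aligned), not a claim about any
particular upstream pipeline.

## Heteroplasmy criteria

Pileups are built per position and strand from base calls passing mapping
quality ≥ 30 and base quality ≥ 20 (`N` calls ignored); coverage counts
quality-passing bases only. A site is reported as heteroplasmic when all
four criteria hold, evaluated in this order so a rejection names the first
failed gate:

1. coverage strictly greater than 400;
2. alternate allele fraction ≥ 1% — the alternate is the most abundant
   non-reference base, and multi-allelic sites report only that top
   alternate;
3. per-strand alternate fraction ≥ 0.6% on both strands;
4. no significant strand imbalance: two-sided Fisher's exact test on the
   2×2 table (alt, ref) × (plus, minus), retain when $p \ge \alpha$ with
   $\alpha = 0.05$.

The strand-balance test is a design choice: the criterion "not
significantly different between strands" does not by itself pin a test or
a level, and Fisher's exact test is the natural choice because the counts
near the 0.6% per-strand floor are small, where asymptotic tests are
unreliable. Likewise "minor allele frequency" is implemented as the
alternate fraction of total coverage; below 50%, where every realistic
call lives, this is identical to min(alt, ref) fraction.

With the default gates, the binding constraint against sequencing error is
the 1% MAF floor: at coverage ~1000 and a uniform per-base error rate of
$10^{-3}$ (errors split across three alternates), a false site needs ≥ 10
identical erroneous calls, which is vanishingly rare; the planted-recovery
tests verify both the ≥ 95% sensitivity at allele fraction 0.05 and the
absence of false calls.

## Tissue of origin

Plasma SNPs are matched to per-tissue call sets from the same animal by
identical (position, alternate allele); allele fractions are deliberately
not compared, because presence, not dosage, is the matching signal. Both
sides must pass the same heteroplasmy criteria — a plasma SNP "detectable
but sub-threshold" in a tissue does not count as a match; this is the
stricter of the two readings and is symmetric between tissues. Categories
partition the plasma set (unique / multiple / unmatched always sum to its
size), and tissues with zero passing sites (e.g. buffy coat) are retained
with count 0 rather than dropped.

## ddPCR quantification

Droplet digital PCR partitions a reaction into ~20,000 droplets of nominal
volume 0.00085 µL. Under Poisson loading, the positive fraction $p$
implies $\lambda = -\ln(1 - p)$ target copies per droplet, and the sample
concentration is $(\lambda / v) \times d$ copies/µL with dilution $d = 20$
by default. The Poisson correction is the instrument's standard occupancy
model and the only one consistent with absolute quantification at non-small
$p$; a `poisson = FALSE` switch gives raw-fraction scaling, which agrees
with the corrected value to <1% for $p$ below about 0.02. Saturated assays
(all droplets positive) are an error, not an estimate: $\lambda$ is
unbounded there. The droplet volume is exposed as a parameter because
instruments differ; 0.00085 µL is the nominal value for the common
droplet-reader class.

## Metabolomics

The workflow mirrors standard targeted-metabolomics practice:

* **Imputation** (`impute_knn`, $k = 10$): feature-wise KNN — the
  neighbours of a metabolite are other metabolites, distance is the mean
  squared difference over mutually observed samples, and a missing entry
  is the mean of the $k$ nearest metabolites observed in that sample. This
  is the convention of the widely used metabolomics suites; $k = 10$ is
  their default.
* **Transformation** (`log2_autoscale`): log2 then per-metabolite
  centring and unit scaling. The standard deviation uses the $n - 1$
  denominator — declared explicitly because textbooks and software differ,
  and the choice changes every downstream loading by a constant factor.
* **PLS-DA** (`plsda`): NIPALS PLS1 on the group indicator coded −1/+1 and
  mean-centred, default $A = 2$ components (matching the two-component
  score plots of common software; configurable). Weights are unit-norm and
  scores orthogonal across components; for a single response the NIPALS
  inner loop converges in one step, so the fit is deterministic with no
  iteration tolerance. Degenerate inputs error out: a constant response,
  more components than $\min(n-1, p)$, or a response fully deflated before
  the requested component count (the fit then retains the components it
  could extract).
* **Validation** (`loocv_q2`): $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$
  with leave-one-out refits including recentring, TSS taken around the
  full-sample mean. $Q^2 = 1$ means perfect held-out prediction; 0 means
  no better than the mean; values can be negative.
* **VIP** (`vip_scores`):
  $\mathrm{VIP}_j = \sqrt{p \sum_a SS_a w_{aj}^2 / \sum_a SS_a}$ with
  $SS_a$ the response sum of squares explained by component $a$; the
  identity $\sum_j \mathrm{VIP}_j^2 = p$ is asserted to relative $10^{-8}$
  on every fit.
* **Volcano** (`volcano`): fold change is the raw-scale ratio of group
  means (log-scale means would give a different, geometric-mean-based FC;
  the raw ratio is declared here), gated direction-agnostically and
  inclusively at 1.2; p-values from Welch's two-sample t-test on log2
  data, Benjamini–Hochberg adjusted, gated strictly at $q < 0.05$.
* **Pathway impact** (`pathway_impact`):
  $I_p = \sum_{j \in \text{sig} \cap p} \mathrm{VIP}_j / \sum_{j \in p}
  \mathrm{VIP}_j \in [0, 1]$, and the per-tissue total metabolomic impact
  is $\sum_p I_p$. The "significant" set feeding it defaults to the
  volcano set; a VIP > 1.5 set can be passed instead — both criteria are
  in common use and the formula is agnostic to the source.

## What the synthetic data emulate — and what they do not

The generators produce, under a single integer seed and bit-reproducibly:

* `make_genomes`: i.i.d. uniform A/C/G/T backgrounds (the simplest null
  for Hamming-distance baselines) with NUMT copies planted at *exact*
  mismatch counts — substitution positions sampled without replacement,
  each to a uniformly chosen different base, so the planted Hamming
  distance is a hard invariant, not an expectation.
* `make_cfdna_fragments`: fragment sizes from a two-component truncated
  normal mixture (means 95 and 167 bp, SDs 15 and 25 bp, weights
  0.25/0.75, truncated to 30–500 bp), chosen so that roughly 15% of
  fragments fall below 100 bp and 40% below 150 bp — the shape of plasma
  cfDNA electropherograms with a sub-nucleosomal and a mononucleosomal
  mode. Fragments are placed uniformly on the circular genome (wrapping
  the origin; wrapped records keep unwrapped coordinates interpreted mod
  $L$), strands are independent coin flips, planted heteroplasmies emit
  the alternate with the planned allele fraction before a uniform
  substitution error, and base qualities are a constant Q37 so that
  quality filters are exercised by explicit low-quality injection rather
  than by noise.
* `make_droplet_assay`: droplets positive independently with probability
  $1 - e^{-\lambda}$.
* `make_metabolite_matrix`: lognormal intensities (baseline log2
  abundances uniform on [10, 20], log2 noise SD 0.5 by default), a planted
  log2 fold-change in the first `n_affected` metabolites of group 2
  (default 20% of a 483-metabolite panel, the order of change a strong
  systemic insult produces), and missing-at-random entries (default 5%).

Deliberately *not* emulated: position- and context-dependent sequencing
error, indels and chimeric reads, PCR duplicates, GC and nucleosome
effects on fragment placement, NUMT-induced mismapping (nuclear fragments
are labelled with their true origin), batch effects, censored
(limit-of-detection) missingness, and correlated metabolite blocks.
Passing tests therefore demonstrate that the *computations* are correct
and that parameter recovery works under the stated statistical model; they
do not certify performance on real libraries, where alignment artefacts
and structured noise can violate these assumptions.

## Problem sizes and test design

The test suite validates each operation against an independent oracle
(brute-force scans, enumeration of 2×2 tables, a step-up BH
reimplementation, closed forms, binomial/Monte-Carlo bounds) at sizes
chosen to make those oracles cheap while keeping the statistics
informative: Hamming-scan equivalence on ≤ 2-kb genome pairs at every
position; planted-SNP recovery on a 2,000-bp circular genome at mean
coverage ~1000 (about 14,000 fragments per sample, 20 planted sites at
allele fraction 0.05, error rate $10^{-3}$); fragment-size convergence at
50,000 fragments (Kolmogorov–Smirnov distance to the generating mixture
< 0.05); Q² separation over 20 seeded matrices per condition at 10
samples/group; ddPCR recovery over 100 seeded assays of 20,000 droplets.
The NIPALS route is additionally cross-checked against an independent
PLS-DA implementation (mixOmics) on identical scaled inputs — scores and
VIP must agree up to component sign.

The acceptance script (`scripts/acceptance.R`) runs the full-scale scan —
a 16,299-bp circular mitochondrial genome (the mouse chrM length) against
a 50-kb nuclear genome at window 101, with one window planted verbatim —
and reports the profile value at the planted centre.

## Known limitations

* The exhaustive scan is $O(L \cdot |N|)$; against a full mammalian
  nuclear genome (~2.7 Gb) it is compute-heavy. The contract was chosen
  for exactness; a seed-and-verify prefilter returning identical values is
  the natural extension.
* Heteroplasmy calling is count-based, with no genotype likelihoods or
  overdispersion model; at coverages far above the defaults, a beta-
  binomial error model would control false positives more gracefully.
* `select_target_regions` does not merge runs across the circular origin.
* The PLS-DA is strictly two-class (PLS1); multi-class designs would need
  a dummy-matrix PLS2 extension.
* Pathway impact treats pathway membership as flat sets; no topology or
  overlap correction.
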