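---
title: "Methods: pan-genome PAV classification, selection scans, and the bottleneck sweep test"
author: "pavpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome PAV classification, selection scans, and the bottleneck sweep test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements, the assumptions behind each piece, the defaults and why they
were chosen, and what the synthetic-data generators do and do not emulate.

## The setting

A resequencing panel of a wild grass species is assembled per individual;
reference and donor gene models are aligned against each assembly and genes
are called present or absent per library, producing a genes × libraries
presence/absence (PAV) matrix. Alongside the PAV view, phased SNPs support
haplotype-based selection scans, and low-coverage data from the
domesticated relative support a diversity-ratio test for a domestication
sweep. The package implements each of these bespoke analysis steps over
standard inputs (VCF, FASTA, TSV matrices), with in-package generators
that create every input synthetically with planted ground truth.

## Presence calling and library QC

A gene is present in a library when its aggregated alignment hit passes
either the single-contig rule (identity and coverage both *strictly above*
the threshold) or the split-gene rule (exons on 2–3 contigs, identity and
coverage both *at least* the stricter threshold). The asymmetric boundary
semantics ("more than" vs "at least") follow the verbal rule the
thresholds come from and are kept deliberately explicit in
`presence_rule()`, because flipping either boundary changes presence
counts. Two presets are provided: within-genus (85/85 strict, 90/90
inclusive) and cross-genus (70/75 strict, 80/80 inclusive), the latter
relaxed to tolerate divergence between genera. Libraries with fewer than
39,000 present genes are dropped (`filter_libraries()`): a library that
sparse has likely lost genes to assembly quality, not biology, and keeping
it would deflate occupancy estimates globally. A library at exactly the
threshold is retained.

## Occupancy classification (core / shell / cloud)

Per-gene occupancy — the fraction of retained libraries carrying the gene
— is clustered in one dimension by successive k-means (k = 1..6, 20 seeded
restarts each). Model selection is by BIC, but *which* BIC matters:

* The within-sum-of-squares form `n ln(WSS_k/n) + k ln(n)` is reported in
  the result (`bic_wss`) but **not** used to choose k. For clustered
  continuous data its argmin is always the largest k tried: splitting a
  genuine cluster in one dimension cuts that cluster's WSS by roughly a
  factor 0.36, so the likelihood term falls by O(n) while the penalty
  grows only by ln(n). No dataset of realistic size can stop it at the
  true k.
* Selection instead uses the Gaussian-mixture log-likelihood implied by
  the k-means solution — cluster proportions as weights, cluster means,
  and within-cluster standard deviations — penalised as
  `-2 logL + (3k - 1) ln n`. Splitting a genuinely unimodal cluster then
  gains almost no mixture likelihood, and the penalty dominates; on data
  with three well-separated occupancy classes the criterion selects
  k = 3. An EM-fitted mixture (e.g. mclust) was considered and rejected:
  free variances let it shave extra components off the skewed
  Beta-binomial classes near occupancy 1.

Clusters are relabelled by descending mean occupancy (core, shell, cloud
for k = 3), so labels never depend on k-means' arbitrary numbering.
Structural-variant presence matrices go through the same operations as a
parameterization: classify occupancy, drop the lowest-occupancy cluster
(likely false positives), merge the rest, and compute Jaccard distances
for ordination.
Degenerate inputs are handled explicitly: fewer distinct occupancy values
than `k_max` shrinks `k_max` with a warning, and a constant vector
returns k = 1.

## Subpopulation enrichment and private genes

For each gene, presence counts per subpopulation o_i are compared with
expectations proportional to subpopulation sizes, e_i = O·n_i/N, by
Pearson's chi-square on (#subpops − 1) degrees of freedom; with four
subpopulations the critical value at α = 0.05 is 7.81. p-values get
Benjamini–Hochberg correction across tested genes. Genes never observed
are excluded (their expected counts would be zero) and logged. Two
statistical caveats are documented rather than hidden: the chi-square
placement model treats the O presences as multinomial over
subpopulations, which is near-exact for rare genes but conservative for
common ones (presences spread over libraries without replacement), and
the per-gene test conditions on O, so it detects *distributional*
imbalance, not overall abundance.

Private genes use a strict definition: frequency > 0.1 inside one
subpopulation and exactly 0 in every other. A tolerance parameter
(default 0) exposes the relaxed alternative, under which a gene can
qualify from more than one side — the strict default cannot.

Presence-profile distances use Jaccard, d = 1 − |∩|/|∪|, with the empty
vs empty pair defined as distance 0 (with a warning): two libraries with
no presences are operationally indistinguishable, and NaN would poison
downstream ordination.

## Windowed diversity and Tajima's D

Per-site diversity is 2c₁c₀/(n(n−1)) over non-missing alleles; window π
divides the site sum by window length (windows are 0-based half-open, so
a 1-based site p belongs to [start, end) iff start < p ≤ end, and
overlapping 100-kb/10-kb tilings cover each site exactly 10 times away
from edges). Tajima's D uses the standard coefficients; S = 0 yields an
undefined marker rather than 0, and n < 4 is an error because the
variance term is not positive. D windows are 10-kb non-overlapping: the
source description of the windowing ("10,000 windows with a slide of
10,000") is ambiguous between a window count and a window size, and the
10-kb reading keeps the slide consistent with the window.

## EHH, iHS, and outlier windows

EHH among carriers of a core allele is the probability two random
carriers are identical from the core out to the marker. iHH is the
trapezoid integral of EHH over physical distance (no genetic map is
assumed), truncated at the first marker where EHH < 0.05 — the default
of the tool family this mirrors — and sites whose EHH is still above the
cutoff at a chromosome edge are dropped, not extrapolated, because their
integrals would be censored unequally between alleles. iHS =
ln(iHH_A/iHH_D) is standardized within 50 equal-width derived-allele-
frequency bins (bins under 20 scored sites merge with neighbours);
unstandardized iHS depends strongly on frequency, and the binning is what
makes |iHS| > 2 comparable across sites. The sweep signature is
windowed: the fraction of sites with |iHS| > 2 per 100-kb window sliding
by 10 kb, with windows under 10 SNPs reported as missing (`min_snps`
exposed) so sparse windows cannot dominate the tail. Outlier flagging
takes the extreme `fraction` (default 0.01, mirroring the bottom-1% rule
used for D) of non-missing windows, including ties at the cut with a
warning.

## The coalescent sweep test

`simulate_coalescent()` is a single-locus Hudson coalescent without
recombination: waiting times between coalescences are exponential with
rate C(k,2)/x(t) under piecewise-constant relative sizes, mutations are
Poisson(θ/2 × total branch length) dropped uniformly on branches
(infinite sites), and π follows from the branch each mutation lands on.
Time is in units of 2N₀ generations, the scaling under which
E[TMRCA] = 1 for n = 2, E[S] = θa₁ and E[π] = θ — the invariants the
test suite checks against closed forms. Windows are simulated without
intra-window recombination, a stated simplification consistent with how
such tests are usually run at 20-kb scale.

The bottleneck is parameterized by start, duration, and severity
(relative size f). Defaults: start 0.08 and duration 0.04 in coalescent
units — equivalent to a bottleneck starting 8,000 years ago with
duration half its age for an annual (one generation per year) species
with N₀ = 50,000, a plausible effective size for a widespread selfing
grass — with severity the free parameter. Severity is calibrated so the
*expected* diversity ratio matches the genome-wide ratio of the
domesticate to its progenitor (22% in the motivating system). Because
any two sampled lineages coalesce marginally as a pair, the expected
ratio is E[T₂] under the bottleneck demography, which has a closed form
for piecewise-constant sizes; the default calibration bisects that
closed form and is exact. A simulation-based calibration (paired
replicates with common random seeds, as one would do if no closed form
were available) is retained as `method = "simulation"` and doubles as an
independent check — its residual Monte-Carlo bias of a fraction of a
point was the reason the analytic route is the default. The diversity
ratio is always the ratio of mean π values (the analogue of a
genome-wide ratio), never the mean of per-window ratios, whose
expectation is inflated by small denominators.

The test itself ranks an observed window ratio against per-replicate
simulated ratios with the add-one estimator
p = (1 + #{ratio ≤ observed})/(kept + 1), so p is never exactly zero;
replicates with a monomorphic constant-size window are discarded and
logged. Fewer than 100 replicates is an error. Under the null the
p-values are uniform, which the suite checks by KS test.

## LD decay

r² is the squared Pearson correlation of allele dosages over
pairwise-complete samples (the genotype-based composite measure);
monomorphic pairs are undefined and logged. Sites are thinned to ≥100 bp
spacing greedily left to right, pairs are limited to 500 sites and 2 Mb
apart, and bin means are taken in left-closed 100-bp bins. The default
decay model is the Hill–Weir drift-recombination expectation of r² with
C = c·d and the sample size fixed, fit by pair-count-weighted least
squares (Levenberg–Marquardt); a hyperbolic a/(1 + b·d) fallback is
recorded in the fit object when used. The extent of LD is the distance
where the monotone fitted curve reaches r² = 0.2, found by root
bisection; a threshold above the curve's value at zero is an error, and
a flat profile yields a degenerate fit with the extent undefined.
LD pruning follows the 50-SNP window / 50-SNP step / r² > 0.5 rule,
removing the *later* site of an offending pair — a deterministic
tie-break chosen because the exact victim choice of the reference tool
is unspecified.

## TE burst and insertion dating

K2P distances count transition and transversion proportions over
comparable sites (gapped or ambiguous columns excluded pairwise, not
listwise, to keep short alignments usable) and correct for multiple
hits; saturation (1−2P−Q ≤ 0 or 1−2Q ≤ 0) is an error for a single pair
and a logged missing value inside a matrix. Dates divide by 2μ because
divergence accrues on both lineages since the burst: age = K/(2μ) per
copy pair, with the mean and min–max range reported (whether a published
"pairwise distance" average is over copy pairs or copy-to-ancestor pairs
is generally unstated; both are recoverable from the matrix). LTR ages
use the same estimator on an element's two terminal repeats, which are
identical at insertion — identical LTRs therefore date an insertion to
0, i.e. younger than one expected substitution. Insertion presence is
called from read pairs spanning the element's junctions; two supporting
pairs per junction are required (one chimeric pair should not flip a
verdict), with `absent` requiring zero junction support plus two pairs
spanning the empty site, and everything else `ambiguous`.

## Annotation name mapping

Locus names carry forward when (1) old and new loci overlap uniquely
(≥1 bp, same strand, each overlapping exactly one locus of the other
set) and (2) at least one translated-transcript pair is a mutual best
hit at ≥70% normalized identity — identical residues divided by the
*longer* sequence, which penalises truncation. Transcript names require
90%, either through a protein MBH (rule 1) or, for models differing
mainly by UTR changes, ≥90% protein identity without MBH but with a
transcript-sequence MBH at 90% (rule 2). Identity is computed by global
alignment with affine gaps (BLOSUM62 for proteins) rather than a local
heuristic aligner: deterministic, dependency-free at this scale, and
identity-equivalent for the near-complete matches these rules act on.
Exact ties in best-hit selection break toward the lexicographically
smaller identifier and are flagged. The mapping is kept injective by
construction. The upstream liftover that would place both annotations in
one coordinate frame is out of scope; coordinates are inputs.

## What the generators emulate — and what they do not

* `gen_pav_matrix()`: Beta-Bernoulli occupancy (concentration 200 by
  default — tight, unimodal classes with realized class-mean occupancies
  within ±0.02 of specification at ≥1,000 genes, and no degenerate
  all-0/all-1 columns). It does *not* emulate assembly-quality gradients
  across libraries or phylogenetic correlation among genes; passing
  classification tests show the clustering machinery recovers planted
  structure, not that real PAV data have three classes.
* `gen_te_family()`: a star genealogy (single burst, independent
  divergence) under a K2P-compatible process with κ = 2, the matched
  model for the K2P estimator; real TE families also recombine, gene
  convert, and nest insertions.
* `gen_sweep_haplotypes()`: a hard sweep in its extreme form — carriers
  literally share one haplotype across the swept interval, with
  independent background sites. That validates EHH/iHS mechanics and
  window recovery; it does not reproduce the LD and frequency spectra of
  forward selection with recombination.
* `gen_ld_haplotypes()`: a haplotype-copying (PAC-like) process whose
  switch probability per bp sets the decay scale; it produces monotone
  mean decay but not a calibrated mapping to recombination rate, so LD
  analyses are checked for shape recovery, not absolute extent.
* `gen_read_pairs_over_junction()`: clean pairs with fixed insert
  geometry; no chimeras, mapping errors, or coverage variation beyond
  what the `min_pairs = 2` rule is there to absorb.
* Coalescent samples: no recombination or migration, two populations
  simulated independently (the ratio test compares diversity levels
  only); a shared-ancestry split model would be needed for joint
  site-frequency statistics.

All generators are pure functions of (parameters, seed); a single global
RNG is seeded per call and no hidden state persists.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the statistical claims are stable:
15,000 genes × 302 libraries for classification; 10,000 coalescent
replicates for moment checks and 1,000 fresh windows for the calibrated
ratio; 200 haplotypes × 400–600 sites for the selection scans; 60
independently seeded 12-copy families for burst dating, because a single
12-copy family carries only ~1.9 expected substitutions per copy and
therefore ~20% Monte-Carlo scatter in its age estimate. Other numerical
conventions: k-means uses 20 restarts per k; within-cluster standard
deviations are floored at 10⁻⁶ in the mixture BIC; EHH integration stops
early once the curve falls below the cutoff (the integral is unchanged);
bisections run on the log scale for the bottleneck severity (the ratio
is log-sensitive in f) and stop at 10⁻⁸ on the analytic root.

## Known limitations

* The enrichment test is conservative for high-occupancy genes (see
  above); an exact conditional test would require permutation over
  library assignments.
* iHS standardization assumes enough scored sites per frequency bin;
  panels with very few polymorphic sites merge into a single bin, where
  the |iHS| > 2 tail is exact by construction but frequency-specific
  sensitivity is lost.
* The sweep test's p-value is only as meaningful as the bottleneck
  parameterization; start, duration and N₀ are exposed because published
  significance levels are not recoverable without the original settings.
* The LD extent is model-dependent; the Hill–Weir and hyperbolic fits
  can differ materially in the tail, and the fit record names the model
  for that reason.
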