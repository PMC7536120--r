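# pavpop

Population genomics of a wild-grass pan-genome: gene presence–absence
variation (PAV), selection scans, a domestication-bottleneck sweep test,
retrotransposon dating, LD decay, and annotation name mapping — with every
analysis exercisable end to end on synthetic data generated in-package with
known ground truth.

## Who this is for

Plant population genomicists working with resequencing panels of a wild
species and its domesticated relative, who need the bespoke statistical steps
that sit *between* the standard tools (aligners, SNP callers, plink,
vcftools) and the biological conclusions:

* classify genes of a pan-genome into **core / shell / cloud** occupancy
  classes and test which genes are over- or under-represented in
  subpopulations;
* scan phased haplotypes for selection with **Tajima's D** and the
  **integrated haplotype score (iHS)** in sliding windows;
* ask whether a candidate region's diversity loss exceeds what a
  **domestication bottleneck** alone explains, via coalescent simulation of
  the diversity ratio π_domesticate/π_wild;
* date a **retrotransposon proliferation burst** and individual insertions
  from Kimura two-parameter (K2P) distances;
* model **LD decay** and its extent at r² = 0.2;
* carry **annotation names** forward between assembly versions with
  mutual-best-hit (MBH) rules.

## The statistics at the core

* **Occupancy classification.** Per-gene occupancy (fraction of libraries
  carrying the gene) is clustered by successive 1-D k-means for k = 1..6
  with seeded restarts; k is selected by BIC computed from the Gaussian
  mixture implied by each k-means solution, `-2 logL + (3k - 1) ln n`.
  Clusters are relabelled by descending mean occupancy: core, shell, cloud.
* **Enrichment.** For each gene with total presence count O across N
  libraries in subpopulations of sizes n_i, expected counts are
  `e_i = O n_i / N` and `X² = Σ (o_i - e_i)²/e_i` on `#subpops - 1` df
  (critical value 7.81 for df = 3, α = 0.05), with Benjamini–Hochberg
  correction across genes.
* **Tajima's D** `= (π - S/a₁) / sqrt(e₁S + e₂S(S-1))` with the standard
  coefficients; **iHS** `= ln(iHH_A / iHH_D)`, the log-ratio of trapezoid
  integrals of extended haplotype homozygosity (EHH) for ancestral and
  derived core alleles, truncated at EHH < 0.05 and standardized within
  derived-allele-frequency bins. Windows are 100 kb sliding by 10 kb for
  the extreme-|iHS| fraction, 10 kb non-overlapping for D.
* **Sweep test.** A Hudson coalescent (no recombination within windows,
  piecewise-constant sizes, time in units of 2N₀ generations) simulates
  paired windows under a calibrated bottleneck vs constant size;
  `p = (1 + #{ratio_sim ≤ ratio_obs}) / (kept + 1)`. Bottleneck severity is
  calibrated by bisection of the closed-form expected pair-coalescence
  time so that the expected diversity ratio matches the genome-wide value
  (22% in the motivating system).
* **TE dating.** `K = -½ ln(1-2P-Q) - ¼ ln(1-2Q)`; a burst is dated as
  `K̄/(2μ)` over copy pairs with μ = 6.5×10⁻⁹ substitutions/bp/yr, an
  insertion as the K2P distance between its two LTRs over 2μ.
* **LD decay.** r² is the squared genotype correlation; bin means every
  100 bp are fit by weighted least squares to the Hill–Weir expected-r²
  curve, and the extent is where the fitted curve reaches 0.2.

## Worked example

The `analysis/` directory holds the full workflow as numbered scripts
(`01_simulate.R` … `07_namemap.R`), each writing its tables under
`results/`. The pan-genome stage, for instance:

```r
library(pavpop)
specs <- list(pav_class_spec(5000, 0.98, label = "core"),
              pav_class_spec(5000, 0.56, label = "shell"),
              pav_class_spec(5000, 0.12, label = "cloud"))
gen <- gen_pav_matrix(specs, 302,
                      c(Central = 130, CentralEast = 78,
                        CentralNorth = 59, WestCoast = 35), seed = 1)
cls <- classify_occupancy(occupancy(gen$pav), seed = 1)
cls
#> occupancy_classification: 15000 genes, k* = 3
#> cluster means: 0.980, 0.560, 0.120
```

Running the scripts in order prints (seed 1):

```
$ Rscript analysis/02_pangenome.R
selected k = 3 clusters; mean occupancies: 98.0%, 56.0%, 12.0%
label concordance with generator truth: 100.0%
15000 genes tested for enrichment; 153 candidates above the chi-square
  critical value; 0 with BH q < 0.05
$ Rscript analysis/04_sweep.R
calibrated severity: 0.0202 (bottleneck 0.08-0.12, 2N0 units)
fresh re-simulation over 1,000 20-kb windows: 21.4%
empirical p for an observed window ratio of 0.06: 0.1464
$ Rscript analysis/06_tedating.R
burst age from 66 copy pairs: mean 37495 years (range 0-82918)
LTR-divergence insertion ages: mean 0 years; 12/12 copies have identical
  LTRs (age 0)
```

Reading the numbers: the three planted occupancy classes are recovered
exactly; under the enrichment null the raw χ² > 7.81 rule flags ~1% of
genes while BH correctly retains none; a single 12-copy TE family dates its
45,000-year burst with ~20% Monte-Carlo scatter (the acceptance experiment
averages many families); and a window at 6% relative diversity is
suggestive but not significant against a bottleneck calibrated to 22% —
sharper localized losses are needed for small p.

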