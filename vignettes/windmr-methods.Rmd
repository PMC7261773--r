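---
title: "Methods: sliding-window differential methylation analysis in windmr"
author: "windmr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window differential methylation analysis in windmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windmr)
```

## The problem

Whole-genome duplication and other large genomic perturbations in plants are
accompanied by DNA methylation changes that can re-tune gene expression.
`windmr` compares two whole-genome bisulfite sequencing (WGBS) methylomes —
typically one pooled methylome per condition, such as a diploid and the
autotetraploid derived from it — at single-cytosine resolution, and asks
where the methylome changed (differentially methylated regions, DMRs) and
whether those changes line up with differential gene expression.

The pipeline has four stages, each exposed as ordinary functions and
orchestrated by `run_pipeline()`:

1. **Profiling.** Per-cytosine methylation levels, per-context
   methylcytosine calls, 50-kb density/level tracks, per-chromosome
   cross-sample correlations, and a per-site divergence summary.
2. **DMR calling.** 100-bp windows at 25-bp steps, a two-group
   Kruskal–Wallis rank test per window, Benjamini–Hochberg correction per
   context, fold-change/trend assignment, and same-trend merging.
3. **Annotation.** DMRs against gene bodies and strand-aware 2-kb flanks.
4. **Association.** Gene expression classes crossed with per-region DMR
   groups, with a seeded random control.

A self-contained simulator (`simulate_methylome_experiment()`) generates
paired methylomes, gene models and an expression table with planted truth,
so every stage is testable without any external data.

## Models and statistics

### Methylation levels and the joint coverage filter

The level of a cytosine is `n_meth / (n_meth + n_unmeth)`. Only sites
covered by at least `min_coverage` reads (default **3**) in *both* samples
enter the comparison (`pair_samples()`); this joint filter is what makes
per-site levels comparable across samples with different depths. Sites are
strand-specific throughout — symmetric CpG pairs are never pooled, because
the downstream test operates on per-cytosine levels.

A covered site is called a methylcytosine (mC) when it carries at least
`min_meth_reads` methylated reads (default **1**). This is deliberately the
simplest rule: with one pooled methylome per condition there is no
replicate structure to support a binomial test against a conversion-error
rate, and the package does not attempt one. The threshold is exposed so a
stricter call is one argument away.

### Per-site divergence

Restricted to sites that are mCs in at least one sample, a site counts as
*increased* when `level_b / level_a > 1.2` and *decreased* symmetrically;
changes beyond 2-fold are tallied separately. Sites where one level is zero
and the other positive have an undefined ratio; dropping them would bias
divergence downward, so they are classified into the ≥2-fold class of the
nonzero direction (this choice is a parameter, not a constant of the code).
The total divergent percentage is exactly the sum of the increased and
decreased percentages, per context and overall.

### The window test

The genome is tiled into 100-bp windows every 25 bp. For one context at a
time, each window collects the jointly covered sites it spans; windows with
fewer than `min_sites` sites (default **4**) are *untested* and excluded
from the multiple-testing family — a rank test on fewer than four
observations per group cannot reach p < 0.05 through the chi-square
approximation and only inflates the family size. Tested windows get a
two-group Kruskal–Wallis statistic on the pooled midranks with the standard
tie-correction divisor, and a p-value from the chi-square distribution with
one degree of freedom. For two groups the statistic is computed in the
algebraically equivalent rank-sum form

$$H = \frac{12\,D^2}{n_1 n_2 (N+1)\,C}, \qquad
  D = R_1 - \tfrac{n_1 (N+1)}{2},$$

which avoids the catastrophic cancellation the textbook
$\sum R_j^2/n_j - 3(N+1)$ form suffers near $H = 0$ (midrank sums are exact
in floating point, so $D$ is exact). When every pooled value is tied the
statistic is defined as $H = 0$, $p = 1$. An exact-permutation p-value is
not used in production — the chi-square approximation is standard practice
at these group sizes — but an exact integer-arithmetic oracle verifies the
statistic in the test suite.

Sites that enter a window are *all* jointly covered cytosines of the
context, not only methylated ones. Conditioning window membership on
observed methylation in either sample was evaluated and rejected: it
selects sites on the very signal being tested and makes the null test
anti-conservative (~0.065 of null windows at p < 0.05 instead of 0.05).

### Multiple testing and DMR calling

Benjamini–Hochberg q-values are computed across all tested windows of one
context genome-wide — not per chromosome, and not pooled across contexts,
whose null behaviours differ too much to share a family. Windows with
q < 0.05 become DMRs; the fold change of a window is the ratio of the mean
levels (`mean_b / mean_a`), the trend is *hyper* (higher in sample B) when
it exceeds 1 and *hypo* otherwise, and by default a region must also pass
the per-site fold-change threshold extended to regions,
`|log(fc)| > log(1.2)`. A window whose sample-A mean is zero has infinite
fold change and trend hyper.

### Merging and annotation

Adjacent same-trend DMRs — overlapping or abutting, with a configurable
maximum gap defaulting to 0 — collapse into a single region spanning their
union; with a 25-bp step, neighbouring significant windows overlap, so the
collapse rule is effective without any gap allowance. The merged fold
change is recomputed from all sites in the merged interval rather than
averaged from the members, the q-value is the members' minimum, and
opposite-trend regions are never merged (both are retained even when they
overlap). Both the window-level and merged DMR counts are reported, since
either may be the quantity of interest.

Gene annotation assigns a DMR to every gene region it overlaps by at least
one base pair: the gene body `[start, end)` and strand-aware upstream and
downstream 2-kb flanks. Multi-assignment is intentional — a DMR crossing a
body boundary annotates both regions.

### Expression association

Genes are classified from the expression table: *non-expressed* when FPKM
< 1 in both samples, otherwise *increased*/*decreased* when FDR < 0.05 by
the sign of the log2 fold change, else *non-diff*; the four classes
partition the gene set. Among the increased and decreased classes
restricted to at least 4-fold change (`|log2fc| >= 2`), genes are grouped
per region by the trends of their overlapping DMRs (hyper / hypo / both /
none), a seeded random control of configurable size (default: the largest
DMR group) is drawn from the same DEG set, and all group pairs are compared
with two-sided Wilcoxon rank-sum tests, BH-corrected within each
(direction, region) family. The boxplot-style summaries report medians and
quartiles. The random control is drawn from the DEG set rather than all
genes — the comparison of interest is *among* strongly changing genes — and
a gene whose only DMR sits in a flank still counts as DMR-containing for
the per-class percentages; both choices are parameters.

## The simulator

`simulation_config()` fixes the synthetic study conditions; all randomness
derives from the mandatory seed, and identical configurations produce
byte-identical output files.

* **Genome.** Two 1-Mb chromosomes of i.i.d. sequence at GC fraction 0.35
  (grape-like). Every cytosine on both strands is classified CG/CHG/CHH
  from its trinucleotide.
* **Methylation landscape.** True levels are piecewise constant over
  segments of mean length 300 bp (uniform 150–450 bp), drawn per segment
  and context from a Beta distribution with concentration 6 and
  context-specific means 0.34 (CG), 0.30 (CHG), 0.16 (CHH) — the scale of
  methylation levels and their context ordering in grapevine buds. The
  segment structure emulates the spatial autocorrelation of real
  methylomes; drawing levels i.i.d. per site would produce an unrealistically
  rough landscape.
* **Reads.** Coverage is Poisson with mean 12 per site and sample;
  methylated counts are binomial in the true level, so observed levels are
  beta-binomial and overdispersed, as in real WGBS.
* **Planted DMRs.** 200 CHH DMRs by default (the context where plant
  methylome divergence concentrates), lengths uniform 100–400 bp, each
  covering at least 8 CHH sites and kept clear of other planted regions.
  Sample B inherits sample A's true levels except inside a planted DMR,
  where the level shifts by ±0.3, clipped to [0, 1] — so hypo-DMRs on lowly
  methylated segments lose only what they have, which is the main source of
  imperfect sensitivity. 40% of planted DMRs are placed inside distinct
  gene bodies, 15% in gene flanks, the rest in intergenic space.
* **Genes and expression.** 250 non-overlapping genes (~60 genes/Mb, a
  grape-like density that leaves ~20% of the genome outside gene regions)
  with log-normal baseline FPKM. Background genes are non-expressed with
  probability 0.2 and DEGs with probability 0.3; large-DEG magnitudes are
  `2.1 + Gamma(4, 8)` so the 4-fold filter does not truncate them, while a
  quarter of background DEGs are drawn below 4-fold so the filter is
  exercised. A gene hosting a planted body hypo-DMR becomes, with
  probability 0.8, an increased DEG with an additional **+1** log2fc
  increment (hyper mirrors downwards) — the coupling the association stage
  must recover. Reported FDRs are generated (small for DEGs), since
  differential-expression testing itself is out of scope. The DEG and
  non-expressed fractions are deliberately enriched relative to a real
  transcriptome so the association groups are estimable on a 2-Mb genome.

### What passing tests do and do not show

The simulator reproduces the *statistical* structure the pipeline relies
on: context-stratified beta-binomial levels, spatial autocorrelation,
sparse localized shifts, coverage noise, and trend-coupled expression. It
does not model bisulfite conversion error, mapping bias, chromosome-scale
methylation gradients (pericentromeric enrichment), replicate variance, or
read-level artefacts. Recovery results on it therefore validate the
machinery — windowing, testing, correction, merging, matching — not the
biological error rates to expect on real libraries.

## Numerical and design notes

* Internal coordinates are 0-based half-open everywhere; the 1-based
  dialects (cytosine report, GFF3) are converted at the file boundary, and
  the conversions are involutions.
* Context is trusted from the report and never re-derived from sequence
  (the genome FASTA is only used by the simulator and for chromosome
  lengths).
* BH ties are resolved by original index, merging scans are
  deterministic, and the association's random control is the only seeded
  randomness in the analysis path.
* Result tables are written with 17 significant digits, so every write →
  read round trip is bit-identical; output files carry a provenance header
  (package version, configuration hash, seed) and no timestamp, keeping
  re-runs byte-identical.
* Degenerate inputs are flagged rather than guessed at: correlations on
  fewer than 3 shared sites or zero variance are `NA`, empty bins have
  undefined mean level, empty association groups are reported with
  `n = 0` and skipped in testing.

### Calibration of the window test

On a simulated null (no planted DMRs) the fraction of tested CHH windows
with raw p < 0.05 comes out slightly *below* 0.05 (about 0.04, recomputed
by `scripts/acceptance.R` as `null_raw_p_below_005`), and no window
survives BH correction. The shortfall is not a coding artefact of the
statistic — on windows whose sites share one true level the fraction is
consistent with the nominal 0.05 (a property test in the suite checks
this) — but a property of rank tests on spatially heterogeneous data: when
per-site true levels differ within a window, the full-permutation null
overstates the rank-sum variance and the test becomes mildly
conservative. Real methylomes are spatially
heterogeneous, so this conservatism is the realistic operating point; it
costs a little power and makes the FDR control slightly stricter than
nominal, and it is why the simulator's segment structure was kept rather
than tuned away.

## Problem sizes

The packaged analyses run at desk scale by design: 2 × 1 Mb genomes
(~700k cytosines, ~80k tested CHH windows), 200 planted DMRs and 250 genes
for the recovery and association scenarios, and a 1-Mb genome for the null
calibration. These sizes put ~25 sites in a typical CHH window and 20–50
genes in the key association groups — enough for stable medians and
recovery rates while a full simulation-plus-analysis cycle stays under two
minutes on one core. Every number quoted above is recomputed by the test
suite or by `scripts/acceptance.R`; none are stored.

## Known limitations

* One pooled methylome per condition: no replicate dispersion modelling
  (the rank test compares sites within a window, not windows across
  replicates).
* The mC call is a read-count threshold, not a test against conversion
  error.
* The chi-square approximation is conservative for heavily tied,
  spatially heterogeneous windows (quantified above).
* Differential expression is consumed, not computed; FDRs in the
  expression table are taken at face value.
* Merging never joins across untested gaps (max-gap defaults to 0), so a
  long disturbed region interrupted by a low-coverage stretch is reported
  as two regions.
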