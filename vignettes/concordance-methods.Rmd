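---
title: "Methods: genotype concordance between BeadChip and WGS call sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype concordance between BeadChip and WGS call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtconcord)
```

## The problem

A BeadChip microarray and a whole-genome sequencing (WGS) pipeline genotype
the same DNA sample by entirely different physics: two-channel bead
fluorescence clustered into AA/AB/BB groups versus aligned short reads fed
to a variant caller. Neither is a gold standard, so their disagreements are
informative about both. This package implements the comparison as a
pipeline: harmonize the two call sets, quantify their concordance through
genotype-class confusion matrices, locate the discordant calls along the
genome and within the array's intensity space, pick compact regions of
discordant variants that a single Sanger read can cover, and, when Sanger
genotypes are available, let them adjudicate.

## Harmonization

Sites enter the comparison only if present and successfully genotyped on
*both* platforms; a no-call on either side removes the site from every
downstream statistic. Array alleles are reported on the plus strand but
array manifests and VCFs disagree often enough that `harmonize_pair()`
first tries a direct match of the BeadChip alleles against the VCF
ref/alt set and then the reverse complement. At complementary-pair sites
(A/T, C/G) a strand flip is undetectable in principle, so mismatching calls
there are excluded and counted as ambiguous rather than guessed. Indel
alleles arrive as `I`/`D` symbols on the array side; `I` maps to the longer
and `D` to the shorter of the VCF ref/alt pair, which is well defined for
the simple insertions and deletions arrays assay. Coordinates are 1-based
point positions throughout; region intervals are closed; the BED writer
converts to 0-based half-open.

Sex chromosomes and the mitochondrion violate the diploid model in males
(and MT in everyone), so the caller passes `exclude_chroms` explicitly —
`c("MT","X","Y")` for a male sample, `"MT"` for a female one — rather than
the package inferring sex.

## The metric engine

With A = reference allele and B/C = alternative alleles in VCF order, each
paired call contributes one cell to a 6×6 confusion matrix over
`{AA, AB, BB, AC, BC, CC}`. `MISSING` never enters a matrix. Multiallelic
class order follows the VCF ALT order, which keeps the labeling
deterministic.

Per focal class the matrix is reduced to 2×2 by pooling the other classes.
The overall precision and sensitivity weight each per-class ratio by its
focal column/row share; algebraically both collapse to `trace/n`, the
genotype concordance, and the test suite asserts this identity on random
matrices rather than trusting the algebra. Accuracy and specificity are
means of per-class values with NaN (zero-denominator) classes excluded.

Two conventions in that mean were genuinely open and are exposed as
arguments of `compute_metrics()`:

- **class universe** (`classes`): averaging over all six classes rewards a
  comparison merely for *lacking* rare classes (absent classes score a
  perfect 1). The default `"present"` averages only classes with a nonzero
  row or column sum.
- **weights** (`class_weights`): the default `"equal"` is the plain mean;
  `"truth"` weights each class by its truth-row share, which converges to
  the micro-average on very unbalanced matrices. On small adjudication
  subsets with a dominant hom-ref class the two can differ by several
  points, and published per-class-mean accuracies are not always
  reconstructible without knowing which rule (and which reference-allele
  labeling) was applied; the package therefore states its rule and keeps
  both computable.

When no platform is a baseline truth, `symmetrize_metrics()` computes the
metrics in both orientations and averages element-wise. Undefined values
stay `NA` — they are never silently zero.

## Mapping discordance

`per_chromosome_discordance()` is a direct ratio per chromosome plus the
pooled genome-wide fraction. `distance_pair_table()` computes, within each
concordance group and chromosome, each interior variant's distance to its
previous and next same-group neighbor; on a log-log plot an evenly spread
group hugs the diagonal, and a rarer group sits further up it. The KDE view
(`kde_density()`) uses a Gaussian product kernel on the log10 scale with
Scott's rule (`sd * m^(-1/6)` per axis) as default bandwidth; no formula
for "cluster evenness" is standard here, so the package exposes the grid
plus one simple summary (the mean `|log10 d_prev − log10 d_next|`,
attribute `bisectrix_offset`) and leaves interpretation to the analyst.

`select_validation_regions()` packs discordant sites into windows of at
most `max_span` bp (default 500, about one Sanger read): repeatedly take
the window covering the most not-yet-covered discordant sites, ties going
to the leftmost window, and emit the tight span of the covered sites.
Greedy maximal cover is not globally optimal in general; the test suite
checks the first pick against an exhaustive search on small instances,
which is the pick that matters for ranking candidate regions. Published
region tables may pad bounds for primer design (one such region spans
510 bp); padding is presentation, not selection, so the span bound here
applies to the tight discordant span only.

## Quality-metric comparisons

`compare_metric_distributions()` is Welch's unequal-variance t-test on the
finite values of two groups, two-sided, significance at 0.05. Degenerate
groups (fewer than two values, or no variance anywhere) return an
`NA`-marked row instead of erroring, so a sweep over many metric/grouping
combinations survives sparse groups. Multiple testing is *not* corrected by
default — each metric is read as its own exploratory question — but
`quality_comparison_table(bonferroni = TRUE)` adjusts across a sweep.

`score_cluster_border()` measures each call's Theta distance from the
canonical center of its called cluster (0, 0.5, 1 for hom-ref, ref-het,
non-ref genotypes) and flags calls beyond a quantile (default 0.9) of the
concordant group's distances. True GenomeStudio cluster centers are fitted
per marker and are not exported in final reports, so the canonical centers
are an idealization; distances are comparable across markers but are not
the scorer's own cluster geometry. This is a documented limitation, not a
bug to fix downstream.

## Sanger adjudication

A Sanger genotype string is a resolved diploid call only when two allele
symbols are present (both chromatogram directions covered the site); a
single symbol plus a dash is a haploid single-read call and is excluded
from metrics even when compatible with both platforms, and `NA` is a failed
reaction. Resolved rows are classified by unordered genotype equality into
Sanger-matches-WGS-only / all-three / Sanger-matches-BeadChip-only /
no-agreement; the five patterns (with UNRESOLVED) partition any table.

`validation_metrics()` builds one confusion matrix per platform with
Sanger as truth. Without a VCF the reference allele at a validation site is
unknown, so class labels are site-local: A is the Sanger-majority allele,
remaining alleles rank by total count then alphabetically. The weighted
precision is provably invariant to this labeling (it is `trace/n`, and
genotype equality does not depend on symbol names); the per-class-mean
accuracy is labeling-dependent in general, which is exactly the convention
ambiguity discussed above and the reason the accuracy convention is stated
explicitly wherever reported.

## The synthetic generator

No subject-level data ships with the package, so `simulate_paired_study()`
generates what the pipeline consumes, at the level of genotype calls (not
reads):

- **Sites** placed uniformly without replacement per chromosome,
  chromosomes weighted by GRCh38 autosome lengths; default 1e5 sites, a
  scale at which binomial noise (~0.02% on a 0.6% rate) sits well below the
  effects tested while a full pipeline run stays under a minute.
- **Genotypes** drawn under Hardy–Weinberg from an alternative-allele
  frequency uniform on [0.05, 0.5]; 10% indels; 1% triallelic SNVs (with
  the alternative frequency split 2:1) so the AC/BC/CC matrix cells are
  exercised rather than structurally empty.
- **Platform calls** equal the truth with probability `1 − error_rate`,
  otherwise a uniformly chosen *different* genotype class of the site.
  Defaults 0.002 (WGS) and 0.004 (BeadChip) give a pairwise discordance
  near `e1 + e2 ≈ 0.6%`, the regime observed when such platform pairs are
  compared in practice (per-sample fractions of roughly 0.3–0.9%). The
  class-uniform error model is the simplest one that reaches every matrix
  cell; it does not emulate allele dropout or any mechanism-specific bias.
- **Intensities**: Theta is Gaussian (sd 0.04) around the called class
  center, truncated to [0, 1]; with `border_enrichment` on, discordant
  calls have their mean shifted halfway toward the nearest cluster border
  (0.25/0.75), reproducing the near-border excess of discordant calls. R is
  log-normal, the GC score decreases linearly in the distance from the
  cluster center, X/Y invert the polar transform, and the B allele
  frequency interpolates Theta between the centers. The enrichment
  magnitude is a free parameter of the simulation — real data constrain its
  existence, not its size.

All randomness flows from one top-level seed; sub-streams use fixed small
offsets, so a seed fixes every downstream number. What passing tests on
synthetic data show is that the *pipeline arithmetic* is right under a
known generating process — they cannot show that real BeadChip errors are
class-uniform, that real clusters are canonical, or that real discordance
is genome-position independent.

## Numerical choices and edge cases

- Empty inputs return empty (or `NA`-valued) results of the right shape;
  an empty confusion matrix yields all-undefined metrics.
- VCF records failing FILTER, or with more than two ALT alleles, are
  dropped and counted in the `"dropped"` attribute; haploid GT strings are
  represented as homozygous.
- Region-selection ties break to the leftmost window in canonical
  chromosome order (1–22, X, Y, MT), making output order deterministic.
- Round-tripping written files is exact because the writers emit the same
  fixed-precision text the readers parse; annotations are integers by
  construction.
- Problem sizes in the test suite: 1e5-site simulations for rate recovery
  (5 seeds), 1000 random matrices for the metric-engine properties, 1000
  null replicates for the Welch type-I check.

## Known limitations

- Strand ambiguity at A/T and C/G SNVs is unresolvable without manifest
  TOP/BOT annotations; such mismatches are excluded, slightly deflating
  discordance if flips are common.
- Canonical Theta centers ignore per-marker cluster geometry.
- The non-reference metric definitions follow the package's stated
  conventions; other toolchains define them differently, so compare
  definitions before comparing numbers.
- The simulator starts at genotype calls; read-level artifacts (mapping
  error, coverage dropouts) are out of scope.
```{r session}
sessionInfo()
```
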