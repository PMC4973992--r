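---
title: "Detecting signatures of selection in replicated divergent lines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting signatures of selection in replicated divergent lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long-term bidirectional artificial selection on a polygenic trait drives
the two selected lines apart at the trait loci and everything linked to
them — but genetic drift drives them apart everywhere else too. With a
*replicated* design (two independent line pairs bred from the same base
population) the two forces can be separated: selection moves the same
loci in the same direction in both replicates, while drift moves random
loci in random directions. `thetascan` implements a genome scan built on
that idea, for shallow whole-genome sequencing (~5x per sample) of a
handful of individuals per line, plus the supporting machinery: window
calibration from linkage disequilibrium (LD), four-gamete-rule haplotype
blocks for fine-mapping, gene-region annotation, and a drift-regression
estimate of how many fixed loci drift alone explains.

## The statistic

Code the presence of the non-reference allele on each of the two allele
copies ("gametes") of every sequenced individual as 0/1 and decompose its
variance over the nested design

$$Y_{ijkm} = \mu + L_i + R_{(i)j} + S_{(ij)k} + G_{(ijk)m},$$

with lines $i$, replicates-within-line $j$, samples $k$ and gametes $m$.
Method-of-moments estimates of the four variance components
$(\hat\sigma^2_L, \hat\sigma^2_{R(L)}, \hat\sigma^2_{S(RL)},
\hat\sigma^2_G)$ come from equating the nested sums of squares to their
expectations, with Henderson-type coefficients that handle unbalanced
cells (missing genotypes are dropped per locus). The scan statistic at a
focal SNP is the intra-class correlation

$$\theta(q) = \frac{\sum_{q=1}^{w}\hat\sigma^2_{L,q}}
{\sum_{q=1}^{w}(\hat\sigma^2_{L,q}+\hat\sigma^2_{R(L),q}+\hat\sigma^2_{S(RL),q}+\hat\sigma^2_{G,q})},$$

a ratio of sums over a window of $w$ consecutive polymorphic SNPs, which
estimates Fst between the lines. Three numerical choices matter:

* **Negative components are retained.** Method-of-moments estimates can
  be negative; truncating them at zero would push $\theta$ upward under
  the null, so window sums use them as computed. A window's $\theta$ can
  therefore be slightly negative; windows with a non-positive component
  total are skipped as undefined.
* **Gamete order is arbitrary.** Genotypes are unphased; every statistic
  depends only on per-sample allele counts, so the within-sample split of
  a heterozygote into gametes never matters.
* **One replicate degenerates gracefully.** With a single replicate the
  replicate stratum has zero degrees of freedom and is dropped — exactly
  the analysis whose error term omits drift, which is what the
  replication argument below is about.

## Significance: genome-wide permutation maxima

Design labels are shuffled onto gametes (or onto whole individuals,
preserving the within-individual pair) once genome-wide; the maximum
windowed $\theta$ over all focal SNPs is recorded; after $n$ shuffles the
critical value at genome-wide p-value *GWp* is the
$\lceil \mathrm{GWp}\cdot n\rceil$-th largest maximum, and the larger
critical value of the two shuffling schemes is used. Because the maximum
is taken over the whole genome, multiplicity is automatic. Signatures of
selection are focal SNPs whose $\theta$ **strictly exceeds** the
threshold.

**Known limitation (measured, not hidden).** Permutation assumes the
design labels are exchangeable. After tens of generations of drift they
are not: each line-by-replicate cell is a genuinely differentiated
population, whereas permuted "cells" are mixtures. The permutation null
therefore under-states the drift tail of $\theta$, and under a drift-only
simulation essentially every dataset yields at least one "signature" at
GWp = 0.01. The acceptance suite runs this calibration experiment at
face value and reports the measured false-positive rate; it fails the
1% target, and we keep it failing rather than re-defining the null. This
is intrinsic to the method, and it is why the package carries the
drift-regression FDR module: the count of fixed/lost loci expected from
drift scales with genome-wide Fst, so regressing the per-scope counts on
Fst and reading the intercept estimates the selection-attributable
fraction after the fact. The permutation machinery itself is correct: when
samples really are exchangeable (all drawn from one population),
permutation p-values are uniform, and that property is tested.

## Window calibration from LD decay

Pairwise $R^2$ between loci with minor allele frequency above 10% is
estimated by the standard EM ("iterative") algorithm for two-locus
haplotype frequencies from unphased genotypes — only the
double-heterozygote class is phase-ambiguous; iteration starts from
linkage equilibrium and stops when frequencies move less than 1e-10. The
scan window $w$ is the smallest SNP-rank separation at which the median
$R^2$ drops below 0.25 (the *LD_25* distance), forced odd; separations
are measured in SNP ranks with bp reported alongside. On data of the
density this package targets that yields $w \approx 7$; windows much
larger dilute the signal with unlinked loci.

A null-floor subtlety: for *phased* haplotypes the expected $R^2$
between independent loci is $\approx 1/N$ for $N$ haplotypes; for
EM-estimated $R^2$ from $n$ unphased diploids the measured floor is
$\approx 1/(n-1)$ — the double-het ambiguity roughly doubles the noise.
Both floors are verified by Monte-Carlo in the test suite.

## Haplotype blocks by the four-gamete rule

Two biallelic loci showing all four gamete types imply at least one
historical recombination between them. Blocks are grown left to right:
the incoming locus is compared against **every** locus already in the
block, a gamete counting as observed when its estimated frequency
exceeds the minor gamete frequency threshold (MGF); four observed
gametes close the block. Raising the MGF demands more common
recombination products, so blocks can only grow — the spine search walks
an MGF grid (0.05–0.25 by 0.01) until at least 95% of SNPs sit inside
multi-SNP blocks ("near-continuous spine"; the 95% quantification is
ours, exposed as a parameter, since no number is stated in the source
convention). For inbred founder pools gametes are counted directly from
the (effectively phased) haplotypes; for line data they come from the EM
estimator, mirroring Haploview's treatment.

## Gene-region annotation

Per gene (exons unioned across transcripts, TSS = 5'-most transcribed
base): promoter = 10 kb upstream of the TSS, strand-aware; UTR bases keep
the UTR label; remaining exonic bases are exon; intronic bases within
150 bp of an exon boundary are junction (JR) — the territory of splice
sites and most branch points — and deeper intron is INJR (both intron
ends, since splice-relevant sequence flanks each exon edge); everything
outside genes and promoters is intergenic. Ties within a gene resolve by
precedence exon > UTR > JR > INJR; a SNP inside two overlapping genes is
annotated once per gene; promoters overlapping an upstream gene's body
still count as promoter for their own gene. Densities divide counts by
the genome-wide unioned size of each class, so small classes (junctions)
can dominate per-Mb despite modest counts. Coordinates follow the
R/Bioconductor convention (1-based, closed intervals) internally, with
BED exports converted to 0-based half-open; this deviates from a
0-based-internal design note deliberately — fighting GRanges conventions
inside an R package invites off-by-one errors at every boundary.

## Drift regression and FDR

Per scope (each replicate; across replicates after averaging each line's
frequencies over its replicates, which cancels drift that went opposite
ways), count the loci divergently fixed between the lines
(non-reference frequency exactly 1 in one line, 0 in the other; a looser
"either line monomorphic" mode exists behind a flag since the source
convention is ambiguous). Under drift alone the count is proportional to
genome-wide Fst with zero intercept, so fitting
$\mathrm{Lost} = b_0 + b_1\,\mathrm{Fst} + e$ by OLS to the per-scope
points makes $b_0$ the number of loci fixed by selection and
$\mathrm{FDR} = (N-b_0)/N$ the drift-attributable fraction per scope
(clamped to [0,1] with a warning; reported both raw and rounded to whole
percent). Genome-wide Fst itself is the plug-in two-population
intra-class ratio computed from pooled read frequencies, combined across
loci as a ratio of sums; it is *not* noise-corrected, so identical
frequency tables give exactly 0 and divergent fixation exactly 1, at the
cost of an upward bias of order 1/(reads per cell).

The related depth calculation: a true heterozygote sequenced to depth
$d$ shows a single allele with probability $2(1/2)^d$ — 6.25% at the 5x
design depth. Such miscalls inflate the gamete variance (denominator)
but leave between-line frequency contrasts unbiased, so they cost power,
not validity.

## What the simulator emulates — and what it does not

The generator produces the world the scan assumes: 8 fully inbred
founders (every locus polymorphic among them; a configurable fraction of
adjacent founder patterns independent, so many four-gamete pairs exist
before any breeding — the multi-parent-cross property that keeps
ancestral blocks small); ~10 generations of random intercrossing into a
MAGIC base of 240 diploids; per replicate, independent base samples
founding a high and a low line of 25 breeding pairs; an additive trait
(causal dosages x effects + Gaussian noise scaled to the base
heritability); within-family truncation selection — the two extreme
offspring of each family enter the next generation, mated rotationally
(family f's first pick with family f+1's second), so every family
contributes and the effective size stays near its ceiling (~100 here,
which after 60 generations produces within-replicate Fst near 0.2, the
regime the method targets); 40 of 60 generations selected, the remainder
relaxed (random picks); finally 10 individuals per line x replicate
"sequenced" with Poisson(5) read depth and a 0.3% per-read error flip.
One master seed drives everything; replicate streams are derived from it
deterministically.

Deliberately not modelled: a realistic genome map (2 chromosomes x 10 Mb
x 1 cM/Mb at desk scale), real founder sequences, sex chromosomes,
dominance or epistasis (the trait is strictly additive — the simplest
model that produces a bidirectional response), new mutation (negligible
for SNPs over 60 generations), or the rotational scheme's husbandry
details beyond "every family contributes". A green simulation test
therefore establishes that the *statistics* behave as designed under the
assumed breeding structure — not that the package reproduces any
particular real dataset.

## Design choices where the design was open

* **Selection schedule**: sources alternate between "30 generations
  continuous" and "40 of 60 total"; both are exposed
  (`n_generations_selected`, `n_generations_total`, defaults 40/60).
* **Permutation granularity**: labels are re-drawn once genome-wide per
  permutation (not per chromosome), matching a genome-wide max
  statistic; line and replicate labels travel together, preserving cell
  sizes.
* **LD separations** are counted in SNP ranks (the window is SNP-count
  based); bp distances are reported alongside.
* **Threshold ties** break conservatively: a focal SNP must strictly
  exceed the critical value.
* **genotype calling** at stricter-than-default evidence thresholds
  treats sub-threshold minor-allele reads as absent rather than
  uncallable; at the default (1 read per allele) an observed two-allele
  locus is never called homozygous.

## Worked example

```{r, eval = FALSE}
library(thetascan)

cfg <- sim_config(n_chromosomes = 2, loci_per_chromosome = 500,
                  n_causal_loci = 1, effect_sizes = 1, heritability = 0.5,
                  seed = 42)
sim <- simulate_experiment(cfg)
scan <- theta_scan(sim$genotypes, w = 7, n_permutations = 2000,
                   gwp = 0.001, mode = "both", seed = 42)
scan$perm$critical_theta
scan$signatures
blocks <- four_gamete_blocks(sim$genotypes, mgf = 0.09)
fdr <- drift_regression(count_fixed_lost(
  estimate_allele_frequency(sim$reads)))
```

Every number this vignette relies on — the 6.25% miscall rate, the
1/(2N) pooled-gamete floor, the FDR arithmetic, the calibration and
power rates — is computed by the test suite or `scripts/acceptance.R`,
not asserted here.

## Known limitations

* The permutation threshold does not control the drift-driven
  false-positive rate (see above); interpret signature lists jointly
  with the drift FDR.
* The EM-based $R^2$ and block calls are exact only as $n \to \infty$;
  at 40 samples the phase-ambiguity noise is visible (tested ~1/(n-1)
  floor).
* Read counts are modelled per locus independently — no mapping bias,
  no copy-number structure; the 4x depth-cap filter exists for real
  data, and the simulator never triggers it.
* The scan assumes exactly two lines; more-level designs would need new
  expected-mean-square coefficients.
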