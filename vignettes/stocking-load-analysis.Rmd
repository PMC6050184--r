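---
title: "Supplementation and the distribution of deleterious mutations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supplementation and the distribution of deleterious mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stockload)
```

## The question and the study system

Lake-dwelling salmonid populations in post-glacial landscapes are small,
isolated, and strongly drift-dominated: each lake has been accumulating its
own genetic fate for on the order of a hundred generations. Managers
supplement ("stock") many of these lakes with fish from other lakes. This
package implements the statistical workflow for asking what that does to
two linked quantities: neutral genetic diversity, and the relative burden
of putatively deleterious mutations.

The reasoning is classical population genetics. In a small isolated deme,
selection against a mildly deleterious allele (selection coefficient $s$,
dominance $h$, genotype fitnesses $1$, $1-hs$, $1-s$) is inefficient once
$N_e s \lesssim 1$; drift then lets deleterious alleles rise in frequency
and occasionally fix. Supplementation is directional admixture: it imports
chromosomes sampled from a source population, restoring polymorphism and
diluting locally drifted-up deleterious alleles. The central observable is
the **load ratio** of a population,

$$ R = \frac{d/D}{\,P/S\,}, $$

where $d$ of the $D$ panel-wide deleterious SNPs are present in the
population (the deleterious allele having local frequency $>0$), and $P$
of the $S$ panel SNPs are locally polymorphic. $R>1$ means deleterious
variants persist locally in excess of overall polymorphism — the signature
of inefficient purging. The "present vs polymorphic" asymmetry matters: a
*fixed* deleterious allele still counts as present but no longer as
polymorphic, so strongly drifted lakes are pushed above 1 from both sides
of the fraction.

## Estimators and conventions

**Expected heterozygosity.** Per SNP, $H_E = 2p(1-p)\cdot n/(n-1)$ with
$n$ the number of genotyped diploid individuals, averaged over SNPs with at
least one call; SNPs monomorphic in the population contribute 0 but stay in
the denominator. This small-sample correction in $n$ (individuals) is the
package's fixed contract; note it differs slightly from the
allele-count correction $2n/(2n-1)$ used by some programs (for genotypes
0/1/1/2 the two give 0.667 and 0.571). Nucleotide diversity `pi` is the
mean corrected heterozygosity over locally polymorphic SNPs, divided by
`sites_per_locus`; the default 1 reports per-variant-site diversity, while
~80 (the read length behind a GBS locus) reproduces the $10^{-3}$ scale of
read-based reports.

**Differentiation.** Pairwise $F_{ST}$ is the Weir–Cockerham $\theta$:
per-locus among-population ($a$), among-individual ($b$) and
within-individual ($c$) variance components, aggregated across loci as
$\sum_\ell a_\ell / \sum_\ell (a_\ell+b_\ell+c_\ell)$ (ratio of sums, the
standard multi-locus estimator, *not* a mean of per-locus ratios).
Significance and CIs come from resampling loci with replacement (the
p-value is the fraction of replicates with $\theta \le 0$); loci are
canonicalized by SNP id before resampling so results do not depend on
column order. Negative estimates are reported as computed; clamping only
at $\pm 1$. Bootstrapping is over loci rather than individuals — the
convention of the assignment tools this mirrors — because the sampling
unit whose noise dominates multi-locus $\theta$ at these sample sizes is
the locus.

**Deleterious annotation.** Hits against a reference transcriptome are
kept at $\ge 25$ identical amino acids of 26 and $\ge 95\%$ identity —
"higher than 25 of 26" is read inclusively, since a strict reading would
leave only perfect matches and contradict the stated denominator. Codon
pairs differing at exactly one site are translated under the standard
genetic code; amino acids map to eight side-chain categories (positive,
negative, polar-uncharged, hydrophobic, cysteine, selenocysteine, glycine,
proline) and each nonsynonymous change gets a directed (`Pos->Neg`) and
undirected (`Neg:Pos`) class; stop-gains are flagged nonsense and excluded
from class ANOVAs. Effect scores below $-2.5$ are deleterious, above
neutral; exactly $-2.5$ or missing is *unclassified* and excluded from
load statistics (the analog of substitutions that cannot be attributed to
either side).

**The deleterious allele is the globally minor allele** (pooled across all
populations, ties to the alternate allele). Local frequencies of that
allele can therefore reach 1, which is what lets fixed deleterious alleles
coexist with high mean frequencies in the same summary row. The
low-frequency fraction (< 5%) is computed over deleterious SNPs *present*
in the lake.

**Group tests.** Welch's unequal-variance t is the default two-group test
(the diagnostic non-integer degrees of freedom, e.g. 8.86 for a 9-vs-15
lake split, identify it); a pooled-variance flag exists. The
population-effect MANOVA uses the long layout — one observation per locus
per population, population as the factor, Pillai trace with its F
approximation — and reduces exactly to the one-way ANOVA for a univariate
response.

## Spatially controlled ordination

Geographic coordinates (latitude, longitude, altitude) are projected to
meters by a local equirectangular projection about the centroid
($x = R\cos\varphi_0\,\Delta\lambda$, $y = R\,\Delta\varphi$,
$R = 6371$ km); at a regional survey's extent the distortion relative to
exact geodesy is negligible. The spatial basis is a distance-based Moran
eigenvector map: Euclidean 3-D distances, truncation at the longest
minimum-spanning-tree edge $t$ (so the neighbor graph stays connected),
replacement of larger distances by $4t$, Gower double-centering of
$-\tfrac12 D^2$, and retention of positive-eigenvalue axes (orthonormal,
centered, ordered by eigenvalue). On the packaged 24-lake coordinates this
yields 9 axes; `vegan::pcnm` on the same distances gives the same leading
eigenpairs, so the 16 axes reported for the original survey must reflect a
different (unstated) truncation or retention variant — the axis *count* is
therefore treated as soft, and downstream code consumes however many axes
the rule yields. On a regular transect the leading axis is a single-period
sinusoid (verified against `vegan::pcnm` to $r = 1.0000$).

Stocking intensity enters as the sink-by-source mass matrix, divided by
lake surface area (a stocking *density*), then Hellinger-transformed
($\sqrt{x_{ij}/x_{i\cdot}}$) so that shared absences of stocking carry no
similarity; all-zero rows (never-stocked lakes) stay zero. Note the
area division is absorbed by the row-relative transform — it is retained
for fidelity to the described procedure and costs nothing. A
covariance-based PCA with broken-stick retention
($b_k = \frac1p\sum_{i=k}^{p} 1/i$; longest prefix with observed
proportion above expectation) compresses the stocking profiles into a few
axes.

Responses are principal coordinates of the pairwise-$\theta$ distance
matrix (negative estimates truncated at 0; axes with $\ge 5\%$ of the
positive-eigenvalue variance kept), or broken-stick-retained PCs of the
lake-averaged Q matrix. db-RDA and partial db-RDA are multivariate least
squares through `vegan::rda`; $R^2$ is the constrained share of total
variance (semipartial for partial models), adjusted as
$1-(1-R^2)\frac{n-1}{n-m-1}$ with $m$ the predictor rank. The permutation
ANOVA permutes response rows for simple models and reduced-model residuals
for partial ones, with $p = (\text{exceedances}+1)/(n_{perm}+1)$; a model
with no residual component returns the attainable minimum
$1/(n_{perm}+1)$.

**Forward selection** tests every remaining candidate at each step and
adds the best one only if its Šidák-adjusted p-value
($1-(1-p_{\min})^k$ over the $k$ candidates examined) stays below
$\alpha$. The adjustment is deliberate: picking the minimum of $k$
permutation p-values without it selects a noise variable with probability
$\approx 1-(1-\alpha)^k$ per step, and calibration tests (type-I rate per
step $\le \alpha$; exact recovery of a planted predictor) only hold with
the correction. At $\alpha = 1$ every candidate that adds rank is still
selected.

**DAPC.** Missing dosages are imputed by the within-lake modal dosage
(ties to the lower dosage; all-missing cells fall back to the global
mode) — a deterministic, dependency-light stand-in for random-forest
imputation, biased toward the local major genotype exactly like the
forest's majority vote at these depths. Cluster number is chosen by BIC
under a spherical equal-variance Gaussian mixture on retained PCs (the
probabilistic counterpart of k-means, via mclust). Two retention/criterion
choices differ from the naive recipe, both forced by measurement: (i) a
raw k-means score $n\log(\mathrm{WSS}/n)+K\log n$ decreases monotonically
in $K$ on any multivariate data (k-means removes 12–18% of WSS per extra
cluster even on pure spherical noise), so it cannot select $K$; (ii)
retaining PCs to 90% of variance keeps hundreds of noise dimensions of a
genotype matrix and makes the mixture BIC collapse to $K=1$ even with
pronounced structure, so the auto rule is Kaiser–Guttman (above-average
eigenvalues, capped at $n/3$). With these choices a two-blob genotype
matrix yields $K=2$ and a simulated 24-deme survey yields pronounced
multi-cluster structure. LDA posteriors on the retained PCs give the
Q matrix; degenerate clusterings fall back to hard assignments.

## The synthetic-data generator

The generator exists so the whole workflow runs, and is validated, with no
external data. It emulates the survey design: 24 demes, 9 never stocked
and 15 stocked, founded from a common ancestral pool and then evolving
independently under Wright–Fisher dynamics with purifying selection on a
deleterious SNP class, plus scheduled admixture pulses into the stocked
demes.

Default conditions (chosen once, as the study conditions): 1,000 unlinked
biallelic loci in class fractions 0.60 synonymous / 0.19
nonsynonymous-neutral / 0.21 deleterious (the composition of a
transcriptome-anchored panel); founder frequencies from Beta(0.5, 2.5), a
rare-skewed approximation to a site-frequency spectrum; $s = 0.05$,
$h = 0.25$ (mildly recessive, as expected for segregating deleterious
variants); 100 generations since founding; deme sizes
$N_e = 80\sqrt{\text{area}/900\,\text{ha}}$ clamped to $[20, 500]$,
because diversity scales with lake size in such systems and the resulting
spread of drift intensities is what produces a wide pairwise-$F_{ST}$
range (0.04–0.48, mean 0.20, on generated data — matching the strong,
heterogeneous differentiation of the real survey, whose printed range is
0.01–0.50 with median polymorphism 0.64 vs 0.66 generated); 24 sampled
individuals per lake with 10% missingness; stocking masses of 10–50 kg
converted at 2 fish/kg into migrant counts, capped at half the sink's
$N_e$, applied in one pulse per sink-source pair somewhere in the second
half of the simulation.

The simulation operates at allele-frequency resolution: the deterministic
selection recursion
$q' = \left[q^2(1-s)+q(1-q)(1-hs)\right]/\bar w$ at deleterious loci,
then binomial resampling of $2N_e$ gametes, then admixture
$q \leftarrow (1-m)q + m\,\hat q_{src}$ with $m = n_{mig}/N_e$ and
$\hat q_{src}$ binomially drawn from the source — the exact
linkage-equilibrium limit of individual-based multiplicative viability
selection on unlinked loci, at a fraction of the cost. Individuals are
drawn under Hardy–Weinberg at the end. Everything derives from one seed;
identical seeds give byte-identical output files.

What the generator does *not* emulate: linkage and hitchhiking, hatchery
domestication selection, residual tetrasomy, non-equilibrium founder
spectra, and locus-specific missingness. Passing tests on generated data
therefore validate the estimators and the direction of the
stocking-versus-drift contrast, not any absolute rate in real surveys.

## Numerical choices and degenerate inputs

Thresholds are read literally: MAF strictly $> 0.05$, call rate
$\ge 50\%$, effect scores strictly below/above $-2.5$, SNP-level filters
applied in the fixed order biallelic → call rate → MAF → one-per-locus so
attrition counts are reproducible (the one-per-locus tie-break keeps the
lowest position). A SNP failing the call-rate rule in *one* population is
dropped globally — the analyses need one shared panel. Bootstrap and
permutation p-values use add-one conventions where stated. The partial-RDA
degenerate case (conditioning block spans the predictors) warns and
returns a zero semipartial $R^2$ rather than erroring, so variance
partitioning stays total. PCoA reports negative eigenvalues but excludes
them from variance proportions; no Lingoes/Cailliez correction by default.
Coincident sites in the spatial module produce a zero MST edge and a
warning suggesting jitter.

Problem sizes in the tests and drivers (e.g. 1,000-locus surveys, 200–500
permutations, 25-seed replications) were chosen as the smallest sizes at
which the checked expectations are comfortably outside sampling noise;
all scale up through the corresponding arguments.

## Known limitations

* The printed-table mode reproduces group statistics from per-lake
  columns rounded to two decimals; recomputed means can differ from
  printed ones by up to ~0.005 for that reason alone.
* The db-MEM axis count for the original survey's coordinates is not
  reproduced (9 positive axes vs 16 reported); leading eigenpairs agree
  with the reference PCNM implementation.
* The MANOVA layout treats loci as independent replicates; linked loci
  would overstate the error degrees of freedom.
* Outlier-locus detection itself (selection scans) is out of scope; the
  pipeline consumes an exclusion list and defines "neutral" as the panel
  minus that list.
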