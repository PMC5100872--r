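---
title: "Training-set construction by uniform coverage of the genetic space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-set construction by uniform coverage of the genetic space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genospace)
```

`genospace` studies one question: when a calibration panel is structured,
how should its training set be chosen so that a genomic prediction model
serves the whole panel, not just its densest corner? This vignette explains
the models and procedures the package implements, the parameters that
matter, the design choices that were genuinely open, and what the synthetic
benchmark can and cannot show.

## Dosage coding and relationship matrices

Panels are stored once, as genotype × marker allele dosages in {0, 1, 2}
with a centimorgan map (`marker_panel()`). Every relationship matrix is a
deterministic function of this one coding:

* **Identity by state.** With $G = \text{dosage}/2$ (so homozygotes score 0
  or 1 and heterozygotes 0.5) and $G_2 = 1 - G$,
  $A_{IBS} = (GG' + G_2G_2')/K$: the proportion of shared alleles. The
  formula is applied literally, which gives a heterozygous genotype a
  self-similarity of 0.5 — a documented quirk of the score coding, not a
  bug. Genetic distance everywhere in the package is $1 - \text{IBS}$.
* **Realized additive relationship.**
  $A_{ij} = \frac1K \sum_k \frac{(G_{ik}-2p_k)(G_{jk}-2p_k)}{2p_k(1-p_k)}$
  on the 0/1/2 dosages, with allele frequencies $p_k$ always taken from the
  full calibration panel passed in, never from a training subset — the
  relationship matrix is a property of the panel, computed before any
  split. Monomorphic markers are a hard error (zero denominator); filter
  first.
* **Gaussian kernel.** $A^* = \exp(-D/\theta)$ where $D$ holds squared
  Euclidean distances between dosage vectors divided by their off-diagonal
  mean. The scaling is our choice (the distance's absolute scale is
  otherwise panel-dependent): it pins the mean scaled distance at 1 so that
  the conventional bandwidth grid $\theta \in [0.05, 5]$ means the same
  thing on a 100-line panel and a 400-line panel.
* **Leave-one-chromosome-out** and **QTL-masked** kinships are the additive
  relationship recomputed on marker complements (excluding a linkage group;
  excluding ±20 cM windows around QTL).

Where a matrix inverse is needed (CD criterion, mixed-model equations) a
ridge of $10^{-8}$ is added to the diagonal at the point of inversion only;
stored matrices are never perturbed.

## Population structure

`pca_ibs()` double-centers the IBS matrix and eigendecomposes it; because
the centered IBS matrix is a Gram matrix of centered genotype scores, the
component scores reproduce IBS-derived distances exactly (Gower's
principal-coordinates property), which is what the PC scatter plots show.

Counting *significant* components is a different task with a sharper
statistical requirement. The Tracy–Widom edge test assumes exchangeable,
homoskedastic matrix entries; raw dosage columns violate this (their
variance is $p(1-p)$, varying several-fold across markers), and we found
the literal IBS spectrum anticonservative under a structureless null. The
package therefore tests the spectrum of the marker-standardized genotype
covariance (`patterson_eigenvalues()`: each marker centered and scaled by
$\sqrt{p(1-p)}$), the normalization the test was designed for, while
`pca_ibs()` remains the literal IBS PCA used for scores and variance
shares. The effective marker count entering the Tracy–Widom centering
constants is estimated from the spectrum itself by moment matching,
$n' = S_1^2 (m+1) / (m S_2 - S_1^2)$ with $S_1 = \sum \lambda_i$,
$S_2 = \sum \lambda_i^2$ — the estimator that exactly inverts the Wishart
trace identities $E[\mathrm{tr}\,W] = mn$ and
$E[\mathrm{tr}\,W^2] = mn(m+n+1)$. Eigenvalues are tested sequentially at
TW critical values 0.9793 ($\alpha = 0.05$, the default, following the
eigenanalysis convention since no level is standard for this diagnostic)
or 2.0234 ($\alpha = 0.01$), stopping at the first non-significant one;
subpopulation count = significant components + 1.

Qualitative subpopulation assignment is k-means on the first $k-1$ score
dimensions with 25 restarts under a fixed seed — deterministic,
dependency-free, and sufficient for its two uses (strata for SU/S and the
within-subpopulation ability breakdown). Differentiation is summarized by
the Weir–Cockerham $F_{st}$ in its diploid variance-components form,
aggregated as a ratio of sums over loci; for fully inbred lines the
within-individual component vanishes since observed heterozygosity is zero.

## The five samplers

**U** draws the training set by maximin elimination: sample a random
candidate, discard all remaining candidates within radius $r$ of it
(distance $1-\text{IBS}$), repeat until the pool is empty. The radius is
found by `find_radius()`: candidate radii are midpoints of the sorted
unique pairwise distances (bracketed by half the minimum and just above
the maximum — so "everyone sampled" really needs $r$ below the minimum
distance), each scored by the median yield of 20 elimination passes, and
the largest radius whose yield still reaches the target wins (bisection;
the yield is monotone in $r$). Two small edge policies are ours: if a pass
overshoots the target the chosen set is trimmed uniformly at random to the
exact size (methods are compared at fixed sizes); if a pass undershoots,
the radius is shrunk by 5% and rerun, and the radius actually used is
recorded on the split — topping up from the discard list would silently
break the min-distance invariant.

**SU** adds the stratum rule: a candidate within $r$ is discarded only if
it shares the new entry's subpopulation, so every group keeps at least one
representative. The trim preserves one genotype per stratum before random
removal, otherwise a trim could undo that guarantee.

**CD** maximizes the mean generalized coefficient of determination of the
validation contrasts $c_i = e_i - \mathbf{1}/n$ (each validation genotype
against the calibration mean):
$$CD(c) = \frac{c'\left(A - \lambda\,(Z'MZ + \lambda A^{-1})^{-1}\right)c}{c'Ac},$$
with $Z$ the training incidence, $M$ the projector orthogonal to the
intercept over training records, and $\lambda = (1-h^2)/h^2$ the
residual-to-additive variance ratio (default $h^2 = 0.85$ when no estimate
exists). At $\lambda = 0$ the criterion is identically 1; it is
non-increasing in $\lambda$. The optimizer proposes single
training↔validation exchanges, sweeping the swap neighborhood in random
order, accepting only strict improvements and restarting the sweep on each
acceptance; it stops when a complete sweep finds nothing (an exchange-local
optimum — which for a single-genotype validation set is provably the global
optimum, a property the tests exploit) or after 800 proposals, which is
ample for stability at the panel sizes used here. The contrast columns
follow the current validation set, so the mean is over exactly the
genotypes being predicted.

**S** allocates $n_{t,s} = n_t \log(n_s) / \sum_s \log(n_s)$, rounded by
largest remainder (the literature is silent on rounding; largest remainder
is exact-sum and base-invariant). The raw formula can demand more
genotypes than a stratum holds — it does for strata of 220 and 129 at
$n_t = 300$, where direct arithmetic gives (158, 142) — so at sampling time
allocations are capped at the stratum sizes and the overflow redistributed
in remainder order. Singleton strata get $\log 1 = 0$, hence nothing, under
the literal formula.

**R** is uniform sampling without replacement.

Splits are characterized by the accession-to-nearest-entry (A–NE)
distances — for each validation genotype, the minimum $1-\text{IBS}$ to any
training entry — and by the representation table: each method's mean
per-subpopulation training count as a percentage deviation from the random
baseline.

## The mixed-model engine

All four prediction models, the CD criterion and the association scan share
one REML/BLUP core. Single-kernel models are fitted spectrally: after
eigendecomposition of the record-level kernel, the restricted likelihood is
profiled down to one dimension in the variance ratio
$\delta = \sigma_e^2/\sigma_g^2$ and optimized by Brent search on the log
scale (tolerance $10^{-8}$ on the ratio; the implementation is verified in
the tests against a brute-force likelihood grid and, during development,
against an independently coded dense REML surface). Multi-kernel models use
the standard fixed-point (EM-type) iteration
$\sigma_j^2 \leftarrow \sigma_j^2\,(y'PH_jPy)/\mathrm{tr}(PH_j)$, at most
500 iterations, relative tolerance $10^{-6}$; non-convergence flags the
result rather than failing, and kernels that are numerically multiples of
the identity (or duplicated) set a degeneracy flag since their variances
cannot be separated. BLUPs for all calibration genotypes come from the
conditional expectation
$\hat g = \sum_j \sigma_j^2 K_j[\cdot,\text{train}]\,V^{-1}(y - X\hat\beta)$,
which coincides with Henderson's mixed-model equations at the same
variance components (a test asserts this to $10^{-6}$).

QTL detection is a per-marker fixed-effect Wald $\chi^2_1$ scan with a
polygenic term whose kinship excludes the tested marker's chromosome
(leave-one-chromosome-out); variance components are estimated once per
chromosome under the null and reused across that chromosome's markers —
the usual "population parameters previously determined" compromise between
exactness and cost. The genome-wide 0.01 threshold is converted to a
per-test threshold through the effective number of independent tests:
per chromosome, the marker-correlation eigenvalues contribute
$f(\lambda) = \mathbb{1}[\lambda \ge 1] + (\lambda - \lfloor\lambda\rfloor)$
(computed per chromosome and summed, because whole-genome correlation
matrices are rank-deficient); eigenvalues are rounded at $10^{-8}$ before
the floor so exact duplicates are not corrupted by floating-point noise.
The inclusive inequality matters: exactly orthogonal markers must count
fully. Significant markers are collapsed to peaks greedily (keep the
smallest p per chromosome, drop others within ±20 cM, repeat) — a
pragmatic rule chosen here, since association practice reports QTL per
linkage group without a canonical peak definition.

Model specifics: the QTL model gives each detected marker its own variance
component via a rank-one dosage kernel $x_qx_q'$, fitted jointly (the
alternative, sequential fitting, is nowhere specified; joint REML is the
cleaner reading of "their own distribution"). QGBLUP adds the ±20 cM-masked
polygenic kernel and reduces *exactly* to GBLUP when the QTL set is empty —
a nesting the tests assert to $10^{-10}$. A user-supplied forced-QTL list
can be merged in, for panels where known major loci should always be
modeled. RKHS tunes $\theta$ by 5-fold cross-validation inside the training
set (ties to the smallest $\theta$, favoring the smoother kernel;
one-point grids skip CV).

## Evaluation

Predictive ability is the Pearson correlation between observed and
predicted phenotypes over the validation set; undefined correlations
(fewer than 3 pairs, zero variance) are `NA`, never zero. Replicated
abilities are aggregated on the Fisher-z scale
($z = \tfrac12\ln\frac{1+r}{1-r}$, mean back-transformed by $\tanh$); the
standard error is reported on the z scale, where the normality assumption
lives, and the output labels the scale explicitly since conventions vary. Within-subpopulation abilities repeat the
computation per group, with groups under 3 validation members flagged
rather than estimated. `run_experiment()` crosses traits × methods ×
models × sizes, drawing realization $i$ with seed $\text{base}+i$ so any
single cell is reproducible in isolation, detecting QTL on the training
set only, and recording per-cell failures without aborting the grid.

## The synthetic benchmark: what it shows and what it cannot

`simulate_panel()` implements the Balding–Nichols model: ancestral
frequencies uniform on (0.05, 0.95), subpopulation frequencies
$\mathrm{Beta}\!\left(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\right)$, fully
homozygous lines (dosage $2\cdot\mathrm{Bernoulli}(p_s)$; a heterozygosity
option exists to exercise the 0.5-score path of the IBS formula),
panel-monomorphic markers resampled, markers placed uniformly on equal-size
chromosomes. `simulate_trait()` layers $n_{qtl}$ large-effect loci (drawn
among markers with MAF ≥ 0.1 so each QTL segregates) over a polygenic
background on all remaining markers, fixes the QTL share of genetic
variance, and sets the noise so realized $h^2 = var(g)/var(y)$ matches the
target; QTL positions, effects and genotypic values are returned as truth.

The default study conditions, chosen once to emulate a structured
diversity panel: five subpopulations of 80/60/50/35/25 lines (unequal,
Flint-maize-like composition), $F_{st} = 0.25$, 2000 markers on five
100 cM chromosomes, polygenic trait at $h^2 = 0.7$. Under these conditions
the package's diagnostics close their loops: Weir–Cockerham recovers the
divergence target within ±0.03, Tracy–Widom finds four significant
components (five subpopulations), REML recovers a variance ratio of 0.5 on
average within ±0.05, the null association scan is calibrated at the 5%
level, and a QTL carrying 30% of phenotypic variance is the top hit
essentially always.

What the generator deliberately omits is linkage disequilibrium and family
substructure: markers are exchangeable given the subpopulation, so within
a subpopulation all lines are statistically interchangeable and pairwise
distances concentrate tightly around their expectation. This has a
consequence worth stating plainly. The uniform-coverage sampler does
exactly what it promises geometrically — its nearest-entry distance
distribution is much narrower than random sampling's (the acceptance
script reports the IQR ratio, about 0.5) — but the *ability* advantage of
U/SU/CD over S/R observed on real panels rests on relatedness gradients
(families, LD blocks, subpopulations of very different diversity) that
give "being close to a training entry" predictive meaning. In an
exchangeable no-LD panel that gradient barely exists, and the measured
ability gains of U and CD over R fluctuate around zero (roughly −0.02 to
+0.04 across panel draws at training size 200 of 250). The benchmark
therefore validates the machinery (invariants, optimizer correctness,
calibration, coverage) and the direction of the coverage effect, but a
passing synthetic run should not be read as reproducing the size of the
gains reported on real maize, wheat or rice panels — nor does a small
synthetic gain impugn them. The CD criterion on such panels has an
additional, analyzable quirk: genotypes from small, strongly diverged
subpopulations have large contrast variance $c'Ac$ and hence high CD even
when predicted imprecisely, so the exchange prefers leaving them in the
validation set — the opposite allocation to U — which is faithful to the
criterion, verified against exhaustive search, and simply a property of
equal-diversity panels.

Problem sizes in the test suite were scaled for a single CPU: panels of
100–500 lines, 120–5000 markers, 15–100 realizations per property; the
acceptance script uses the full study conditions above with 100
realizations.

## Known limitations

* No LD-aware or phasing imputation: missing calls are filled per marker
  from allele frequencies (expected dosage or Bernoulli draw), the
  documented substitute for external imputation tools; adequate below a
  few percent missingness.
* The GWAS fixes chromosome-level variance components at the null fit;
  markers in strong LD with large polygenic contributions may be slightly
  mis-calibrated relative to full per-marker REML.
* Admixed, fractional subpopulation membership is out of scope: k-means
  gives hard assignments.
* Dominance and epistatic relationship matrices are not provided; RKHS is
  the package's route to non-additive signal.
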