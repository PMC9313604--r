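---
title: "Dissecting mid-parent heterosis into dominance and digenic epistasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting mid-parent heterosis into dominance and digenic epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterokit)
```

## The problem

When inbred lines from diverged pools (say temperate and tropical maize) are
crossed, the F1 hybrids routinely outperform their mid-parent value. The
quantitative-genetic question is *which* effects carry that mid-parent
heterosis (MPH): single-locus dominance, or digenic epistasis
(additive-by-additive, additive-by-dominance, dominance-by-dominance
interactions) activated by the new heterozygous background. `heterokit`
implements the full chain of analyses needed to ask this question on a
multi-hybrid panel — and a simulator that generates such panels with known
truth, so every step can be validated end to end.

## Trait model and the heterotic-effect decomposition

All genetics is biallelic and uses the F-metric parametrization: additive
covariable $u = \mathrm{code} - 1 \in \{-1, 0, 1\}$ and dominance covariable
$v = \mathbb{1}[\mathrm{code} = 1]$. The genotypic value is

$$G = \mu + \sum_i a_i u_i + \sum_i d_i v_i + \sum_{i<j} aa_{ij} u_i u_j +
\sum_{(i,j)} ad_{ij} v_i u_j + \sum_{i<j} dd_{ij} v_i v_j,$$

with $ad_{ij}$ ordered: dominance covariable at $i$, additive at $j$.

For a hybrid of two fully inbred parents, classify each locus by the
parental codes into $R_{kl}$ ($k$ = female, $l$ = male, each 0 or 2). Then
$\mathrm{MPH} = G_{F1} - (G_{P1} + G_{P2})/2$ decomposes exactly into
per-locus heterotic effects:

* a polymorphic locus ($R_{20}$ or $R_{02}$) receives its dominance effect
  $d_i$, signed half-shares $\mp\frac12 aa_{ij}$ of its aa interactions
  (negative for a partner in the same polymorphic class, positive for the
  opposite class), $+\frac12 ad_{ij}$ for additive partners in $R_{22}$ and
  $-\frac12 ad_{ij}$ for partners in $R_{00}$, and $+\frac12 dd_{ij}$ for
  polymorphic dd partners;
* a monomorphic locus ($R_{22}$/$R_{00}$) contributes only
  $\pm\frac12\sum ad$ terms with dominance at a polymorphic partner.

Each digenic effect splits half-and-half between its member loci, so
$\sum_i h_i = \mathrm{MPH}$ holds identically. This single identity pins
every sign and class rule, and `heterotic_effects()` is tested against it on
random epistatic architectures to $10^{-10}$. One sign (the $R_{00}$ branch)
is not recoverable from common renderings of the class rules; it is fixed
here as $-\frac12\sum ad$, the unique choice under which the identity holds,
verified by brute-force evaluation of genotypic values.

## Kernels for the variance partition

MPH variance is partitioned with
$y = g_d + g_{aa} + g_{ad} + g_{dd} + e$, $g_x \sim N(0, K_x\sigma^2_x)$,
$e \sim N(0, TT'\sigma^2_e)$. $T$ maps the stacked (hybrid, parent) entry
values to MPH (+1, −½, −½), so MPH inherits the correlated residual
structure $TT'$ — hybrids sharing a parent share residual error.

The kernels come from the covariables that actually carry each component of
MPH:

* dominance: $v_i$ per hybrid, $K_d = VV'$;
* dominance-by-dominance: $v_iv_j$, so $K_{dd}$ is the pairwise-coding
  kinship, computed as $\tfrac12[(VV')\circ(VV') - (V\circ V)(V\circ V)']$;
* additive-by-dominance: $v_iu_j$ with $u$ the hybrid additive coding,
  $K_{ad} = (VV')\circ(UU') - (V\circ U)(V\circ U)'$ over ordered pairs;
* additive-by-additive: here the hybrid's own $u$ is useless — a hybrid is
  heterozygous ($u=0$) exactly where its parents differ, so $u_iu_j$ lives
  on monomorphic pairs where aa cancels out of MPH. The covariable that
  carries aa into MPH is $\partial\,\mathrm{MPH}/\partial aa_{ij} =
  -m_im_j$ with $m = (\text{female} - \text{male})/2$, the *signed
  polymorphism indicator* (invariant as a product to swapping the parents).
  `mph_codings()` returns $(U, V, M)$ and `build_kinships()` uses $M$ for
  $K_{aa}$.

Two further construction choices matter numerically:

* **Self-pairs are removed** (the `exact_pairs` switch). The plain Hadamard
  square $(VV')\circ(VV')$ contains within-locus terms equal to $VV'$
  itself, i.e. a copy of the dominance kernel inside the epistatic ones,
  which measurably biases the partition toward dominance.
* **Each kernel is double-centered** ($K \leftarrow HKH$, the `center`
  switch), which is exactly equivalent to centering every *product
  covariable* across hybrids. The F-metric codings themselves are never
  centered — centering the codings before taking products discards the
  main-effect-aligned content that real epistatic covariables carry and
  badly mis-attributes epistatic signal. Uncentered kernels share a large
  common mean mass (the parametrization is deliberately non-orthogonal);
  the model's intercept absorbs that direction, and removing it from the
  kernels is what makes the four components distinguishable at all.

Kernels are normalized to unit mean diagonal. Reported genetic-variance
proportions rescale each $\sigma^2_x$ by its kernel's expected realized
variance per unit, $\overline{\mathrm{diag}\,K_x} - \overline{K_x}$, so they
are on the same scale as variance fractions of simulated components.

## Fitting: Gibbs over eigendecomposed kernels

`fit_multikernel()` pre-whitens $y$ and the kernels with $(TT')^{-1/2}$,
eigendecomposes each kernel once, and then every update is $O(n^2)$: with
orthonormal eigenvectors the conditional posterior of the factor scores is
diagonal. Variance priors are scaled-inverse-$\chi^2$ with `df0 = 5` and
scales matched to an equal split of half the sample variance across terms
(exposed in the arguments). Defaults are 10,000 iterations, 2,000 burn-in,
thinning 5; `n_chains` pools several independent chains, which stabilizes
posterior means when the kernels are strongly correlated (a random update
order is used for the same reason). A split-chain diagnostic above 1.2
triggers a warning. Whitening with $TT' = I$ is bit-identical to the
unwhitened path.

`predict_dominance_effects()` is the primal counterpart for the ∫RD weights:
a coordinate-wise Gibbs sampler for the Bayesian ridge
$y = \mu + V\beta + e$, $\beta_j \sim N(0, \sigma^2_\beta)$, whose
posterior-mean effects agree with the GBLUP backsolve from $K_d$ (tested,
$r > 0.95$); a sparser Bayes variant was considered and deliberately not
implemented — the ridge is the variant whose dual is the dominance kernel
used everywhere else.

## An identifiability limit users must know about

On panels crossed between strongly diverged pools the four kernels are
*nearly collinear*. Two mechanisms: (i) highly polymorphic crosses make the
polymorphism patterns $v$ similar across hybrids, so products of similar
base matrices correlate; (ii) with most minor alleles private to one pool,
$m_im_j \approx \pm v_iv_j$ with nearly constant sign, so
$K_{aa} \approx K_{dd}$. At a 24 × 20-parent NC II with pool divergence
$F_{ST} = 0.3$ and 1,000 SNPs we measure pairwise kernel correlations of
0.94–0.998 *after* centering and exact-pair construction. The consequence,
verified three independent ways (data drawn exactly from a single kernel are
misattributed; direct REML shows the same confusion with boundary pile-up;
longer chains move posterior means toward the misattribution, i.e. the
likelihood itself prefers it), is that single-fit component shares carry
large uncertainty, and the additive-by-dominance kernel — the one most
correlated with all others — tends to absorb mixtures. Averaged over
repeated panels the dominance and ad shares center well, while aa tends to
read low and dd high by up to ~0.15 under a 0.4/0.3/0.2/0.1 truth. Summed
epistatic shares and model *rankings* (which kernel predicts best in
cross-validation) are far more robust than the four-way split, and we
recommend interpreting real-data partitions at that resolution. This mirrors
the known strong correlation between dominance and epistatic marker kinships
in such panels.

## Two-stage trial analysis and combining ability

Stage 1 fits, per environment, entry (fixed cell means) + replicate +
incomplete block (both random, i.i.d.) by EM-REML on Henderson's equations
(`emreml()`): convergence at max relative change $<10^{-6}$ or 500
iterations; vanishing components are floored at zero after convergence; the
REML log-likelihood is non-decreasing across iterations (tested). For a
balanced complete design the adjusted means equal raw entry means exactly —
OLS equals GLS because the design span is $V$-invariant. Stage 2 combines
stage-1 values with environment random, unweighted (a deliberate
simplification; the stage-1 standard errors are returned so a weighted
variant can be layered on). The combining-ability model adds female GCA,
male GCA (a single GCA term with summed incidence when the parent sets
coincide, as in a diallel), SCA, and their environment interactions where
the layout identifies them; SCA×E requires replicates within environments.
Entry-mean heritability is
$H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/E + \sigma^2_e/(ER))$, with
the $GE$ term read as the genotype-by-environment variance (the standard
entry-mean form; the alternative reading $\sigma^2_G/E$ of an ambiguous
rendering was rejected as dimensionally senseless for an entry-mean basis).

## Distances and sweeps

Rogers' distance per pair is the mean over loci of
$\sqrt{\tfrac12\sum_j (X_{uj}-Y_{uj})^2}$ (for biallelic diploids:
$|x-y|/2$ on the 0/1/2 codes); the heterotic genetic distance ∫RD weights
each locus by the absolute predicted SNP dominance effect, rescaled to sum
to the locus count so that uniform weights reduce ∫RD to RD exactly. The
absolute value is used because a distance must be sign-free; weights should
come from `predict_dominance_effects()` fitted on the complementary folds
when the distances feed a cross-validated analysis. Windowed
Weir–Cockerham $F_{ST}$ uses the per-locus $a, b, c$ components combined by
ratio-of-sums over 1-Mb windows stepped 100 kb (half-open, 1-based starts);
windows with fewer than 3 usable loci are flagged. Nucleotide diversity per
locus is $2p(1-p)\,n/(n-1)$ on non-missing allele counts; sweep windows are
those in the joint top-5% tails of $F_{ST}$ and the diversity ratio.

## The genome-wide scan

`whiten()` builds $\Sigma = \sum_x \hat\sigma^2_x K_x + \hat\sigma^2_e TT'$
from the null-model fit and returns $y^* = \Sigma^{-1/2} y$ plus a
covariable transformer; the components are fixed once for all tests (the
population-parameters-previously-determined scheme — exact per-marker
refits cost $m^2$ REML fits and change desk-scale results negligibly).
`scan_components()` then F-tests (1 df, with intercept) every dominance
covariable and every aa ($-m_im_j$), dd ($v_iv_j$) and ad ($v_iu_j$, both
orientations) pair covariable; significance at $\alpha/n$ for dominance and
$\alpha/[n(n-1)]$ for pairs, $\alpha = 0.001$ by default with 0.05 as the
small-panel preset. Significant effects are integrated into $h_i$ by the
class rules above (the scan's aa covariable is the MPH derivative, so its
estimate is the aa effect itself, sign included). The scan is run on MPH by
default; hybrid phenotypes can be scanned instead by supplying
`build_codings()` output, in which case the aa covariable reverts to
$u_iu_j$. Step three predicts each hybrid's MPH as $\sum_i h_i$ and tests
the Pearson correlation with observed MPH against its permutation null,
$p = (1 + \#\{r_{perm} \ge r_{obs}\})/(n_{perm}+1)$; signed MPH is the
default statistic with an absolute-value variant available, and a normal
approximation to the permutation null is reported alongside for thresholds
finer than the raw permutation resolution.

## What the simulator does and does not emulate

`simulate_parents()` draws ancestral allele frequencies Uniform(0.1, 0.9)
and pool frequencies from the Balding–Nichols beta at the target
divergence; parents are fully inbred (one allele drawn and doubled).
Realized Weir–Cockerham $F_{ST}$ tracks the target within ±0.05 over
0–0.3. Architectures draw i.i.d. normal effects on the QTL and on random
epistatic pairs, then rescale each class so realized variance fractions
match the target exactly — empirical calibration, because epistatic
variance depends on realized genotype frequencies; calibration can be on
genotypic values or on MPH (`scale = "mph"`, which requires a zero additive
fraction since additive effects cancel in MPH). Phenotypes add environment,
replicate, incomplete-block and plot noise calibrated to a plot-level
heritability; noise splits 15/15/70 across replicate/block/residual with
environment variance at half the noise variance — at $h^2 = 1$ phenotypes
equal genotypic values exactly. Everything re-runs bit-identically under a
fixed seed via a deterministic sub-seed registry.

Not emulated: linkage and recombination (parents are drawn, not bred),
selection history, multi-allelic loci, genotyping error, spatial field
trend. Passing tests therefore certify the statistical machinery on
exchangeable-locus panels, not robustness to linkage disequilibrium decay
patterns or assay artifacts of real chips.

## Problem sizes and numerical choices

The test suite exercises the study-scale design at 24 × 20 parents
(480 hybrids, 1,000 SNPs) for the variance partition (10 panels, two pooled
chains of 5,000 iterations), 400 hybrids × 200 markers for scan error
control (200 null scans; power at 50 seeds), 16 × 15 parents for
cross-validated kernel ranking, and 1,000 replicates for permutation
uniformity; smaller toys cover the exact identities. Degenerate inputs are
handled explicitly: monomorphic loci are kept by the simulator and dropped
by QC or skipped as constant covariables; zero-variance predictions give
permutation $p = 1$ by convention; a non-PD whitening matrix gets a 1e-8
ridge with a message; kernels with no heterozygosity error out. LD pruning
removes the lower-MAF member of the worst offending pair first (ties: the
later position), which makes the survivor set well-defined and idempotent.
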