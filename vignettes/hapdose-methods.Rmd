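---
title: "Decomposing imputation quality metrics: models and methods"
author: "hapdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing imputation quality metrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapdose)
```

## The problem

Genotype imputation infers untyped variants in a target sample from a phased
reference haplotype panel.  Two families of quality metrics are in routine
use.  The *empirical* accuracy — dosage $r^2$, here called EmpRsq — is the
squared Pearson correlation between the imputed dosage and the true
genotype, and requires external truth (sequencing data, or a leave-one-out
re-imputation of array markers).  The *model-based* score Rsq requires no
truth: it is the ratio of the observed variance of the imputed dosages to
the binomial variance $p(1-p)$ expected under Hardy–Weinberg at the
alternative allele frequency $p$ of the imputed data.  The two are routinely
treated as interchangeable, but they measure different things: Rsq measures
how *certain* the dosages are (how close to 0 and 1 at the haploid level),
EmpRsq how *correct* they are.  Confidently wrong dosages inflate Rsq while
depressing EmpRsq.  hapdose exists to quantify that gap, to reproduce the
mechanism that creates it inside the imputation model itself, and to let
users run the same diagnostics on their own VCFs.

## The decomposition

Write $y = (y_1, \dots, y_n)$ for the imputed allelic dosages
($y_i \in [0,1]$ at the haploid level) and $x = (x_1, \dots, x_n)$ for the
true alleles ($x_i \in \{0,1\}$), and regress $y = \beta_0 + x\,\beta + e$.
All variances here are population variances (divisor $n$), so the sums of
squares satisfy $SS_{tot} = n\,\mathrm{Var}(y)$ exactly; this choice is what
makes the identities below exact rather than approximate.  With

$$\mathrm{EmpRsq} = \frac{\mathrm{Cov}(x,y)^2}{\mathrm{Var}(x)\mathrm{Var}(y)}
  = \frac{SS_{reg}}{SS_{tot}}, \qquad
  \mathrm{Rsq} = \frac{\mathrm{Var}(y)}{p(1-p)} = \frac{SS_{tot}/n}{p(1-p)},$$

splitting $SS_{tot} = SS_{reg} + SS_{res}$ gives an exact two-part
decomposition of Rsq.  The residual part is the
**MAF-adjusted residual error**

$$\mathrm{MARE} = \frac{SS_{res}/n}{p(1-p)} = (1 - \mathrm{EmpRsq})\,
  \mathrm{Rsq},$$

and the regression part defines

$$\beta_{imp} = \sqrt{\mathrm{EmpRsq} \times \mathrm{Rsq}},$$

which equals the raw regression slope $\mathrm{Cov}(x,y)/\mathrm{Var}(x)$
exactly when the truth variance matches the binomial variance at the dosage
AAF ($\mathrm{Var}(x) = p(1-p)$), i.e. when the allele frequencies of truth
and dosages agree.  Any two of (Rsq, EmpRsq, MARE, $\beta_{imp}$) determine
the other two; a variant's position in the (EmpRsq, Rsq) plane, read
against the theoretical MARE and $\beta_{imp}$ surfaces
(`theoretical_surfaces()`), reveals the shape of its dosage distribution:
high MARE means confident-but-wrong dosages, low $\beta_{imp}$ means
dosages shrunk toward the allele frequency.

Conventions and edge cases:

* `decompose_metrics()` computes $p$ from the imputed dosages by default
  (that is how Rsq is defined in imputation info files); an override allows
  truth-based frequencies for sensitivity checks.
* Monomorphic truth or dosages make EmpRsq (and, for $p \in \{0,1\}$, Rsq)
  undefined.  These are returned as `NA` with machine-readable flags
  (`monomorphic_true`, `monomorphic_imputed`), never dropped silently;
  summaries exclude flagged records and keep their counts.
* A negative truth–dosage correlation would make the slope negative while
  the squared correlation hides the sign.  $\beta_{imp}$ only makes sense
  on the nonnegative branch, so such records carry a `negative_slope` flag
  and a missing $\beta_{imp}$.
* Diploid data use $\mathrm{Rsq} = \mathrm{Var}(DS)/(2p(1-p))$ and EmpRsq
  as the squared correlation of DS with the genotype dose in $\{0,1,2\}$;
  MARE and $\beta_{imp}$ follow unchanged.  The haploid-to-diploid change
  only rescales the binomial variance, which is the natural reading when
  the per-haplotype dosages of an individual are exchangeable.  Dosage
  $r^2$ computed from unphased diploid data can differ slightly from the
  haploid EmpRsq; the package computes both levels when haploid dosages
  are available and leaves the choice to the user.

## The haplotype-copying model

The imputation engine is a minimal Li–Stephens hidden Markov model.  The
hidden state at marker $m$ is which of the $H$ panel haplotypes the target
is copying.  Between adjacent markers the chain jumps with probability
$\theta_m$ (the *template switching rate* of that interval), landing
uniformly on all $H$ templates including the current one — the standard
uniform-jump kernel, so the stay probability is $(1-\theta) + \theta/H$.
At a typed marker the observed target allele matches the copied template
with probability $1 - \varepsilon_m$ and mismatches with probability
$\varepsilon_m$ (the *error rate*: genotyping error, gene conversion,
recurrent mutation).  Untyped markers emit nothing.  The haploid dosage is
the posterior-weighted mean of the panel alleles,
$\mathrm{HDS}(m) = \sum_h P(\text{copy } h \mid \text{data})\,A_{mh}$.

Numerical contract: the forward and backward recursions are rescaled at
every marker, so likelihoods never underflow even for $10^5$ markers;
posteriors are renormalized per marker; dosages are clamped to $[0,1]$
against floating-point drift.  $\theta$ is clamped to
$(10^{-10}, 1-10^{-10})$ and $\varepsilon$ to $(10^{-6}, 0.49)$ so the
kernel stays nondegenerate.  The default $\varepsilon$ when none is
estimated is $10^{-3}$ per marker: emission must be nondegenerate, and the
scientific focus of the package is $\theta$.  Targets are haploid
(pre-phased); diploid individuals are two haplotype columns paired
downstream by `diploid_dosage()`.  Missing target genotypes at typed
markers are treated as untyped at that site.  A single region is bounded at
roughly $10^5$ markers $\times$ $10^3$ haplotypes; larger inputs are
rejected rather than silently chunked.

Leave-one-out dosages (`loo_dosage()`) are computed in one pass: the
posterior at a typed marker with its own emission removed is proportional
to the pre-emission forward vector times the backward vector, which equals
a full re-run with only that marker hidden (the test suite asserts this
equivalence marker by marker).  This is the standard way to score
imputation at array sites without external truth.

Why this shapes Rsq but not EmpRsq: a small $\theta$ makes the chain
persist on single templates, concentrating the posterior and pushing HDS
toward 0/1 — higher variance, higher Rsq, more "confident alleles"
(HDS $> 0.9$) — without adding information about the true allele.  A large
$\theta$ forgets the scaffold and shrinks HDS toward the panel allele
frequency — lower Rsq — while the ranking of dosages, and hence the
correlation with truth, degrades far more slowly.  `scale_theta()` plus
`run_theta_scaling()` reproduce exactly this experiment on synthetic data.

## Parameter estimation

`estimate_hmm_params()` is a leave-one-haplotype-out Baum–Welch estimator:
each panel haplotype in turn is treated as a fully typed target against the
remaining panel; the E-step accumulates posterior template-jump
probabilities per interval (jump events include landing back on the same
template, matching the kernel above) and posterior mismatch probabilities
per marker; the M-step divides by the number of held-out sweeps.  The
pooled held-out log-likelihood is a proper EM objective, hence
non-decreasing over iterations (asserted with $10^{-8}$ slack).
Initialization is fixed ($\theta = 0.01$, $\varepsilon = 10^{-3}$
uniformly) so runs are reproducible; convergence is declared when the
largest relative parameter change drops below $10^{-4}$, capped at 20
iterations.  $\varepsilon$ is estimated jointly with $\theta$, with a
$10^{-6}$ floor — whether production imputation tools estimate or fix it
is not documented, and joint estimation with a floor degrades gracefully
to the fixed-$\varepsilon$ behavior when the panel is clean.  A `pooled`
mode fits one shared $\theta$ for small panels where per-interval
estimates are noisy; the mode is recorded on the returned object.  A panel
of identical haplotypes carries no information about switching: it is
returned floor-clamped with a `degenerate` flag instead of being fitted.

`total_theta()` sums the per-interval rates over a region — a one-number
summary of panel haplotype dissimilarity.  Absolute totals are estimator-
and data-specific and are not comparable across implementations; the
package's claims about them are directional (they fall with single-ancestry
panel size, rise with ancestral diversity at fixed size), and those are the
properties the acceptance checks assert.

`theta_from_genetic_map()` applies the fixed transform used by
genetic-map-driven pipelines: 0.01 cM corresponds to a 1% switching rate,
i.e. $\theta$ equals the centimorgan distance numerically, clamped into the
open unit interval.  Marker positions off the map grid are interpolated
linearly; positions beyond the map ends are extrapolated with the terminal
segment's rate and logged.

## The panel simulator

`build_panel()` generates everything the other modules need, with no
external data: ancestral allele frequencies drawn uniformly from
$[0.02, 0.98]$; per-ancestry frequencies diverged under the
Balding–Nichols model ($\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, so
$E[q]=p$ and $\mathrm{Var}[q]=F\,p(1-p)$); founder haplotypes drawn
independently per marker; and panel/target haplotypes built as founder
mosaics whose copying index switches between adjacent markers with a fixed
probability.  The mosaic structure is what creates linkage disequilibrium,
and the founder switch rate is therefore the simulator-side analogue of
$\theta$.  In the simulator a switch moves to a *different* founder
(uniform over the others), so the observed founder-switch count is exactly
binomial and testable; the HMM kernel keeps the jump-including-self
convention because that is how the imputation model is parameterized.
`simulate_targets_ls()` additionally draws targets from the copying process
over the panel itself — the generative model the engine assumes — which is
the clean way to test calibration: when targets come from the imputation
model, posterior dosages are well calibrated and mean Rsq matches mean
EmpRsq (the acceptance suite checks the gap is below 0.05).

The **standard synthetic benchmark** used across modules is fixed once:
two ancestries at $F_{ST} = 0.1$, 150 + 150 panel haplotypes from 20
founders each, 1000 markers, founder-mosaic copy rate 0.02, mutation rate
$10^{-3}$, 30 + 30 held-out targets, a 25% typed-marker array mask, seed
20240113.  These sizes are desk-scale stand-ins for the real setting
(thousands of reference haplotypes, $\sim 10^4$ array markers per
chromosome arm): large enough for stable means over a few hundred
variants, small enough that the full fold sweep runs in well under a
minute.  The array mask always types both endpoint markers, so untyped
sites are interpolations between scaffold markers, matching how genotyping
arrays bracket imputed regions.  Trend experiments (panel size, diversity)
use 300-marker panels — total-$\theta$ ordering stabilizes with far fewer
markers than metric means do.

What the simulator does **not** model: demographic history (growth,
admixture dating), phasing error, sequencing error, indels, multiallelic
sites, and realistic allele-frequency spectra (no excess of rare
variants).  Passing tests on this scene therefore demonstrate the internal
mechanism — switch rate shapes certainty and Rsq, not accuracy — and the
correctness of the estimators, not the absolute metric levels of any real
panel.

## Experiment drivers and summaries

`run_theta_scaling()` scales $\theta$ by each fold (default
$\{0.01, 0.1, 0.5, 1, 2, 10, 100\}$; `theta_fold_grid()` gives a 21-point
log-spaced grid), imputes all targets, and evaluates two surfaces: the
leave-one-out dosages at typed markers (the default, truth-free surface)
and the ordinary imputed dosages at untyped markers against the held-out
truth.  Summary means for each fold cover that fold's unflagged records —
the same convention used when summarizing real imputation runs — rather
than an intersection across folds: at extreme upscaling most records
become monomorphic-dosage or negative-slope, and conditioning every fold's
mean on surviving fold 100 would bias the comparison toward common,
easy variants.  Flagged records stay in the per-variant tables with their
flags.

Threshold counts use strict inequalities exactly as conventionally
printed: confident alleles are HDS $> 0.9$, high-Rsq variants Rsq $> 0.7$,
and the pre-analysis filter Rsq $< 0.3$ is the `threshold = 0.3` override.
The deviation is always reported as Rsq $-$ EmpRsq.
`bin_and_bootstrap()` resamples variants (not samples) within bins of
width 0.05 on either the EmpRsq or the Rsq axis — published analyses use
dosage-$r^2$ bins for the deviation and Rsq bins for MARE, so both axes
are supported and the caller chooses.

`run_panel_composition()` builds a panel per scenario, estimates
parameters by EM, records total $\theta$, imputes the scenario's targets,
and splits counts by ancestry-specific variants (alternate allele carried
by exactly one ancestry block).  Replicates of the trend experiments
redraw the panel with fresh seeds: the EM estimator is exactly invariant
to sample order, so literal order-shuffling (the protocol used with
order-sensitive estimators) would produce ten identical numbers; fresh
draws put the replicate variability where it actually lives, in the panel
realization.  All drivers are deterministic given their seeds, and every
random quantity in the package flows through an explicit seed argument.

## Known limitations

* No state-space compression, windowing, or multithreading: the engine is
  meant for method-level experiments and desk-scale regions, not
  biobank-scale production imputation.
* The EM surrogate reproduces the qualitative size/diversity dependence of
  switch-rate estimates, not any production tool's absolute values; its
  per-mismatch $\varepsilon$ estimates absorb model misfit as well as
  genotype error.
* Biallelic SNVs only, with strict input validation; unphased or
  multiallelic records are rejected with the offending position named
  rather than coerced.
* The negative-correlation branch of $\beta_{imp}$ is deliberately not
  defined; such variants are flagged for inspection instead.
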