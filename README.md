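# hapdose

Genotype imputation pipelines report two kinds of quality scores for every
variant: the model-based **Rsq** (the ratio of the imputed-dosage variance
to the binomial variance *p*(1 − *p*) at the imputed allele frequency,
computable without any truth data) and the empirical **dosage r²**
(**EmpRsq**, the squared Pearson correlation between imputed dosage and
true genotype).  They are widely treated as interchangeable, but Rsq
measures how *certain* the dosages are while EmpRsq measures how *correct*
they are — and the certainty is set largely by one knob of the underlying
Li–Stephens haplotype-copying HMM, the template switching rate θ.  When θ
is small relative to the true panel–target relatedness (the typical
situation for an under-represented ancestry inside a large multi-ancestry
reference panel), dosages are pushed toward 0/1, Rsq inflates, and more
variants pass Rsq filters, without any gain in actual accuracy.

`hapdose` is an R package for studying and diagnosing this mechanism:

- **Exact decomposition of Rsq.**  Writing the regression of dosage on
  truth as `y = β₀ + x·β + e`, Rsq splits exactly into
  `Rsq = EmpRsq·Rsq + MARE` with `MARE = (1 − EmpRsq)·Rsq` (the
  MAF-adjusted residual error: large when dosages are confidently wrong)
  and `β_imp = √(EmpRsq·Rsq)` (the slope-like component: small when
  dosages are shrunk toward the allele frequency).  Any two of the four
  metrics determine the other two
  (`decompose_metrics()`, `theoretical_surfaces()`).
- **A minimal Li–Stephens imputation engine** with explicit per-interval
  switching rates θ and per-marker error rates ε, haploid dosages (HDS),
  single-pass leave-one-out dosages at typed markers, and manual θ scaling
  (`ls_impute()`, `loo_dosage()`, `scale_theta()`; compiled forward–backward
  core).
- **Parameter estimation**: leave-one-haplotype-out Baum–Welch over a
  panel (`estimate_hmm_params()`, `total_theta()`) and the fixed
  genetic-map transform 0.01 cM = 1% switching rate
  (`theta_from_genetic_map()`).
- **A multi-ancestry panel simulator** (Balding–Nichols divergence +
  founder-mosaic LD) so every claim is testable without external data
  (`build_panel()`, `standard_benchmark_spec()`).
- **Experiment drivers** for θ-scaling sweeps and panel-composition
  scenarios, with MAF-stratified summaries, confident-allele (HDS > 0.9)
  and high-Rsq (Rsq > 0.7) counts, and binned bootstrap CIs of
  Rsq − EmpRsq (`run_theta_scaling()`, `run_panel_composition()`,
  `bin_and_bootstrap()`).
- **Strict VCF I/O** for phased panels and `GT:DS:HDS` dosage output
  (`read_panel()`, `write_dosages()`, `write_info_table()`), plus a thin
  command-line front end (`inst/cli/hapdose.R`) with subcommands
  `decompose`, `impute`, `loo`, `estimate-theta`, `map-theta`,
  `simulate-panel`, `exp-theta-scaling`, `exp-composition`.

## Worked example

Decompose one variant (4 haplotypes, truth `0,0,1,1`, dosages
`0.1,0.2,0.8,0.9`):

```r
library(hapdose)
decompose_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
#>   aaf rsq emprsq mare beta_imp slope n flags
#> 1 0.5 0.5   0.98 0.01      0.7   0.7 4    ok
```

Var(y) = 0.125 against the binomial 0.25 gives Rsq = 0.5 — the dosages are
under-dispersed (shrunk toward 0.5) — while the correlation with truth is
nearly perfect (EmpRsq = 0.98); the residual component MARE = 0.01 is tiny
and β_imp = 0.7 quantifies the shrinkage of the group means.

Now the mechanism, end to end on the built-in synthetic benchmark: build a
two-ancestry panel, estimate θ by EM, then re-impute with θ scaled down and
up, scoring leave-one-out dosages at the typed (array) markers:

```r
sim  <- build_panel(standard_benchmark_spec())
mask <- mask_array(1000, typed_fraction = 0.25, seed = 20240113)
est  <- estimate_hmm_params(sim$panel, max_iter = 10)
est
#> <hmm_params> 999 intervals (provenance: estimated)
#>   total theta 22.78, mean epsilon 0.00127

res <- run_theta_scaling(sim$panel, sim$targets, mask, est,
                         folds = c(0.1, 1, 10))
subset(res$summary, surface == "loo_typed" & bin == "all",
       c(fold, n, mean_rsq, mean_emprsq, mean_dev))
#>  fold   n   mean_rsq mean_emprsq    mean_dev
#>   0.1 224 0.67729327   0.5159988  0.16129450
#>   1.0 224 0.52236022   0.5441745 -0.02181423
#>  10.0 219 0.02440997   0.1626323 -0.13822235
res$counts
#>  fold confident_alleles high_rsq
#>   0.1             24162      512
#>   1.0             21902      110
#>  10.0             11874        0
```

Scaling θ down by 10× inflates mean Rsq from 0.52 to 0.68 and multiplies
the count of Rsq > 0.7 variants almost fivefold, while the empirical
accuracy barely moves (0.54 → 0.52): the extra "quality" is pure certainty,
and the deviation Rsq − EmpRsq flips from −0.02 to +0.16.  Scaling θ up
shrinks dosages toward the panel mean and collapses Rsq far faster than
EmpRsq.

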