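# mrewas

Mendelian randomization for epigenome-wide association: estimate the
**causal** effect of red-blood-cell (RBC) folate on cord-blood DNA
methylation, locus by locus, using MTHFR genetic variants as an
instrument — with the full supporting pipeline (synthetic data
generation, methylation preprocessing, genotype QC, a genome-wide 2SLS
scan with bootstrap confidence intervals, a confounding simulation study,
and gene-set enrichment).

## The scientific problem

Observed folate–methylation associations are confounded: everything that
shapes maternal diet can also shape the infant epigenome. Two MTHFR
variants (C677T, A1298C) reduce enzyme activity and shift RBC folate,
are fixed at conception, and have no assumed direct pathway to
locus-specific methylation — so their additive allele count is an
instrumental variable. Per CpG locus the model is

```
A_i = α₀ + α₁ Z_i + α₂ C_i + α_c u_i + e_x,i        (first stage)
y_i = β₀ + β₁ A_i + β₂ C_i + β_c u_i + e_y,i        (outcome)
```

with `A` log RBC folate, `Z ∈ {0,1,2}` the variant count (valid because
the variants sit on opposite haplotypes), `C` an observed covariate
(planned conception), `u` an unmeasured confounder, and `y` methylation
on the arcsine square-root scale `y = asin(√β)`, `β = M/(M+U+100)`.
Ordinary least squares (OLS) of `y` on `A` is biased whenever
`α_c β_c ≠ 0`; two-stage least squares (2SLS) is consistent for the
causal effect `β₁` and equals the Wald ratio in this just-identified
case. Standard errors use the conventional 2SLS correction
(second-stage residuals recomputed from the observed exposure).

## Worked example

Generate a 50-subject cohort with a planted causal effect at four loci,
preprocess, run QC, scan, and inspect the top locus:

```r
library(mrewas)

ch <- gen_cohort(cohort_spec(n = 50, alpha1 = 0.4, sigma_x = 0.25, seed = 9))
pp <- gen_probe_panel(200, frac_sex = 0.1, frac_cross_reactive = 0.05,
                      frac_missing = 0.03, seed = 9)
b1 <- rep(0, 200); b1[51:54] <- 0.5    # four causal loci
prof <- effect_profile(200, beta1 = b1, sigma_y = 0.05,
                       mean_exposure = mean(ch$cohort$log_rbc_folate))
pan <- gen_methylation(ch$cohort, ch$confounder, prof, pp$annotations,
                       seed = 9, missing_probes = pp$missing_probes,
                       nonnormal_probes = pp$annotations$probe_id[190:194])

pre <- preprocess_panel(pan, alpha = 0.05)
pre$report
#> Probe filter report
#>   input                           200
#>   after_autosome_restriction      180
#>   after_cross_reactive_removal    170
#>   after_complete_case             164
#>   after_normality_filter          151

qc_report(ch$cohort)
#> Instrument QC report
#> ...
#> Codominant vs additive: F = 3.827 (1, 46 df), p = 0.05651
#> First-stage instrument strength: F = 71.431 (1, 47 df), p = 5.439e-11

sc <- genomewide_scan(pre$y, ch$cohort, alpha = 0.05, betas = pre$betas,
                      bootstrap_reps = 200, seed = 9)
sc
#> MR scan of 151 loci, n = 50 subjects
#>   significant at alpha = 0.05 (unadjusted): 7
#>   first-stage F = 71.431
#> 2SLS vs OLS estimates: r = 0.987 (R^2 = 0.975), p = 1.03e-120
#>   2SLS range: [-0.064, 0.549]; OLS range: [-0.038, 0.537]
#>   top-10 overlap: 6 loci

top <- rank_loci(sc$results)$probe_id[1]   # "cg00000052", a planted locus
d <- data.frame(meth = pre$y[top, ], folate = ch$cohort$log_rbc_folate,
                variants = ch$cohort$variant_count,
                planned = ch$cohort$conception_planned)
summary(tsls(meth ~ folate + planned | variants + planned, data = d))
#> Two-stage least squares
#> ...
#>             Estimate Std. Error t value Pr(>|t|)
#> (Intercept) -2.93185    0.15428 -19.003   <2e-16 ***
#> folate       0.53183    0.02214  24.022   <2e-16 ***
#> planned     -0.01988    0.01395  -1.425    0.161
#>
#> Residual standard error: 0.04854 on 47 degrees of freedom
#> First-stage (instrument strength) F = 71.431 on 1 and 47 DF, p = 5.439e-11
```

The planted effect (0.5) is recovered at 0.532 ± 0.022.

Other entry points:

* `run_confounding_sim()` / `confounding_sweep()` — the MR-vs-OLS
  simulation study (MR: smaller median bias, wider spread).
* `bootstrap_delta_beta()` — percentile bootstrap CIs on the raw
  β-value scale.
* `enrich()` / `nearest_gene_assignment()` — hypergeometric gene-set
  enrichment of significant loci.
* `run_pipeline(read_run_config("config.yaml"))` or the CLI wrapper
  `inst/scripts/mrewas.R` — the end-to-end pipeline with file outputs
  and a manifest.

See the methods vignette
(`vignettes/mendelian-randomization-methylation.Rmd`) for the model,
assumptions, generator calibration and limitations.

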