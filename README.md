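# sgwas — spatial-kernel mixed-model GWAS

`sgwas` is an R package for genome-wide association testing of traits that
are strongly shaped by brain activity, written for imaging-genetics studies
that have per-sample regional brain measurements (imaging-derived
phenotypes, IDPs) alongside genotypes. Instead of leaving individual brain
structure in the residual, it turns each individual's regional profile into
a spatial-interaction kernel pattern, uses the cross-individual Pearson
similarity of those patterns as the covariance of a GLMM random effect, and
score-tests every variant inside that model:

    g(E[Y | b]) = X a + G beta + b(S),     b(S) ~ MVN(0, tau * V(S))

where `V(S)[i, j] = corr(R_s(i), R_s(j))` and
`R_s(i) = { exp(-||s_k(i) - s_l(i)||^2 / 2 sigma^2) : k < l }` is the
individual's Gaussian-RBF kernel profile over ROI pairs. The null model is
fitted once by penalized quasi-likelihood with average-information REML;
each SNP then costs one score test (`U = g'Pz`, `Var(U) = g'Pg`,
chi-square on 1 df).

Around the core test the package provides the full study pipeline:

* fixed- and random-effects (DerSimonian–Laird) meta-analysis across
  studies with Cochran's Q and allele harmonization
  (`harmonize_studies()`, `meta_analyze()`);
* GCTA-style GRM construction and AI-REML SNP heritability with
  boundary-corrected significance tests (`compute_grm()`, `estimate_h2()`,
  `h2_scan()`);
* two-sample Mendelian randomization: IVW estimate, Cochran's Q, and
  leave-one-out sensitivity analysis (`mr_analyze()`);
* PLINK bed/bim/fam and VCF readers, MAF / exact-HWE / missingness QC
  (`read_genotypes()`, `qc_filter()`);
* a simulation module reproducing the reference benchmark design
  (`simulate_cohort()`, `benchmark_auc()`), and a CLI
  (`inst/cli/sgwas.R`) covering `simulate`, `kernel`, `assoc`, `meta`,
  `h2`, `mr` and `benchmark` subcommands.

See `vignettes/spatial-kernel-gwas.Rmd` for the models, defaults and design
decisions.

## Worked example

Simulate a cohort in which causal SNPs carry 30% of the phenotypic variance
and a kernel-structured brain effect most of the rest, then run the spatial
association scan:

```r
library(sgwas)

cfg <- sim_config(n_samples = 400, n_snps = 50, n_causal = 10,
                  total_snp_effect = 0.3, n_rois = 40, seed = 42)
cohort <- simulate_cohort(cfg)

X <- cbind(`(Intercept)` = 1, cohort$covariates)
assoc <- run_assoc(cohort$genotypes, cohort$phenotype, X, cohort$similarity)

attr(assoc, "null_fit")
#> Null spatial GLMM (gaussian family)
#>   n = 400 ; tau = 0.2991 ; phi = 0.61
#>   converged: TRUE in 2 PQL iterations

head(assoc[order(assoc$P), c("id", "AF", "BETA", "SE", "P")], 5)
#>      id    AF   BETA     SE        P
#>  snp020 0.274  0.568 0.0703 6.62e-16
#>  snp013 0.487  0.481 0.0669 6.55e-13
#>  snp021 0.422 -0.349 0.0637 4.30e-08
#>  snp002 0.455  0.348 0.0644 6.39e-08
#>  snp050 0.343  0.280 0.0667 2.73e-05
```

The null fit recovers the planted variance split (`tau = 0.30` against a
true brain share of `0.5 * (1 - 0.3) = 0.35`, the rest in `phi`). Ranking
SNPs by `-log10(P)` recovers the 10 planted causal variants almost
perfectly here:

```r
ord <- match(assoc$id, cohort$genotypes$variants$id)
auc_score(cohort$causal_mask[ord], -log10(assoc$P))
#> [1] 0.98
```

`lambda_GC` on this scan is 1.7 — inflated, as it should be when 20% of
tested SNPs are truly causal; on null cohorts (`total_snp_effect = 0`) it
sits at 1.0, which is what the calibration tests check.

Meta-analysis follows the textbook arithmetic; e.g. two studies with
effects 0.1 and 0.3 and standard errors 0.1 and 0.2 combine to:

```r
fixed_effect_meta(c(0.1, 0.3), c(0.1, 0.2))[c("beta", "var")]
#> $beta  0.14
#> $var   0.008
```

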