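# pearcrc

Genetic and epigenetic association analysis of the *PEAR1* locus with
incident colorectal cancer in family-based cohorts.

## The problem

Platelet endothelial aggregation receptor 1 (*PEAR1*) modulates platelet
activation and angiogenesis, both implicated in colorectal carcinogenesis.
Testing whether variation at this locus is associated with incident
colorectal cancer in a family-based population cohort raises four
methodological problems that this package solves as one reusable, tested
pipeline:

1. **Genotype statistics in pedigree data** — allele/genotype frequencies,
   an exact Hardy-Weinberg test restricted to unrelated founders, and a
   data-driven decision on pooling minor-allele homozygotes (TT) with
   heterozygotes (TG) into a single carrier group.
2. **Family-clustered survival association** — a Cox proportional-hazards
   fit of time to cancer on carrier status and nine covariates, with
   pedigree-cluster-robust sandwich standard errors, a Kolmogorov-type
   supremum diagnostic for proportionality, and (adjusted) cumulative
   incidence curves. The partial likelihood for carrier status is

   L(β) = ∏ᵢ:δᵢ₌₁ exp(βᵀxᵢ) / Σⱼ∈R(tᵢ) exp(βᵀxⱼ),

   maximized by Newton-Raphson, with the sandwich covariance
   A⁻¹(Σ_g U_g U_gᵀ)A⁻¹ built from score residuals U summed within
   pedigree g.
3. **Resampling defenses** — a carrier-label permutation null (how often
   does a random pseudo-carrier set reach the observed significance?) and
   a case-exclusion bootstrap (does the association survive deleting 2-9
   of the ~49 cancer cases?).
4. **Promoter methylation discovery** — for 16 CpG sites measured in a
   subset: duplicate-assay QC, rank inverse-normal transformation (Blom),
   PLS discriminant analysis against a covariate-standardized case
   outcome, factor-count selection by leave-one-out PRESS with the
   van der Voet T² randomization test, Wold VIP scores
   (VIPⱼ = √(p·Σ_a SS_a (w_{ja}/‖w_a‖)² / Σ_a SS_a), threshold 1.1), and a
   V-plot quadrant classification of risk-associated sites.

Because the original cohort data are private, the package ships a
synthetic cohort generator (`simulate_cohort()`) that emulates the
published study structure — 2532 participants in 439 singletons plus 278
families, minor-allele frequency 9.6% with Mendelian transmission, the
published covariate moments, ~49 events over a median ~18 years of
follow-up, and a 929 × 16 methylation submatrix with two latent factors
and planted case effects at sites 2/13 (protective) and 11/12
(deleterious). Every estimator in the package is validated by recovering
what the generator plants.

## Worked example

```r
library(pearcrc)

sim <- simulate_cohort(generator_config(seed = 20))
sim
#> Simulated cohort: n = 2532, 52 events, 493 carriers (19.5%)
#>   methylation subset: 929 subjects, 16 cases

gs <- genotype_summary(sim$cohort, founders_only = TRUE)
gs$counts; gs$frequencies; gs$hwe_p; gs$pooling
#> Genotype counts: TT = 29  TG = 464  GG = 2039  (n = 2532)
#> MAF 0.1031 (carriers 493/2532 = 19.5%)
#> HWE exact p (founders) = 0.12
#> TT vs TG: p = 0.978 (unadjusted), 0.694 (sex/age-adjusted) -> pool carriers

fit <- fit_cox(sim$cohort, terms = primary_terms(), cluster_by = "pedigree_id")
carrier_hr_report(fit)$formatted
#> "2.08 (1.18-3.67; p=0.012)"
supremum_ph_test(fit, n_replications = 1000, seed = 20)$p[["carrier"]]
#> 0.92

m <- sim$methylation
covs <- data.frame(time_interval_y = m$time_interval_y,
                   sim$cohort[match(m$ids, sim$cohort$id),
                              c("sex", "age_y", "bmi", "chol_ratio",
                                "creat_umol_l", "smoker", "drinker",
                                "antiplatelet")])
plsda_analysis(m$methylation, m$case, covs, seed = 20)
#> PLS-DA on 929 subjects (0 excluded for missingness)
#>   selected 2 factor(s); X-variance explained: 26.6%, 15.1%
#>   sites above VIP threshold:
#>  site      vip corr_rescaled    quadrant
#>     2 1.340318     -1.605021  lower-risk
#>    11 1.238256      1.477120 higher-risk
#>    12 1.580956      1.986976 higher-risk
#>    13 1.791634     -2.322048  lower-risk
```

Reading the output: the cohort draw carries a true carrier hazard ratio of
2.17; the clustered multivariable fit estimates 2.08 (95% CI 1.18-3.67)
with no evidence against proportional hazards (supremum p = 0.92). The
founder genotypes are compatible with Hardy-Weinberg equilibrium, and the
TT/TG pooling check keeps the carrier model. The methylation stage selects
the two generating latent factors and flags exactly the four planted CpG
sites in the correct V-plot quadrants.

`run_pipeline()` chains all stages (genotype summary, clustered fit,
diagnostics, permutation null, case-exclusion bootstrap, PLS-DA,
descriptive comparisons) and can write a JSON report;
`permutation_null()` and `case_exclusion_bootstrap()` run the resampling
defenses individually. Cohorts and methylation panels move through plain
tab-delimited files via `write_cohort_tsv()` / `read_cohort_tsv()` /
`write_methylation_tsv()`.

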