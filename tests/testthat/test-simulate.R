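test_that("pedigree structure matches the configured totals", {
  ped <- simulate_pedigrees(generator_config(seed = 2))
  expect_equal(nrow(ped), 2532)
  sizes <- table(ped$pedigree_id)
  expect_equal(sum(sizes == 1), 439)
  expect_equal(sum(sizes > 1), 278)
  expect_true(all(sizes[sizes > 1] >= 2))

  one <- simulate_pedigrees(generator_config(n_participants = 1,
                                             n_singletons = 1, n_families = 0,
                                             target_events = 1,
                                             meth_subset_n = 1, seed = 1))
  expect_equal(nrow(one), 1)
  expect_true(one$founder)
})

test_that("a single family of ten is a well-formed two-founder pedigree", {
  cfg <- generator_config(n_participants = 10, n_singletons = 0,
                          n_families = 1, target_events = 1,
                          meth_subset_n = 10, meth_case_n = 1, seed = 5)
  ped <- simulate_pedigrees(cfg)
  expect_equal(sum(ped$founder), 2)
  kids <- ped[!ped$founder, ]
  expect_equal(nrow(kids), 8)
  # both parents resolve to in-pedigree founders; traversal terminates
  for (i in seq_len(nrow(kids))) {
    for (par in c(kids$father_id[i], kids$mother_id[i])) {
      expect_false(is.na(par))
      expect_equal(ped$pedigree_id[par], kids$pedigree_id[i])
      expect_true(ped$founder[par])      # depth-1 ancestry: no cycles
    }
  }
  expect_error(simulate_pedigrees(
    generator_config(n_participants = 10, n_singletons = 9, n_families = 1,
                     target_events = 1, meth_subset_n = 5, seed = 1)),
    "family")
})

test_that("genotypes follow Hardy-Weinberg founders and Mendelian children", {
  # carrier fraction at the default minor-allele frequency
  frac <- vapply(1:30, function(s) {
    ped <- simulate_pedigrees(generator_config(seed = s))
    mean(simulate_genotypes(ped, 0.096, s) %in% c("TT", "TG"))
  }, numeric(1))
  expect_lt(abs(mean(frac) - (1 - (1 - 0.096)^2)), 0.01)

  ped <- simulate_pedigrees(generator_config(seed = 1))
  expect_true(all(simulate_genotypes(ped, 1e-12, 1) == "GG"))

  # transmission table from many two-parent/one-child trios
  n_trio <- 1200
  trio <- data.frame(
    id = seq_len(3 * n_trio),
    pedigree_id = rep(sprintf("T%04d", seq_len(n_trio)), each = 3),
    founder = rep(c(TRUE, TRUE, FALSE), n_trio),
    father_id = ifelse(rep(c(TRUE, TRUE, FALSE), n_trio), NA,
                       3 * rep(seq_len(n_trio), each = 3) - 2),
    mother_id = ifelse(rep(c(TRUE, TRUE, FALSE), n_trio), NA,
                       3 * rep(seq_len(n_trio), each = 3) - 1))
  g <- simulate_genotypes(trio, 0.5, seed = 42)
  fa <- g[seq(1, length(g), 3)]; mo <- g[seq(2, length(g), 3)]
  kid <- g[seq(3, length(g), 3)]
  # TT x GG -> always TG
  hom_cross <- (fa == "TT" & mo == "GG") | (fa == "GG" & mo == "TT")
  expect_true(sum(hom_cross) > 50)
  expect_true(all(kid[hom_cross] == "TG"))
  # TG x TG -> 1:2:1
  het_cross <- fa == "TG" & mo == "TG"
  expect_true(sum(het_cross) > 200)
  props <- table(factor(kid[het_cross], c("TT", "TG", "GG"))) / sum(het_cross)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 0.07))
})

test_that("founder genotypes pass the HWE exact test across seeds", {
  pass <- vapply(1:100, function(s) {
    cfg <- generator_config(seed = s)
    ped <- simulate_pedigrees(cfg)
    g <- simulate_genotypes(ped, cfg$maf, s + 7000)[ped$founder]
    hwe_exact_test(genotype_counts(sum(g == "TT"), sum(g == "TG"),
                                   sum(g == "GG"))) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.98)
})

test_that("covariates reproduce the configured moments and family clustering", {
  cfg <- generator_config(seed = 1)
  ped <- simulate_pedigrees(cfg)
  ages <- c(); iccs <- c()
  for (s in 1:8) {
    cov <- simulate_covariates(ped, cfg, s)
    ages <- c(ages, mean(cov$age_y))
    iccs <- c(iccs, icc_anova(cov$age_y, ped$pedigree_id))
  }
  expect_lt(abs(mean(ages) - 44.8), 0.6)
  expect_lt(abs(mean(iccs) - 0.2), 0.05)
  cov <- simulate_covariates(ped, cfg, 99)
  expect_lt(abs(mean(cov$bmi) - 25.8), 0.4)
  expect_lt(abs(mean(cov$smoker) - 0.303), 0.03)
  expect_equal(cov$chol_ratio, cov$chol_total_mmol_l / cov$chol_hdl_mmol_l)

  cfg2 <- cfg
  cfg2$covariate_moments$bmi$sd <- 0
  cov2 <- simulate_covariates(ped, cfg2, 1)
  expect_true(all(cov2$bmi == 25.8))
  cfg3 <- cfg
  cfg3$covariate_moments$smoker$prevalence <- 1.4
  expect_error(pearcrc:::validate_generator_config(cfg3), "prevalence")
})

test_that("survival stage calibrates the baseline hazard to the event target", {
  ev <- vapply(1:60, function(s) {
    sum(simulate_cohort(generator_config(seed = s),
                        methylation = FALSE)$cohort$event)
  }, numeric(1))
  expect_lt(abs(mean(ev) - 49), 2)

  # fixed censoring at 18 years, no effects: the calibrated rate inverts the
  # closed form P(event) = 1 - exp(-lambda * C)
  p_target <- 1 - exp(-0.001 * 18)
  cfg <- generator_config(followup_min = 18, followup_max = 18,
                          true_log_hr_carrier = 0,
                          covariate_log_hr = c(age_y = 0),
                          target_events = 2532 * p_target, seed = 4)
  sim <- simulate_cohort(cfg, methylation = FALSE)
  expect_equal(sim$truth$baseline_rate, 0.001, tolerance = 1e-6)
  expect_error(simulate_cohort(generator_config(target_events = 5000)),
               "target")
})

test_that("null carrier effect yields hazard-ratio estimates centered at one", {
  betas <- vapply(1:60, function(s) {
    sim <- simulate_cohort(generator_config(true_log_hr_carrier = 0, seed = s),
                           methylation = FALSE)
    fit_cox(sim$cohort, primary_terms())$beta[["carrier"]]
  }, numeric(1))
  expect_gt(exp(mean(betas)), 0.9)
  expect_lt(exp(mean(betas)), 1.1)
})

test_that("identical seed and configuration reproduce the cohort exactly", {
  a <- simulate_cohort(generator_config(seed = 123))
  b <- simulate_cohort(generator_config(seed = 123))
  expect_identical(a, b)
  c_ <- simulate_cohort(generator_config(seed = 124))
  expect_false(identical(a$cohort$time_y, c_$cohort$time_y))
})

test_that("methylation submatrix has the planted structure", {
  sim <- simulate_cohort(generator_config(seed = 6))
  m <- sim$methylation
  expect_equal(dim(m$methylation), c(929, 16))
  expect_true(all(m$methylation >= 0 & m$methylation <= 1))
  expect_equal(sum(m$case), 16)
  cc <- correlation_matrix(m$methylation)
  expect_gte(mean(abs(cc[upper.tri(cc)])), 0.3)

  # noise washes out the latent correlation
  noisy <- simulate_cohort(generator_config(seed = 6, meth_noise_sd = 60))
  ccn <- correlation_matrix(noisy$methylation$methylation)
  expect_lt(mean(abs(ccn[upper.tri(ccn)])), 0.08)

  # planted site 11 shifts upward in cases, site 13 downward
  d11 <- d13 <- numeric(0)
  for (s in 1:10) {
    ms <- simulate_cohort(generator_config(seed = s))$methylation
    d11 <- c(d11, mean(ms$methylation[ms$case == 1, 11]) -
               mean(ms$methylation[ms$case == 0, 11]))
    d13 <- c(d13, mean(ms$methylation[ms$case == 1, 13]) -
               mean(ms$methylation[ms$case == 0, 13]))
  }
  expect_gt(mean(d11), 0.1)
  expect_lt(mean(d13), -0.1)

  # time intervals track the configured medians by case status
  expect_lt(median(m$time_interval_y[m$case == 1]), 0)
  expect_gt(median(m$time_interval_y[m$case == 0]), 0)
})

test_that("cohort tables round-trip through the tab-delimited format", {
  sim <- simulate_cohort(small_config(8))
  tmp <- tempfile(fileext = ".tsv")
  write_cohort_tsv(sim, tmp)
  back <- read_cohort_tsv(tmp)
  expect_equal(back$carrier,
               as.integer(sim$cohort$genotype %in% c("TT", "TG")))
  expect_equal(back$time_y, sim$cohort$time_y, tolerance = 1e-6)
  tmp2 <- tempfile(fileext = ".tsv")
  write_methylation_tsv(sim, tmp2)
  mb <- read_methylation_tsv(tmp2)
  expect_equal(dim(mb$methylation), dim(sim$methylation$methylation))
  expect_equal(mb$methylation, unname(sim$methylation$methylation),
               tolerance = 0.005, ignore_attr = TRUE)
})
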