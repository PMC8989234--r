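#' Run the full analysis pipeline
#'
#' Executes every stage on a simulated or user-supplied cohort: genotype
#' summary (counts, allele frequencies, Hardy-Weinberg exact test in
#' founders where available, pooling check), the primary family-clustered
#' proportional-hazards fit with the supremum proportional-hazards
#' diagnostic and cumulative-incidence curves, the carrier-label
#' permutation null, the case-exclusion bootstrap, the methylation PLS-DA
#' stage (skipped with a note when no methylation data are present) and
#' the between-group descriptive table.
#'
#' @param config A [generator_config()] used to simulate the cohort, or
#'   NULL when `cohort` is supplied.
#' @param cohort Optional cohort data frame (as from [read_cohort_tsv()]).
#' @param methylation Optional list with `methylation` matrix, `case` and
#'   covariate data for the PLS-DA stage; taken from the simulation when
#'   `config` is used.
#' @param n_permutation_runs,n_exclusion_runs_per_k,k_range Resampling
#'   sizes (defaults kept modest; raise for production use).
#' @param n_ph_replications Multiplier replicates of the supremum test.
#' @param seed Seed governing all stochastic stages.
#' @param out_json Optional path: writes the report as JSON.
#' @return List of class `pipeline_report` with one element per stage.
#' @export
run_pipeline <- function(config = generator_config(), cohort = NULL,
                         methylation = NULL,
                         n_permutation_runs = 200,
                         n_exclusion_runs_per_k = 100, k_range = 2:9,
                         n_ph_replications = 500,
                         seed = NULL, out_json = NULL) {
  truth <- NULL
  if (is.null(cohort)) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    sim <- simulate_cohort(config)
    cohort <- sim$cohort
    if (is.null(methylation) && !is.null(sim$methylation)) {
      m <- sim$methylation
      methylation <- list(methylation = m$methylation, case = m$case,
                          covariates = data.frame(
                            time_interval_y = m$time_interval_y,
                            cohort[match(m$ids, cohort$id),
                                   c("sex", "age_y", "bmi", "chol_ratio",
                                     "creat_umol_l", "smoker", "drinker",
                                     "antiplatelet")]))
    }
    truth <- sim$truth
  }
  if (is.null(seed)) seed <- if (!is.null(config)) config$seed else 1
  seed <- as.integer(seed)
  if (is.null(cohort$carrier)) {
    cohort$carrier <- as.integer(cohort$genotype %in% c("TT", "TG"))
  }

  geno <- genotype_summary(cohort, founders_only = !is.null(cohort$founder))
  fit <- fit_cox(cohort, terms = primary_terms(), cluster_by = "pedigree_id")
  report <- list(
    genotype = geno,
    cox = fit,
    carrier = carrier_hr_report(fit),
    ph_test = supremum_ph_test(fit, n_replications = n_ph_replications,
                               seed = stage_seed(seed, 6)),
    incidence_unadjusted = cumulative_incidence(cohort, adjust = "none"),
    incidence_adjusted = cumulative_incidence(cohort, adjust = "sex_age"),
    permutation = permutation_null(cohort, n_runs = n_permutation_runs,
                                   seed = stage_seed(seed, 7)),
    case_exclusion = case_exclusion_bootstrap(
      cohort, k_range = k_range, n_runs_per_k = n_exclusion_runs_per_k,
      seed = stage_seed(seed, 8)),
    descriptives = compare_groups(cohort),
    truth = truth,
    seed = seed
  )
  if (!is.null(methylation)) {
    report$plsda <- plsda_analysis(methylation$methylation, methylation$case,
                                   methylation$covariates,
                                   seed = stage_seed(seed, 9))
  } else {
    report$plsda_skipped <- "no methylation data supplied"
  }
  class(report) <- "pipeline_report"
  if (!is.null(out_json)) write_pipeline_json(report, out_json)
  report
}

# serializable summary of a pipeline report
pipeline_summary <- function(report) {
  out <- list(
    seed = report$seed,
    genotype = list(
      counts = unclass(report$genotype$counts),
      maf = report$genotype$frequencies$maf,
      carrier_count = report$genotype$frequencies$carrier_count,
      hwe_p = report$genotype$hwe_p,
      pooled = report$genotype$pooling$pool),
    cox = list(n = report$cox$n, n_events = report$cox$n_events,
               carrier_hr = report$carrier$hr,
               carrier_ci = c(report$carrier$ci_lo, report$carrier$ci_hi),
               carrier_p = report$carrier$p,
               ph_test_p = as.list(report$ph_test$p)),
    permutation = list(
      n_runs = report$permutation$n_runs,
      alpha = report$permutation$alpha,
      n_below_alpha = report$permutation$n_below_alpha,
      permutation_p = report$permutation$permutation_p),
    case_exclusion = list(
      by_k = report$case_exclusion$by_k,
      mean_hr = report$case_exclusion$mean_hr,
      mean_hr_ci = report$case_exclusion$mean_hr_ci)
  )
  if (!is.null(report$plsda)) {
    out$plsda <- list(
      selected_factors = report$plsda$selection$selected,
      x_variance_explained = report$plsda$model$x_variance_explained,
      vip = report$plsda$vip,
      quadrants = report$plsda$v_plot$quadrant)
  }
  out
}

write_pipeline_json <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(pipeline_summary(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Genotype stage ==\n")
  print(x$genotype$counts); print(x$genotype$frequencies)
  cat(sprintf("HWE exact p = %.3f\n", x$genotype$hwe_p))
  print(x$genotype$pooling)
  cat("\n== Primary association ==\n")
  print(x$cox)
  cat("Carrier:", x$carrier$formatted, "\n")
  cat("\n== Resampling defenses ==\n")
  print(x$permutation)
  print(x$case_exclusion)
  if (!is.null(x$plsda)) {
    cat("\n== Methylation PLS-DA ==\n")
    print(x$plsda)
  } else cat("\n(PLS-DA stage skipped:", x$plsda_skipped, ")\n")
  invisible(x)
}
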