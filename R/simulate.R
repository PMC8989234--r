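#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the family-structured cohort simulator. Defaults
#' emulate the published structure of the source cohort: 2532 participants
#' of whom 439 are singletons and the rest belong to 278 families; a
#' minor-allele frequency of 9.6% under Hardy-Weinberg equilibrium with
#' Mendelian transmission inside pedigrees; covariate means/SDs and
#' prevalences matching the enrolment table; roughly 49 colorectal-cancer
#' events under administrative censoring between 8.2 and 29.6 years; and a
#' 929 x 16 promoter-methylation submatrix with two latent factors, high
#' inter-site correlation, and case-associated effects planted at sites 2
#' and 13 (protective) and 11 and 12 (deleterious).
#'
#' @param n_participants Total cohort size.
#' @param n_singletons Number of participants outside any family.
#' @param n_families Number of multi-member pedigrees.
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param covariate_moments Named list; continuous entries have `mean`,
#'   `sd` and clamp bounds `lower`/`upper`, binary entries a `prevalence`.
#' @param family_rho Within-family intraclass correlation of continuous
#'   covariates, induced by a shared family effect.
#' @param chol_corr Correlation between total and HDL cholesterol.
#' @param true_log_hr_carrier True log hazard ratio of minor-allele
#'   carriage.
#' @param covariate_log_hr Named vector of nuisance log hazard ratios
#'   (default: age +0.05 per year, all else zero).
#' @param target_events Expected number of events the baseline hazard is
#'   calibrated to.
#' @param followup_min,followup_max Administrative censoring times are
#'   uniform on this interval (years).
#' @param meth_subset_n Size of the methylation subset.
#' @param meth_case_n Number of cases in the methylation subset.
#' @param meth_loadings 16 x 2 matrix of latent-factor loadings on the
#'   logit scale.
#' @param meth_noise_sd Residual SD on the logit scale.
#' @param meth_site_means Baseline methylation proportions per site.
#' @param planted_effects Named numeric vector mapping CpG site index to a
#'   signed case effect, in units of the site's logit-scale SD.
#' @param interval_cases,interval_noncases Median and quartiles (years) of
#'   the diagnosis/censoring minus methylation-measurement interval, fitted
#'   by an asymmetric Laplace law.
#' @param seed Integer seed; together with the configuration it fully
#'   determines the output.
#'
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    n_participants = 2532,
    n_singletons = 439,
    n_families = 278,
    maf = 0.096,
    covariate_moments = default_covariate_moments(),
    family_rho = 0.2,
    chol_corr = 0.2,
    true_log_hr_carrier = log(2.17),
    covariate_log_hr = c(age_y = 0.05),
    target_events = 49,
    followup_min = 8.2,
    followup_max = 29.6,
    meth_subset_n = 929,
    meth_case_n = 16,
    meth_loadings = default_meth_loadings(),
    meth_noise_sd = 1,
    meth_site_means = default_meth_site_means(),
    planted_effects = c("2" = -1.5, "13" = -1.5, "11" = 1.5, "12" = 1.5),
    interval_cases = c(median = -2.6, q1 = -4.4, q3 = 1.9),
    interval_noncases = c(median = 3.1, q1 = -0.1, q3 = 4.4),
    seed = 1) {
  cfg <- list(
    n_participants = n_participants, n_singletons = n_singletons,
    n_families = n_families, maf = maf,
    covariate_moments = covariate_moments, family_rho = family_rho,
    chol_corr = chol_corr, true_log_hr_carrier = true_log_hr_carrier,
    covariate_log_hr = covariate_log_hr, target_events = target_events,
    followup_min = followup_min, followup_max = followup_max,
    meth_subset_n = meth_subset_n, meth_case_n = meth_case_n,
    meth_loadings = meth_loadings, meth_noise_sd = meth_noise_sd,
    meth_site_means = meth_site_means, planted_effects = planted_effects,
    interval_cases = interval_cases, interval_noncases = interval_noncases,
    seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$maf <= 0 || cfg$maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (cfg$n_singletons > cfg$n_participants) {
    stop("more singletons than participants")
  }
  n_fam_members <- cfg$n_participants - cfg$n_singletons
  if (cfg$n_families > 0 && n_fam_members < 2 * cfg$n_families) {
    stop("family sizes incompatible: need at least 2 members per family")
  }
  if (cfg$n_families == 0 && n_fam_members > 0) {
    stop("non-singleton participants but zero families")
  }
  for (nm in names(cfg$covariate_moments)) {
    m <- cfg$covariate_moments[[nm]]
    if (!is.null(m$prevalence)) {
      if (m$prevalence < 0 || m$prevalence > 1) {
        stop("prevalence of '", nm, "' outside [0, 1]")
      }
    } else if (m$sd < 0) {
      stop("negative SD for '", nm, "'")
    }
  }
  if (cfg$target_events > cfg$n_participants) {
    stop("target event count exceeds cohort size")
  }
  if (!is.matrix(cfg$meth_loadings) || !all(dim(cfg$meth_loadings) == c(16, 2))) {
    stop("meth_loadings must be a 16 x 2 matrix")
  }
  if (cfg$meth_subset_n > cfg$n_participants) {
    stop("methylation subset larger than cohort")
  }
  invisible(cfg)
}

#' @rdname generator_config
#' @export
default_covariate_moments <- function() {
  list(
    sex = list(prevalence = 0.512),                     # 1 = female
    age_y = list(mean = 44.8, sd = 14.6, lower = 18, upper = 100),
    bmi = list(mean = 25.8, sd = 4.4, lower = 14, upper = 60),
    chol_total_mmol_l = list(mean = 5.54, sd = 1.20, lower = 1.5, upper = 12),
    chol_hdl_mmol_l = list(mean = 1.37, sd = 0.38, lower = 0.4, upper = 3.5),
    creat_umol_l = list(mean = 91.7, sd = 18.3, lower = 35, upper = 250),
    gluc_mmol_l = list(mean = 5.06, sd = 1.33, lower = 2.2, upper = 25),
    smoker = list(prevalence = 0.303),
    drinker = list(prevalence = 0.281),
    antiplatelet = list(prevalence = 0.116)
  )
}

#' @rdname generator_config
#' @export
default_meth_loadings <- function() {
  # one strong shared factor (same sign at all 16 sites, so inter-site
  # correlations are high and positive) and a weaker bipolar factor
  cbind(rep(0.8, 16), rep(c(0.45, -0.45), each = 8))
}

#' @rdname generator_config
#' @export
default_meth_site_means <- function() {
  # baseline methylation proportions, varying across the promoter
  c(0.35, 0.42, 0.55, 0.61, 0.48, 0.52, 0.66, 0.38,
    0.45, 0.58, 0.50, 0.47, 0.62, 0.41, 0.53, 0.57)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort config: n = %d (%d singletons, %d ",
                     "families), MAF %.3f,\n  true carrier HR %.2f, target ",
                     "events %d, methylation subset %d (%d cases), seed %d\n"),
              x$n_participants, x$n_singletons, x$n_families, x$maf,
              exp(x$true_log_hr_carrier), x$target_events, x$meth_subset_n,
              x$meth_case_n, x$seed))
  invisible(x)
}

stage_seed <- function(seed, stage) as.integer((seed * 16 + stage) %% 2147483647)

#' Simulate pedigree structure
#'
#' Assigns participants to singletons and nuclear families. Family sizes
#' follow a truncated geometric law (minimum two members) whose mean is set
#' so the family members exactly fill the non-singleton remainder; a few
#' deterministic unit adjustments enforce the exact total. Each family has
#' two founders; all other members are their children, with explicit
#' parent links.
#'
#' @param config A [generator_config()].
#' @return Data frame: `id`, `pedigree_id`, `founder`, `father_id`,
#'   `mother_id` (NA for founders and singletons).
#' @export
simulate_pedigrees <- function(config) {
  validate_generator_config(config)
  set.seed(stage_seed(config$seed, 1))
  n <- config$n_participants
  n_fam <- config$n_families
  n_members <- n - config$n_singletons
  sizes <- integer(0)
  if (n_fam > 0) {
    mean_extra <- n_members / n_fam - 2
    prob <- 1 / (1 + mean_extra)
    sizes <- 2 + stats::rgeom(n_fam, prob)
    excess <- sum(sizes) - n_members
    while (excess > 0) {
      big <- which(sizes > 2)
      take <- big[sample.int(length(big), min(length(big), excess))]
      sizes[take] <- sizes[take] - 1
      excess <- sum(sizes) - n_members
    }
    while (excess < 0) {
      add <- sample.int(n_fam, min(n_fam, -excess))
      sizes[add] <- sizes[add] + 1
      excess <- sum(sizes) - n_members
    }
  }
  id <- seq_len(n)
  pedigree_id <- character(n)
  founder <- logical(n)
  father <- rep(NA_integer_, n)
  mother <- rep(NA_integer_, n)
  pos <- 1
  for (s in seq_len(config$n_singletons)) {
    pedigree_id[pos] <- sprintf("S%04d", s)
    founder[pos] <- TRUE
    pos <- pos + 1
  }
  for (f in seq_along(sizes)) {
    idx <- pos:(pos + sizes[f] - 1)
    pedigree_id[idx] <- sprintf("F%04d", f)
    founder[idx[1:2]] <- TRUE
    if (sizes[f] > 2) {
      kids <- idx[-(1:2)]
      father[kids] <- idx[1]
      mother[kids] <- idx[2]
    }
    pos <- pos + sizes[f]
  }
  data.frame(id = id, pedigree_id = pedigree_id, founder = founder,
             father_id = father, mother_id = mother,
             stringsAsFactors = FALSE)
}

#' Simulate genotypes with Mendelian transmission
#'
#' Founders are drawn from Hardy-Weinberg proportions at the configured
#' minor-allele frequency; non-founders receive one allele from each
#' parent.
#'
#' @param pedigrees Output of [simulate_pedigrees()].
#' @param maf Minor-allele frequency.
#' @param seed Integer seed.
#' @return Character vector of genotypes (`"TT"`, `"TG"`, `"GG"`).
#' @export
simulate_genotypes <- function(pedigrees, maf, seed) {
  set.seed(seed)
  n <- nrow(pedigrees)
  count <- rep(NA_integer_, n)        # minor-allele dose 0/1/2
  fnd <- which(pedigrees$founder)
  probs <- c(maf^2, 2 * maf * (1 - maf), (1 - maf)^2)
  count[fnd] <- sample(c(2L, 1L, 0L), length(fnd), replace = TRUE, prob = probs)
  todo <- which(!pedigrees$founder)
  guard <- 0
  while (length(todo)) {
    ready <- todo[!is.na(count[pedigrees$father_id[todo]]) &
                  !is.na(count[pedigrees$mother_id[todo]])]
    if (!length(ready)) stop("malformed pedigree: unresolvable parent links")
    a1 <- stats::rbinom(length(ready), 1, count[pedigrees$father_id[ready]] / 2)
    a2 <- stats::rbinom(length(ready), 1, count[pedigrees$mother_id[ready]] / 2)
    count[ready] <- as.integer(a1 + a2)
    todo <- setdiff(todo, ready)
    guard <- guard + 1
    if (guard > n) stop("malformed pedigree: cycle detected")
  }
  c("GG", "TG", "TT")[count + 1]
}

#' Simulate baseline covariates
#'
#' Continuous covariates are normal with the configured mean/SD, share a
#' family-level random effect inducing intraclass correlation
#' `family_rho`, and are clamped at wide physiologic bounds. Total and HDL
#' cholesterol are generated jointly (correlation `chol_corr`) and their
#' ratio derived. Binary covariates are Bernoulli at the configured
#' prevalence.
#'
#' @param pedigrees Output of [simulate_pedigrees()].
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Data frame of covariates including `chol_ratio`.
#' @export
simulate_covariates <- function(pedigrees, config, seed) {
  set.seed(seed)
  n <- nrow(pedigrees)
  fam <- match(pedigrees$pedigree_id, unique(pedigrees$pedigree_id))
  n_fam <- max(fam)
  rho <- config$family_rho
  mom <- config$covariate_moments
  std_normal_with_family <- function() {
    u <- stats::rnorm(n_fam)[fam]
    sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
  }
  out <- list()
  z_total <- NULL
  for (nm in names(mom)) {
    m <- mom[[nm]]
    if (!is.null(m$prevalence)) {
      out[[nm]] <- stats::rbinom(n, 1, m$prevalence)
    } else {
      z <- std_normal_with_family()
      if (nm == "chol_total_mmol_l") z_total <- z
      if (nm == "chol_hdl_mmol_l" && !is.null(z_total)) {
        z <- config$chol_corr * z_total +
          sqrt(1 - config$chol_corr^2) * std_normal_with_family()
      }
      out[[nm]] <- pmin(pmax(m$mean + m$sd * z, m$lower), m$upper)
    }
  }
  out <- as.data.frame(out)
  if (all(c("chol_total_mmol_l", "chol_hdl_mmol_l") %in% names(out))) {
    out$chol_ratio <- out$chol_total_mmol_l / out$chol_hdl_mmol_l
  }
  out
}

#' Simulate survival outcomes
#'
#' Event times are exponential with subject-specific rate
#' `baseline * exp(lp)`, where the linear predictor contains the carrier
#' effect and any nuisance covariate effects (age centered at its sample
#' mean). Administrative censoring times are uniform on the configured
#' follow-up window. The baseline rate is calibrated by root-finding so the
#' expected event count, given the drawn covariates and censoring times,
#' equals `target_events`.
#'
#' @param genotypes Genotype vector.
#' @param covariates Covariate data frame.
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Data frame with `event`, `time_y`, `carrier` and the attribute
#'   `baseline_rate`.
#' @export
simulate_survival <- function(genotypes, covariates, config, seed) {
  set.seed(seed)
  n <- length(genotypes)
  if (config$target_events > n) stop("target event count exceeds cohort size")
  carrier <- as.integer(genotypes %in% c("TT", "TG"))
  lp <- config$true_log_hr_carrier * carrier
  for (nm in names(config$covariate_log_hr)) {
    if (!nm %in% names(covariates)) next
    x <- covariates[[nm]]
    lp <- lp + config$covariate_log_hr[[nm]] * (x - mean(x))
  }
  risk <- exp(lp)
  cens <- stats::runif(n, config$followup_min, config$followup_max)
  expected_events <- function(log_lambda0) {
    sum(1 - exp(-exp(log_lambda0) * risk * cens)) - config$target_events
  }
  root <- stats::uniroot(expected_events, lower = log(1e-10), upper = log(10),
                         tol = 1e-12)
  lambda0 <- exp(root$root)
  tev <- stats::rexp(n, rate = lambda0 * risk)
  event <- as.integer(tev <= cens)
  out <- data.frame(event = event, time_y = pmin(tev, cens), carrier = carrier)
  attr(out, "baseline_rate") <- lambda0
  out
}

# asymmetric Laplace matched to a printed median and quartiles
rasym_laplace <- function(n, median, q1, q3) {
  scale_l <- (median - q1) / log(2)
  scale_r <- (q3 - median) / log(2)
  side <- stats::runif(n) < 0.5
  e <- stats::rexp(n)
  ifelse(side, median - scale_l * e, median + scale_r * e)
}

#' Simulate the promoter methylation submatrix
#'
#' Selects a methylation subset of the cohort containing `meth_case_n`
#' cases (or all cases if fewer occurred), generates 16-site methylation
#' from a two-latent-factor model on the logit scale, shifts planted sites
#' in cases by the configured signed effects (in units of the site's total
#' logit-scale SD), maps to proportions, and draws the interval between
#' diagnosis/censoring and the methylation measurement from asymmetric
#' Laplace laws matched to the configured medians and quartiles.
#'
#' @param cohort Cohort table with `id` and `event`.
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List: `ids`, `methylation` (n x 16 proportions), `case`,
#'   `time_interval_y`, `truth` (planted sites/effects, loadings).
#' @export
simulate_methylation <- function(cohort, config, seed) {
  set.seed(seed)
  n_sub <- config$meth_subset_n
  if (n_sub > nrow(cohort)) stop("methylation subset larger than cohort")
  cases_avail <- which(cohort$event == 1)
  n_case <- min(config$meth_case_n, length(cases_avail))
  case_rows <- if (length(cases_avail) > n_case) {
    sort(sample(cases_avail, n_case))
  } else cases_avail
  noncase_pool <- setdiff(seq_len(nrow(cohort)), cases_avail)
  noncase_rows <- sort(sample(noncase_pool, n_sub - length(case_rows)))
  rows <- sort(c(case_rows, noncase_rows))
  case <- as.integer(rows %in% case_rows)

  L <- config$meth_loadings
  mu <- stats::qlogis(config$meth_site_means)
  FF <- matrix(stats::rnorm(n_sub * 2), n_sub, 2)
  E <- matrix(stats::rnorm(n_sub * 16, sd = config$meth_noise_sd), n_sub, 16)
  M <- sweep(FF %*% t(L), 2, mu, "+") + E
  site_sd <- sqrt(rowSums(L^2) + config$meth_noise_sd^2)
  for (s in names(config$planted_effects)) {
    j <- as.integer(s)
    M[case == 1, j] <- M[case == 1, j] +
      config$planted_effects[[s]] * site_sd[j]
  }
  meth <- stats::plogis(M)
  colnames(meth) <- sprintf("cpg%02d", 1:16)

  ti <- numeric(n_sub)
  ic <- config$interval_cases
  inc <- config$interval_noncases
  ti[case == 1] <- rasym_laplace(sum(case), ic["median"], ic["q1"], ic["q3"])
  ti[case == 0] <- rasym_laplace(sum(1 - case), inc["median"], inc["q1"],
                                 inc["q3"])

  list(ids = cohort$id[rows], methylation = meth, case = case,
       time_interval_y = ti,
       truth = list(planted_effects = config$planted_effects,
                    loadings = L, noise_sd = config$meth_noise_sd,
                    site_sd_logit = site_sd))
}

#' Simulate a complete cohort
#'
#' Runs the pedigree, genotype, covariate, survival and methylation stages
#' with seeds derived from the configuration seed, and assembles the
#' standard cohort table.
#'
#' @param config A [generator_config()].
#' @param methylation Generate the methylation subset (default TRUE).
#' @return Object of class `simulated_cohort`: `cohort` (data frame with
#'   id, pedigree_id, founder, covariates, genotype, carrier, event,
#'   time_y), `methylation` (see [simulate_methylation()]) and `truth`.
#' @examples
#' sim <- simulate_cohort(generator_config(seed = 7))
#' table(sim$cohort$genotype)
#' @export
simulate_cohort <- function(config = generator_config(), methylation = TRUE) {
  validate_generator_config(config)
  ped <- simulate_pedigrees(config)
  geno <- simulate_genotypes(ped, config$maf, stage_seed(config$seed, 2))
  cov <- simulate_covariates(ped, config, stage_seed(config$seed, 3))
  surv <- simulate_survival(geno, cov, config, stage_seed(config$seed, 4))
  cohort <- cbind(ped[, c("id", "pedigree_id", "founder")], cov,
                  genotype = geno, surv)
  meth <- NULL
  if (methylation) {
    meth <- simulate_methylation(cohort, config, stage_seed(config$seed, 5))
  }
  structure(list(
    cohort = cohort,
    methylation = meth,
    truth = list(true_hr_carrier = exp(config$true_log_hr_carrier),
                 covariate_log_hr = config$covariate_log_hr,
                 baseline_rate = attr(surv, "baseline_rate"),
                 planted_effects = config$planted_effects,
                 config = config)
  ), class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: n = %d, %d events, %d carriers (%.1f%%)\n",
              nrow(x$cohort), sum(x$cohort$event), sum(x$cohort$carrier),
              100 * mean(x$cohort$carrier)))
  if (!is.null(x$methylation)) {
    cat(sprintf("  methylation subset: %d subjects, %d cases\n",
                length(x$methylation$ids), sum(x$methylation$case)))
  }
  invisible(x)
}

#' Covariates of the primary multivariable model
#'
#' The carrier indicator plus the full adjustment set used by the primary
#' association analysis: sex, age, body mass index, total-to-HDL
#' cholesterol ratio, serum creatinine, plasma glucose, smoking, drinking
#' and antiplatelet use.
#' @return Character vector of column names.
#' @export
primary_terms <- function() {
  c("carrier", "sex", "age_y", "bmi", "chol_ratio", "creat_umol_l",
    "gluc_mmol_l", "smoker", "drinker", "antiplatelet")
}

#' Write / read the standard cohort and methylation tables
#'
#' Tab-delimited cohort tables use a fixed column order; methylation tables
#' are written in percent with two decimals.
#'
#' @param sim A `simulated_cohort` (or a cohort data frame for
#'   `write_cohort_tsv`).
#' @param path Output file path.
#' @name cohort_io
#' @export
write_cohort_tsv <- function(sim, path) {
  cohort <- if (inherits(sim, "simulated_cohort")) sim$cohort else sim
  cols <- c("id", "pedigree_id", "sex", "age_y", "bmi", "chol_total_mmol_l",
            "chol_hdl_mmol_l", "chol_ratio", "creat_umol_l", "gluc_mmol_l",
            "smoker", "drinker", "antiplatelet", "genotype", "event", "time_y")
  extra <- intersect(c("founder"), names(cohort))
  utils::write.table(cohort[, c(cols, extra)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_tsv <- function(path) {
  cohort <- utils::read.delim(path, stringsAsFactors = FALSE)
  cohort$carrier <- as.integer(cohort$genotype %in% c("TT", "TG"))
  cohort
}

#' @rdname cohort_io
#' @export
write_methylation_tsv <- function(sim, path) {
  meth <- if (inherits(sim, "simulated_cohort")) sim$methylation else sim
  df <- data.frame(id = meth$ids,
                   round(100 * meth$methylation, 2),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_methylation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(ids = df$id,
       methylation = as.matrix(df[, grep("^cpg", names(df))]) / 100)
}
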