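#' Carrier-label permutation null
#'
#' Randomization defense for the primary association: the carrier state is
#' randomly reassigned to `n_carriers` participants (all covariates and
#' outcomes held fixed), the full multivariable family-clustered
#' proportional-hazards model is refitted, and the carrier Wald p-value
#' recorded. The number of runs reaching significance below `alpha`
#' estimates how often an association as extreme as the observed one arises
#' by chance alone.
#'
#' @param cohort Cohort table.
#' @param n_carriers Number of pseudo-carriers per run (default: the
#'   observed carrier count).
#' @param n_runs Number of permutation runs.
#' @param alpha Significance threshold applied to each run's carrier p.
#' @param seed Integer seed.
#' @param terms Model terms (default [primary_terms()]).
#' @return Object of class `permutation_result`: `n_runs`, `n_failed`,
#'   `alpha`, `n_below_alpha`, `permutation_p` (= (count+1)/(runs+1) over
#'   converged runs), `p_values`, `seed`.
#' @export
permutation_null <- function(cohort, n_carriers = NULL, n_runs = 1000,
                             alpha = 0.013, seed = 1,
                             terms = primary_terms()) {
  cohort <- as.data.frame(cohort)
  if (is.null(cohort$carrier)) {
    cohort$carrier <- as.integer(cohort$genotype %in% c("TT", "TG"))
  }
  if (is.null(n_carriers)) n_carriers <- sum(cohort$carrier)
  n <- nrow(cohort)
  if (n_carriers >= n) stop("n_carriers must be smaller than the cohort")
  set.seed(seed)
  p_values <- rep(NA_real_, n_runs)
  for (run in seq_len(n_runs)) {
    cohort$carrier <- 0L
    cohort$carrier[sample.int(n, n_carriers)] <- 1L
    fit <- tryCatch(fit_cox(cohort, terms = terms,
                            cluster_by = "pedigree_id"),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      p_values[run] <- fit$table["carrier", "p"]
    }
  }
  ok <- !is.na(p_values)
  if (mean(!ok) > 0.01) {
    warning(sprintf("%d of %d permutation runs failed to converge",
                    sum(!ok), n_runs))
  }
  n_below <- sum(p_values[ok] < alpha)
  structure(list(n_runs = sum(ok), n_failed = sum(!ok), alpha = alpha,
                 n_below_alpha = n_below,
                 permutation_p = (n_below + 1) / (sum(ok) + 1),
                 p_values = p_values, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("Carrier-label permutation: %d/%d runs with p < %.3f ",
                     "(permutation p = %.4f)\n"),
              x$n_below_alpha, x$n_runs, x$alpha, x$permutation_p))
  if (x$n_failed) cat("  ", x$n_failed, "non-converged runs excluded\n")
  invisible(x)
}

#' Case-exclusion bootstrap
#'
#' Robustness defense that refits the primary model after randomly
#' removing `k` of the cancer cases (non-cases untouched), for each `k` in
#' `k_range`. Reported per `k`: the fraction of runs in which the carrier
#' term keeps significance below `alpha_keep`. Reported overall: the mean
#' carrier hazard ratio across all runs of all `k`, with a normal-theory
#' 95% confidence interval for that mean.
#'
#' @param cohort Cohort table.
#' @param k_range Integer vector of case-exclusion counts (default 2:9).
#' @param n_runs_per_k Runs per exclusion count.
#' @param alpha_keep Significance retention threshold (default 0.05).
#' @param seed Integer seed.
#' @param terms Model terms (default [primary_terms()]).
#' @return Object of class `case_exclusion_result`: `by_k` (data frame
#'   with k, n_runs, retention), `hr_all` (all HR estimates), `mean_hr`,
#'   `mean_hr_ci` (95% CI of the mean), `alpha_keep`, `seed`.
#' @export
case_exclusion_bootstrap <- function(cohort, k_range = 2:9,
                                     n_runs_per_k = 1000, alpha_keep = 0.05,
                                     seed = 1, terms = primary_terms()) {
  cohort <- as.data.frame(cohort)
  if (is.null(cohort$carrier)) {
    cohort$carrier <- as.integer(cohort$genotype %in% c("TT", "TG"))
  }
  cases <- which(cohort$event == 1)
  if (max(k_range) >= length(cases)) {
    stop("cannot exclude ", max(k_range), " of ", length(cases), " cases")
  }
  set.seed(seed)
  by_k <- data.frame(k = k_range, n_runs = 0L, n_failed = 0L,
                     retention = NA_real_, mean_hr = NA_real_)
  hr_all <- numeric(0)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    hrs <- rep(NA_real_, n_runs_per_k)
    ps <- rep(NA_real_, n_runs_per_k)
    for (run in seq_len(n_runs_per_k)) {
      drop_rows <- if (k > 0) cases[sample.int(length(cases), k)] else integer(0)
      sub <- if (length(drop_rows)) cohort[-drop_rows, , drop = FALSE] else cohort
      fit <- tryCatch(fit_cox(sub, terms = terms, cluster_by = "pedigree_id"),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$converged) {
        hrs[run] <- fit$table["carrier", "hr"]
        ps[run] <- fit$table["carrier", "p"]
      }
    }
    ok <- !is.na(ps)
    if (mean(!ok) > 0.01) {
      warning(sprintf("k = %d: %d of %d runs failed to converge",
                      k, sum(!ok), n_runs_per_k))
    }
    by_k$n_runs[ki] <- sum(ok)
    by_k$n_failed[ki] <- sum(!ok)
    by_k$retention[ki] <- mean(ps[ok] < alpha_keep)
    by_k$mean_hr[ki] <- mean(hrs[ok])
    hr_all <- c(hr_all, hrs[ok])
  }
  m <- mean(hr_all)
  se <- stats::sd(hr_all) / sqrt(length(hr_all))
  structure(list(by_k = by_k, hr_all = hr_all, mean_hr = m,
                 mean_hr_ci = m + c(-1, 1) * stats::qnorm(0.975) * se,
                 alpha_keep = alpha_keep, seed = seed),
            class = "case_exclusion_result")
}

#' @export
print.case_exclusion_result <- function(x, ...) {
  cat(sprintf("Case-exclusion bootstrap (alpha_keep = %.3f)\n", x$alpha_keep))
  print(transform(x$by_k, retention = round(retention, 3),
                  mean_hr = round(mean_hr, 3)))
  cat(sprintf("Mean HR over all runs: %.2f (95%% CI %.2f-%.2f)\n",
              x$mean_hr, x$mean_hr_ci[1], x$mean_hr_ci[2]))
  invisible(x)
}
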