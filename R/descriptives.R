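#' Between-group descriptive comparisons
#'
#' Compares baseline characteristics between two groups (by default minor
#' allele carriers versus major-allele homozygotes): continuous variables
#' by the large-sample z-test on means, binary variables by Fisher's exact
#' test (two-sided, summing all tables no more probable than the observed
#' one).
#'
#' @param cohort Cohort table.
#' @param group Name of the 0/1 grouping column (default `"carrier"`).
#' @param variables Variables to compare; binary variables are detected as
#'   having at most two distinct values.
#' @return Data frame of class `group_comparison`: variable, type,
#'   per-group summaries, test, p.
#' @export
compare_groups <- function(cohort, group = "carrier",
                           variables = setdiff(primary_terms(), "carrier")) {
  cohort <- as.data.frame(cohort)
  if (group == "carrier" && is.null(cohort$carrier)) {
    cohort$carrier <- as.integer(cohort$genotype %in% c("TT", "TG"))
  }
  g <- cohort[[group]]
  stopifnot(length(unique(g)) == 2)
  lev <- sort(unique(g))
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    x1 <- x[g == lev[2]]; x0 <- x[g == lev[1]]
    binary <- length(unique(stats::na.omit(x))) <= 2
    if (binary) {
      tab <- table(factor(g, levels = lev), factor(x, levels = sort(unique(x))))
      p <- if (ncol(tab) < 2) NA_real_ else stats::fisher.test(tab)$p.value
      data.frame(variable = v, type = "binary",
                 group1 = mean(x1), group0 = mean(x0),
                 test = "fisher_exact", p = p)
    } else {
      if (stats::sd(x1) == 0 && stats::sd(x0) == 0) {
        return(data.frame(variable = v, type = "continuous",
                          group1 = mean(x1), group0 = mean(x0),
                          test = "z", p = NA_real_))
      }
      z <- (mean(x1) - mean(x0)) /
        sqrt(stats::var(x1) / length(x1) + stats::var(x0) / length(x0))
      data.frame(variable = v, type = "continuous",
                 group1 = mean(x1), group0 = mean(x0),
                 test = "z", p = 2 * stats::pnorm(-abs(z)))
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Within-individual paired changes
#'
#' Baseline versus follow-up comparison on the same subjects: continuous
#' variables by the paired t-test with a confidence interval for the mean
#' change; binary variables by McNemar's test (without continuity
#' correction) with a Wald interval for the difference of proportions
#' built from the discordant counts. When no pairs are discordant the
#' McNemar statistic is undefined and an exact binomial fallback (p = 1)
#' is flagged.
#'
#' @param baseline,followup Data frames with the same subjects in the same
#'   order.
#' @param variables Variables to compare.
#' @return Data frame of class `paired_change`: variable, type, baseline
#'   and follow-up summaries, change, CI bounds, test, p.
#' @export
paired_change <- function(baseline, followup, variables) {
  stopifnot(nrow(baseline) == nrow(followup))
  n <- nrow(baseline)
  rows <- lapply(variables, function(v) {
    b <- baseline[[v]]; f <- followup[[v]]
    binary <- length(unique(stats::na.omit(c(b, f)))) <= 2
    if (binary) {
      n01 <- sum(b == 0 & f == 1)   # discordant: gained the characteristic
      n10 <- sum(b == 1 & f == 0)   # discordant: lost it
      change <- 100 * (mean(f) - mean(b))
      if (n01 + n10 == 0) {
        return(data.frame(variable = v, type = "binary",
                          baseline = 100 * mean(b), followup = 100 * mean(f),
                          change = change, ci_lo = change, ci_hi = change,
                          test = "exact_binomial_fallback", p = 1))
      }
      stat <- (n01 - n10)^2 / (n01 + n10)
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
      se <- sqrt(n01 + n10 - (n01 - n10)^2 / n) / n
      ci <- change + c(-1, 1) * stats::qnorm(0.975) * 100 * se
      data.frame(variable = v, type = "binary",
                 baseline = 100 * mean(b), followup = 100 * mean(f),
                 change = change, ci_lo = ci[1], ci_hi = ci[2],
                 test = "mcnemar", p = p)
    } else {
      tt <- stats::t.test(f, b, paired = TRUE)
      data.frame(variable = v, type = "continuous",
                 baseline = mean(b), followup = mean(f),
                 change = unname(tt$estimate),
                 ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                 test = "paired_t", p = tt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("paired_change", "data.frame")
  out
}

#' Odds ratio from a 2x2 table or a logistic fit
#'
#' The table form computes OR = ad/bc with a Woolf (log-scale Wald)
#' confidence interval, applying the Haldane-Anscombe 0.5 correction when
#' a cell is empty. The vector form fits logistic regression of case on
#' exposure and optional covariates with Wald inference; without
#' covariates it agrees with the table form.
#'
#' @param a,b,c_,d Counts: exposed cases, exposed controls, unexposed
#'   cases, unexposed controls.
#' @param case,exposure Alternative vector interface (0/1 each).
#' @param covariates Optional data frame of adjustment covariates for the
#'   vector form.
#' @return List of class `odds_ratio_result`: `or`, `ci_lo`, `ci_hi`,
#'   `p`, `corrected` (zero-cell flag), `method`.
#' @examples
#' odds_ratio(10, 20, 30, 40)$or  # 0.667
#' @export
odds_ratio <- function(a = NULL, b = NULL, c_ = NULL, d = NULL,
                       case = NULL, exposure = NULL, covariates = NULL) {
  if (!is.null(case)) {
    dat <- data.frame(.case = case, .exp = exposure)
    if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
    fit <- stats::glm(.case ~ ., data = dat, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-12, maxit = 100))
    est <- stats::coef(fit)[".exp"]
    se <- sqrt(diag(stats::vcov(fit))[".exp"])
    return(structure(list(
      or = unname(exp(est)),
      ci_lo = unname(exp(est - stats::qnorm(0.975) * se)),
      ci_hi = unname(exp(est + stats::qnorm(0.975) * se)),
      p = unname(2 * stats::pnorm(-abs(est / se))),
      corrected = FALSE, method = "logistic"), class = "odds_ratio_result"))
  }
  counts <- c(a, b, c_, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts == 0) && sum(counts) == 0) stop("empty table")
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  lor <- log(counts[1] * counts[4] / (counts[2] * counts[3]))
  se <- sqrt(sum(1 / counts))
  structure(list(
    or = exp(lor),
    ci_lo = exp(lor - stats::qnorm(0.975) * se),
    ci_hi = exp(lor + stats::qnorm(0.975) * se),
    p = 2 * stats::pnorm(-abs(lor / se)),
    corrected = corrected, method = "woolf"), class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f; p = %.3f) [%s%s]\n",
              x$or, x$ci_lo, x$ci_hi, x$p, x$method,
              if (x$corrected) ", 0.5 zero-cell correction" else ""))
  invisible(x)
}
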