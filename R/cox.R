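#' Family-clustered Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with step-halving
#' and reports, alongside the model-based covariance, a cluster-robust
#' sandwich covariance in which per-subject score residuals are summed
#' within pedigrees before the outer product. Hazard ratios, Wald
#' confidence intervals and p-values are based on the robust standard
#' errors, which is the appropriate inference for family-based cohorts in
#' which risk factors cluster within pedigrees.
#'
#' @param cohort Data frame with columns `time_y` (> 0), `event` (0/1),
#'   the covariates named in `terms`, and the cluster column.
#' @param terms Character vector of covariate column names; a `carrier`
#'   column is derived from `genotype` when requested but absent.
#' @param cluster_by Name of the cluster column (default `"pedigree_id"`).
#'   With every subject in its own cluster the sandwich reduces to the
#'   ordinary unclustered robust variance.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol Convergence tolerance on the Euclidean norm of the score.
#' @param max_iter Maximum Newton iterations.
#'
#' @return An object of class `cox_fit`: `beta`, `cov_model`, `cov_robust`,
#'   a per-term `table` (beta, robust/model SE, HR, 95% CI, p), `loglik`,
#'   `n`, `n_events`, `converged`, and internal state reused by
#'   [supremum_ph_test()].
#' @examples
#' coh <- simulate_cohort(generator_config(seed = 1))$cohort
#' fit <- fit_cox(coh, terms = c("carrier", "sex", "age_y"))
#' fit$table["carrier", ]
#' @export
fit_cox <- function(cohort, terms, cluster_by = "pedigree_id",
                    ties = c("breslow", "efron"),
                    tol = 1e-9, max_iter = 100) {
  ties <- match.arg(ties)
  cohort <- as.data.frame(cohort)
  if ("carrier" %in% terms && is.null(cohort$carrier)) {
    cohort$carrier <- as.integer(cohort$genotype %in% c("TT", "TG"))
  }
  missing_cols <- setdiff(c("time_y", "event", terms), names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  time <- as.numeric(cohort$time_y)
  status <- as.integer(cohort$event)
  if (any(time <= 0)) stop("all follow-up times must be positive")
  if (!all(status %in% c(0L, 1L))) stop("event must be 0/1")
  if (sum(status) < 1) stop("no events in cohort")
  X <- as.matrix(cohort[, terms, drop = FALSE])
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant covariate(s): ", paste(terms[sds == 0], collapse = ", "))
  }
  cluster <- if (is.null(cohort[[cluster_by]])) seq_len(nrow(X)) else
    cohort[[cluster_by]]

  n <- nrow(X)
  p <- ncol(X)
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)

  ord <- order(time)
  time <- time[ord]; status <- status[ord]
  Xc <- Xc[ord, , drop = FALSE]
  cluster <- cluster[ord]

  ut <- unique(time[status == 1L])          # ascending
  G <- length(ut)
  r <- match(ut, time)                      # first risk-set index per event time
  grp <- findInterval(time, ut)             # last event time <= t_i (0 if none)
  ev_grp <- grp[status == 1L]               # group of each death
  d <- as.numeric(tabulate(ev_grp, nbins = G))
  Xev <- Xc[status == 1L, , drop = FALSE]
  xdsum <- rowsum(Xev, ev_grp, reorder = TRUE)    # G x p sums of x over deaths

  ij <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  XX <- Xc[, ij[, 1], drop = FALSE] * Xc[, ij[, 2], drop = FALSE]  # n x p(p+1)/2

  revcs <- function(m) {
    m <- as.matrix(m)
    apply(m[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  }
  unpack <- function(v) {
    S <- matrix(0, p, p)
    S[cbind(ij[, 1], ij[, 2])] <- v
    S[cbind(ij[, 2], ij[, 1])] <- v
    S
  }

  # Breslow quantities at a given beta; Efron adjusts tied-death denominators
  tie_w <- function(w) rowsum(w[status == 1L], ev_grp, reorder = TRUE)
  eval_at <- function(beta) {
    eta <- drop(Xc %*% beta)
    w <- exp(pmin(eta, 300))
    cw <- revcs(w)
    cXw <- revcs(Xc * w)
    cXXw <- revcs(XX * w)
    S0 <- cw[r, 1]
    S1 <- cXw[r, , drop = FALSE]
    S2v <- cXXw[r, , drop = FALSE]
    ll <- sum(eta[status == 1L])
    U <- colSums(xdsum)
    I <- matrix(0, p, p)
    if (ties == "breslow" || max(d) == 1) {
      ll <- ll - sum(d * log(S0))
      U <- U - colSums(S1 * (d / S0))
      for (j in seq_len(G)) {
        xbar <- S1[j, ] / S0[j]
        I <- I + d[j] * (unpack(S2v[j, ]) / S0[j] - tcrossprod(xbar))
      }
    } else {
      s0t <- drop(tie_w(w))
      s1t <- rowsum((Xc * w)[status == 1L, , drop = FALSE], ev_grp, reorder = TRUE)
      s2t <- rowsum((XX * w)[status == 1L, , drop = FALSE], ev_grp, reorder = TRUE)
      for (j in seq_len(G)) {
        for (k in seq_len(d[j]) - 1) {
          f <- k / d[j]
          s0 <- S0[j] - f * s0t[j]
          s1 <- S1[j, ] - f * s1t[j, ]
          s2 <- unpack(S2v[j, ] - f * s2t[j, ])
          ll <- ll - log(s0)
          U <- U - s1 / s0
          I <- I + s2 / s0 - tcrossprod(s1 / s0)
        }
      }
    }
    list(ll = ll, U = U, I = I, w = w, S0 = S0, S1 = S1)
  }

  beta <- rep(0, p)
  st <- eval_at(beta)
  converged <- FALSE
  diagnostic <- NULL
  iter <- 0
  for (iter in seq_len(max_iter)) {
    delta <- tryCatch(solve(st$I, st$U), error = function(e) NULL)
    if (is.null(delta)) {
      diagnostic <- "singular information matrix"
      break
    }
    step <- 1
    repeat {
      cand <- beta + step * delta
      st_new <- eval_at(cand)
      if (is.finite(st_new$ll) && st_new$ll >= st$ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    beta <- beta + step * delta
    st <- st_new
    if (sqrt(sum(st$U^2)) < tol) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 15) {
      diagnostic <- paste0("estimate diverging (|beta| > 15); likely monotone ",
                           "likelihood: no events in one level of a covariate")
      break
    }
  }
  if (!converged && is.null(diagnostic)) diagnostic <- "max iterations reached"

  cov_model <- tryCatch(solve(st$I), error = function(e) matrix(NA_real_, p, p))

  # Breslow-form score residuals (exact when no ties or ties = "breslow")
  xbar <- st$S1 / st$S0                     # G x p
  h <- d / st$S0                            # baseline hazard increments
  cumh <- cumsum(h)
  cumhx <- apply(xbar * h, 2, cumsum)       # G x p
  Hi <- c(0, cumh)[grp + 1]
  HXi <- rbind(0, cumhx)[grp + 1, , drop = FALSE]
  dres <- matrix(0, n, p)
  dres[status == 1L, ] <- Xev - xbar[ev_grp, , drop = FALSE]
  score_resid <- dres - st$w * (Xc * Hi - HXi)

  Gmat <- rowsum(score_resid, cluster, reorder = FALSE)
  cov_robust <- if (all(is.finite(cov_model))) {
    cov_model %*% crossprod(Gmat) %*% cov_model
  } else matrix(NA_real_, p, p)

  se_rob <- sqrt(pmax(diag(cov_robust), 0))
  se_mod <- sqrt(pmax(diag(cov_model), 0))
  z <- beta / se_rob
  tab <- data.frame(
    beta = beta,
    se = se_rob,
    se_model = se_mod,
    hr = exp(beta),
    ci_lo = exp(beta - stats::qnorm(0.975) * se_rob),
    ci_hi = exp(beta + stats::qnorm(0.975) * se_rob),
    p = 2 * stats::pnorm(-abs(z)),
    row.names = terms
  )
  dimnames(cov_model) <- dimnames(cov_robust) <- list(terms, terms)

  structure(list(
    terms = terms, beta = stats::setNames(beta, terms),
    cov_model = cov_model, cov_robust = cov_robust,
    table = tab, loglik = st$ll, n = n, n_events = sum(status),
    converged = converged, diagnostic = diagnostic, iter = iter,
    ties = ties, centers = centers,
    detail = list(time = time, status = status, X = Xc, w = st$w,
                  ut = ut, d = d, S0 = st$S0, xbar = xbar, grp = grp,
                  ev_grp = ev_grp, xdsum = xdsum, h = h,
                  score_resid = score_resid, info = st$I,
                  cluster = cluster, order = ord)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox PH fit (%s ties), n = %d, events = %d%s\n", x$ties, x$n,
              x$n_events, if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  print(round(x$table[, c("hr", "ci_lo", "ci_hi", "p")], digits))
  invisible(x)
}

#' Formatted hazard-ratio report for the carrier term
#'
#' @param fit A converged [fit_cox()] object containing the term.
#' @param term Term to report (default `"carrier"`).
#' @return List with `hr`, `ci_lo`, `ci_hi`, `p` at machine precision and a
#'   `formatted` string with HR/CI to 2 decimals and p to 3.
#' @export
carrier_hr_report <- function(fit, term = "carrier") {
  stopifnot(inherits(fit, "cox_fit"))
  if (!term %in% rownames(fit$table)) stop("term '", term, "' not in fit")
  row <- fit$table[term, ]
  list(hr = row$hr, ci_lo = row$ci_lo, ci_hi = row$ci_hi, p = row$p,
       formatted = sprintf("%.2f (%.2f-%.2f; p=%.3f)",
                           row$hr, row$ci_lo, row$ci_hi, row$p))
}

#' Supremum-type test of the proportional-hazards assumption
#'
#' Kolmogorov-type diagnostic based on the observed score process: the
#' cumulative sum over event times of the standardized Schoenfeld
#' contributions per covariate. Under proportional hazards the process is a
#' mean-zero bridge; its supremum is compared against replicates generated
#' by attaching standard-normal multipliers to per-subject score-residual
#' processes (with the usual correction for estimation of the regression
#' coefficients).
#'
#' @param fit A converged [fit_cox()] object.
#' @param n_replications Number of multiplier replicates (default 1000).
#' @param seed Integer seed for the multipliers.
#' @return Object of class `ph_test`: per-term `sup_statistic`, `p`, and
#'   `n_replications`. p-values lie in `[1/(n_replications+1), 1]`.
#' @export
supremum_ph_test <- function(fit, n_replications = 1000, seed = 1) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) stop("refusing to test a non-converged fit")
  dt <- fit$detail
  n <- fit$n
  p <- length(fit$terms)
  G <- length(dt$ut)
  status <- dt$status

  # observed process: cumulative score over event times, scaled by sqrt(n)
  inc <- dt$xdsum - dt$xbar * dt$d                      # G x p
  Wobs <- apply(inc, 2, cumsum) / sqrt(n)
  Wobs <- matrix(Wobs, nrow = G)
  sup_obs <- apply(abs(Wobs), 2, max)

  # per-subject score process evaluated at each event time, stacked G*p
  # columns; column (j-1)*p + k holds subject contributions U_ik(t_j)
  cumh <- cumsum(dt$h)
  cumhx <- apply(dt$xbar * dt$h, 2, cumsum)
  M <- matrix(0, n, G * p)
  Xev <- dt$X[status == 1L, , drop = FALSE]
  dterm <- matrix(0, n, p)
  dterm[status == 1L, ] <- Xev - dt$xbar[dt$ev_grp, , drop = FALSE]
  for (j in seq_len(G)) {
    gi <- pmin(dt$grp, j)                               # events up to min(t_i, t_j)
    Hij <- c(0, cumh)[gi + 1]
    HXij <- rbind(0, cumhx)[gi + 1, , drop = FALSE]
    died_by_j <- status == 1L & dt$grp <= j
    dt_j <- dterm
    dt_j[!died_by_j, ] <- 0
    M[, (j - 1) * p + seq_len(p)] <- dt_j - dt$w * (dt$X * Hij - HXij)
  }

  # partial information I(t_j) for the estimation correction:
  # I_j increment = d_j (S2_j/S0_j - xbar_j xbar_j'), accumulated over j
  w <- dt$w
  r <- match(dt$ut, dt$time)
  ij <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  XX <- dt$X[, ij[, 1], drop = FALSE] * dt$X[, ij[, 2], drop = FALSE]
  cXXw <- apply((XX * w)[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  cXXw <- matrix(cXXw, nrow = n)
  Ipart <- array(0, dim = c(G, p, p))
  acc <- matrix(0, p, p)
  for (j in seq_len(G)) {
    S2 <- matrix(0, p, p)
    S2[cbind(ij[, 1], ij[, 2])] <- cXXw[r[j], ]
    S2[cbind(ij[, 2], ij[, 1])] <- cXXw[r[j], ]
    acc <- acc + dt$d[j] * (S2 / dt$S0[j] - tcrossprod(dt$xbar[j, ]))
    Ipart[j, , ] <- acc
  }
  Iinv <- solve(dt$info)

  set.seed(seed)
  Gm <- matrix(stats::rnorm(n * n_replications), n, n_replications)
  R <- crossprod(Gm, M)                                 # nrep x (G*p)
  Cr <- crossprod(Gm, dt$score_resid) %*% Iinv          # nrep x p
  sup_star <- matrix(0, n_replications, p)
  for (k in seq_len(p)) {
    cols <- (seq_len(G) - 1) * p + k
    corr <- Cr %*% t(Ipart[, , k, drop = TRUE])         # nrep x G (row k of I(t) c)
    if (p == 1) corr <- Cr %*% t(matrix(Ipart[, 1, 1], ncol = 1))
    Wk <- (R[, cols, drop = FALSE] - corr) / sqrt(n)
    sup_star[, k] <- apply(abs(Wk), 1, max)
  }
  # replicates at or above the observed supremum, with a machine-noise floor
  # so degenerate processes (e.g. a single event time, where both are exact
  # zeros) count as ties rather than coin flips
  thresh <- pmax(sup_obs * (1 - 1e-9) - 1e-10, 0)
  pvals <- (colSums(sweep(sup_star, 2, thresh, ">=")) + 1) / (n_replications + 1)

  structure(list(sup_statistic = stats::setNames(sup_obs, fit$terms),
                 p = stats::setNames(pvals, fit$terms),
                 n_replications = n_replications),
            class = "ph_test")
}

#' @export
print.ph_test <- function(x, ...) {
  cat("Supremum test of proportional hazards (", x$n_replications,
      " multiplier replicates)\n", sep = "")
  print(data.frame(sup = round(x$sup_statistic, 3), p = round(x$p, 4)))
  invisible(x)
}

#' Cumulative incidence curves by carrier status
#'
#' Unadjusted curves are one minus the Kaplan-Meier estimator per group
#' with Greenwood standard errors. Sex/age-adjusted curves use direct
#' standardization: a proportional-hazards fit on sex and age within each
#' group, a Breslow baseline cumulative hazard, and averaging of the
#' implied survival over the whole cohort's sex/age distribution.
#'
#' @param cohort Cohort table with `time_y`, `event`, `carrier` (or
#'   `genotype`), `sex`, `age_y`.
#' @param group_by Grouping column (default `"carrier"`).
#' @param adjust `"none"` or `"sex_age"`.
#' @return List of class `incidence_curves`: one data frame per group with
#'   `time`, `incidence`, `se` (NA for adjusted curves), plus `adjusted`
#'   and `zero_event_groups` flags.
#' @export
cumulative_incidence <- function(cohort, group_by = "carrier",
                                 adjust = c("none", "sex_age")) {
  adjust <- match.arg(adjust)
  cohort <- as.data.frame(cohort)
  if (group_by == "carrier" && is.null(cohort$carrier)) {
    cohort$carrier <- as.integer(cohort$genotype %in% c("TT", "TG"))
  }
  groups <- sort(unique(cohort[[group_by]]))
  out <- list()
  zero_event <- character(0)
  for (g in groups) {
    sub <- cohort[cohort[[group_by]] == g, , drop = FALSE]
    gname <- as.character(g)
    if (sum(sub$event) == 0) {
      zero_event <- c(zero_event, gname)
      out[[gname]] <- data.frame(time = sort(unique(sub$time_y)),
                                 incidence = 0, se = 0)
      next
    }
    if (adjust == "none") {
      km <- survival::survfit(survival::Surv(time_y, event) ~ 1, data = sub)
      out[[gname]] <- data.frame(time = km$time,
                                 incidence = 1 - km$surv,
                                 se = km$std.err * km$surv)
    } else {
      fit <- fit_cox(sub, terms = c("sex", "age_y"), cluster_by = "pedigree_id")
      dtl <- fit$detail
      H0 <- cumsum(dtl$h)                    # baseline cumhaz at event times
      Z <- sweep(as.matrix(cohort[, c("sex", "age_y")]), 2, fit$centers)
      risk <- exp(drop(Z %*% fit$beta))
      inc <- vapply(H0, function(hh) 1 - mean(exp(-hh * risk)), numeric(1))
      out[[gname]] <- data.frame(time = dtl$ut, incidence = inc, se = NA_real_)
    }
  }
  structure(list(curves = out, adjusted = adjust,
                 zero_event_groups = zero_event),
            class = "incidence_curves")
}

#' @export
print.incidence_curves <- function(x, ...) {
  cat("Cumulative incidence (", x$adjusted, " adjustment)\n", sep = "")
  for (g in names(x$curves)) {
    cur <- x$curves[[g]]
    cat(sprintf("  group %s: final incidence %.4f at t = %.1f (%d steps)\n",
                g, cur$incidence[nrow(cur)], cur$time[nrow(cur)], nrow(cur)))
  }
  if (length(x$zero_event_groups)) {
    cat("  zero-event group(s):", paste(x$zero_event_groups, collapse = ", "), "\n")
  }
  invisible(x)
}
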