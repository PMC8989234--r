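#' Duplicate-measurement quality filter
#'
#' Methylation assays run in duplicate are kept as the mean of the two
#' readings unless the pair's sample standard deviation (|d1 - d2|/sqrt(2))
#' reaches 5 percentage points, in which case the measurement is
#' disregarded.
#'
#' @param dup1,dup2 Duplicate measurements in percent (0-100); vectorized.
#' @param sd_limit Disregard threshold in percentage points (default 5).
#' @return List with `keep` (logical), `value` (mean in percent, NA when
#'   dropped) and `pair_sd`.
#' @examples
#' qc_duplicate_filter(40, 50)$keep   # FALSE: SD 7.07
#' qc_duplicate_filter(60, 66)$value  # 63
#' @export
qc_duplicate_filter <- function(dup1, dup2, sd_limit = 5) {
  if (any(c(dup1, dup2) < 0 | c(dup1, dup2) > 100, na.rm = TRUE)) {
    stop("duplicate measurements must lie in [0, 100] percent")
  }
  pair_sd <- abs(dup1 - dup2) / sqrt(2)
  keep <- pair_sd < sd_limit
  value <- ifelse(keep, (dup1 + dup2) / 2, NA_real_)
  list(keep = keep, value = value, pair_sd = pair_sd)
}

#' Rank-based inverse-normal transformation
#'
#' Sorts the values, assigns average ranks to ties, and maps rank r to the
#' normal quantile of (r - 3/8)/(n + 1/4) (Blom offset). Missing values
#' propagate; n counts the non-missing values.
#'
#' @param values Numeric vector.
#' @param offset Rank offset constant (default 3/8).
#' @return Transformed vector of the same length.
#' @examples
#' rank_inverse_normal(c(5, 1, 3))
#' @export
rank_inverse_normal <- function(values, offset = 3/8) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) stop("need at least two non-missing values")
  out <- rep(NA_real_, length(values))
  if (stats::var(values[ok]) == 0) {
    warning("all values identical; transform is degenerate (all zero)")
    out[ok] <- 0
    return(out)
  }
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - offset) / (n + 1 - 2 * offset))
  out
}

#' Covariate-standardized case outcome for PLS
#'
#' Regresses case status on the adjustment covariates by logistic
#' regression and returns the response residuals (observed minus fitted
#' probability), centered and scaled to unit variance. This is the
#' continuous outcome the PLS discriminant analysis predicts, so that the
#' methylation associations are standardized to the cohort's covariate
#' distribution. Under (quasi-)separation the logistic fit is replaced by
#' linear-probability residuals, with a warning.
#'
#' @param case 0/1 case indicator.
#' @param covariates Data frame of adjustment covariates (complete).
#' @return Numeric vector with attribute `method` (`"logistic"` or
#'   `"linear"`).
#' @export
adjusted_outcome <- function(case, covariates) {
  if (length(unique(case)) < 2) stop("case status is constant")
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(case))
  dat <- cbind(.case = case, covariates)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.case ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged) {
    warning("separation in the logistic adjustment; using linear-probability residuals")
    fit <- stats::lm(.case ~ ., data = dat)
    method <- "linear"
  } else {
    method <- "logistic"
  }
  res <- case - stats::fitted(fit)
  if (stats::sd(res) < 1e-12) {
    warning("residuals are numerically zero; covariates determine case status")
    out <- res
  } else {
    out <- (res - mean(res)) / stats::sd(res)
  }
  attr(out, "method") <- method
  out
}

#' Partial least squares fit (NIPALS, single response)
#'
#' Extracts up to `a_max` latent factors from column-standardized
#' predictors by the NIPALS algorithm: each factor's weight vector is the
#' normalized covariance of the deflated predictors with the response, the
#' score is the corresponding linear combination, and predictors are
#' deflated by the factor's loading. Scores of different factors are
#' orthogonal.
#'
#' @param X Predictor matrix (subjects x sites), typically the
#'   inverse-normal transformed methylation values.
#' @param y Continuous response (the covariate-standardized outcome).
#' @param a_max Maximum number of factors.
#' @return Object of class `pls_model`: scaling constants, `weights` W,
#'   `scores` T, `x_loadings` P, `y_loadings` q, `x_variance_explained`
#'   (percent per factor) and `n_factors` actually extracted.
#' @export
pls_fit <- function(X, y, a_max = 8) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= a_max) stop("need more subjects than factors")
  if (anyNA(X) || anyNA(y)) stop("missing values; exclude incomplete subjects first")
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(X)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("constant predictor column(s): ", paste(nm, collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2, means), 2, sds, "/")
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  ys <- (y - y_mean) / y_sd
  ssx_total <- sum(Xs^2)

  W <- matrix(0, p, a_max)
  TT <- matrix(0, n, a_max)
  P <- matrix(0, p, a_max)
  q <- numeric(a_max)
  xve <- numeric(a_max)
  Xa <- Xs
  A <- 0
  for (a in seq_len(a_max)) {
    w <- drop(crossprod(Xa, ys))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10) break
    w <- w / nw
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-10) break
    p_a <- drop(crossprod(Xa, t_a)) / tt
    q_a <- sum(t_a * ys) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    A <- a
    W[, a] <- w
    TT[, a] <- t_a
    P[, a] <- p_a
    q[a] <- q_a
    xve[a] <- 100 * tt * sum(p_a^2) / ssx_total
  }
  idx <- seq_len(A)
  structure(list(
    means = means, sds = sds, y_mean = y_mean, y_sd = y_sd,
    weights = W[, idx, drop = FALSE], scores = TT[, idx, drop = FALSE],
    x_loadings = P[, idx, drop = FALSE], y_loadings = q[idx],
    x_variance_explained = xve[idx], n_factors = A, n = n, p = p
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d factors on %d x %d data\n", x$n_factors, x$n, x$p))
  cat("  X-variance explained (%):",
      paste(sprintf("%.1f", x$x_variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Regression coefficients and predictions from a PLS model
#'
#' @param model A [pls_fit()] object.
#' @param n_factors Number of factors to use (default: all extracted).
#' @return `pls_coefficients`: coefficients on the standardized scale.
#' @export
pls_coefficients <- function(model, n_factors = model$n_factors) {
  stopifnot(inherits(model, "pls_model"), n_factors >= 1,
            n_factors <= model$n_factors)
  idx <- seq_len(n_factors)
  W <- model$weights[, idx, drop = FALSE]
  P <- model$x_loadings[, idx, drop = FALSE]
  q <- model$y_loadings[idx]
  drop(W %*% solve(crossprod(P, W), q))
}

#' @rdname pls_coefficients
#' @param newdata Matrix of predictors on the original scale.
#' @return `predict_pls`: predictions on the original response scale.
#' @export
predict_pls <- function(model, newdata, n_factors = model$n_factors) {
  newdata <- matrix(newdata, ncol = model$p)
  Xs <- sweep(sweep(newdata, 2, model$means), 2, model$sds, "/")
  if (n_factors == 0) return(rep(model$y_mean, nrow(Xs)))
  b <- pls_coefficients(model, n_factors)
  model$y_mean + model$y_sd * drop(Xs %*% b)
}

#' Leave-one-out PRESS curve
#'
#' For each candidate factor count A (0 to `a_max`), predicts each subject
#' from a model fitted to the remaining subjects and accumulates the
#' squared prediction residuals. A = 0 uses the leave-one-out mean of the
#' response.
#'
#' @param X Predictor matrix.
#' @param y Response.
#' @param a_max Maximum factor count.
#' @return List of class `press_cv`: `press` (named vector, factor counts
#'   0..a_max) and `sq_residuals` (n x (a_max+1) matrix of per-subject
#'   squared leave-one-out residuals).
#' @export
press_cv <- function(X, y, a_max = 8) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= a_max + 1) stop("too few subjects for leave-one-out with a_max factors")
  sq <- matrix(NA_real_, n, a_max + 1)
  for (i in seq_len(n)) {
    fit <- pls_fit(X[-i, , drop = FALSE], y[-i], a_max = a_max)
    sq[i, 1] <- (y[i] - mean(y[-i]))^2
    for (A in seq_len(a_max)) {
      Aeff <- min(A, fit$n_factors)
      pred <- if (Aeff == 0) mean(y[-i]) else
        predict_pls(fit, X[i, , drop = FALSE], Aeff)
      sq[i, A + 1] <- (y[i] - pred)^2
    }
  }
  press <- colSums(sq)
  names(press) <- 0:a_max
  structure(list(press = press, sq_residuals = sq), class = "press_cv")
}

#' van der Voet factor selection
#'
#' Compares each candidate factor count with the PRESS-minimizing count
#' through the paired difference of per-subject squared cross-validation
#' residuals. The null distribution of the summed difference is generated
#' by random sign flips; the selected model is the smallest factor count
#' whose two-sided p-value exceeds `p_threshold` (the minimum-PRESS model
#' itself has p = 1).
#'
#' @param cv A [press_cv()] result (or a matrix of per-subject squared
#'   residuals with factor counts 0.. in columns).
#' @param p_threshold Retention threshold (default 0.10).
#' @param n_randomizations Number of sign-flip draws.
#' @param seed Integer seed.
#' @return List of class `vdv_selection`: `selected` (factor count),
#'   `p_by_factors`, `press`, `a_min`.
#' @export
vdv_select <- function(cv, p_threshold = 0.10, n_randomizations = 2000,
                       seed = 1) {
  sq <- if (inherits(cv, "press_cv")) cv$sq_residuals else as.matrix(cv)
  if (anyNA(sq)) stop("residual matrix must be complete")
  n <- nrow(sq)
  counts <- 0:(ncol(sq) - 1)
  press <- colSums(sq)
  a_min <- counts[which.min(press)]
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n * n_randomizations, replace = TRUE),
                  n, n_randomizations)
  pvals <- vapply(seq_along(counts), function(ci) {
    d <- sq[, ci] - sq[, which.min(press)]
    Tobs <- sum(d)
    if (all(d == 0)) return(1)
    Tstar <- drop(crossprod(d, signs))
    mean(abs(Tstar) >= abs(Tobs))
  }, numeric(1))
  names(pvals) <- counts
  selected <- counts[which(pvals > p_threshold)[1]]
  structure(list(selected = selected, p_by_factors = pvals,
                 press = stats::setNames(press, counts), a_min = a_min),
            class = "vdv_selection")
}

#' @export
print.vdv_selection <- function(x, ...) {
  cat(sprintf("van der Voet selection: %d factor(s) (minimum PRESS at %d)\n",
              x$selected, x$a_min))
  print(round(rbind(PRESS = x$press, p = x$p_by_factors), 4))
  invisible(x)
}

#' Variable importance in projection (VIP) scores
#'
#' Wold's VIP summarizes each predictor's contribution to the retained
#' PLS factors, weighting squared normalized weights by each factor's
#' explained response variation. VIPs are normalized so their squares sum
#' to the number of predictors; scores above a threshold (conventionally
#' 1.1 here) flag influential sites.
#'
#' @param model A [pls_fit()] object.
#' @param n_factors Number of retained factors.
#' @return Numeric vector of VIP scores per predictor.
#' @export
vip_scores <- function(model, n_factors = model$n_factors) {
  stopifnot(inherits(model, "pls_model"), n_factors >= 1,
            n_factors <= model$n_factors)
  idx <- seq_len(n_factors)
  W <- model$weights[, idx, drop = FALSE]
  ss <- model$y_loadings[idx]^2 * colSums(model$scores[, idx, drop = FALSE]^2)
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  sqrt(model$p * drop(wn2 %*% ss) / sum(ss))
}

#' V-plot table: VIP against rescaled outcome correlation
#'
#' For each site, pairs its VIP score with the Pearson correlation between
#' the (transformed) site values and the adjusted outcome, centered across
#' sites and rescaled to unit SD. Sites with VIP above the threshold fall
#' in the higher-risk quadrant when the rescaled correlation is positive
#' and in the lower-risk quadrant when negative.
#'
#' @param model A [pls_fit()] object.
#' @param X Transformed predictor matrix used in the fit.
#' @param y_adj Adjusted outcome used in the fit.
#' @param vip_threshold VIP threshold (default 1.1).
#' @param n_factors Retained factors for the VIP computation.
#' @return Data frame of class `v_plot_table`: `site`, `vip`, `corr`,
#'   `corr_rescaled`, `quadrant`.
#' @export
v_plot <- function(model, X, y_adj, vip_threshold = 1.1,
                   n_factors = model$n_factors) {
  vip <- vip_scores(model, n_factors)
  corr <- drop(stats::cor(as.matrix(X), y_adj))
  corr_rescaled <- (corr - mean(corr)) / stats::sd(corr)
  quadrant <- ifelse(vip > vip_threshold & corr_rescaled > 0, "higher-risk",
              ifelse(vip > vip_threshold & corr_rescaled < 0, "lower-risk",
                     "below-threshold"))
  out <- data.frame(site = seq_along(vip), vip = vip, corr = corr,
                    corr_rescaled = corr_rescaled, quadrant = quadrant,
                    stringsAsFactors = FALSE)
  class(out) <- c("v_plot_table", "data.frame")
  out
}

#' Pairwise correlation matrix of methylation sites
#'
#' Pearson correlations with pairwise-complete handling of missing
#' values; pairs with fewer than three complete observations are set to
#' NA and flagged.
#'
#' @param X Methylation matrix (subjects x sites).
#' @return Correlation matrix with attribute `insufficient_pairs`.
#' @export
correlation_matrix <- function(X) {
  X <- as.matrix(X)
  cc <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(X))
  bad <- npair < 3
  diag(bad) <- FALSE
  cc[bad] <- NA_real_
  attr(cc, "insufficient_pairs") <- sum(bad) / 2
  cc
}

#' Full methylation discriminant analysis
#'
#' Pipeline over a 16-site methylation panel: subjects with any missing
#' site are excluded; each site is rank inverse-normal transformed; the
#' case outcome is standardized to the covariate distribution
#' ([adjusted_outcome()]); a PLS model is fitted; the factor count is
#' chosen by leave-one-out PRESS with the van der Voet test; VIP scores
#' and the V-plot quadrant classification are computed.
#'
#' @param methylation Matrix of methylation proportions (subjects x 16).
#' @param case 0/1 case indicator.
#' @param covariates Adjustment covariates (including the measurement
#'   time-interval variable).
#' @param a_max Maximum candidate factor count.
#' @param vip_threshold VIP threshold (default 1.1).
#' @param seed Seed for the van der Voet randomization.
#' @return List of class `plsda_result`: `model`, `selection`, `vip`,
#'   `v_plot`, `correlations`, `y_adj`, `n_used`, `n_excluded`.
#' @export
plsda_analysis <- function(methylation, case, covariates, a_max = 8,
                           vip_threshold = 1.1, seed = 1) {
  methylation <- as.matrix(methylation)
  complete <- stats::complete.cases(methylation) &
    stats::complete.cases(covariates) & !is.na(case)
  n_excluded <- sum(!complete)
  M <- methylation[complete, , drop = FALSE]
  case <- case[complete]
  covariates <- as.data.frame(covariates)[complete, , drop = FALSE]
  X <- apply(M, 2, rank_inverse_normal)
  y <- adjusted_outcome(case, covariates)
  model <- pls_fit(X, y, a_max = a_max)
  cv <- press_cv(X, y, a_max = min(a_max, model$n_factors))
  sel <- vdv_select(cv, seed = seed)
  A <- max(1, sel$selected)
  vp <- v_plot(model, X, y_adj = y, vip_threshold = vip_threshold,
               n_factors = A)
  structure(list(model = model, selection = sel,
                 vip = vip_scores(model, A), v_plot = vp,
                 correlations = correlation_matrix(M),
                 y_adj = y, n_used = sum(complete),
                 n_excluded = n_excluded, n_factors_used = A),
            class = "plsda_result")
}

#' @export
print.plsda_result <- function(x, ...) {
  cat(sprintf("PLS-DA on %d subjects (%d excluded for missingness)\n",
              x$n_used, x$n_excluded))
  cat(sprintf("  selected %d factor(s); X-variance explained: %s\n",
              x$selection$selected,
              paste(sprintf("%.1f%%",
                            x$model$x_variance_explained[seq_len(x$n_factors_used)]),
                    collapse = ", ")))
  above <- x$v_plot[x$v_plot$quadrant != "below-threshold", ]
  if (nrow(above)) {
    cat("  sites above VIP threshold:\n")
    print(above[, c("site", "vip", "corr_rescaled", "quadrant")], row.names = FALSE)
  } else cat("  no sites above the VIP threshold\n")
  invisible(x)
}
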