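test_that("duplicate QC drops pairs with SD of 5 points or more", {
  expect_false(qc_duplicate_filter(40, 50)$keep)       # SD 7.07
  expect_equal(qc_duplicate_filter(40, 50)$pair_sd, 10 / sqrt(2))
  ok <- qc_duplicate_filter(40, 40)
  expect_true(ok$keep); expect_equal(ok$value, 40)
  near <- qc_duplicate_filter(60, 66)                  # SD 4.24
  expect_true(near$keep); expect_equal(near$value, 63)
  expect_error(qc_duplicate_filter(-1, 50), "0, 100")
})

test_that("inverse-normal transform follows the Blom formula", {
  got <- rank_inverse_normal(c(5, 1, 3))
  expect_equal(got, qnorm((c(3, 1, 2) - 3/8) / 3.25), tolerance = 1e-12)
  expect_equal(round(got, 4), c(0.8694, -0.8694, 0))

  # order equivariance and odd-n symmetry
  set.seed(1)
  x <- rnorm(41)
  perm <- sample(41)
  expect_equal(rank_inverse_normal(x)[perm], rank_inverse_normal(x[perm]))
  expect_equal(mean(rank_inverse_normal(x)), 0, tolerance = 1e-12)

  # ties get average ranks; missing propagates
  y <- c(2, 2, 9, NA)
  ty <- rank_inverse_normal(y)
  expect_equal(ty[1], ty[2])
  expect_true(is.na(ty[4]))
  expect_warning(z <- rank_inverse_normal(c(3, 3, 3)), "identical")
  expect_equal(z, c(0, 0, 0))
})

test_that("covariate standardization preserves the outcome under a null", {
  set.seed(2)
  cors <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 400
    case <- rbinom(n, 1, 0.08)
    covs <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.5))
    cor(adjusted_outcome(case, covs), case)
  }, numeric(1))
  expect_gt(mean(cors), 0.95)

  expect_error(adjusted_outcome(rep(0, 50), data.frame(a = rnorm(50))),
               "constant")
  set.seed(3)
  case <- rbinom(120, 1, 0.3)
  expect_warning(
    expect_warning(out <- adjusted_outcome(case, data.frame(a = case)),
                   "separation"),
    "zero")
  expect_equal(attr(out, "method"), "linear")
})

test_that("NIPALS agrees with the Krylov-subspace representation", {
  set.seed(7)
  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- X %*% c(1, -0.5, 0, 0.2) + rnorm(20)
  mod <- pls_fit(X, y, a_max = 3)
  for (A in 1:3) {
    expect_lt(max(abs(pls_coefficients(mod, A) - pls_krylov_oracle(X, y, A))),
              1e-8)
  }
})

test_that("PLS degenerates correctly at the boundaries", {
  set.seed(8)
  x <- matrix(rnorm(30), 30, 1)
  y <- 2 * x + rnorm(30, sd = 0.5)
  mod <- pls_fit(x, y, a_max = 1)
  expect_equal(abs(mod$weights[1, 1]), 1, tolerance = 1e-12)
  pred <- predict_pls(mod, x, 1)
  expect_equal(1 - sum((y - pred)^2) / sum((y - mean(y))^2),
               cor(x, y)[1]^2, tolerance = 1e-10)

  # noiseless two-factor structure: two factors explain all X variance
  TT <- matrix(rnorm(60 * 2), 60, 2)
  P <- matrix(rnorm(16 * 2), 16, 2)
  X2 <- TT %*% t(P)
  y2 <- TT %*% c(1, -1)
  mod2 <- pls_fit(X2, y2, a_max = 4)
  expect_equal(sum(mod2$x_variance_explained[1:2]), 100, tolerance = 1e-6)

  Xc <- cbind(rnorm(20), 1)
  expect_error(pls_fit(Xc, rnorm(20)), "constant")
})

test_that("PLS scores are orthogonal and one factor reduces to OLS on the score", {
  set.seed(9)
  X <- matrix(rnorm(50 * 16), 50, 16)
  y <- rnorm(50)
  mod <- pls_fit(X, y, a_max = 5)
  S <- crossprod(mod$scores)
  off <- abs(S[upper.tri(S)])
  lim <- 1e-8 * sqrt(outer(diag(S), diag(S)))[upper.tri(S)]
  expect_true(all(off < lim))

  ys <- (y - mean(y)) / sd(y)
  expect_equal(mod$y_loadings[1],
               unname(coef(lm(ys ~ mod$scores[, 1] - 1))), tolerance = 1e-10)

  # full-rank extraction accounts for all of X
  X5 <- matrix(rnorm(40 * 5), 40, 5)
  mod5 <- pls_fit(X5, rnorm(40), a_max = 5)
  expect_equal(sum(mod5$x_variance_explained), 100, tolerance = 1e-8)
})

test_that("leave-one-out PRESS matches hand computation and overfits on noise", {
  cv0 <- press_cv(matrix(rnorm(9), 3, 3), c(1, 2, 3), a_max = 0)
  expect_equal(unname(cv0$press["0"]), 4.5, tolerance = 1e-12)

  # fitting factors to pure noise cannot beat the leave-one-out mean
  worse <- vapply(1:30, function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(40 * 8), 40, 8)
    y <- rnorm(40)
    pr <- press_cv(X, y, a_max = 4)$press
    pr["1"] >= pr["0"]
  }, logical(1))
  expect_gte(mean(worse), 0.9)

  # exact linear signal along the dominant direction: PRESS(1) near zero
  set.seed(10)
  scores <- rnorm(40)
  X <- scores %*% t(c(2, 1, -1, 0.5)) + matrix(rnorm(160, sd = 1e-4), 40, 4)
  y <- scores
  pr <- press_cv(X, y, a_max = 2)$press
  expect_lt(pr["1"] / pr["0"], 1e-4)
  expect_error(press_cv(matrix(rnorm(12), 4, 3), rnorm(4), a_max = 4), "few")
})

test_that("van der Voet selection compares against the minimum-PRESS model", {
  set.seed(11)
  base <- matrix(abs(rnorm(50)), 50, 1)
  sq <- cbind(10 * base, base)        # factor counts 0 and 1
  sel <- vdv_select(sq, seed = 1)
  expect_equal(sel$a_min, 1)
  expect_equal(unname(sel$p_by_factors["1"]), 1)
  expect_lte(sel$p_by_factors["0"], 0.001)
  expect_equal(sel$selected, 1)

  # the minimum itself is always selectable
  sq2 <- cbind(base, base)
  sel2 <- vdv_select(sq2, seed = 2)
  expect_equal(unname(sel2$p_by_factors["0"]), 1)
  expect_equal(sel2$selected, 0)
})

test_that("two-factor recovery holds on generator-default methylation", {
  picks <- vapply(1:10, function(s) {
    sim <- simulate_cohort(generator_config(seed = s))
    m <- sim$methylation
    covs <- data.frame(
      time_interval_y = m$time_interval_y,
      sim$cohort[match(m$ids, sim$cohort$id),
                 c("sex", "age_y", "bmi", "chol_ratio", "creat_umol_l",
                   "smoker", "drinker", "antiplatelet")])
    plsda_analysis(m$methylation, m$case, covs, seed = s + 100)$selection$selected
  }, numeric(1))
  expect_gte(mean(picks == 2), 0.8)
})

test_that("VIP scores follow Wold's normalization", {
  set.seed(12)
  X <- matrix(rnorm(60 * 16), 60, 16)
  y <- X[, 1] - X[, 2] + rnorm(60)
  mod <- pls_fit(X, y, a_max = 4)
  expect_equal(sum(vip_scores(mod, 4)^2), 16, tolerance = 1e-6)

  uniform <- structure(list(
    weights = matrix(rep(1 / 4, 16), 16, 1),
    scores = matrix(rnorm(20), 20, 1), y_loadings = 0.7, p = 16,
    n_factors = 1), class = "pls_model")
  expect_equal(vip_scores(uniform, 1), rep(1, 16), tolerance = 1e-12)

  sparse <- structure(list(
    weights = matrix(c(1, 1, rep(0, 14)) / sqrt(2), 16, 1),
    scores = matrix(rnorm(20), 20, 1), y_loadings = 0.7, p = 16,
    n_factors = 1), class = "pls_model")
  expect_equal(vip_scores(sparse, 1), c(sqrt(8), sqrt(8), rep(0, 14)),
               tolerance = 1e-12)
})

test_that("V-plot quadrants classify planted sites by sign", {
  sim <- simulate_cohort(generator_config(seed = 2))
  m <- sim$methylation
  covs <- data.frame(
    time_interval_y = m$time_interval_y,
    sim$cohort[match(m$ids, sim$cohort$id),
               c("sex", "age_y", "bmi", "chol_ratio", "creat_umol_l",
                 "smoker", "drinker", "antiplatelet")])
  res <- plsda_analysis(m$methylation, m$case, covs, seed = 77)
  vp <- res$v_plot
  expect_setequal(vp$site[vp$quadrant == "higher-risk"], c(11, 12))
  expect_setequal(vp$site[vp$quadrant == "lower-risk"], c(2, 13))

  # threshold zero classifies every site by sign alone
  vp0 <- v_plot(res$model, apply(m$methylation, 2, rank_inverse_normal),
                res$y_adj, vip_threshold = 0, n_factors = res$n_factors_used)
  expect_true(all(vp0$quadrant != "below-threshold"))
  expect_equal(vp0$quadrant == "higher-risk", vp0$corr_rescaled > 0)
})

test_that("correlation matrix handles degenerate and missing columns", {
  x <- rnorm(30)
  X <- cbind(a = x, b = x, c = -x, d = rnorm(30))
  cc <- correlation_matrix(X)
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
  expect_true(isSymmetric(cc))
  expect_equal(unname(diag(cc)), rep(1, 4))

  Xm <- X
  Xm[1:28, "d"] <- NA                  # only 2 complete pairs with d
  ccm <- correlation_matrix(Xm)
  expect_true(is.na(ccm["a", "d"]))
  expect_gt(attr(ccm, "insufficient_pairs"), 0)
})

test_that("subjects with missing sites are excluded from the discriminant fit", {
  sim <- simulate_cohort(generator_config(seed = 3))
  m <- sim$methylation
  meth <- m$methylation
  meth[5:14, 3] <- NA
  covs <- data.frame(
    time_interval_y = m$time_interval_y,
    sim$cohort[match(m$ids, sim$cohort$id), c("sex", "age_y")])
  res <- plsda_analysis(meth, m$case, covs, seed = 5)
  expect_equal(res$n_excluded, 10)
  expect_equal(res$n_used, 919)
})
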