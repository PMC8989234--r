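# Independent oracles used to freeze expected values. Each is a deliberately
# naive route (enumeration, closed form, brute-force search) kept separate
# from the implementation it checks.

# Hardy-Weinberg exact p by full enumeration of genotype configurations
# consistent with the observed allele counts, using plain factorials.
hwe_oracle <- function(n_minor_hom, n_het, n_major_hom) {
  n <- n_minor_hom + n_het + n_major_hom
  n_minor <- 2 * n_minor_hom + n_het
  if (n_minor == 0 || n_minor == 2 * n) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  probs <- vapply(hets, function(h) {
    a <- (n_minor - h) / 2          # minor homozygotes
    c_ <- n - a - h                 # major homozygotes
    if (a < 0 || c_ < 0) return(0)
    exp(lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(c_) +
          h * log(2) +
          lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n))
  }, numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of the probabilities of all tables with the same margins whose
# probability does not exceed that of the observed table.
fisher_oracle <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  lo <- max(0, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  probs <- exp(lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k))
  obs <- probs[match(a, xs)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force maximizer of the Cox partial likelihood for a single binary
# covariate with distinct event times (no ties).
cox_brute_force <- function(time, event, x, lower = -5, upper = 5) {
  loglik <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  stats::optimize(loglik, c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# PLS regression coefficients via the Krylov-subspace representation
# (Helland): B_A = K (K' S K)^{-1} K' s with s = X'y, S = X'X and
# K = [s, S s, S^2 s, ...], computed on the standardized scale.
pls_krylov_oracle <- function(X, y, A) {
  Xs <- scale(X)
  ys <- drop(scale(y))
  s <- drop(crossprod(Xs, ys))
  S <- crossprod(Xs)
  K <- matrix(0, ncol(Xs), A)
  v <- s
  for (a in seq_len(A)) {
    K[, a] <- v
    v <- drop(S %*% v)
  }
  drop(K %*% solve(crossprod(K, S %*% K), crossprod(K, s)))
}

# intraclass correlation via the one-way ANOVA estimator (unbalanced)
icc_anova <- function(x, fam) {
  tab <- table(fam)
  keep <- fam %in% names(tab[tab >= 2])
  x <- x[keep]; fam <- droplevels(factor(fam[keep]))
  a <- nlevels(fam); N <- length(x)
  ni <- as.numeric(table(fam))
  gm <- mean(x)
  mi <- tapply(x, fam, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((x - mi[fam])^2)
  msb <- ssb / (a - 1); msw <- ssw / (N - a)
  k0 <- (N - sum(ni^2) / N) / (a - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

# small deterministic survival data set without ties
toy_survival <- function(n = 120, seed = 1, frailty_sd = 0, n_fam = 30,
                         beta = 0.5) {
  set.seed(seed)
  fam <- sample.int(n_fam, n, replace = TRUE)
  x <- stats::rbinom(n, 1, 0.5)
  u <- stats::rnorm(n_fam, sd = frailty_sd)[fam]
  t_ev <- stats::rexp(n, rate = 0.1 * exp(beta * x + u))
  cens <- stats::runif(n, 2, 25)
  data.frame(time_y = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
             x1 = x, z = stats::rnorm(n), pedigree_id = fam)
}

# reduced-size generator configuration for fast Monte-Carlo tests
small_config <- function(seed, n = 600, events = 40, ...) {
  generator_config(
    n_participants = n, n_singletons = round(n * 0.17),
    n_families = round(n * 0.11), target_events = events,
    meth_subset_n = min(200, n), meth_case_n = 8, seed = seed, ...)
}
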