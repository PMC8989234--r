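#' Genotype counts for a biallelic marker
#'
#' Bundles the three genotype counts of a biallelic SNP under the carrier
#' coding used throughout the package: the minor-allele homozygote (TT),
#' the heterozygote (TG) and the major-allele homozygote (GG).
#'
#' @param n_minor_hom Count of minor-allele homozygotes (TT).
#' @param n_het Count of heterozygotes (TG).
#' @param n_major_hom Count of major-allele homozygotes (GG).
#'
#' @return An object of class `genotype_counts` with elements
#'   `n_minor_hom`, `n_het`, `n_major_hom` and `total`.
#' @examples
#' genotype_counts(23, 438, 2071)
#' @export
genotype_counts <- function(n_minor_hom, n_het, n_major_hom) {
  counts <- c(n_minor_hom = n_minor_hom, n_het = n_het,
              n_major_hom = n_major_hom)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  out <- as.list(counts)
  out$total <- sum(counts)
  structure(out, class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("Genotype counts: TT =", x$n_minor_hom, " TG =", x$n_het,
      " GG =", x$n_major_hom, " (n =", x$total, ")\n")
  invisible(x)
}

#' Count genotypes in a cohort table
#'
#' @param cohort A cohort data frame with a `genotype` column coded
#'   `"TT"`, `"TG"` or `"GG"`.
#' @return A [genotype_counts()] object.
#' @export
count_genotypes <- function(cohort) {
  g <- as.character(cohort$genotype)
  bad <- setdiff(unique(g), c("TT", "TG", "GG"))
  if (length(bad)) stop("unknown genotype code(s): ", paste(bad, collapse = ", "))
  genotype_counts(sum(g == "TT"), sum(g == "TG"), sum(g == "GG"))
}

#' Allele frequencies and carrier summary
#'
#' Computes the minor-allele frequency, major-allele frequency and the
#' minor-allele carrier count/fraction from genotype counts.
#'
#' @param counts A [genotype_counts()] object.
#' @return A list of class `allele_frequencies` with `maf`, `major_freq`,
#'   `carrier_count`, `carrier_fraction` and `n`.
#' @examples
#' allele_frequencies(genotype_counts(23, 438, 2071)) # maf close to 9.6%
#' @export
allele_frequencies <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$total == 0) stop("cannot compute allele frequencies from zero genotypes")
  maf <- (2 * counts$n_minor_hom + counts$n_het) / (2 * counts$total)
  structure(list(
    maf = maf,
    major_freq = 1 - maf,
    carrier_count = counts$n_minor_hom + counts$n_het,
    carrier_fraction = (counts$n_minor_hom + counts$n_het) / counts$total,
    n = counts$total
  ), class = "allele_frequencies")
}

#' @export
print.allele_frequencies <- function(x, ...) {
  cat(sprintf("MAF %.4f (carriers %d/%d = %.1f%%)\n",
              x$maf, x$carrier_count, x$n, 100 * x$carrier_fraction))
  invisible(x)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic marker. Conditional on the observed
#' allele counts, the number of heterozygotes follows a known discrete
#' distribution under random mating; the p-value sums the probabilities of
#' all heterozygote counts whose conditional probability does not exceed
#' that of the observed configuration.
#'
#' @param counts A [genotype_counts()] object.
#' @return The exact two-sided p-value in (0, 1].
#' @examples
#' hwe_exact_test(genotype_counts(1, 2, 1)) # 1
#' @export
hwe_exact_test <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- counts$total
  if (n == 0) stop("empty genotype table")
  n_minor <- 2 * counts$n_minor_hom + counts$n_het
  n_major <- 2 * counts$n_major_hom + counts$n_het
  # orient so the rarer allele drives the enumeration (label-swap invariant)
  nA <- min(n_minor, n_major)
  if (nA == 0) return(1)
  obs_het <- counts$n_het
  hets <- seq(nA %% 2, nA, by = 2)
  # log conditional probability of each heterozygote count given allele counts
  logp <- hets * log(2) +
    lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((2 * n - nA - hets) / 2) +
    lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(obs_het, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Minor-homozygote versus heterozygote pooling check
#'
#' Carriers of the minor allele are pooled with heterozygotes in the primary
#' carrier analysis only when the two carrier genotypes confer
#' indistinguishable risk. This check fits the family-clustered
#' proportional-hazards model on carriers only, with a TT-vs-TG indicator,
#' unadjusted and sex/age-adjusted, and pools when the smaller of the two
#' Wald p-values is at or above `alpha`.
#'
#' @param cohort Cohort table (see [simulate_cohort()] for the layout).
#' @param alpha Pooling threshold on the minimum p-value (default 0.05).
#' @return A list of class `pooling_check` with `p_unadjusted`,
#'   `p_adjusted`, `pool` (logical) and `forced` (TRUE when the comparison
#'   is degenerate and pooling is the only option).
#' @export
pooling_check <- function(cohort, alpha = 0.05) {
  carriers <- cohort[cohort$genotype %in% c("TT", "TG"), , drop = FALSE]
  n_tt <- sum(carriers$genotype == "TT")
  n_tg <- sum(carriers$genotype == "TG")
  n_ev <- sum(carriers$event)
  forced <- n_tt == 0 || n_tg == 0 || n_ev == 0 ||
    sum(carriers$event[carriers$genotype == "TT"]) == 0 ||
    sum(carriers$event[carriers$genotype == "TG"]) == 0
  if (forced) {
    return(structure(list(p_unadjusted = NA_real_, p_adjusted = NA_real_,
                          pool = TRUE, forced = TRUE),
                     class = "pooling_check"))
  }
  carriers$tt <- as.integer(carriers$genotype == "TT")
  p_of <- function(terms) {
    fit <- tryCatch(
      fit_cox(carriers, terms = terms, cluster_by = "pedigree_id"),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(NA_real_)
    fit$table["tt", "p"]
  }
  p_un <- p_of("tt")
  p_ad <- p_of(c("tt", "sex", "age_y"))
  ps <- c(p_un, p_ad)
  if (all(is.na(ps))) {
    return(structure(list(p_unadjusted = p_un, p_adjusted = p_ad,
                          pool = TRUE, forced = TRUE),
                     class = "pooling_check"))
  }
  structure(list(p_unadjusted = p_un, p_adjusted = p_ad,
                 pool = min(ps, na.rm = TRUE) >= alpha, forced = FALSE),
            class = "pooling_check")
}

#' @export
print.pooling_check <- function(x, ...) {
  if (x$forced) {
    cat("TT vs TG comparison degenerate; carriers pooled by necessity\n")
  } else {
    cat(sprintf("TT vs TG: p = %.3f (unadjusted), %.3f (sex/age-adjusted) -> %s\n",
                x$p_unadjusted, x$p_adjusted,
                if (x$pool) "pool carriers" else "do not pool"))
  }
  invisible(x)
}

#' Genotype summary for a cohort
#'
#' Convenience wrapper producing counts, allele frequencies, the
#' Hardy-Weinberg exact p-value (optionally restricted to pedigree
#' founders, the conventional choice in family data) and the pooling
#' decision.
#'
#' @param cohort Cohort table.
#' @param founders_only Restrict the Hardy-Weinberg test to founders
#'   (requires a logical `founder` column).
#' @return List with `counts`, `frequencies`, `hwe_p`, `pooling`.
#' @export
genotype_summary <- function(cohort, founders_only = FALSE) {
  counts <- count_genotypes(cohort)
  hwe_cohort <- cohort
  if (founders_only) {
    if (is.null(cohort$founder)) stop("founders_only requires a 'founder' column")
    hwe_cohort <- cohort[as.logical(cohort$founder), , drop = FALSE]
  }
  list(counts = counts,
       frequencies = allele_frequencies(counts),
       hwe_p = hwe_exact_test(count_genotypes(hwe_cohort)),
       pooling = pooling_check(cohort))
}
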