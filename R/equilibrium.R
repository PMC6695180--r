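#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Exact test conditional on the observed allele counts, in the
#' Levene/Guo-Thompson tradition: the test statistic is the conditional
#' probability of the genotype array given the allele counts,
#' \deqn{P(\mathrm{array} \mid \mathrm{counts}) =
#'   \frac{N!\,\prod_a c_a!\,2^{H}}{(2N)!\,\prod_g n_g!},}
#' where \eqn{c_a} are allele counts, \eqn{n_g} genotype counts and \eqn{H}
#' the number of heterozygotes. The null distribution is sampled by randomly
#' re-pairing the 2N observed alleles into N genotypes; the p-value is the
#' add-one Monte-Carlo estimate
#' `p = (1 + #\{permuted arrays at most as probable as observed\}) / (B + 1)`,
#' so p can never be 0 and is bounded below by `1/(B+1)`.
#'
#' A monomorphic locus admits a single genotype array, so the test is
#' degenerate: p = 1 is returned with `degenerate = TRUE`.
#'
#' @param gt a [genotype_table()].
#' @param locus locus name.
#' @param n_permutations number of Monte-Carlo re-pairings B (>= 100).
#' @param seed integer seed for the re-pairing stream.
#' @return a one-row data frame (class `hwe_test`) with columns `locus`,
#'   `statistic` (log conditional probability of the observed array),
#'   `p_value`, `n_permutations`, `seed`, `degenerate`, `n_used`.
#' @references Guo SW, Thompson EA (1992) Performing the exact test of
#'   Hardy-Weinberg proportion for multiple alleles. Biometrics 48:361-372.
#' @export
hwe_exact_mc <- function(gt, locus, n_permutations = 10000L, seed = 1L) {
  if (n_permutations < 100L) stop("n_permutations must be at least 100")
  uc <- usable_calls(gt, locus)
  if (nrow(uc) < 2L) stop("locus ", sQuote(locus), ": fewer than 2 usable calls")
  av <- c(uc$a1, uc$a2)
  lev <- sort_alleles(unique(av))
  k <- length(lev)
  res <- data.frame(locus = locus, statistic = NA_real_, p_value = 1,
                    n_permutations = as.integer(n_permutations),
                    seed = as.integer(seed), degenerate = FALSE,
                    n_used = nrow(uc))
  class(res) <- c("hwe_test", "data.frame")
  if (k == 1L) {
    res$statistic <- 0
    res$degenerate <- TRUE
    return(res)
  }
  a1 <- match(uc$a1, lev); a2 <- match(uc$a2, lev)
  obs <- hwe_log_cond_prob(a1, a2, k)
  # sorted canonical order: re-pairing conditions only on allele counts, so
  # the Monte-Carlo stream (and p) is invariant to input row order
  av_codes <- sort(c(a1, a2))
  n <- length(a1)
  hits <- 0L
  eps <- 1e-9
  withr_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- sample(av_codes)
      s <- hwe_log_cond_prob(perm[seq_len(n)], perm[n + seq_len(n)], k)
      if (s <= obs + eps) hits <- hits + 1L
    }
  })
  res$statistic <- obs
  res$p_value <- (1 + hits) / (n_permutations + 1)
  res
}

# log of the count-dependent part of the conditional probability of a
# genotype array given allele counts: H*log(2) - sum(log n_g!). The terms in
# N, 2N and the allele counts are invariant under re-pairing and cancel from
# all comparisons.
hwe_log_cond_prob <- function(a1, a2, k) {
  g <- (pmin(a1, a2) - 1L) * k + pmax(a1, a2)
  tab <- tabulate(g, nbins = k * k)
  sum(a1 != a2) * log(2) - sum(lgamma(tab[tab > 0L] + 1))
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Association between unphased single-locus genotypes, tested without any
#' haplotype inference: the statistic is the log-likelihood-ratio G on the
#' genotype-by-genotype contingency table (individuals as units), and the
#' null distribution is generated by permuting one locus's genotype column
#' across individuals, which preserves both marginal genotype distributions.
#' The p-value uses the add-one Monte-Carlo rule. Only samples with usable
#' calls at both loci enter the table.
#'
#' @param gt a [genotype_table()].
#' @param locus_a,locus_b locus names.
#' @param n_permutations number of permutations B (>= 100).
#' @param seed integer seed.
#' @return a one-row data frame with columns `locus_a`, `locus_b`,
#'   `statistic` (G), `p_value`, `n_permutations`, `seed`, `degenerate`,
#'   `n_used`.
#' @export
ld_permutation_test <- function(gt, locus_a, locus_b, n_permutations = 10000L,
                                seed = 1L) {
  if (n_permutations < 100L) stop("n_permutations must be at least 100")
  ua <- usable_calls(gt, locus_a); ub <- usable_calls(gt, locus_b)
  shared <- intersect(ua$sample_id, ub$sample_id)
  if (length(shared) < 2L) stop("fewer than 2 samples usable at both loci")
  ua <- ua[match(shared, ua$sample_id), ]; ub <- ub[match(shared, ub$sample_id), ]
  ga <- paste(pmin(ua$a1, ua$a2), pmax(ua$a1, ua$a2), sep = "/")
  gb <- paste(pmin(ub$a1, ub$a2), pmax(ub$a1, ub$a2), sep = "/")
  res <- data.frame(locus_a = locus_a, locus_b = locus_b, statistic = 0,
                    p_value = 1, n_permutations = as.integer(n_permutations),
                    seed = as.integer(seed), degenerate = FALSE,
                    n_used = length(shared))
  if (length(unique(ga)) < 2L || length(unique(gb)) < 2L) {
    res$degenerate <- TRUE
    return(res)
  }
  fa <- factor(ga); fb <- factor(gb)
  ia <- as.integer(fa); ib <- as.integer(fb)
  na <- nlevels(fa); nb <- nlevels(fb)
  # margins are invariant under permutation, so expected counts are fixed
  e <- as.numeric(outer(tabulate(ia, na), tabulate(ib, nb))) / length(ia)
  gstat <- function(ibp) {
    o <- tabulate((ia - 1L) * nb + ibp, na * nb)
    nz <- o > 0L
    2 * sum(o[nz] * log(o[nz] / e[nz]))
  }
  obs <- gstat(ib)
  hits <- 0L
  withr_seed(seed, {
    for (b in seq_len(n_permutations)) {
      if (gstat(sample(ib)) >= obs - 1e-9) hits <- hits + 1L
    }
  })
  res$statistic <- obs
  res$p_value <- (1 + hits) / (n_permutations + 1)
  res
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of comparisons the correction spans (>= 1).
#' @return the per-test threshold `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 543) # 0.000092 at 6 decimals
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (length(m) != 1L || is.na(m) || m < 1) stop("m must be a positive integer")
  alpha / m
}

#' Annotate a batch of test results with Bonferroni significance
#'
#' Flags each result significant iff `p < alpha/m` and reports how many
#' results fall below `alpha` before and below `alpha/m` after correction.
#'
#' @param results data frame with a `p_value` column (e.g. rows from
#'   [hwe_exact_mc()] or [ld_permutation_test()]).
#' @param alpha family-wise error rate.
#' @param m number of comparisons; defaults to `nrow(results)`.
#' @return `results` with an added logical column
#'   `significant_after_correction`, plus attributes `n_significant_raw`,
#'   `n_significant_corrected` and `threshold`.
#' @export
multiple_test_summary <- function(results, alpha = 0.05, m = nrow(results)) {
  if (!is.data.frame(results) || !"p_value" %in% names(results))
    stop("results must be a data frame with a p_value column")
  thr <- bonferroni_threshold(alpha, m)
  results$significant_after_correction <- results$p_value < thr
  attr(results, "threshold") <- thr
  attr(results, "n_significant_raw") <- sum(results$p_value < alpha)
  attr(results, "n_significant_corrected") <- sum(results$significant_after_correction)
  results
}

# evaluate `code` under a locally-set RNG seed, restoring the caller's state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
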