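#' Allele frequencies at a locus
#'
#' Straight counting estimate: each usable diploid call contributes two
#' alleles, frequencies are counts over the effective allele count 2N.
#' Missing, off-ladder and tri-allelic calls are excluded (and reported via
#' the attributes `n_excluded`), matching how forensic population reports
#' treat anomalous calls.
#'
#' @param gt a [genotype_table()].
#' @param locus locus name.
#' @return named numeric vector of frequencies (names sorted in repeat-unit
#'   order, sum exactly 1) with attributes `n2` (effective allele count) and
#'   `n_excluded` (calls dropped).
#' @export
allele_frequencies <- function(gt, locus) {
  uc <- usable_calls(gt, locus)
  if (!nrow(uc)) stop("locus ", sQuote(locus), ": no usable calls")
  counts <- table(c(uc$a1, uc$a2))
  p <- as.numeric(counts) / sum(counts)
  names(p) <- names(counts)
  p <- p[sort_alleles(names(p))]
  attr(p, "n2") <- as.integer(sum(counts))
  attr(p, "n_excluded") <- length(gt$sample_ids) - nrow(uc)
  p
}

#' Frequency table for every locus of a genotype table
#'
#' @param gt a [genotype_table()].
#' @param min_usable loci with fewer usable calls are dropped with a warning.
#' @return a [freq_table()].
#' @export
estimate_frequencies <- function(gt, min_usable = 2L) {
  stopifnot(inherits(gt, "genotype_table"))
  freqs <- list(); n2 <- integer()
  for (l in gt$loci) {
    uc <- usable_calls(gt, l)
    if (nrow(uc) < min_usable) {
      warning("locus ", sQuote(l), " skipped: only ", nrow(uc), " usable calls")
      next
    }
    p <- allele_frequencies(gt, l)
    n2[[l]] <- attr(p, "n2")
    attributes(p) <- list(names = names(p))
    freqs[[l]] <- p
  }
  if (!length(freqs)) stop("no locus has enough usable calls")
  freq_table(freqs, sample_size_2n = n2, population = gt$population)
}

#' Minimum reportable allele frequency (NRC 5/2N floor)
#'
#' @param n_individuals number of individuals typed.
#' @return the floor 5/(2N).
#' @examples
#' maf_floor(543) # 0.0046 at 4 decimals
#' @export
maf_floor <- function(n_individuals) {
  if (length(n_individuals) != 1L || is.na(n_individuals) || n_individuals < 1)
    stop("n_individuals must be a single integer >= 1")
  5 / (2 * n_individuals)
}

#' Observed heterozygosity at a locus
#'
#' Fraction of usable diploid calls whose two alleles differ.
#'
#' @inheritParams allele_frequencies
#' @return proportion in \[0, 1\].
#' @export
observed_heterozygosity <- function(gt, locus) {
  uc <- usable_calls(gt, locus)
  if (!nrow(uc)) stop("locus ", sQuote(locus), ": no usable calls")
  mean(uc$a1 != uc$a2)
}

#' Expected heterozygosity from allele frequencies
#'
#' `1 - sum(p^2)`, optionally with the small-sample (unbiased) correction
#' `2N/(2N - 1)`.
#'
#' @param p numeric vector of allele frequencies.
#' @param n2 allele count 2N, required when `unbiased = TRUE`.
#' @param unbiased apply the `2N/(2N-1)` correction.
#' @return proportion in \[0, 1\].
#' @export
expected_heterozygosity <- function(p, n2 = NULL, unbiased = FALSE) {
  check_freq_vector(p)
  he <- 1 - sum(p^2)
  if (unbiased) {
    if (is.null(n2) || n2 < 2) stop("unbiased correction needs the allele count 2N >= 2")
    he <- he * n2 / (n2 - 1)
  }
  he
}

#' Polymorphism information content (Botstein)
#'
#' `PIC = 1 - sum(p^2) - (sum(p^2))^2 + sum(p^4)`, the expected informativeness
#' of a codominant marker for linkage/parentage. Always bounded above by the
#' (uncorrected) expected heterozygosity; 0 for a monomorphic locus.
#'
#' @param p numeric vector of allele frequencies.
#' @return PIC in \[0, 1).
#' @export
pic <- function(p) {
  check_freq_vector(p)
  s2 <- sum(p^2)
  1 - s2 - s2^2 + sum(p^4)
}

#' Random match probability at one locus
#'
#' The probability that two randomly chosen individuals share an (unspecified)
#' genotype: the sum of squared genotype proportions. Two variants:
#' `mode = "observed"` squares the genotype proportions actually seen in a
#' genotype table; `mode = "expected"` assumes Hardy-Weinberg proportions,
#' which collapses to `2 (sum p^2)^2 - sum p^4`. Power of discrimination is
#' the complement `PD = 1 - PM`.
#'
#' @param x a [genotype_table()] (observed mode) or a frequency vector
#'   (expected mode).
#' @param locus locus name (observed mode only).
#' @param mode `"observed"` or `"expected"`.
#' @return PM in (0, 1\].
#' @export
match_probability <- function(x, locus = NULL, mode = c("observed", "expected")) {
  mode <- match.arg(mode)
  if (mode == "observed") {
    if (!inherits(x, "genotype_table")) stop("observed mode needs a genotype_table")
    uc <- usable_calls(x, locus)
    if (!nrow(uc)) stop("locus ", sQuote(locus), ": no usable calls")
    g <- paste(pmin(uc$a1, uc$a2), pmax(uc$a1, uc$a2), sep = "/")
    sum((table(g) / length(g))^2)
  } else {
    check_freq_vector(x)
    s2 <- sum(x^2)
    2 * s2^2 - sum(x^4)
  }
}

#' Power of exclusion from observed heterozygosity
#'
#' `PE = h^2 (1 - 2 h H^2)` with `h` the observed heterozygosity and
#' `H = 1 - h`: the prior probability that a locus excludes a random
#' non-father in a standard trio case.
#'
#' @param ho observed heterozygosity in \[0, 1\].
#' @return PE in \[0, 1\], strictly increasing in `ho`.
#' @examples
#' power_of_exclusion(0.7919) # 0.5841 at 4 decimals
#' @export
power_of_exclusion <- function(ho) {
  if (any(ho < 0 | ho > 1)) stop("observed heterozygosity must lie in [0, 1]")
  H <- 1 - ho
  ho^2 * (1 - 2 * ho * H^2)
}

#' Typical paternity index from observed heterozygosity
#'
#' `TPI = 1 / (2 (1 - Ho))`, the paternity index expected for a
#' non-excluded random man.
#'
#' @param ho observed heterozygosity in \[0, 1).
#' @return TPI >= 0.5, strictly increasing in `ho`.
#' @export
typical_paternity_index <- function(ho) {
  if (any(ho < 0 | ho > 1)) stop("observed heterozygosity must lie in [0, 1]")
  if (any(ho == 1)) stop("TPI is unbounded at Ho = 1")
  1 / (2 * (1 - ho))
}

#' Full forensic summary for one locus
#'
#' Assembles the standard per-locus report row: number of alleles, MAF
#' floor, observed and (unbiased) expected heterozygosity, PIC, match
#' probability and power of discrimination (both observed- and
#' expected-genotype variants), power of exclusion and typical paternity
#' index, plus an optional Monte-Carlo Hardy-Weinberg p-value.
#'
#' @param gt a [genotype_table()].
#' @param locus locus name.
#' @param hwe if `TRUE`, run [hwe_exact_mc()] and include its p-value.
#' @param hwe_permutations,seed Monte-Carlo settings for the HWE test.
#' @return a one-row data frame.
#' @export
locus_summary <- function(gt, locus, hwe = FALSE, hwe_permutations = 10000L,
                          seed = 1L) {
  p <- allele_frequencies(gt, locus)
  n2 <- attr(p, "n2")
  ho <- observed_heterozygosity(gt, locus)
  pm_obs <- match_probability(gt, locus, mode = "observed")
  pm_exp <- match_probability(as.numeric(p), mode = "expected")
  out <- data.frame(
    locus = locus,
    n = n2 / 2,
    Na = length(p),
    MAF = maf_floor(n2 / 2),
    Ho = ho,
    He = expected_heterozygosity(as.numeric(p), n2 = n2, unbiased = TRUE),
    PIC = pic(as.numeric(p)),
    PM = pm_obs,
    PD = 1 - pm_obs,
    PM_expected = pm_exp,
    PD_expected = 1 - pm_exp,
    PE = power_of_exclusion(ho),
    TPI = if (ho < 1) typical_paternity_index(ho) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (hwe) {
    t <- hwe_exact_mc(gt, locus, n_permutations = hwe_permutations, seed = seed)
    out$hwe_p <- t$p_value
  }
  out
}

#' Forensic summary for all loci of a genotype table
#'
#' @inheritParams locus_summary
#' @param min_usable loci with fewer usable calls are dropped with a warning.
#' @return data frame, one row per locus (see [locus_summary()]).
#' @export
summarize_loci <- function(gt, hwe = FALSE, hwe_permutations = 10000L,
                           seed = 1L, min_usable = 2L) {
  stopifnot(inherits(gt, "genotype_table"))
  rows <- list()
  for (l in gt$loci) {
    if (nrow(usable_calls(gt, l)) < min_usable) {
      warning("locus ", sQuote(l), " skipped: fewer than ", min_usable,
              " usable calls")
      next
    }
    rows[[l]] <- locus_summary(gt, l, hwe = hwe,
                               hwe_permutations = hwe_permutations, seed = seed)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combined match probability and power of discrimination across loci
#'
#' Loci are treated as independent: the combined match probability is the
#' product of per-locus match probabilities, `CMP = prod(PM_l)`, and the
#' combined power of discrimination its complement `CPD = 1 - CMP`.
#'
#' @param pm per-locus match probabilities in \[0, 1\] (equivalently
#'   `1 - PD`).
#' @return list with elements `cmp`, `cpd` and `n_loci`.
#' @examples
#' combined_stats(c(0.1, 0.1)) # cmp 0.01, cpd 0.99
#' @export
combined_stats <- function(pm) {
  if (!length(pm)) stop("need at least one locus")
  if (any(is.na(pm) | pm < 0 | pm > 1)) stop("match probabilities must lie in [0, 1]")
  cmp <- prod(pm)
  list(cmp = cmp, cpd = 1 - cmp, n_loci = length(pm))
}

check_freq_vector <- function(p) {
  if (!is.numeric(p) || !length(p)) stop("frequency vector must be non-empty numeric")
  if (any(is.na(p) | p < 0)) stop("frequencies must be non-negative")
  if (abs(sum(p) - 1) > 0.01) stop("frequencies must sum to 1 (got ", round(sum(p), 4), ")")
  invisible(p)
}
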