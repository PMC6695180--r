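#' Simulation configuration for synthetic STR cohorts
#'
#' Bundles everything the generator needs: cohort size, the locus panel with
#' its true allele frequencies, an inbreeding coefficient FIS, and (for
#' structured mode) the number of populations and their divergence FST.
#'
#' The default panel emulates a GlobalFiler-style study: 21 autosomal STR
#' loci whose allele counts span roughly 7 to 48 (frequencies drawn once
#' from a symmetric Dirichlet per locus), typed in a cohort of N = 543
#' individuals.
#'
#' @param n_individuals cohort size per population (default 543).
#' @param loci named list of per-locus allele frequency vectors (named by
#'   allele label); `NULL` builds the default 21-locus panel from
#'   [default_panel()] using `seed`.
#' @param fis inbreeding coefficient in \[0, 1\] (default 0).
#' @param fst Balding-Nichols divergence for structured mode, in (0, 1).
#' @param n_populations number of populations (>= 1).
#' @param anomaly_rates named list with per-call probabilities `off_ladder`
#'   and `tri_allelic` (defaults 0).
#' @param seed integer seed driving every random draw.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 543L, loci = NULL, fis = 0,
                       fst = 0.05, n_populations = 1L,
                       anomaly_rates = list(off_ladder = 0, tri_allelic = 0),
                       seed = 1L) {
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  if (fis < 0 || fis > 1) stop("fis must lie in [0, 1]")
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  if (n_populations < 1L) stop("n_populations must be >= 1")
  rates <- utils::modifyList(list(off_ladder = 0, tri_allelic = 0), anomaly_rates)
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) stop("anomaly rates must lie in [0, 1]")
  if (is.null(loci)) loci <- default_panel(seed = seed)
  for (l in names(loci)) {
    p <- loci[[l]]
    if (is.null(names(p))) stop("locus ", sQuote(l), ": alleles must be named")
    if (abs(sum(p) - 1) > 1e-9) stop("locus ", sQuote(l), ": frequencies must sum to 1")
    if (any(p <= 0)) stop("locus ", sQuote(l), ": frequencies must be positive")
  }
  structure(list(n_individuals = as.integer(n_individuals), loci = loci,
                 fis = fis, fst = fst, n_populations = as.integer(n_populations),
                 anomaly_rates = rates, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw a random allele-frequency vector
#'
#' Symmetric Dirichlet draw (gamma normalization), giving strictly positive
#' frequencies that sum to 1. Lower `concentration` gives more skewed
#' spectra, as real STR loci show.
#'
#' @param n_alleles number of alleles (>= 1).
#' @param concentration Dirichlet concentration parameter (> 0), default 1.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return numeric vector of length `n_alleles`, positive, summing to 1.
#' @export
sample_frequency_vector <- function(n_alleles, concentration = 1, seed = NULL) {
  if (n_alleles < 1L) stop("n_alleles must be >= 1")
  if (concentration <= 0) stop("concentration must be positive")
  draw <- function() {
    g <- stats::rgamma(n_alleles, shape = concentration, rate = 1)
    while (sum(g) == 0) g <- stats::rgamma(n_alleles, shape = concentration, rate = 1)
    g / sum(g)
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Default synthetic 21-locus STR panel
#'
#' Builds a GlobalFiler-sized panel: 21 loci whose allele counts are spread
#' over 7..48 (the range real forensic panels show, from compact loci like
#' TPOX to the hypervariable SE33), with allele labels on a realistic repeat
#' range and a sprinkling of microvariant labels (x.1/x.2/x.3) at the loci
#' where real panels have them.
#'
#' @param n_loci number of loci (default 21).
#' @param seed integer seed.
#' @param concentration Dirichlet concentration for the frequency draws.
#' @return named list of allele-frequency vectors, usable as the `loci`
#'   field of [sim_config()].
#' @export
default_panel <- function(n_loci = 21L, seed = 1L, concentration = 1.5) {
  withr_seed(seed, {
    counts <- round(seq(7, 48, length.out = n_loci))
    loci <- list()
    for (i in seq_len(n_loci)) {
      k <- counts[i]
      base <- sample(5:30, 1L)
      ru <- base + seq_len(ceiling(k / 2)) - 1L
      labels <- as.character(ru)
      # microvariant companions until the locus has k labels
      extra <- paste0(rep(ru, each = 3L), ".", rep(1:3, length(ru)))
      labels <- c(labels, extra)[seq_len(k)]
      p <- sample_frequency_vector(k, concentration = concentration)
      names(p) <- labels
      loci[[sprintf("L%02d", i)]] <- p[sort_alleles(labels)]
    }
    loci
  })
}

#' Simulate a diploid genotype table under HWE with optional inbreeding
#'
#' Single-population generator. Each call is drawn under the standard
#' inbreeding mixture: with probability `fis` the two allele copies are
#' identical by descent (one allele drawn, duplicated), otherwise both are
#' drawn independently from the locus frequencies. This realizes
#' `P(hom i) = p_i^2 + f p_i (1 - p_i)` and `P(het ij) = 2 p_i p_j (1 - f)`.
#' Draws are independent across loci and individuals; output is
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()] with `n_populations = 1`.
#' @param population label for the output table.
#' @return a [genotype_table()]; anomaly injection is a separate step
#'   ([inject_anomalies()]).
#' @export
simulate_genotypes <- function(cfg, population = "synthetic") {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_populations != 1L) stop("use simulate_structured_populations() for n_populations > 1")
  withr_seed(cfg$seed, sim_one_population(cfg$loci, cfg$n_individuals,
                                          cfg$fis, population))
}

sim_one_population <- function(loci, n, fis, population) {
  L <- length(loci)
  a1 <- matrix(NA_character_, n, L); a2 <- matrix(NA_character_, n, L)
  for (j in seq_len(L)) {
    p <- loci[[j]]
    labels <- names(p)
    x <- sample(labels, n, replace = TRUE, prob = p)
    y <- sample(labels, n, replace = TRUE, prob = p)
    ibd <- stats::runif(n) < fis
    y[ibd] <- x[ibd]
    a1[, j] <- x; a2[, j] <- y
  }
  genotype_table(a1, a2,
                 sample_ids = sprintf("S%04d", seq_len(n)),
                 loci = names(loci), population = population)
}

#' Simulate diverged populations under the Balding-Nichols model
#'
#' Each population's allele frequencies at each locus are drawn around the
#' ancestral frequencies of `cfg$loci` from the multi-allelic Balding-Nichols
#' distribution, a Dirichlet with parameters `p * (1 - F) / F` where
#' `F = cfg$fst`; the biallelic marginal is the classical
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`. Each population is then sampled under HWE
#' (`fis` is applied within populations) from its drawn frequencies.
#'
#' @param cfg a [sim_config()] with `n_populations >= 2`.
#' @return named list of [genotype_table()]s (`pop1`, `pop2`, ...), with the
#'   drawn per-population frequency tables attached as attribute
#'   `"true_frequencies"` (a list of [freq_table()]s).
#' @export
simulate_structured_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_populations < 2L) stop("structured mode needs n_populations >= 2")
  F <- cfg$fst
  withr_seed(cfg$seed, {
    out <- list(); truth <- list()
    for (k in seq_len(cfg$n_populations)) {
      lab <- paste0("pop", k)
      loci_k <- lapply(cfg$loci, function(p) {
        g <- stats::rgamma(length(p), shape = p * (1 - F) / F, rate = 1)
        while (sum(g) == 0) g <- stats::rgamma(length(p), shape = p * (1 - F) / F, rate = 1)
        q <- g / sum(g)
        # Dirichlet mass on a boundary has probability 0 but finite-precision
        # draws can hit it; nudge so downstream positivity checks hold
        if (any(q <= 0)) { q <- q + 1e-12; q <- q / sum(q) }
        names(q) <- names(p)
        q
      })
      truth[[lab]] <- freq_table(loci_k,
                                 sample_size_2n = 2L * cfg$n_individuals,
                                 population = lab, tol = 1e-6)
      out[[lab]] <- sim_one_population(loci_k, cfg$n_individuals, cfg$fis, lab)
    }
    attr(out, "true_frequencies") <- truth
    out
  })
}

#' Inject off-ladder and tri-allelic anomalies into a genotype table
#'
#' Synthetic counterpart of the rare events forensic QC flags: with
#' probability `rates$off_ladder` a call has one allele replaced by `"OL"`;
#' with probability `rates$tri_allelic` a call gains a third allele (one
#' repeat unit above its larger allele). Events are drawn per (sample,
#' locus) call, mutually exclusively (off-ladder wins ties).
#'
#' @param gt a [genotype_table()].
#' @param rates named list with elements `off_ladder` and `tri_allelic`,
#'   each a probability.
#' @param seed integer seed.
#' @return the modified [genotype_table()], with the placement log (a data
#'   frame `sample_id`, `locus`, `kind`) attached as attribute
#'   `"injection_log"`.
#' @export
inject_anomalies <- function(gt, rates = list(off_ladder = 0, tri_allelic = 0),
                             seed = 1L) {
  stopifnot(inherits(gt, "genotype_table"))
  rates <- utils::modifyList(list(off_ladder = 0, tri_allelic = 0), rates)
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) stop("rates must lie in [0, 1]")
  n <- length(gt$sample_ids); L <- length(gt$loci)
  a1 <- gt$allele1; a2 <- gt$allele2
  extra <- gt$extra
  withr_seed(seed, {
    u <- matrix(stats::runif(n * L), n, L)
    callable <- !is.na(a1)
    ol <- u < rates$off_ladder & callable
    tri <- !ol & u < rates$off_ladder + rates$tri_allelic & callable
    if (any(ol)) {
      w <- which(ol, arr.ind = TRUE)
      side <- stats::runif(nrow(w)) < 0.5
      a1[w[side, , drop = FALSE]] <- "OL"
      a2[w[!side, , drop = FALSE]] <- "OL"
    }
    if (any(tri)) {
      w <- which(tri, arr.ind = TRUE)
      base <- ifelse(is_off_ladder(a1[w]), a2[w], pmax(a1[w], a2[w]))
      ok <- !is_off_ladder(base)
      w <- w[ok, , drop = FALSE]; base <- base[ok]
      tri[] <- FALSE; tri[w] <- TRUE
      if (nrow(w)) {
        hi <- parse_allele(base)
        third <- ifelse(hi$partial_bases > 0L,
                        paste0(hi$repeat_units + 1L, ".", hi$partial_bases),
                        as.character(hi$repeat_units + 1L))
        extra <- rbind(extra, data.frame(sample_id = gt$sample_ids[w[, 1L]],
                                         locus = gt$loci[w[, 2L]],
                                         allele = third))
      }
    }
    log <- rbind(
      if (any(ol)) { w <- which(ol, arr.ind = TRUE)
        data.frame(sample_id = gt$sample_ids[w[, 1L]], locus = gt$loci[w[, 2L]],
                   kind = "off_ladder") },
      if (any(tri)) { w <- which(tri, arr.ind = TRUE)
        data.frame(sample_id = gt$sample_ids[w[, 1L]], locus = gt$loci[w[, 2L]],
                   kind = "tri_allelic") })
    if (is.null(log)) log <- data.frame(sample_id = character(),
                                        locus = character(), kind = character())
    out <- genotype_table(a1, a2, sample_ids = gt$sample_ids, loci = gt$loci,
                          population = gt$population, extra = extra)
    attr(out, "injection_log") <- log[order(match(log$sample_id, gt$sample_ids),
                                            match(log$locus, gt$loci)), ,
                                      drop = FALSE]
    out
  })
}

#' Write the generator's ground truth alongside its output
#'
#' Writes the per-locus true frequencies (via [write_frequency_table()]) and
#' a small key-value text file recording FIS, FST, seed and cohort size, so
#' downstream estimates can be checked against what generated the data.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation_truth <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ft <- freq_table(cfg$loci, sample_size_2n = 2L * cfg$n_individuals,
                   population = "truth", tol = 1e-6)
  write_frequency_table(ft, file.path(dir, "true_frequencies.csv"))
  writeLines(c(paste0("n_individuals: ", cfg$n_individuals),
               paste0("n_populations: ", cfg$n_populations),
               paste0("fis: ", cfg$fis),
               paste0("fst: ", cfg$fst),
               paste0("seed: ", cfg$seed)),
             file.path(dir, "truth.txt"))
  invisible(dir)
}
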