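#' Run the full single-population study pipeline
#'
#' From a genotype table to the complete report a forensic population study
#' publishes: per-locus allele frequency table, the forensic parameter panel
#' (Na, MAF, Ho, He, PIC, PM/PD in both observed and HWE-expected variants,
#' PE, TPI), combined match probability / power of discrimination, per-locus
#' Monte-Carlo HWE exact tests and pairwise LD permutation tests with
#' Bonferroni annotation, and the anomaly (off-ladder / tri-allelic) report.
#' A JSON manifest records parameters and seeds so a run can be reproduced
#' exactly.
#'
#' @param gt a [genotype_table()], or a path readable by [read_genotypes()].
#' @param out_dir output directory (created if needed).
#' @param permutations Monte-Carlo permutation count B for the HWE and LD
#'   tests.
#' @param seed integer seed for all Monte-Carlo draws.
#' @param alpha family-wise error rate for the Bonferroni screen.
#' @param bonferroni_m divisor m of the Bonferroni threshold; defaults to
#'   the sample size N, the convention of the study this pipeline mirrors
#'   (m equal to the number of tests is the textbook choice; pass it
#'   explicitly if preferred).
#' @param ld run the pairwise LD tests (quadratic in loci; disable for quick
#'   looks).
#' @return invisibly, a list with the computed `summary`, `combined`, `hwe`,
#'   `ld`, `anomalies` and the output paths.
#' @export
run_summarize <- function(gt, out_dir, permutations = 10000L, seed = 1L,
                          alpha = 0.05, bonferroni_m = NULL, ld = TRUE) {
  if (is.character(gt)) gt <- read_genotypes(gt)
  stopifnot(inherits(gt, "genotype_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(gt$sample_ids)
  if (is.null(bonferroni_m)) bonferroni_m <- n

  ft <- estimate_frequencies(gt)
  write_frequency_table(ft, file.path(out_dir, "allele_frequencies.csv"))

  summary <- summarize_loci(gt)
  loci_used <- summary$locus

  hwe <- do.call(rbind, lapply(seq_along(loci_used), function(i)
    hwe_exact_mc(gt, loci_used[i], n_permutations = permutations,
                 seed = seed + i)))
  hwe <- multiple_test_summary(hwe, alpha = alpha, m = bonferroni_m)
  summary$hwe_p <- hwe$p_value[match(summary$locus, hwe$locus)]
  write_locus_summary(summary, file.path(out_dir, "locus_summary.csv"))
  utils::write.csv(format_num(hwe), file.path(out_dir, "hwe_tests.csv"),
                   row.names = FALSE)

  comb <- combined_stats(summary$PM)
  comb_exp <- combined_stats(summary$PM_expected)
  utils::write.csv(
    data.frame(mode = c("observed", "expected"),
               cmp = c(comb$cmp, comb_exp$cmp),
               cpd = c(comb$cpd, comb_exp$cpd),
               n_loci = comb$n_loci),
    file.path(out_dir, "combined_stats.csv"), row.names = FALSE)

  ld_res <- NULL
  if (ld && length(loci_used) >= 2L) {
    pairs <- utils::combn(loci_used, 2L)
    ld_res <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i)
      ld_permutation_test(gt, pairs[1L, i], pairs[2L, i],
                          n_permutations = permutations, seed = seed + 1000L + i)))
    ld_res <- multiple_test_summary(ld_res, alpha = alpha, m = bonferroni_m)
    utils::write.csv(format_num(ld_res), file.path(out_dir, "ld_tests.csv"),
                     row.names = FALSE)
  }

  anomalies <- detect_anomalies(gt)
  utils::write.csv(anomalies, file.path(out_dir, "anomalies.csv"),
                   row.names = FALSE)

  manifest <- list(
    tool = "strpopkit", step = "summarize",
    n_samples = n, n_loci = length(gt$loci), loci = gt$loci,
    population = gt$population, permutations = permutations, seed = seed,
    alpha = alpha, bonferroni_m = bonferroni_m,
    bonferroni_threshold = bonferroni_threshold(alpha, bonferroni_m),
    ld = ld, n_anomalies = nrow(anomalies))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = summary, combined = comb,
                 combined_expected = comb_exp, hwe = hwe, ld = ld_res,
                 anomalies = anomalies, frequencies = ft, out_dir = out_dir))
}

#' Run the inter-population comparison pipeline
#'
#' Aligns the tables on their shared locus panel, then writes the pairwise
#' distance matrix (FST by default, optionally Nei distances), the
#' neighbor-joining tree in Newick format, and the nonmetric-MDS ordination
#' (coordinates plus stress-1 and RSQ), with a JSON manifest.
#'
#' @param tables list of [freq_table()]s, or paths readable by
#'   [read_frequency_table()].
#' @param out_dir output directory.
#' @param estimator FST estimator, `"nei_gst"` or `"weir_cockerham"`.
#' @param nei also compute the Nei `standard_ds` distance matrix and build
#'   the tree from it instead of FST.
#' @param mds_dims NMDS target dimension (default 2); set 0 to skip.
#' @param seed integer seed (NMDS).
#' @return invisibly, a list with `fst`, `nei` (or NULL), `tree`,
#'   `ordination` and the output paths.
#' @export
run_compare <- function(tables, out_dir, estimator = c("nei_gst", "weir_cockerham"),
                        nei = TRUE, mds_dims = 2L, seed = 1L) {
  estimator <- match.arg(estimator)
  if (is.character(tables)) tables <- lapply(tables, read_frequency_table)
  if (length(tables) < 2L) stop("need at least two frequency tables")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  al <- align_loci(tables)
  writeLines(attr(al, "loci_used"), file.path(out_dir, "loci_used.txt"))

  fst <- pairwise_fst(al, estimator = estimator)
  utils::write.csv(as.data.frame(unclass(fst)),
                   file.path(out_dir, "fst_matrix.csv"))
  nei_d <- NULL
  if (nei) {
    nei_d <- nei_distance(al, variant = "standard_ds")
    utils::write.csv(as.data.frame(unclass(nei_d)),
                     file.path(out_dir, "nei_ds_matrix.csv"))
  }

  tree_input <- if (nei) nei_d else fst
  tree <- NULL
  if (nrow(fst) >= 3L) {
    if (max(tree_input) == 0) {
      warning("all pairwise distances are zero; no tree written")
    } else {
      tree <- neighbor_joining(tree_input)
      writeLines(to_newick(tree), file.path(out_dir, "nj_tree.nwk"))
    }
  }

  ord <- NULL
  if (mds_dims >= 1L && nrow(fst) > mds_dims && max(tree_input) > 0) {
    ord <- nmds(tree_input, k = mds_dims, seed = seed)
    coords <- as.data.frame(ord$points)
    names(coords) <- paste0("dim", seq_len(ncol(coords)))
    utils::write.csv(cbind(population = rownames(ord$points), coords),
                     file.path(out_dir, "mds_coordinates.csv"), row.names = FALSE)
    writeLines(c(sprintf("stress: %.6f", ord$stress),
                 sprintf("rsq: %.6f", ord$rsq)),
               file.path(out_dir, "mds_fit.txt"))
  }

  manifest <- list(
    tool = "strpopkit", step = "compare",
    populations = names(al), n_loci_used = length(attr(al, "loci_used")),
    loci_used = attr(al, "loci_used"), estimator = estimator,
    nei = nei, mds_dims = mds_dims, seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fst = fst, nei = nei_d, tree = tree, ordination = ord,
                 aligned = al, out_dir = out_dir))
}

#' Write the forensic locus summary as a parameters-by-loci CSV
#'
#' Transposed (report-style) layout: loci across the columns, parameters
#' down the rows, values to 4 decimals.
#'
#' @param summary data frame from [summarize_loci()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_locus_summary <- function(summary, path) {
  params <- setdiff(names(summary), "locus")
  m <- t(as.matrix(summary[params]))
  colnames(m) <- summary$locus
  out <- data.frame(parameter = params,
                    apply(m, 2L, function(v) formatC(v, digits = 4L, format = "f")),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_num <- function(df) {
  num <- vapply(df, is.numeric, TRUE) & !names(df) %in% c("n_permutations", "seed", "n_used")
  df[num] <- lapply(df[num], function(v) signif(v, 6L))
  df
}
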