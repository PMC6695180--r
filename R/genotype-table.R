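#' Construct a diploid STR genotype table
#'
#' The central container for raw typing data: one row per individual, one
#' column pair per locus. Allele calls are textual labels as produced by the
#' typing kit (`"12"`, `"31.2"`, `"OL"`); missing calls are `NA` in both
#' slots. Genotypes are unordered pairs — `8/9` and `9/8` are the same call.
#' Tri-allelic patterns (three peaks at one locus in one individual, e.g. a
#' duplication) are carried in `extra` and flagged by [detect_anomalies()];
#' they are never used silently in diploid statistics.
#'
#' @param allele1,allele2 character matrices (samples x loci) of allele
#'   labels, `NA` for missing. Dimnames are ignored; `sample_ids` and `loci`
#'   give the coordinates.
#' @param sample_ids character vector of unique sample identifiers.
#' @param loci character vector of locus names, in panel order.
#' @param population single population label.
#' @param extra optional data frame with columns `sample_id`, `locus`,
#'   `allele` listing third alleles of tri-allelic calls.
#' @return an object of class `genotype_table`.
#' @examples
#' gt <- genotype_table(
#'   allele1 = matrix(c("8", "8"), 2, 1),
#'   allele2 = matrix(c("9", "8"), 2, 1),
#'   sample_ids = c("s1", "s2"), loci = "TPOX"
#' )
#' gt
#' @export
genotype_table <- function(allele1, allele2, sample_ids, loci,
                           population = "synthetic", extra = NULL) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "character"; storage.mode(allele2) <- "character"
  sample_ids <- as.character(sample_ids); loci <- as.character(loci)
  if (length(sample_ids) < 1L) stop("a genotype table needs at least one sample")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(loci)) stop("duplicate locus names")
  if (!all(dim(allele1) == c(length(sample_ids), length(loci))) ||
      !all(dim(allele2) == dim(allele1))) {
    stop("allele matrices must be samples x loci and congruent")
  }
  # half-missing calls are not a valid diploid state
  half <- xor(is.na(allele1), is.na(allele2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1L, ]
    stop(sprintf("call with a single missing allele at sample %s (row %d), locus %s",
                 sample_ids[w[1L]], w[1L], loci[w[2L]]))
  }
  parse_allele(c("0", stats::na.omit(c(allele1, allele2))))  # validates labels
  dimnames(allele1) <- dimnames(allele2) <- list(sample_ids, loci)
  if (is.null(extra)) {
    extra <- data.frame(sample_id = character(), locus = character(),
                        allele = character())
  } else {
    extra <- as.data.frame(extra)[, c("sample_id", "locus", "allele")]
    if (!all(extra$locus %in% loci)) stop("extra alleles at unknown loci")
    if (!all(extra$sample_id %in% sample_ids)) stop("extra alleles for unknown samples")
  }
  structure(list(allele1 = allele1, allele2 = allele2,
                 sample_ids = sample_ids, loci = loci,
                 population = as.character(population)[1L], extra = extra),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d samples x %d loci, population %s\n",
              length(x$sample_ids), length(x$loci), sQuote(x$population)))
  an <- detect_anomalies(x)
  if (nrow(an)) cat(sprintf("  anomalies: %d (%s)\n", nrow(an),
                            paste(names(table(an$kind)), table(an$kind),
                                  sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$sample_ids), length(x$loci))

#' Read a wide-format genotype file
#'
#' Expects one row per individual and two columns per locus named
#' `<locus><suffix1>` / `<locus><suffix2>` (default `TPOX_1`, `TPOX_2`), with
#' an optional `<locus><suffix3>` column holding third alleles of tri-allelic
#' calls. The first column is taken as the sample identifier unless
#' `id_column` names another. CSV, TSV (by extension or `sep`) and XLSX (via
#' the readxl package, if installed) are accepted. Anomalous calls
#' (off-ladder, tri-allelic) are kept and routed to [detect_anomalies()],
#' never dropped.
#'
#' @param path input file.
#' @param loci optional character vector restricting (and ordering) the locus
#'   panel; unknown requested loci are an error.
#' @param suffixes length-2 or -3 character vector of column suffixes.
#' @param sep field separator; `NULL` infers from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @param id_column name of the sample-id column, default the first column.
#' @param population population label to attach.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, loci = NULL, suffixes = c("_1", "_2", "_3"),
                           sep = NULL, id_column = NULL,
                           population = "unknown") {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package")
    }
    df <- as.data.frame(readxl::read_excel(path, col_types = "text"))
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character", check.names = FALSE,
                            strip.white = TRUE)
  }
  if (ncol(df) < 3L) stop("genotype file needs an id column plus two columns per locus")
  if (is.null(id_column)) id_column <- names(df)[1L]
  if (!id_column %in% names(df)) stop("id column ", sQuote(id_column), " not found")
  ids <- df[[id_column]]
  geno_cols <- setdiff(names(df), id_column)

  suff_re <- paste0("(", paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", suffixes),
                               collapse = "|"), ")$")
  stems <- unique(sub(suff_re, "", geno_cols))
  col_of <- function(stem, k) {
    nm <- paste0(stem, suffixes[k])
    if (nm %in% names(df)) nm else NA_character_
  }
  have12 <- vapply(stems, function(s) !is.na(col_of(s, 1L)) && !is.na(col_of(s, 2L)), TRUE)
  if (!all(have12)) {
    stop("odd column count: loci without both allele columns: ",
         paste(stems[!have12], collapse = ", "))
  }
  if (is.null(loci)) {
    loci <- stems
  } else if (!all(loci %in% stems)) {
    stop("requested loci absent from file: ",
         paste(setdiff(loci, stems), collapse = ", "))
  }

  clean <- function(v) { v <- trimws(v); v[v == ""] <- NA; v }
  a1 <- sapply(loci, function(l) clean(df[[col_of(l, 1L)]]))
  a2 <- sapply(loci, function(l) clean(df[[col_of(l, 2L)]]))
  a1 <- matrix(a1, nrow = nrow(df)); a2 <- matrix(a2, nrow = nrow(df))

  extra <- NULL
  if (length(suffixes) >= 3L) {
    ex <- lapply(loci, function(l) {
      cn <- col_of(l, 3L)
      if (is.na(cn)) return(NULL)
      v <- clean(df[[cn]])
      if (!any(!is.na(v))) return(NULL)
      data.frame(sample_id = ids[!is.na(v)], locus = l, allele = v[!is.na(v)])
    })
    ex <- do.call(rbind, ex)
    if (!is.null(ex) && nrow(ex)) extra <- ex
  }

  # re-validate with coordinates so bad tokens are reported usably (1-based rows)
  ok <- is.na(c(a1, a2)) | grepl("^([0-9]+(\\.[0-3])?|[Oo][Ll])$", trimws(c(a1, a2)))
  if (!all(ok)) {
    w <- which(!ok)[1L]
    n <- nrow(df)
    row <- (w - 1L) %% n + 1L
    col <- loci[((w - 1L) %/% n) %% length(loci) + 1L]
    stop(sprintf("unparseable allele %s at row %d, locus %s",
                 sQuote(c(a1, a2)[w]), row, col))
  }
  genotype_table(a1, a2, sample_ids = ids, loci = loci,
                 population = population, extra = extra)
}

#' Write a genotype table in the wide two-columns-per-locus format
#'
#' @param gt a [genotype_table()].
#' @param path output path; `.tsv` extension selects tab separation.
#' @param suffixes column suffixes, as in [read_genotypes()].
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path, suffixes = c("_1", "_2", "_3")) {
  stopifnot(inherits(gt, "genotype_table"))
  out <- data.frame(sample_id = gt$sample_ids, check.names = FALSE)
  for (l in gt$loci) {
    out[[paste0(l, suffixes[1L])]] <- gt$allele1[, l]
    out[[paste0(l, suffixes[2L])]] <- gt$allele2[, l]
  }
  if (nrow(gt$extra)) {
    for (l in unique(gt$extra$locus)) {
      v <- rep(NA_character_, length(gt$sample_ids))
      rows <- gt$extra[gt$extra$locus == l, ]
      v[match(rows$sample_id, gt$sample_ids)] <- rows$allele
      out[[paste0(l, suffixes[3L])]] <- v
    }
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Detect off-ladder and tri-allelic anomalies
#'
#' One record per affected (sample, locus) cell, in deterministic order
#' (sample first, then locus, both in table order). These calls are excluded
#' from frequency estimation and equilibrium testing at the affected locus
#' but are counted and reported, mirroring standard forensic QC practice.
#'
#' @param gt a [genotype_table()].
#' @return data frame with columns `sample_id`, `locus`, `kind`
#'   (`"off_ladder"` or `"tri_allelic"`) and `detail`.
#' @export
detect_anomalies <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  recs <- list()
  ol <- is_off_ladder(gt$allele1) | is_off_ladder(gt$allele2)
  ol[is.na(ol)] <- FALSE
  dim(ol) <- dim(gt$allele1)
  if (any(ol)) {
    w <- which(ol, arr.ind = TRUE)
    recs[[1L]] <- data.frame(
      sample_id = gt$sample_ids[w[, 1L]], locus = gt$loci[w[, 2L]],
      kind = "off_ladder",
      detail = paste0("call (", gt$allele1[ol], ",", gt$allele2[ol], ")"))
  }
  if (nrow(gt$extra)) {
    i <- match(gt$extra$sample_id, gt$sample_ids)
    j <- match(gt$extra$locus, gt$loci)
    recs[[2L]] <- data.frame(
      sample_id = gt$extra$sample_id, locus = gt$extra$locus,
      kind = "tri_allelic",
      detail = paste0("call (", gt$allele1[cbind(i, j)], ",",
                      gt$allele2[cbind(i, j)], ",", gt$extra$allele, ")"))
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    return(data.frame(sample_id = character(), locus = character(),
                      kind = character(), detail = character()))
  }
  out <- out[order(match(out$sample_id, gt$sample_ids),
                   match(out$locus, gt$loci)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Usable (diploid, non-anomalous) calls at one locus
#'
#' Internal workhorse for the statistics layer: drops missing, off-ladder and
#' tri-allelic calls and returns the two allele label vectors side by side.
#'
#' @param gt a [genotype_table()].
#' @param locus locus name.
#' @return data frame with columns `sample_id`, `a1`, `a2`.
#' @keywords internal
#' @export
usable_calls <- function(gt, locus) {
  stopifnot(inherits(gt, "genotype_table"))
  if (!locus %in% gt$loci) stop("locus ", sQuote(locus), " not in table")
  a1 <- gt$allele1[, locus]; a2 <- gt$allele2[, locus]
  bad <- is.na(a1) | is_off_ladder(a1) | is_off_ladder(a2)
  tri <- gt$sample_ids %in% gt$extra$sample_id[gt$extra$locus == locus]
  keep <- !(bad | tri)
  data.frame(sample_id = gt$sample_ids[keep], a1 = unname(a1[keep]),
             a2 = unname(a2[keep]))
}
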