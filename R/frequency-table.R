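#' Construct a per-locus allele frequency table
#'
#' The unit of inter-population comparison: for each locus, a named vector of
#' relative allele frequencies, together with the allele count 2N the
#' frequencies were estimated from. Frequencies must be strictly positive and
#' sum to 1 per locus (within `tol`); absent alleles are simply not listed.
#'
#' @param freqs named list, one element per locus: a named numeric vector
#'   (names are allele labels, values relative frequencies).
#' @param sample_size_2n integer vector of per-locus allele counts (2N),
#'   recycled if scalar; may be `NA` for literature tables of unknown depth.
#' @param population population label.
#' @param tol per-locus tolerance on `|sum - 1|` (default 1e-6; published
#'   tables rounded to 5 decimals are read with a wider tolerance by
#'   [read_frequency_table()]).
#' @param renormalize if `TRUE`, divide each locus by its sum after the
#'   tolerance check.
#' @return an object of class `freq_table`.
#' @export
freq_table <- function(freqs, sample_size_2n = NA_integer_,
                       population = "unknown", tol = 1e-6,
                       renormalize = FALSE) {
  if (!length(freqs)) stop("frequency table has no loci")
  if (is.null(names(freqs)) || any(!nzchar(names(freqs)))) stop("loci must be named")
  sample_size_2n <- rep_len(as.integer(sample_size_2n), length(freqs))
  names(sample_size_2n) <- names(freqs)
  for (l in names(freqs)) {
    p <- freqs[[l]]
    if (!length(p) || is.null(names(p))) stop("locus ", sQuote(l), ": alleles must be named")
    if (any(p <= 0)) stop("locus ", sQuote(l), ": non-positive frequency")
    s <- sum(p)
    if (abs(s - 1) > tol) {
      stop(sprintf("locus %s: frequencies sum to %.6f, outside tolerance %g",
                   sQuote(l), s, tol))
    }
    if (renormalize) p <- p / s
    freqs[[l]] <- p[sort_alleles(names(p))]
  }
  structure(list(freqs = freqs, sample_size_2n = sample_size_2n,
                 population = as.character(population)[1L]),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  na <- vapply(x$freqs, length, 1L)
  cat(sprintf("<freq_table> %s: %d loci, %d-%d alleles per locus, %d total\n",
              sQuote(x$population), length(x$freqs), min(na), max(na), sum(na)))
  invisible(x)
}

#' Number of alleles per locus
#' @param ft a [freq_table()].
#' @return named integer vector.
#' @export
n_alleles <- function(ft) {
  stopifnot(inherits(ft, "freq_table"))
  vapply(ft$freqs, length, 1L)
}

#' Read an allele-frequency matrix
#'
#' Layout: allele labels down the first column, loci across, blank cells for
#' absent alleles — the layout population reports print. Leading comment
#' lines `# population: <label>` and `# 2N: <counts>` (single value or one
#' per locus) carry metadata and are optional.
#'
#' Published tables are rounded (typically to 5 decimals), so per-locus sums
#' rarely equal 1 exactly; sums within `tol` of 1 are accepted and, if
#' `renormalize = TRUE`, rescaled to exactly 1.
#'
#' @param path CSV file as described.
#' @param tol accepted deviation of each locus sum from 1 (default 0.005).
#' @param renormalize rescale each locus to sum exactly 1 (default `FALSE`).
#' @param population,sample_size_2n override metadata from the file.
#' @return a [freq_table()].
#' @examples
#' path <- system.file("extdata", "bahrain_allele_freqs.csv", package = "strpopkit")
#' ft <- read_frequency_table(path)
#' n_alleles(ft)[c("TPOX", "SE33")]
#' @export
read_frequency_table <- function(path, tol = 0.005, renormalize = FALSE,
                                 population = NULL, sample_size_2n = NULL) {
  hdr <- readLines(path, n = 10L)
  meta <- grep("^#", hdr, value = TRUE)
  if (is.null(population)) {
    m <- grep("^#\\s*population:", meta, value = TRUE)
    population <- if (length(m)) trimws(sub("^#\\s*population:", "", m[1L])) else "unknown"
  }
  if (is.null(sample_size_2n)) {
    m <- grep("^#\\s*2N:", meta, value = TRUE)
    sample_size_2n <- if (length(m)) {
      as.integer(strsplit(trimws(sub("^#\\s*2N:", "", m[1L])), "[,\\s]+")[[1L]])
    } else NA_integer_
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        colClasses = c("character"))
  if (ncol(df) < 2L) stop("frequency file needs an allele column plus loci columns")
  alleles <- df[[1L]]
  num <- df[, -1L, drop = FALSE]
  freqs <- lapply(names(num), function(l) {
    v <- suppressWarnings(as.numeric(num[[l]]))
    bad <- !is.na(v) & !nzchar(trimws(num[[l]])) # never true; placeholder for clarity
    keep <- !is.na(v)
    if (any(v[keep] < 0)) stop("locus ", sQuote(l), ": negative frequency")
    p <- v[keep]
    names(p) <- alleles[keep]
    p
  })
  names(freqs) <- names(num)
  empty <- !vapply(freqs, length, 1L)
  if (any(empty)) stop("loci with no alleles: ", paste(names(num)[empty], collapse = ", "))
  freq_table(freqs, sample_size_2n = sample_size_2n, population = population,
             tol = tol, renormalize = renormalize)
}

#' Write an allele-frequency matrix
#'
#' Inverse of [read_frequency_table()]: allele labels in repeat-unit order
#' down the rows, loci across, values printed to `digits` decimals (default
#' 5, the precision of published forensic tables), blanks for absent
#' alleles, and metadata comment lines for the population label and 2N.
#'
#' @param ft a [freq_table()].
#' @param path output CSV path.
#' @param digits decimals to print.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(ft, path, digits = 5L) {
  stopifnot(inherits(ft, "freq_table"))
  all_alleles <- sort_alleles(unique(unlist(lapply(ft$freqs, names))))
  loci <- names(ft$freqs)
  m <- matrix("", length(all_alleles), length(loci),
              dimnames = list(all_alleles, loci))
  for (l in loci) {
    p <- ft$freqs[[l]]
    m[names(p), l] <- formatC(p, digits = digits, format = "f")
  }
  n2 <- ft$sample_size_2n
  n2line <- if (length(unique(n2)) == 1L) as.character(n2[1L]) else paste(n2, collapse = ",")
  lines <- c(paste0("# population: ", ft$population),
             paste0("# 2N: ", n2line),
             paste(c("allele", loci), collapse = ","),
             paste(all_alleles, apply(m, 1L, paste, collapse = ","), sep = ","))
  writeLines(lines, path)
  invisible(path)
}
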