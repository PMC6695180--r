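#' Parse STR allele labels
#'
#' STR alleles are named by their repeat count, with microvariants carrying a
#' partial-repeat suffix: `"9.3"` means 9 full repeats plus 3 bases. Peaks
#' falling outside the kit's allelic ladder are recorded as `"OL"`
#' (off-ladder) and carry no repeat information. Alleles are kept as integer
#' pairs, never as floating-point numbers, so that `"9.3"` and `"31.2"` have
#' exact equality and ordering semantics (9.3 is not the number 9.3).
#'
#' @param x character vector of allele labels: an integer (`"8"`), an
#'   integer with a single partial-repeat digit 0-3 (`"31.2"`), or `"OL"`
#'   (case-insensitive).
#' @return An object of class `str_allele`: a data frame with integer columns
#'   `repeat_units` and `partial_bases` (both `NA` for off-ladder entries) and
#'   logical `off_ladder`.
#' @examples
#' parse_allele(c("9.3", "8", "OL"))
#' format_allele(parse_allele("31.2"))
#' @seealso [format_allele()], [sort_alleles()]
#' @export
parse_allele <- function(x) {
  if (length(x) == 0L) stop("no allele labels supplied")
  x <- trimws(as.character(x))
  out <- data.frame(
    repeat_units = rep(NA_integer_, length(x)),
    partial_bases = rep(NA_integer_, length(x)),
    off_ladder = rep(FALSE, length(x))
  )
  ol <- toupper(x) == "OL"
  out$off_ladder[ol] <- TRUE
  plain <- grepl("^[0-9]+$", x)
  micro <- grepl("^[0-9]+\\.[0-3]$", x)
  bad <- !(ol | plain | micro)
  if (any(bad)) {
    stop("malformed allele label(s): ",
         paste(sQuote(x[bad]), collapse = ", "),
         " (expected an integer, integer.d with d in 0-3, or \"OL\")")
  }
  out$repeat_units[plain] <- as.integer(x[plain])
  out$partial_bases[plain] <- 0L
  rp <- strsplit(x[micro], ".", fixed = TRUE)
  out$repeat_units[micro] <- as.integer(vapply(rp, `[`, "", 1L))
  out$partial_bases[micro] <- as.integer(vapply(rp, `[`, "", 2L))
  class(out) <- c("str_allele", "data.frame")
  out
}

#' Format STR alleles back to their textual labels
#'
#' Inverse of [parse_allele()]: integer alleles print without a decimal part,
#' microvariants as `repeat.bases`, off-ladder entries as `"OL"`.
#'
#' @param a an `str_allele` object.
#' @return character vector of labels.
#' @export
format_allele <- function(a) {
  stopifnot(inherits(a, "str_allele"))
  out <- ifelse(a$partial_bases > 0L,
                paste0(a$repeat_units, ".", a$partial_bases),
                as.character(a$repeat_units))
  out[a$off_ladder] <- "OL"
  out
}

#' Sort allele labels in repeat-unit order
#'
#' Orders labels by `(repeat_units, partial_bases)` so that `"9.3"` sorts
#' between `"9"` and `"10"` (numeric sorting of the labels would be wrong for
#' microvariants such as `"9.3"` vs `"9.21"`, and lexical sorting puts `"10"`
#' before `"9"`). Off-ladder labels have no defined order and are an error.
#'
#' @param labels character vector of allele labels (no `"OL"`).
#' @return the labels, sorted.
#' @export
sort_alleles <- function(labels) {
  a <- parse_allele(labels)
  if (any(a$off_ladder)) stop("off-ladder alleles have no defined order")
  labels[order(a$repeat_units, a$partial_bases)]
}

#' @export
print.str_allele <- function(x, ...) {
  cat("<str_allele> ", paste(format_allele(x), collapse = " "), "\n")
  invisible(x)
}

#' Test whether a label denotes an off-ladder allele
#' @param labels character vector.
#' @return logical vector.
#' @export
is_off_ladder <- function(labels) toupper(trimws(as.character(labels))) == "OL"
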