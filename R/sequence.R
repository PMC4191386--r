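#' Normalize an RNA sequence string
#'
#' Uppercases and converts DNA-style `T` to `U`. In strict mode any character
#' that is not one of `A`, `C`, `G`, `U` (already uppercase) is rejected
#' instead of normalized.
#'
#' @param x Character vector of sequences.
#' @param strict If `TRUE`, reject lowercase input and `T` instead of
#'   normalizing them.
#' @return Character vector over the alphabet `A`, `C`, `G`, `U`.
#' @export
normalize_rna <- function(x, strict = FALSE) {
  if (strict) {
    bad <- grepl("[^ACGU]", x)
    if (any(bad)) {
      stop("strict mode: sequence contains characters outside {A,C,G,U}: ",
           x[bad][1], call. = FALSE)
    }
    return(x)
  }
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("sequence contains non-nucleotide characters after normalization: ",
         x[bad][1], call. = FALSE)
  }
  x
}

#' GC content as a percentage
#'
#' @param seq Character vector of RNA sequences.
#' @return Numeric vector, `100 * (#G + #C) / n` for each sequence.
#' @examples
#' gc_percent(c("GCGC", "AUAU"))
#' @export
gc_percent <- function(seq) {
  seq <- normalize_rna(seq)
  vapply(strsplit(seq, ""), function(ch) {
    100 * sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1))
}

# IUPAC degenerate nucleotide codes -> nucleotide domains
IUPAC_DOMAINS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' IUPAC code for "any nucleotide but this one"
#'
#' Maps a nucleotide to the three-letter IUPAC code of its complement set:
#' `A -> B`, `C -> D`, `G -> H`, `U -> V`. Used to constrain design positions
#' to be distinct from a reference nucleotide.
#'
#' @param nt Character vector of single nucleotides (`A`, `C`, `G`, `U`;
#'   `T`/lowercase are normalized first).
#' @return Character vector of IUPAC codes.
#' @examples
#' not_code(c("A", "G", "U"))
#' @export
not_code <- function(nt) {
  nt <- normalize_rna(nt)
  if (any(nchar(nt) != 1L)) {
    stop("not_code() expects single nucleotides", call. = FALSE)
  }
  unname(c(A = "B", C = "D", G = "H", U = "V")[nt])
}

#' Parse an IUPAC constraint pattern
#'
#' Whitespace is ignored (patterns are often printed in blocks of ten).
#'
#' @param text IUPAC pattern string.
#' @param length Optional expected length; an error is raised on mismatch.
#' @return Object of class `iupac_pattern`: a list with `codes` (character
#'   vector of length n) and `domains` (list of per-position nucleotide sets).
#' @export
iupac_pattern <- function(text, length = NULL) {
  codes <- strsplit(gsub("\\s", "", toupper(text)), "")[[1]]
  codes[codes == "T"] <- "U"
  unknown <- setdiff(codes, names(IUPAC_DOMAINS))
  if (length(unknown) > 0) {
    stop("unknown IUPAC code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(length) && length(codes) != length) {
    stop("pattern length ", length(codes), " != expected length ", length,
         call. = FALSE)
  }
  structure(list(codes = codes, domains = IUPAC_DOMAINS[codes]),
            class = "iupac_pattern")
}

#' @export
print.iupac_pattern <- function(x, ...) {
  cat("<iupac_pattern> length", length(x$codes), "\n")
  cat(paste(x$codes, collapse = ""), "\n")
  invisible(x)
}

#' Does a sequence match an IUPAC pattern?
#'
#' @param seq Character vector of RNA sequences.
#' @param pattern An [iupac_pattern()] or pattern string.
#' @return Logical vector.
#' @export
iupac_match <- function(seq, pattern) {
  if (!inherits(pattern, "iupac_pattern")) pattern <- iupac_pattern(pattern)
  seq <- normalize_rna(seq)
  vapply(strsplit(seq, ""), function(ch) {
    length(ch) == length(pattern$codes) &&
      all(mapply(function(nt, dom) nt %in% dom, ch, pattern$domains))
  }, logical(1))
}
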