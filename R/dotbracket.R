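#' Parse a dot-bracket secondary structure
#'
#' Stack-parses a string over `.`, `(`, `)` into a base-pair list. Coordinates
#' are 1-based throughout. Structures must respect the minimum hairpin loop of
#' three unpaired nucleotides (`j - i >= 4` for every pair).
#'
#' @param text Dot-bracket string.
#' @param min_loop Minimum number of unpaired nucleotides enclosed by a pair
#'   (Turner convention: 3). Set to 0 to accept any nesting.
#' @return Object of class `dotbracket`: list with `text`, `n`, and `pairs`
#'   (tibble with columns `i < j`).
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(text, min_loop = 3L) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  ch <- strsplit(text, "")[[1]]
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad) > 0) {
    stop("invalid structure character '", ch[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  stack <- integer(0)
  i_open <- integer(0)
  j_close <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (length(stack) == 0) {
        stop("unbalanced structure: unmatched ')' at position ", k,
             call. = FALSE)
      }
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (k - i < min_loop + 1L) {
        stop("hairpin loop shorter than ", min_loop, " at pair (", i, ",", k,
             ")", call. = FALSE)
      }
      i_open <- c(i_open, i)
      j_close <- c(j_close, k)
    }
  }
  if (length(stack) > 0) {
    stop("unbalanced structure: unmatched '(' at position ",
         stack[length(stack)], call. = FALSE)
  }
  ord <- order(i_open)
  structure(
    list(text = text, n = length(ch),
         pairs = tibble::tibble(i = i_open[ord], j = j_close[ord])),
    class = "dotbracket"
  )
}

#' @export
print.dotbracket <- function(x, ...) {
  cat("<dotbracket> n =", x$n, ",", nrow(x$pairs), "pairs\n")
  cat(x$text, "\n")
  invisible(x)
}

#' @export
as.character.dotbracket <- function(x, ...) x$text

as_dotbracket <- function(x, min_loop = 3L) {
  if (inherits(x, "dotbracket")) x else parse_dotbracket(x, min_loop)
}

#' Partner table of a structure
#'
#' @param db A [parse_dotbracket()] structure (or string).
#' @return Integer vector `p` of length n with `p[i]` the partner of `i`, or
#'   `0` when `i` is unpaired.
#' @export
pair_table <- function(db) {
  db <- as_dotbracket(db)
  p <- integer(db$n)
  p[db$pairs$i] <- db$pairs$j
  p[db$pairs$j] <- db$pairs$i
  p
}

#' Base-pair distance between two structures
#'
#' Cardinality of the symmetric difference of the two pair sets.
#'
#' @param a,b Structures of equal length (dot-bracket strings or
#'   [parse_dotbracket()] objects).
#' @return Non-negative integer.
#' @export
bp_distance <- function(a, b) {
  a <- as_dotbracket(a)
  b <- as_dotbracket(b)
  if (a$n != b$n) stop("structures differ in length", call. = FALSE)
  key <- function(d) paste(d$pairs$i, d$pairs$j)
  ka <- key(a)
  kb <- key(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Build a dot-bracket string from a pair list
#'
#' @param n Sequence length.
#' @param pairs Data frame with columns `i`, `j`.
#' @return A `dotbracket` object.
#' @export
dotbracket_from_pairs <- function(n, pairs) {
  ch <- rep(".", n)
  ch[pairs$i] <- "("
  ch[pairs$j] <- ")"
  parse_dotbracket(paste(ch, collapse = ""))
}
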