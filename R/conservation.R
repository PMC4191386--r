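#' Construct an alignment block
#'
#' @param records Data frame with columns `id` and `aligned` (equal-width
#'   rows; gaps are `-` or `.`).
#' @param ss_cons Optional consensus-structure annotation string.
#' @return Object of class `alignment_block` (see [read_stockholm()]).
#' @export
alignment_block <- function(records, ss_cons = NULL) {
  records <- tibble::as_tibble(records)[, c("id", "aligned")]
  widths <- unique(nchar(records$aligned))
  if (length(widths) != 1) {
    stop("aligned rows have unequal lengths: ",
         paste(widths, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records$id)) {
    stop("duplicate sequence ids in alignment", call. = FALSE)
  }
  structure(list(records = records, ss_cons = ss_cons, width = widths),
            class = "alignment_block")
}

alignment_matrix <- function(block) {
  m <- do.call(rbind, strsplit(toupper(block$records$aligned), ""))
  m[m == "T"] <- "U"
  rownames(m) <- block$records$id
  m
}

#' Map alignment columns to reference positions
#'
#' @param alignment An `alignment_block`.
#' @param ref_id Id of the reference row.
#' @return Tibble with columns `column` (alignment column index) and
#'   `position` (1..n over the reference's non-gap residues).
#' @export
map_columns_to_reference <- function(alignment, ref_id) {
  ref <- alignment$records$aligned[alignment$records$id == ref_id]
  if (length(ref) != 1) {
    stop("reference id not found in alignment: ", ref_id, call. = FALSE)
  }
  ch <- strsplit(ref, "")[[1]]
  cols <- which(!ch %in% c("-", "."))
  tibble::tibble(column = cols, position = seq_along(cols))
}

#' Per-position nucleotide conservation profile
#'
#' Nucleotide frequencies over the aligned residues at every reference
#' position. By default frequencies are computed over non-gap residues only;
#' `gap_inclusive = TRUE` divides by the full sequence count instead.
#'
#' @inheritParams map_columns_to_reference
#' @param gap_inclusive Count gaps in the denominator?
#' @return Tibble with columns `position`, `column`, `ref_nt`, `coverage`
#'   (non-gap residue count), and frequencies `A`, `C`, `G`, `U`.
#' @export
conservation_profile <- function(alignment, ref_id, gap_inclusive = FALSE) {
  mapping <- map_columns_to_reference(alignment, ref_id)
  m <- alignment_matrix(alignment)
  purrr::map_dfr(seq_len(nrow(mapping)), function(k) {
    col <- m[, mapping$column[k]]
    res <- col[!col %in% c("-", ".")]
    denom <- if (gap_inclusive) length(col) else length(res)
    freq <- vapply(c("A", "C", "G", "U"),
                   function(nt) if (denom == 0) 0 else sum(res == nt) / denom,
                   numeric(1))
    tibble::tibble(
      position = mapping$position[k],
      column = mapping$column[k],
      ref_nt = m[ref_id, mapping$column[k]],
      coverage = length(res),
      A = freq[["A"]], C = freq[["C"]], G = freq[["G"]], U = freq[["U"]]
    )
  })
}

#' Conserved positions above a threshold
#'
#' @param profile A [conservation_profile()] tibble.
#' @param threshold Minimum frequency of the majority nucleotide, as a
#'   fraction in (0, 1]. Named presets: `"strict"` = 0.96 (the operative
#'   design threshold) and `"relaxed"` = 0.95.
#' @return Tibble with columns `position`, `nt` (majority nucleotide),
#'   `freq`.
#' @export
conserved_positions <- function(profile, threshold = 0.96) {
  if (is.character(threshold)) {
    threshold <- switch(threshold, strict = 0.96, relaxed = 0.95,
                        stop("unknown threshold preset: ", threshold,
                             call. = FALSE))
  }
  stopifnot(threshold > 0, threshold <= 1)
  freqs <- as.matrix(profile[, c("A", "C", "G", "U")])
  top <- max.col(freqs, ties.method = "first")
  top_freq <- freqs[cbind(seq_len(nrow(freqs)), top)]
  keep <- top_freq >= threshold
  tibble::tibble(
    position = profile$position[keep],
    nt = c("A", "C", "G", "U")[top[keep]],
    freq = top_freq[keep]
  )
}

#' Build a design constraint pattern from a reference sequence
#'
#' Conserved positions receive their conserved nucleotide, override positions
#' receive the given IUPAC code, and every remaining position is constrained
#' to be distinct from the reference nucleotide ([not_code()]).
#'
#' @param ref_seq Reference sequence (string).
#' @param conserved Named character vector `position -> nucleotide` (or a
#'   tibble with columns `position`, `nt` as returned by
#'   [conserved_positions()]).
#' @param overrides Named character vector `position -> IUPAC code`.
#' @return An [iupac_pattern()].
#' @examples
#' build_design_pattern("ACGU", conserved = c(`2` = "C"),
#'                      overrides = c(`4` = "H"))
#' @export
build_design_pattern <- function(ref_seq, conserved = NULL, overrides = NULL) {
  nt <- strsplit(normalize_rna(ref_seq), "")[[1]]
  n <- length(nt)
  codes <- not_code(nt)
  if (is.data.frame(conserved)) {
    conserved <- stats::setNames(conserved$nt, conserved$position)
  }
  as_pos <- function(x, what) {
    p <- as.integer(names(x))
    if (any(is.na(p)) || any(p < 1) || any(p > n)) {
      stop(what, " positions must be names within 1..", n, call. = FALSE)
    }
    p
  }
  cpos <- if (length(conserved) > 0) as_pos(conserved, "conserved") else integer(0)
  opos <- if (length(overrides) > 0) as_pos(overrides, "override") else integer(0)
  clash <- intersect(cpos, opos)
  if (length(clash) > 0) {
    stop("position(s) both conserved and overridden: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  codes[cpos] <- normalize_rna(unname(conserved))
  codes[opos] <- toupper(unname(overrides))
  iupac_pattern(paste(codes, collapse = ""))
}

#' Select candidates by a filter-and-rank criterion
#'
#' Applies the published selection scheme: filter by a GC window and by
#' bounds on the Boltzmann probability of the target, then order by one
#' measure column (ties broken lexicographically by sequence) and report the
#' requested order statistic.
#'
#' @param records Data frame of measure records (must contain `seq`, the
#'   `objective` column, and `gc` / `prob_target` when those filters are
#'   used).
#' @param objective Name of the measure column to optimize.
#' @param direction `"min"` or `"max"`.
#' @param gc_window Optional `c(lo, hi)` integer percent window
#'   (`lo <= gc < hi + 1`).
#' @param prob_min,prob_max Optional bounds on `prob_target` (fractions).
#' @param rank Order statistic(s) to return (default 1 = the optimum);
#'   `NULL` returns the whole ordered set.
#' @return The selected rows, with `rank` and `objective` columns appended;
#'   zero rows when the filtered set is empty or smaller than `rank`.
#' @export
select_candidates <- function(records, objective, direction = c("min", "max"),
                              gc_window = NULL, prob_min = NULL,
                              prob_max = NULL, rank = 1) {
  direction <- match.arg(direction)
  if (!objective %in% names(records)) {
    stop("objective column not found: ", objective, call. = FALSE)
  }
  out <- tibble::as_tibble(records)
  if (!is.null(gc_window)) {
    out <- dplyr::filter(out, .data$gc >= gc_window[1],
                         .data$gc < gc_window[2] + 1)
  }
  if (!is.null(prob_min)) out <- dplyr::filter(out, .data$prob_target >= prob_min)
  if (!is.null(prob_max)) out <- dplyr::filter(out, .data$prob_target <= prob_max)
  key <- out[[objective]]
  if (direction == "max") key <- -key
  out <- out[order(key, out$seq), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$objective <- objective
  if (is.null(rank)) out else out[out$rank %in% rank, , drop = FALSE]
}
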