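#' Read a FASTA file into a tibble
#'
#' Sequences are normalized to uppercase RNA (`T -> U`).
#'
#' @param path Path to a FASTA file.
#' @param strict Passed to [normalize_rna()].
#' @return Tibble with columns `id`, `seq`, `length`.
#' @export
read_fasta <- function(path, strict = FALSE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- normalize_rna(as.character(set), strict = strict)
  tibble::tibble(
    id = sub("\\s.*$", "", names(set)),
    seq = unname(seqs),
    length = nchar(unname(seqs))
  )
}

#' Write sequences to a FASTA file
#'
#' @param data Data frame with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path) {
  set <- Biostrings::BStringSet(data$seq)
  names(set) <- data$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a Stockholm alignment
#'
#' Minimal Stockholm 1.0 reader: sequence rows are collected (multi-block
#' files are concatenated per id) and the `#=GC SS_cons` consensus-structure
#' line is captured when present. Gap characters are `-` and `.`.
#'
#' @param path Path to a Stockholm file.
#' @return Object of class `alignment_block`: list with `records` (tibble
#'   `id`, `aligned`), `ss_cons` (string or `NULL`), and `width`.
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^# STOCKHOLM", lines[1])) {
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path,
         call. = FALSE)
  }
  ids <- character(0)
  seqs <- list()
  ss_cons <- character(0)
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (line == "" || line == "//") next
    if (startsWith(line, "#")) {
      if (grepl("^#=GC\\s+SS_cons\\s+", line)) {
        ss_cons <- c(ss_cons, sub("^#=GC\\s+SS_cons\\s+", "", line))
      }
      next
    }
    fields <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(fields) != 2) {
      stop("malformed Stockholm sequence line ", k, ": ", line, call. = FALSE)
    }
    id <- fields[1]
    if (!id %in% ids) {
      ids <- c(ids, id)
      seqs[[id]] <- fields[2]
    } else {
      seqs[[id]] <- paste0(seqs[[id]], fields[2])
    }
  }
  aligned <- toupper(unlist(seqs[ids], use.names = FALSE))
  aligned <- gsub("T", "U", aligned, fixed = TRUE)
  widths <- unique(nchar(aligned))
  if (length(widths) > 1) {
    stop("aligned rows have unequal lengths: ",
         paste(widths, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      records = tibble::tibble(id = ids, aligned = aligned),
      ss_cons = if (length(ss_cons) > 0) paste(ss_cons, collapse = "") else NULL,
      width = if (length(widths) == 1) widths else 0L
    ),
    class = "alignment_block"
  )
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("<alignment_block>", nrow(x$records), "sequences x", x$width,
      "columns\n")
  if (!is.null(x$ss_cons)) cat("SS_cons:", x$ss_cons, "\n")
  invisible(x)
}

#' Write an alignment to Stockholm format
#'
#' @param block An `alignment_block` (or list with `records`, `ss_cons`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(block, path) {
  pad <- max(nchar(block$records$id), 12L)
  lines <- c(
    "# STOCKHOLM 1.0",
    sprintf("%-*s %s", pad, block$records$id, block$records$aligned)
  )
  if (!is.null(block$ss_cons)) {
    lines <- c(lines, sprintf("%-*s %s", pad, "#=GC SS_cons", block$ss_cons))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' Thin wrappers around readr with the column conventions used throughout the
#' package (header row, no quoting surprises).
#'
#' @param path File path.
#' @param data Data frame to write.
#' @return A tibble (`read_measures_tsv`) or `path` invisibly.
#' @export
read_measures_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_measures_tsv
#' @export
write_measures_tsv <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}
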