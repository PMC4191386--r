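new_dos_histogram <- function(data, reference, method, n_samples = NA_integer_,
                              seed = NA_integer_) {
  out <- tibble::as_tibble(data)
  attr(out, "reference") <- reference$text
  attr(out, "method") <- method
  attr(out, "n_samples") <- n_samples
  attr(out, "seed") <- seed
  class(out) <- c("dos_histogram", class(tibble::tibble()))
  out
}

#' @export
print.dos_histogram <- function(x, ...) {
  cat("<dos_histogram>", attr(x, "method"), "|", nrow(x), "distance classes")
  if (!is.na(attr(x, "n_samples"))) {
    cat(" |", attr(x, "n_samples"), "samples (seed", attr(x, "seed"), ")")
  }
  cat("\n")
  NextMethod()
}

# structure energies for one sequence, batched through the engine
engine_eval_batch <- function(seq, structures, engine) {
  if (length(structures) == 0) return(numeric(0))
  if (engine$backend == "toy") {
    return(-vapply(structures,
                   function(s) sum(strsplit(s, "")[[1]] == "("),
                   numeric(1), USE.NAMES = FALSE))
  }
  ops <- lapply(structures,
                function(s) list(op = "eval", seq = seq, structure = s))
  vapply(vienna_call(ops, engine), function(r) r$energy, numeric(1))
}

#' Density of states over base-pair distance, by Boltzmann sampling
#'
#' Estimates `p(k) = Z_k / Z`, the Boltzmann probability of the set of
#' structures at base-pair distance `k` from a reference structure, from a
#' seeded sample of the ensemble. The lowest-energy sampled structure at each
#' occupied `k` is retained as the representative.
#'
#' @param seq RNA sequence.
#' @param reference Reference structure (dot-bracket); usually the MFE
#'   structure.
#' @param n_samples Number of Boltzmann samples.
#' @param seed Sampler seed (deterministic output for a fixed seed).
#' @param engine An [rna_engine()].
#' @return A `dos_histogram`: tibble with columns `k`, `p`, `count`,
#'   `representative`, `rep_energy`, ordered by `k`.
#' @export
sampled_density <- function(seq, reference, n_samples = 1000, seed = 1L,
                            engine = NULL) {
  engine <- as_engine(engine)
  stopifnot(n_samples >= 1)
  ref <- as_dotbracket(reference)
  seq <- normalize_rna(seq)
  if (nchar(seq) != ref$n) {
    stop("sequence and reference differ in length", call. = FALSE)
  }
  ss <- rna_sample(seq, n_samples, seed = seed, engine = engine)
  us <- unique(ss)
  counts <- as.integer(table(factor(ss, levels = us)))
  dist <- vapply(us, function(s) bp_distance(s, ref), numeric(1),
                 USE.NAMES = FALSE)
  energy <- engine_eval_batch(seq, us, engine)
  per_struct <- tibble::tibble(structure = us, count = counts, k = dist,
                               energy = energy)
  hist <- per_struct |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(
      p = sum(.data$count) / n_samples,
      count = sum(.data$count),
      representative = .data$structure[which.min(.data$energy)],
      rep_energy = min(.data$energy),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$k)
  new_dos_histogram(hist, ref, "sampled", as.integer(n_samples),
                    as.integer(seed))
}

#' Exhaustively enumerate secondary structures of a short sequence
#'
#' All secondary structures over AU/UA/CG/GC/GU/UG pairs with a minimum
#' hairpin loop of `min_loop` unpaired nucleotides. Counts grow quickly:
#' intended for oracle computations at small `n`.
#'
#' @param seq RNA sequence.
#' @param min_loop Minimum hairpin loop length.
#' @return Character vector of dot-bracket strings (includes the open
#'   structure).
#' @export
enumerate_structures <- function(seq, min_loop = 3) {
  seq <- normalize_rna(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pairable <- outer(ch, ch, function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  })
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return("")
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- paste0(".", rec(i + 1L, j))
    ks <- seq_len(j)
    ks <- ks[ks >= i + min_loop + 1L & pairable[i, ks]]
    for (k in ks) {
      inner <- rec(i + 1L, k - 1L)
      rest <- rec(k + 1L, j)
      out <- c(out, as.vector(outer(inner, rest, function(a, b) {
        paste0("(", a, ")", b)
      })))
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

#' Exact density of states for short sequences
#'
#' Computes `p(k) = Z_k / Z` exactly by exhaustive structure enumeration,
#' together with the `MFE_k` structure (lowest-energy structure at each
#' distance class).
#'
#' @inheritParams sampled_density
#' @param max_n Enumeration length bound (default 20).
#' @return A `dos_histogram` (see [sampled_density()]); `count` is the number
#'   of structures in each class.
#' @export
exact_density_small <- function(seq, reference, engine = NULL, max_n = 20) {
  engine <- as_engine(engine)
  ref <- as_dotbracket(reference)
  seq <- normalize_rna(seq)
  if (nchar(seq) != ref$n) {
    stop("sequence and reference differ in length", call. = FALSE)
  }
  if (nchar(seq) > max_n) {
    stop("sequence length ", nchar(seq), " exceeds the enumeration bound ",
         max_n, "; use sampled_density()", call. = FALSE)
  }
  structs <- enumerate_structures(seq)
  energy <- engine_eval_batch(seq, structs, engine)
  weight <- exp(-energy / engine$RT)
  dist <- vapply(structs, function(s) bp_distance(s, ref), numeric(1),
                 USE.NAMES = FALSE)
  z <- sum(weight)
  hist <- tibble::tibble(structure = structs, weight = weight, k = dist,
                         energy = energy) |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(
      p = sum(.data$weight) / z,
      count = dplyr::n(),
      representative = .data$structure[which.min(.data$energy)],
      rep_energy = min(.data$energy),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$k)
  new_dos_histogram(hist, ref, "exact")
}

#' Two-peak density-of-states screen
#'
#' A candidate placement passes when (i) the distance class `k = 0` carries
#' probability at least `tau0` (the reference structure region is dominant),
#' and (ii) the smoothed histogram has a local maximum at some `k >= k_min`
#' with smoothed mass at least `tau1` whose representative structure contains
#' every pair of the `sequester` structure (the alternate fold that
#' sequesters the ribozyme). With `sequester = NULL` only the peak-shape
#' condition is tested.
#'
#' @param hist A `dos_histogram`.
#' @param sequester Optional structure whose pairs the second-peak
#'   representative must contain.
#' @param tau0 Minimum probability at `k = 0`.
#' @param tau1 Minimum smoothed mass of the second peak.
#' @param k_min Minimum distance of the second peak.
#' @param smooth Moving-average window (odd) for peak detection.
#' @return List with `pass`, `p0`, `witness_k`, `witness_structure`, and
#'   `peaks` (tibble of candidate local maxima with their smoothed mass and,
#'   when a sequester is given, whether its pairs are contained).
#' @export
two_peak_filter <- function(hist, sequester = NULL, tau0 = 0.1, tau1 = 0.05,
                            k_min = 10, smooth = 3) {
  stopifnot(inherits(hist, "dos_histogram"), smooth %% 2 == 1)
  kmax <- max(hist$k)
  dense <- numeric(kmax + 1)
  dense[hist$k + 1] <- hist$p
  half <- (smooth - 1) / 2
  sm <- vapply(seq_along(dense), function(i) {
    w <- max(1, i - half):min(length(dense), i + half)
    mean(dense[w])
  }, numeric(1))
  p0 <- dense[1]
  is_max <- vapply(seq_along(sm), function(i) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < length(sm)) sm[i + 1] else -Inf
    sm[i] >= left && sm[i] >= right && sm[i] > 0
  }, logical(1))
  cand_k <- which(is_max) - 1
  cand_k <- cand_k[cand_k >= k_min & sm[cand_k + 1] >= tau1]
  seq_pairs <- NULL
  if (!is.null(sequester)) {
    sq <- as_dotbracket(sequester)
    seq_pairs <- sq$pairs
  }
  contains_sequester <- vapply(cand_k, function(k) {
    if (is.null(seq_pairs)) return(TRUE)
    if (nrow(seq_pairs) == 0) return(TRUE)
    rep_row <- hist$representative[hist$k == k]
    if (length(rep_row) == 0) return(FALSE)
    rp <- as_dotbracket(rep_row[1])$pairs
    have <- paste(rp$i, rp$j)
    all(paste(seq_pairs$i, seq_pairs$j) %in% have)
  }, logical(1))
  peaks <- tibble::tibble(
    k = cand_k,
    mass = sm[cand_k + 1],
    representative = vapply(cand_k, function(k) {
      r <- hist$representative[hist$k == k]
      if (length(r) == 0) NA_character_ else r[1]
    }, character(1)),
    contains_sequester = contains_sequester
  )
  ok <- peaks[peaks$contains_sequester, , drop = FALSE]
  pass <- p0 >= tau0 && nrow(ok) > 0
  best <- if (nrow(ok) > 0) ok[which.max(ok$mass), ] else NULL
  list(
    pass = pass,
    p0 = p0,
    witness_k = if (pass) best$k else NA_integer_,
    witness_structure = if (pass) best$representative else NA_character_,
    peaks = peaks
  )
}
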