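#' Conserved-site positions of the 54-nt hammerhead design
#'
#' The 16 positions 6-8, 22-25, 27-29, 44-49 carrying the catalytic-core
#' constraints (1-based in the 54-nt design).
#'
#' @param offset Added to every position; use `offset = 2` for coordinates in
#'   the GG/CC-extended 58-nt transcript.
#' @return Integer vector of length 16.
#' @export
conserved_site <- function(offset = 0L) {
  c(6:8, 22:25, 27:29, 44:49) + as.integer(offset)
}

#' Extend a design to its in-vitro transcript
#'
#' Designed 54-nt hammerheads were transcribed with a GG prepended and a CC
#' appended for T7 transcription efficiency; the published selection measures
#' refer to these 58-nt transcripts.
#'
#' @param seq Character vector of sequences.
#' @param left,right Extension sequences.
#' @return Character vector of extended sequences.
#' @export
extend_transcript <- function(seq, left = "GG", right = "CC") {
  paste0(left, normalize_rna(seq), right)
}

check_bppm <- function(bppm, tol = 1e-5) {
  n <- nrow(bppm)
  row_paired <- rowSums(bppm) + colSums(bppm) - 2 * diag(bppm)
  total <- row_paired + diag(bppm)
  if (any(abs(total - 1) > tol)) {
    stop("base-pair probability matrix rows do not sum to 1 (max deviation ",
         signif(max(abs(total - 1)), 3), ")", call. = FALSE)
  }
  invisible(n)
}

pstar_row <- function(bppm, i) {
  n <- nrow(bppm)
  p <- numeric(n)
  if (i > 1) p[1:(i - 1)] <- bppm[1:(i - 1), i]
  if (i < n) p[(i + 1):n] <- bppm[i, (i + 1):n]
  p[i] <- bppm[i, i]
  p
}

xlogx <- function(p, base) {
  p <- pmax(p, 0)
  out <- numeric(length(p))
  pos <- p > 1e-300
  out[pos] <- p[pos] * log(p[pos], base = base)
  out
}

#' Structural positional entropy
#'
#' Per-position entropy of the pairing-state distribution from a base-pair
#' probability matrix.
#'
#' * `"full"`: Shannon entropy over the n states "paired with j" / "unpaired",
#'   `H(i) = -sum_j p*(i,j) log p*(i,j)` (maximum `log n` at the uniform
#'   distribution).
#' * `"binary"`: entropy of the paired/unpaired dichotomy,
#'   `H_b(i) = -(p_u log p_u + (1 - p_u) log(1 - p_u))` with
#'   `p_u = p*(i,i)` (maximum 1 bit).
#' * `"binary_sum"`: the sum-of-binary-terms variant
#'   `-sum_j (p log p + (1-p) log(1-p))`; provided for completeness, not used
#'   by the calibrated selection measures.
#'
#' `0 log 0` is taken as 0 throughout.
#'
#' @param bppm Base-pair probability matrix from [rna_partition()].
#' @param mode `"full"`, `"binary"` or `"binary_sum"`.
#' @param base Logarithm base: 2 for bits (default), `exp(1)` for nats.
#' @return Numeric vector of per-position entropies.
#' @export
positional_entropy <- function(bppm, mode = c("full", "binary", "binary_sum"),
                               base = 2) {
  mode <- match.arg(mode)
  n <- check_bppm(bppm)
  vapply(seq_len(n), function(i) {
    p <- pstar_row(bppm, i)
    switch(mode,
      full = -sum(xlogx(p, base)),
      binary = {
        pu <- p[i]
        -(xlogx(pu, base) + xlogx(1 - pu, base))
      },
      binary_sum = -sum(xlogx(p, base) + xlogx(1 - p, base))
    )
  }, numeric(1))
}

#' Ensemble defect
#'
#' Expected number of nucleotides whose pairing status in a Boltzmann-sampled
#' structure differs from the target: `sum_i (1 - p*(i, pi(i)))` where `pi(i)`
#' is the partner of `i` in the target (or `i` itself when unpaired).
#'
#' @inheritParams positional_entropy
#' @param target Target structure (dot-bracket or [parse_dotbracket()]).
#' @param positions Optional subset of positions (default: all).
#' @return Expected mismatch count (normalize by `length(positions)` for the
#'   normalized ensemble defect).
#' @export
ensemble_defect <- function(bppm, target, positions = NULL) {
  n <- check_bppm(bppm)
  db <- as_dotbracket(target)
  if (db$n != n) stop("target length != matrix size", call. = FALSE)
  pt <- pair_table(db)
  if (is.null(positions)) positions <- seq_len(n)
  sum(vapply(positions, function(i) {
    j <- if (pt[i] == 0) i else pt[i]
    1 - bppm[min(i, j), max(i, j)]
  }, numeric(1)))
}

#' Per-position expected base-pair distance profile
#'
#' `d(i)` counts, in expectation, the base-pair disagreements to which
#' position `i` is a party: `sum_{j:(i,j) in target} (1 - p*(i,j)) +
#' sum_{j:(i,j) not in target} p*(i,j)`. Each target pair contributes once per
#' endpoint, so `sum_i d(i)` double-counts pair terms relative to the
#' whole-molecule expected base-pair distance.
#'
#' @inheritParams ensemble_defect
#' @return Numeric vector `d(i)`.
#' @export
ebpd_profile <- function(bppm, target) {
  n <- check_bppm(bppm)
  db <- as_dotbracket(target)
  if (db$n != n) stop("target length != matrix size", call. = FALSE)
  pt <- pair_table(db)
  vapply(seq_len(n), function(i) {
    p <- pstar_row(bppm, i)
    d <- 0
    if (pt[i] > 0) d <- d + (1 - p[pt[i]])
    others <- setdiff(seq_len(n), c(i, if (pt[i] > 0) pt[i]))
    d + sum(p[others])
  }, numeric(1))
}

#' Expected base-pair distance to a target structure
#'
#' Boltzmann-average symmetric-difference cardinality between ensemble
#' structures and the target:
#' `sum_{(i,j) in target} (1 - p*(i,j)) + sum_{(i,j) not in target} p*(i,j)`.
#' With `positions` given, the sum of per-position contributions
#' ([ebpd_profile()]) over that subset is returned instead (pair terms then
#' count once per endpoint inside the subset).
#'
#' @inheritParams ensemble_defect
#' @return Expected distance (whole molecule) or site-restricted sum.
#' @export
expected_bp_distance <- function(bppm, target, positions = NULL) {
  n <- check_bppm(bppm)
  db <- as_dotbracket(target)
  if (db$n != n) stop("target length != matrix size", call. = FALSE)
  if (!is.null(positions)) {
    return(sum(ebpd_profile(bppm, target)[positions]))
  }
  pt <- pair_table(db)
  in_target <- matrix(FALSE, n, n)
  if (nrow(db$pairs) > 0) in_target[cbind(db$pairs$i, db$pairs$j)] <- TRUE
  ut <- upper.tri(bppm)
  sum(1 - bppm[in_target]) + sum(bppm[ut & !in_target])
}

#' Structural diversity of the Boltzmann ensemble
#'
#' * `"vienna"`: expected base-pair distance between two independent draws,
#'   `sum_{i<j} 2 p*(i,j) (1 - p*(i,j))`.
#' * `"morgan_higgs"`: `sum_i (1 - sum_j p*(i,j)^2)`, the per-position
#'   probability that two draws disagree on the pairing state of `i`.
#'
#' @inheritParams positional_entropy
#' @param variant `"vienna"` or `"morgan_higgs"`.
#' @return Non-negative scalar.
#' @export
structural_diversity <- function(bppm, variant = c("vienna", "morgan_higgs")) {
  variant <- match.arg(variant)
  n <- check_bppm(bppm)
  if (variant == "vienna") {
    p <- bppm[upper.tri(bppm)]
    sum(2 * p * (1 - p))
  } else {
    sum(vapply(seq_len(n), function(i) 1 - sum(pstar_row(bppm, i)^2),
               numeric(1)))
  }
}

#' Maximum-discrepancy between two per-position profiles
#'
#' Used for entropy and expected-base-pair-distance deviation of a candidate
#' from a reference molecule: `max_i |x_cand(i) - x_ref(i)|` over `positions`.
#'
#' @param candidate,reference Numeric per-position profiles of equal length.
#' @param positions Optional subset of positions (default: all).
#' @param stat `"max"` (default) or `"mean"` over the positions.
#' @return Non-negative scalar.
#' @export
discrepancy <- function(candidate, reference, positions = NULL,
                        stat = c("max", "mean")) {
  stat <- match.arg(stat)
  if (length(candidate) != length(reference)) {
    stop("profiles differ in length", call. = FALSE)
  }
  if (is.null(positions)) positions <- seq_along(candidate)
  d <- abs(candidate[positions] - reference[positions])
  if (stat == "max") max(d) else mean(d)
}

#' Per-position ensemble profile
#'
#' @inheritParams ensemble_defect
#' @param target Optional target structure; adds the `ebpd` column.
#' @param base Logarithm base for the entropies.
#' @return Tibble with columns `position`, `p_unpaired`, `entropy_full`,
#'   `entropy_binary`, and `ebpd` when a target is supplied.
#' @export
ensemble_profile <- function(bppm, target = NULL, base = 2) {
  n <- check_bppm(bppm)
  out <- tibble::tibble(
    position = seq_len(n),
    p_unpaired = diag(bppm),
    entropy_full = positional_entropy(bppm, "full", base),
    entropy_binary = positional_entropy(bppm, "binary", base)
  )
  if (!is.null(target)) out$ebpd <- ebpd_profile(bppm, target)
  out
}

# batched partition-function + structure-energy evaluation: one delegated
# call for the whole set of sequences when the backend is ViennaRNA
engine_pf_eval <- function(seqs, structures, engine) {
  seqs <- normalize_rna(seqs)
  texts <- vapply(structures, function(s) as_dotbracket(s)$text, character(1))
  mapply(function(s, db) check_structure_pairs(s, as_dotbracket(db)),
         seqs, texts)
  if (engine$backend == "toy") {
    return(lapply(seq_along(seqs), function(k) {
      part <- toy_partition_cpp(seqs[k], engine$RT)
      list(ensemble_energy = part$ensemble_energy,
           bppm = new_bppm(part$bppm),
           energy = -nrow(as_dotbracket(texts[k])$pairs))
    }))
  }
  ops <- c(
    lapply(seqs, function(s) list(op = "pf", seq = s)),
    mapply(function(s, db) list(op = "eval", seq = s, structure = db),
           seqs, texts, SIMPLIFY = FALSE)
  )
  res <- vienna_call(ops, engine)
  m <- length(seqs)
  lapply(seq_len(m), function(k) {
    pf <- res[[k]]
    n <- nchar(seqs[k])
    mat <- matrix(0, n, n)
    if (length(pf$pairs) > 0) {
      tri <- matrix(unlist(pf$pairs), ncol = 3, byrow = TRUE)
      mat[cbind(as.integer(tri[, 1]), as.integer(tri[, 2]))] <- tri[, 3]
    }
    diag(mat) <- as.numeric(pf$unpaired)
    list(ensemble_energy = pf$ensemble_energy,
         bppm = new_bppm(mat),
         energy = res[[m + k]]$energy)
  })
}

measure_one <- function(pe, seq, target, engine, site, base,
                        reference = NULL) {
  bppm <- pe$bppm
  db <- as_dotbracket(target)
  n <- db$n
  prof <- ensemble_profile(bppm, target = db, base = base)
  hb <- positional_entropy(bppm, "binary", base)
  rec <- tibble::tibble(
    prob_target = exp(-(pe$energy - pe$ensemble_energy) / engine$RT),
    gc = gc_percent(seq),
    entropy = mean(prof$entropy_full),
    entropy_site = mean(prof$entropy_full[site]),
    entropy_binary = mean(hb),
    entropy_binary_site = mean(hb[site]),
    ensemble_defect = ensemble_defect(bppm, db),
    ensemble_defect_site = ensemble_defect(bppm, db, site),
    norm_ensemble_defect = ensemble_defect(bppm, db) / n,
    ebpd = expected_bp_distance(bppm, db),
    ebpd_site = expected_bp_distance(bppm, db, site),
    diversity_vienna = structural_diversity(bppm, "vienna"),
    diversity_morgan_higgs = structural_diversity(bppm, "morgan_higgs")
  )
  if (!is.null(reference)) {
    rec$entropy_dis <- discrepancy(prof$entropy_full, reference$entropy_full)
    rec$entropy_dis_site <- discrepancy(prof$entropy_full,
                                        reference$entropy_full, site)
    rec$entropy_binary_dis <- discrepancy(hb, reference$entropy_binary)
    rec$entropy_binary_dis_site <- discrepancy(hb, reference$entropy_binary,
                                               site)
    rec$ebpd_dis_site <- discrepancy(prof$ebpd, reference$ebpd, site)
  }
  rec
}

#' Selection measures for candidate sequences
#'
#' Computes, for every row of `data`, the full record of scalar selection
#' measures used to rank inverse-folding solutions: Boltzmann probability of
#' the target, GC content, average full and binary positional entropy (whole
#' molecule and conserved site), ensemble defect, expected base-pair distance,
#' Vienna and Morgan-Higgs structural diversity, and -- when a reference
#' sequence is given -- maximum discrepancies of the entropy and
#' expected-distance profiles from the reference.
#'
#' @param data Data frame with columns `id` and `seq`.
#' @param target Target structure shared by all candidates (dot-bracket).
#' @param engine An [rna_engine()].
#' @param site Conserved-site positions (default [conserved_site()] when the
#'   target is 54 nt, otherwise must be supplied for site measures).
#' @param reference Optional reference sequence (e.g. the wild-type viroid)
#'   for discrepancy measures; folded with the same engine and target.
#' @param base Logarithm base for the entropies (2 = bits).
#' @return `data` with one measure column per record field appended.
#' @export
measure_suite <- function(data, target, engine = NULL, site = NULL,
                          reference = NULL, base = 2) {
  engine <- as_engine(engine)
  db <- as_dotbracket(target)
  if (is.null(site)) {
    if (db$n != 54) {
      stop("supply `site` positions for targets that are not the 54-nt design",
           call. = FALSE)
    }
    site <- conserved_site()
  }
  ref_prof <- NULL
  if (!is.null(reference)) {
    ref_part <- rna_partition(reference, engine)
    ref_prof <- ensemble_profile(ref_part$bppm, target = db, base = base)
    ref_prof$entropy_binary <- positional_entropy(ref_part$bppm, "binary", base)
  }
  pes <- engine_pf_eval(data$seq, rep(list(db), length(data$seq)), engine)
  recs <- mapply(measure_one, pes, data$seq,
                 MoreArgs = list(target = db, engine = engine, site = site,
                                 base = base, reference = ref_prof),
                 SIMPLIFY = FALSE)
  dplyr::bind_cols(tibble::as_tibble(data), dplyr::bind_rows(recs))
}

#' Selection measures under the published transcript convention
#'
#' The published per-candidate measures for the designed hammerheads refer to
#' the 58-nt in-vitro transcripts (designs extended by GG/CC, see
#' [extend_transcript()]), scored against the MFE structure of the extended
#' transcript, with positional entropy in nats averaged over all transcript
#' positions. This wrapper applies exactly that convention and reports
#' `pos_ent` (mean full entropy, nats), `ens_def` (whole-transcript ensemble
#' defect), `norm_ens_def` (`ens_def` / transcript length), `prob_target`
#' (Boltzmann probability of the transcript MFE structure) and the
#' conserved-site discrepancy columns when a reference is given.
#'
#' @param data Data frame with columns `id` and `seq` (54-nt designs).
#' @param engine An [rna_engine()]; the calibrated default is Turner 1999,
#'   37 C, dangles 2.
#' @param reference Optional 54-nt reference sequence (wild-type) for
#'   discrepancy measures, extended the same way.
#' @return `data` with measure columns appended.
#' @export
hh_measures <- function(data, engine = NULL, reference = NULL) {
  engine <- as_engine(engine)
  site_ext <- conserved_site(offset = 2L)
  ref_prof <- NULL
  if (!is.null(reference)) {
    ref_ext <- extend_transcript(reference)
    ref_mfe <- rna_mfe(ref_ext, engine)$structure
    ref_part <- rna_partition(ref_ext, engine)
    ref_prof <- ensemble_profile(ref_part$bppm, target = ref_mfe,
                                 base = exp(1))
    ref_prof$entropy_binary <- positional_entropy(ref_part$bppm, "binary",
                                                  exp(1))
  }
  ext <- extend_transcript(data$seq)
  s0 <- rna_mfe_batch(ext, engine)
  pes <- engine_pf_eval(ext, as.list(s0), engine)
  recs <- lapply(seq_along(ext), function(k) {
    s <- data$seq[k]
    rec <- measure_one(pes[[k]], ext[k], s0[k], engine, site_ext,
                       base = exp(1), reference = ref_prof)
    tibble::tibble(
      pos_ent = rec$entropy,
      ens_def = rec$ensemble_defect,
      norm_ens_def = rec$norm_ensemble_defect,
      prob_target = rec$prob_target,
      gc = gc_percent(s),
      entropy_binary_site = rec$entropy_binary_site,
      ebpd_dis_site = if ("ebpd_dis_site" %in% names(rec)) rec$ebpd_dis_site
                      else NA_real_,
      entropy_binary_dis_site = if ("entropy_binary_dis_site" %in% names(rec))
        rec$entropy_binary_dis_site else NA_real_
    )
  })
  dplyr::bind_cols(tibble::as_tibble(data), dplyr::bind_rows(recs))
}
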