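#' Configure a thermodynamic engine
#'
#' The package computes every ensemble quantity through a pluggable engine.
#' Two backends are provided:
#'
#' * `"turner1999"` / `"turner2004"`: the Turner nearest-neighbour model, by
#'   delegation to ViennaRNA (loaded with the corresponding parameter file).
#'   These are the production backends; `turner1999` is the default because
#'   the hammerhead target structure is only an MFE structure under the 1999
#'   parameters.
#' * `"toy"`: a built-in Nussinov-style model (-1 kcal/mol per AU/GC/GU pair,
#'   minimum hairpin loop of 3) with exact inside/outside partition function
#'   and seedable Boltzmann sampling. Small enough to verify against exhaustive
#'   structure enumeration; used for oracle tests and fast demonstrations.
#'
#' @param params One of `"turner1999"`, `"turner2004"`, `"toy"`.
#' @param temperature Temperature in degrees Celsius (default 37).
#' @param dangles Dangling-end model tag passed to the delegated engine
#'   (0, 1 or 2). ViennaRNA's partition function has no dangles = 1 model, so
#'   1 and 2 give identical ensemble quantities; 2 is the calibrated default
#'   (see [calibrate_dangles()]). Ignored by the toy backend.
#' @return Object of class `rna_engine`.
#' @examples
#' rna_engine("toy")
#' @export
rna_engine <- function(params = c("turner1999", "turner2004", "toy"),
                       temperature = 37, dangles = 2L) {
  params <- match.arg(params)
  stopifnot(dangles %in% 0:2)
  RT <- 0.0019872 * (temperature + 273.15) # kcal/mol; 0.61632 at 37 C
  structure(
    list(
      params = params,
      backend = if (params == "toy") "toy" else "vienna",
      temperature = temperature,
      dangles = as.integer(dangles),
      RT = RT
    ),
    class = "rna_engine"
  )
}

#' @export
print.rna_engine <- function(x, ...) {
  cat("<rna_engine>", x$params, "| T =", x$temperature,
      "C | RT =", signif(x$RT, 6), "kcal/mol | dangles =", x$dangles, "\n")
  invisible(x)
}

as_engine <- function(engine) {
  if (is.null(engine)) rna_engine() else engine
}

new_bppm <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  structure(mat, class = c("bppm", "matrix"))
}

#' @export
print.bppm <- function(x, ...) {
  cat("<bppm> n =", nrow(x), "| pairs with p > 0.01:",
      sum(x[upper.tri(x)] > 0.01), "\n")
  invisible(x)
}

check_structure_pairs <- function(seq, db) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) != db$n) {
    stop("sequence and structure differ in length", call. = FALSE)
  }
  if (nrow(db$pairs) > 0) {
    a <- ch[db$pairs$i]
    b <- ch[db$pairs$j]
    ok <- paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop("non-complementary pair (", db$pairs$i[bad], ",", db$pairs$j[bad],
           "): ", a[bad], "-", b[bad], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Minimum free energy structure
#'
#' @param seq RNA sequence (single string).
#' @param engine An [rna_engine()]; default Turner 1999.
#' @return List with `structure` (a [parse_dotbracket()] object) and `energy`
#'   (kcal/mol).
#' @export
rna_mfe <- function(seq, engine = NULL) {
  engine <- as_engine(engine)
  seq <- normalize_rna(seq)
  if (engine$backend == "toy") {
    res <- toy_fold_cpp(seq)
  } else {
    res <- vienna_call(list(list(op = "mfe", seq = seq)), engine)[[1]]
  }
  list(structure = parse_dotbracket(res$structure), energy = res$energy)
}

#' MFE structures for many sequences at once
#'
#' Batch variant of [rna_mfe()] returning only the structure strings; used by
#' the inverse-folding search where thousands of leaf checks are needed.
#'
#' @param seqs Character vector of sequences.
#' @inheritParams rna_mfe
#' @return Character vector of dot-bracket strings.
#' @export
rna_mfe_batch <- function(seqs, engine = NULL) {
  engine <- as_engine(engine)
  if (length(seqs) == 0) return(character(0))
  seqs <- normalize_rna(seqs)
  if (engine$backend == "toy") {
    as.character(toy_fold_batch_cpp(seqs))
  } else {
    ops <- lapply(seqs, function(s) list(op = "mfe", seq = s))
    vapply(vienna_call(ops, engine), function(r) r$structure, character(1))
  }
}

#' Free energy of a sequence/structure pair
#'
#' @inheritParams rna_mfe
#' @param structure Dot-bracket string or [parse_dotbracket()] object; every
#'   pair must be AU/UA/CG/GC/GU/UG.
#' @return Energy in kcal/mol.
#' @export
rna_free_energy <- function(seq, structure, engine = NULL) {
  engine <- as_engine(engine)
  seq <- normalize_rna(seq)
  db <- as_dotbracket(structure)
  check_structure_pairs(seq, db)
  if (engine$backend == "toy") {
    -nrow(db$pairs)
  } else {
    vienna_call(list(list(op = "eval", seq = seq, structure = db$text)),
                engine)[[1]]$energy
  }
}

#' Partition function and base-pair probability matrix
#'
#' @inheritParams rna_mfe
#' @return List with `ensemble_energy` (-RT log Z, kcal/mol) and `bppm`
#'   (n x n matrix: upper triangle = pair probabilities, diagonal =
#'   unpaired probabilities).
#' @export
rna_partition <- function(seq, engine = NULL) {
  engine <- as_engine(engine)
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (engine$backend == "toy") {
    res <- toy_partition_cpp(seq, engine$RT)
    bppm <- res$bppm
    # mirror into the upper triangle representation with unpaired diagonal
    return(list(ensemble_energy = res$ensemble_energy,
                bppm = new_bppm(bppm)))
  }
  res <- vienna_call(list(list(op = "pf", seq = seq)), engine)[[1]]
  mat <- matrix(0, n, n)
  if (length(res$pairs) > 0) {
    tri <- matrix(unlist(res$pairs), ncol = 3, byrow = TRUE)
    mat[cbind(as.integer(tri[, 1]), as.integer(tri[, 2]))] <- tri[, 3]
  }
  diag(mat) <- as.numeric(res$unpaired)
  list(ensemble_energy = res$ensemble_energy, bppm = new_bppm(mat))
}

#' Boltzmann probability of a structure
#'
#' `P(S, s) = exp(-E(S, s) / RT) / Z`.
#'
#' @inheritParams rna_free_energy
#' @return Probability in (0, 1].
#' @export
rna_boltzmann_probability <- function(seq, structure, engine = NULL) {
  engine <- as_engine(engine)
  seq <- normalize_rna(seq)
  db <- as_dotbracket(structure)
  check_structure_pairs(seq, db)
  if (engine$backend == "toy") {
    part <- toy_partition_cpp(seq, engine$RT)
    e <- -nrow(db$pairs)
    return(exp(-(e - part$ensemble_energy) / engine$RT))
  }
  res <- vienna_call(list(
    list(op = "eval", seq = seq, structure = db$text),
    list(op = "pf", seq = seq)
  ), engine)
  exp(-(res[[1]]$energy - res[[2]]$ensemble_energy) / engine$RT)
}

#' Sample secondary structures from the Boltzmann ensemble
#'
#' Draws are i.i.d. and deterministic given `seed`.
#'
#' @inheritParams rna_mfe
#' @param n Number of samples.
#' @param seed Integer seed for the sampler.
#' @return Character vector of dot-bracket strings.
#' @export
rna_sample <- function(seq, n, seed = 1L, engine = NULL) {
  engine <- as_engine(engine)
  seq <- normalize_rna(seq)
  stopifnot(n >= 1)
  if (engine$backend == "toy") {
    return(withr::with_seed(seed, as.character(toy_sample_cpp(seq, n, engine$RT))))
  }
  res <- vienna_call(list(list(op = "sample", seq = seq, n = n, seed = seed)),
                     engine)[[1]]
  unlist(res$structures)
}
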