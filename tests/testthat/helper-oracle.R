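# Brute-force oracles for the toy backend: every ensemble quantity computed
# directly from the exhaustively enumerated structure set.

toy_oracle_ensemble <- function(seq, engine = rna_engine("toy")) {
  structs <- enumerate_structures(seq)
  energy <- -vapply(strsplit(structs, ""),
                    function(ch) sum(ch == "("), numeric(1))
  w <- exp(-energy / engine$RT)
  z <- sum(w)
  n <- nchar(seq)
  bppm <- matrix(0, n, n)
  diag(bppm) <- 0
  unpaired <- numeric(n)
  for (k in seq_along(structs)) {
    pt <- pair_table(structs[k])
    p <- w[k] / z
    for (i in seq_len(n)) {
      if (pt[i] == 0) {
        unpaired[i] <- unpaired[i] + p
      } else if (pt[i] > i) {
        bppm[i, pt[i]] <- bppm[i, pt[i]] + p
      }
    }
  }
  diag(bppm) <- unpaired
  list(structs = structs, energy = energy, weight = w, z = z,
       ensemble_energy = -engine$RT * log(z), bppm = bppm)
}

# Boltzmann-enumeration definitions of the selection measures
toy_oracle_measures <- function(seq, target, engine = rna_engine("toy")) {
  or <- toy_oracle_ensemble(seq, engine)
  tgt <- pair_table(target)
  n <- nchar(seq)
  p <- or$weight / or$z
  defect <- 0
  ebpd <- 0
  per_pos_mismatch <- numeric(n)
  for (k in seq_along(or$structs)) {
    pt <- pair_table(or$structs[k])
    mismatch <- pt != tgt
    defect <- defect + p[k] * sum(mismatch)
    ebpd <- ebpd + p[k] * bp_distance(or$structs[k], target)
    per_pos_mismatch <- per_pos_mismatch + p[k] * mismatch
  }
  # vienna diversity: expected pair distance between two independent draws
  div <- 0
  for (a in seq_along(or$structs)) {
    for (b in seq_along(or$structs)) {
      div <- div + p[a] * p[b] * bp_distance(or$structs[a], or$structs[b])
    }
  }
  list(defect = defect, ebpd = ebpd, per_pos_mismatch = per_pos_mismatch,
       diversity_vienna = div)
}

# brute-force complete inverse folding over the full 4^n space
toy_brute_force_designs <- function(problem) {
  n <- problem$target$n
  nts <- c("A", "C", "G", "U")
  grid <- do.call(expand.grid,
                  c(rep(list(nts), n), stringsAsFactors = FALSE))
  seqs <- do.call(paste0, grid)
  keep <- iupac_match(seqs, problem$pattern)
  if (!is.null(problem$gc_window)) {
    gc <- gc_percent(seqs)
    keep <- keep & gc >= problem$gc_window[1] & gc < problem$gc_window[2] + 1
  }
  for (s in problem$compatible_with) {
    ok <- vapply(strsplit(seqs, ""), function(ch) {
      all(paste0(ch[s$pairs$i], ch[s$pairs$j]) %in%
            c("AU", "UA", "CG", "GC", "GU", "UG"))
    }, logical(1))
    keep <- keep & ok
  }
  for (s in problem$incompatible_with) {
    formable <- vapply(strsplit(seqs, ""), function(ch) {
      nrow(s$pairs) == 0 ||
        all(paste0(ch[s$pairs$i], ch[s$pairs$j]) %in%
              c("AU", "UA", "CG", "GC", "GU", "UG"))
    }, logical(1))
    keep <- keep & !formable
  }
  seqs <- seqs[keep]
  if (length(seqs) == 0) return(character(0))
  mfes <- rna_mfe_batch(seqs, problem$engine)
  sort(seqs[mfes == problem$target$text])
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
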