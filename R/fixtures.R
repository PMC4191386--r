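#' The 54-nt hammerhead target structure
#'
#' Rfam RF00008 consensus structure of the PLMVd hammerhead region, which is
#' also its Turner-1999 MFE structure; the inverse-folding target for the ten
#' designed ribozymes.
#'
#' @return A [parse_dotbracket()] structure of length 54.
#' @export
hammerhead_target <- function() {
  parse_dotbracket(
    ".((((((.(((((...))))).......((((........))))...)))))).")
}

#' The 54-code IUPAC design constraint pattern
#'
#' Conserved catalytic-core positions fixed to the wild-type nucleotides,
#' cleavage-site position 8 constrained to H (not G), and all remaining
#' positions constrained to differ from the wild type.
#'
#' @return An [iupac_pattern()] of length 54.
#' @export
hammerhead_pattern <- function() {
  iupac_pattern(paste0(
    "HBVHBGUHVH VHDVBBHDBD BCUGAVGAGV DVBVHBBBVH BHBCGAAACV DBVB"))
}

#' The ten designed hammerhead candidates
#'
#' Designed 54-nt sequences HH1-HH10 with the published selection criteria.
#'
#' @return Tibble with columns `id`, `seq`, `criteria`.
#' @export
hh_candidates <- function() {
  tibble::tribble(
    ~id, ~seq, ~criteria,
    "HH1", "UUAAUGUAGAGCGAUUCGUUCCUGAAGAGCUAUAAUUUCUUAGCGAAACAUUAU",
    "GC-content 30-39%, P(S0,s) >= 40%, smallest binary entropy distance for conserved site",
    "HH2", "UUAUUGUAGCGCGAUUCGCGCCUGAAGAGAUGCGUUUUAACAUCGAAACAGUAU",
    "GC-content 40-49%, P(S0,s) >= 40%, smallest binary entropy distance for conserved site",
    "HH3", "CUAUUGUAGCGCGAUUCGCGCCUGAAGAGAUCUGUUUUAUGAUCGAAACAGUAU",
    "GC-content 40-49%, P(S0,s) >= 40%, second smallest binary entropy distance for conserved site",
    "HH4", "UGGAUGUAGCGCGAUUCGCGCCUGAAGAGCGGUCAUCCAUCCGCGAAACAUUCU",
    "GC-content 50-59%, P(S0,s) >= 40%, smallest binary entropy distance for conserved site",
    "HH5", "CUCAGGUAGCGCGAUUCGCGCCUGAGGAGGGGUCUGGUAUCCCCGAAACCUGAU",
    "GC-content 60-69%, P(S0,s) >= 40%, smallest binary entropy distance for conserved site",
    "HH6", "UGGCGGUAGCGCGAUUCGCGCCUGAAGAGGGGUAACGCGUCCCCGAAACCGUCU",
    "GC-content 30-39%, P(S0,s) >= 40%, largest binary entropy distance for conserved site",
    "HH7", "UCAAUGUCGCGCGAUUCGCGCCUGAAGAGAUGGAAUUUAACAUCGAAACAUUGU",
    "GUC in positions 6-8, smallest ensemble defect",
    "HH8", "UCAAUGUAGCGCGAUUCGCGCCUGAAGAGAUGGAAUUUAACAUCGAAACAUUGU",
    "smallest ensemble defect",
    "HH9", "UUAAUGUCGCGCGAUUCGCGCCUGAAGAGAUCUGACUUCUGAUCGAAACAUUAU",
    "P(S0,s) <= 20%, smallest binary entropy distance for conserved site",
    "HH10", "UUAAGGUCGCGCGAUUCGCGCCUGACGAGCUAUAUUUUAUUAGCGAAACCUUAU",
    "smallest binary entropy distance for conserved site"
  )
}

#' Published cleavage kinetics and selection measures for HH1-HH10
#'
#' Observed cleavage rate `k_obs` (1/min), maximal fraction cleaved `f_max`,
#' mean squared error of the kinetics fit, average full positional entropy
#' `pos_ent` (nats, over the 58-nt transcript), whole-transcript ensemble
#' defect `ens_def`, and the conserved-site expected-base-pair-distance
#' discrepancy `ebpd_dis_act`.
#'
#' @return Tibble with one row per candidate.
#' @export
hh_kinetics <- function() {
  tibble::tribble(
    ~id, ~k_obs, ~f_max, ~mse, ~pos_ent, ~ens_def, ~ebpd_dis_act,
    "HH1", 0.037, 0.79, 0.0029, 0.270882, 4.167687, 0.0501207,
    "HH2", 0.0057, 0.74, 0.003, 0.287235, 4.552053, 0.0386253,
    "HH3", 0.0027, 0.65, 0.0039, 0.259577, 4.121914, 0.0410984,
    "HH4", 0.0127, 0.55, 0.0048, 0.403846, 6.755976, 0.0354213,
    "HH5", 0.0085, 0.52, 0.0066, 0.382235, 6.240083, 0.033132,
    "HH6", 0.102, 0.73, 0.0047, 0.414872, 8.138131, 0.059864,
    "HH7", 0.25, 0.74, 0.0107, 0.119159, 2.383671, 0.0406728,
    "HH8", 0.02, 0.68, 0.0124, 0.078518, 1.45179, 0.0662421,
    "HH9", 0.025, 0.76, 0.0015, 0.247886, 4.525597, 0.0328018,
    "HH10", 0.14, 0.77, 0.01, 0.286425, 4.975979, 0.0269354
  )
}

#' Reconstructed wild-type PLMVd hammerhead (synthetic reference)
#'
#' The 54-nt wild-type sequence (PLMVd plus-strand hammerhead region) is not
#' printed in the design record; this reconstruction inverts the design
#' pattern ([hammerhead_pattern()]): non-conserved positions carry the
#' three-letter complement of the wild-type nucleotide (B/D/H/V -> A/C/G/U),
#' conserved positions carry the wild-type nucleotide itself, and position 8
#' is the cytidine cleavage site. Consistency checks: GC content 40.74%
#' (reported: 40.7%) and Turner-1999 MFE equal to [hammerhead_target()].
#'
#' @return A single sequence string (54 nt).
#' @export
plmvd_reference <- function() {
  codes <- hammerhead_pattern()$codes
  inv <- c(B = "A", D = "C", H = "G", V = "U",
           A = "A", C = "C", G = "G", U = "U")
  nt <- unname(inv[codes])
  nt[8] <- "C"
  paste(nt, collapse = "")
}

#' The 54-nt ensemble-defect comparison sequence
#'
#' First sequence returned by the NUPACK web server for the same design
#' problem; used as the published normalized-ensemble-defect comparison point.
#'
#' @return A single sequence string (54 nt).
#' @export
nupack_reference <- function() {
  paste0("CGCCGGUAGC", "CUGACCCAGG", "CCUGAAGAGC", "UCUACCCCCC",
         "GAGCGAAACC", "GGCU")
}

#' The 166-nt modular hammerhead design
#'
#' Designed RNA harboring a type III hammerhead module in its terminal
#' stem-loop (cleavage site GUC at positions 114-116), selected by the
#' density-of-states two-peak screen.
#'
#' @return A single sequence string (166 nt).
#' @export
designed_166nt <- function() {
  paste0(
    "GCCGC", "GUAUA", "AGGGC", "UGCGA", "UAAGG", "GCAGU", "CCGUU", "UCUAC",
    "GGGCG", "GCCGU", "AAACC", "GCCCA", "CUACG", "CGGCG", "UGGUU", "AAGCC",
    "GGAAA", "GGAGA", "CCGGC", "AGGAG", "GGUAA", "UGGGC", "CGCGU", "CGCGG",
    "CGCGG", "GAGCG", "CGCCG", "CCUGA", "UGAGU", "CCGUG", "AGGAC", "GAAAC",
    "GCGGCC"
  )
}
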