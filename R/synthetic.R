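#' Generate a synthetic alignment with planted conservation
#'
#' Builds an ungapped reference row plus `n_seqs` aligned rows whose column
#' frequencies follow a planted conservation map: at mapped positions the
#' given nucleotide is drawn with the given frequency (other nucleotides
#' uniformly otherwise); unmapped positions are uniform. Optionally replaces
#' residues of non-reference rows with gaps at rate `gap_prob`. Deterministic
#' for a fixed seed.
#'
#' @param n_seqs Number of non-reference rows.
#' @param length Alignment width.
#' @param conservation_map Data frame with columns `position`, `nt`, `freq`
#'   (`freq` in (0, 1]).
#' @param seed Integer seed.
#' @param ref_id Id of the reference row.
#' @param gap_prob Per-residue gap probability in non-reference rows.
#' @return An [alignment_block()] whose first record is the reference.
#' @export
generate_synthetic_alignment <- function(n_seqs, length,
                                         conservation_map = NULL,
                                         seed = 1L, ref_id = "REF",
                                         gap_prob = 0) {
  nts <- c("A", "C", "G", "U")
  cm <- if (is.null(conservation_map)) {
    tibble::tibble(position = integer(0), nt = character(0),
                   freq = numeric(0))
  } else {
    tibble::as_tibble(conservation_map)
  }
  if (nrow(cm) > 0) {
    stopifnot(all(cm$position >= 1), all(cm$position <= length),
              all(cm$nt %in% nts))
    if (any(cm$freq <= 0 | cm$freq > 1)) {
      stop("conservation frequencies must lie in (0, 1]", call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    ref <- sample(nts, length, replace = TRUE)
    ref[cm$position] <- cm$nt
    rows <- vapply(seq_len(n_seqs), function(s) {
      ch <- sample(nts, length, replace = TRUE)
      for (r in seq_len(nrow(cm))) {
        p <- cm$position[r]
        if (stats::runif(1) <= cm$freq[r]) {
          ch[p] <- cm$nt[r]
        } else {
          ch[p] <- sample(setdiff(nts, cm$nt[r]), 1)
        }
      }
      if (gap_prob > 0) {
        gaps <- stats::runif(length) < gap_prob
        ch[gaps] <- "-"
      }
      paste(ch, collapse = "")
    }, character(1))
    alignment_block(tibble::tibble(
      id = c(ref_id, sprintf("SYN%03d", seq_len(n_seqs))),
      aligned = c(paste(ref, collapse = ""), rows)
    ))
  })
}

#' Generate synthetic cleavage time series
#'
#' Simulates the first-order cleavage model
#' `F(t) = f_max - (f_max - f0) exp(-k_obs t)` with additive Gaussian noise,
#' clipped to `[0, 1]`. Default times span the observable range of rates on
#' the order of 0.003-0.25 per minute.
#'
#' @param k_obs Cleavage rate (1/min).
#' @param f_max,f0 Plateau and initial fraction cleaved.
#' @param noise_sd Gaussian noise standard deviation (0 for exact values).
#' @param times Sampling times in minutes.
#' @param replicates Number of replicate series.
#' @param seed Integer seed.
#' @return Tibble with columns `replicate`, `time_min`, `fraction_cleaved`.
#' @export
generate_synthetic_kinetics <- function(k_obs, f_max = 0.7, f0 = 0,
                                        noise_sd = 0.05,
                                        times = c(0, 2, 5, 10, 20, 40, 80,
                                                  160, 320),
                                        replicates = 3, seed = 1L) {
  stopifnot(k_obs >= 0, f0 >= 0, f_max <= 1, f0 <= f_max, noise_sd >= 0,
            all(times >= 0), replicates >= 1)
  model <- f_max - (f_max - f0) * exp(-k_obs * times)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(replicates), function(r) {
      noisy <- model + stats::rnorm(length(times), sd = noise_sd)
      tibble::tibble(
        replicate = r,
        time_min = times,
        fraction_cleaved = pmin(pmax(noisy, 0), 1)
      )
    })
  })
}
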