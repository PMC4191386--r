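toy <- rna_engine("toy")

# a deterministic hand-made two-state matrix: position pairs (1,6) with p,
# unpaired otherwise (n = 6)
two_state_bppm <- function(p) {
  m <- diag(6)
  m[1, 6] <- p
  m[1, 1] <- 1 - p
  m[6, 6] <- 1 - p
  m
}

test_that("positional entropy: certain states give zero, even split gives 1 bit", {
  m <- two_state_bppm(0)
  expect_equal(positional_entropy(m, "full"), rep(0, 6))
  expect_equal(positional_entropy(m, "binary"), rep(0, 6))
  m <- two_state_bppm(0.5)
  h <- positional_entropy(m, "binary")
  expect_equal(h[1], 1)
  expect_equal(h[6], 1)
  expect_equal(h[2], 0)
  hf <- positional_entropy(m, "full")
  expect_equal(hf[1], 1) # two equiprobable states
  # nats
  expect_equal(positional_entropy(m, "binary", base = exp(1))[1], log(2))
})

test_that("binary_sum variant reduces to binary for a two-state position", {
  m <- two_state_bppm(0.3)
  expect_equal(positional_entropy(m, "binary_sum")[1],
               2 * positional_entropy(m, "binary")[1])
})

test_that("entropy validates matrix normalization", {
  m <- two_state_bppm(0.5)
  m[2, 2] <- 0.4
  expect_error(positional_entropy(m), "sum to 1")
})

test_that("ensemble defect is zero against a certain target and counts mismatches", {
  m <- two_state_bppm(1)
  expect_equal(ensemble_defect(m, "(....)"), 0)
  expect_equal(ensemble_defect(m, "......"), 2) # both 1 and 6 always mispaired
  m <- two_state_bppm(0.25)
  expect_equal(ensemble_defect(m, "(....)"), 2 * 0.75)
  expect_equal(ensemble_defect(m, "(....)", positions = 1), 0.75)
  expect_equal(ensemble_defect(m, "......"), 2 * 0.25)
  expect_error(ensemble_defect(m, "(...)"), "length")
})

test_that("toy ensembles: defect, EBPD and diversity match Boltzmann enumeration", {
  set.seed(21)
  for (rep in 1:8) {
    s <- random_rna(sample(8:13, 1))
    target <- rna_mfe(s, toy)$structure
    or <- toy_oracle_measures(s, target, toy)
    part <- rna_partition(s, toy)
    expect_equal(ensemble_defect(part$bppm, target), or$defect,
                 tolerance = 1e-9)
    expect_equal(expected_bp_distance(part$bppm, target), or$ebpd,
                 tolerance = 1e-9)
    expect_equal(structural_diversity(part$bppm, "vienna"),
                 or$diversity_vienna, tolerance = 1e-9)
    # per-position defect decomposition
    prof_defect <- vapply(seq_len(target$n), function(i) {
      ensemble_defect(part$bppm, target, positions = i)
    }, numeric(1))
    expect_equal(prof_defect, unname(or$per_pos_mismatch), tolerance = 1e-9)
  }
})

test_that("ebpd profile double-counts every pair term relative to the whole", {
  s <- "GGCGAAACGCC"
  target <- rna_mfe(s, toy)$structure
  bppm <- rna_partition(s, toy)$bppm
  d <- ebpd_profile(bppm, target)
  whole <- expected_bp_distance(bppm, target)
  # every disagreement term involves exactly two endpoints
  expect_equal(sum(d), 2 * whole, tolerance = 1e-9)
})

test_that("site-restricted additive measures never exceed whole-molecule", {
  s <- extend_transcript(hh_candidates()$seq[2])
  target <- rna_mfe(s)$structure
  bppm <- rna_partition(s)$bppm
  site <- conserved_site(offset = 2)
  expect_lte(ensemble_defect(bppm, target, site),
             ensemble_defect(bppm, target))
  expect_lte(expected_bp_distance(bppm, target, site),
             sum(ebpd_profile(bppm, target)))
})

test_that("structural diversity closed forms", {
  # two equiprobable structures differing by one pair
  m <- two_state_bppm(0.5)
  expect_equal(structural_diversity(m, "vienna"), 2 * 0.5 * 0.5)
  # uniform row: morgan-higgs per position 1 - sum p^2
  expect_equal(structural_diversity(diag(4), "morgan_higgs"), 0)
  expect_equal(structural_diversity(two_state_bppm(1), "vienna"), 0)
})

test_that("discrepancy is a max-abs difference over selected positions", {
  x <- c(0, 0, 0.2, 0)
  y <- c(0, 0.5, 0.2, 0)
  expect_equal(discrepancy(x, x), 0)
  expect_equal(discrepancy(x, y), 0.5)
  expect_equal(discrepancy(x, y, positions = c(3, 4)), 0)
  expect_equal(discrepancy(x, y, stat = "mean"), 0.125)
  expect_error(discrepancy(x, y[1:3]), "length")
})

test_that("engine round-trip discrepancy of a profile with itself is zero", {
  s <- hh_candidates()$seq[3]
  bppm <- rna_partition(s)$bppm
  prof1 <- ensemble_profile(bppm, hammerhead_target())
  prof2 <- ensemble_profile(rna_partition(s)$bppm, hammerhead_target())
  expect_lt(discrepancy(prof1$entropy_full, prof2$entropy_full), 1e-12)
})

test_that("measure_suite returns the full record and normalized defect in [0,1]", {
  data <- hh_candidates()[1:2, c("id", "seq")]
  rec <- measure_suite(data, hammerhead_target(),
                       reference = plmvd_reference())
  expect_equal(nrow(rec), 2)
  needed <- c("prob_target", "gc", "entropy", "entropy_site",
              "entropy_binary", "entropy_binary_site", "ensemble_defect",
              "ensemble_defect_site", "norm_ensemble_defect", "ebpd",
              "ebpd_site", "diversity_vienna", "diversity_morgan_higgs",
              "entropy_dis", "entropy_dis_site", "entropy_binary_dis",
              "entropy_binary_dis_site", "ebpd_dis_site")
  expect_true(all(needed %in% names(rec)))
  expect_true(all(rec$norm_ensemble_defect >= 0 &
                    rec$norm_ensemble_defect <= 1))
  expect_true(all(rec$prob_target > 0 & rec$prob_target <= 1))
  expect_true(all(rec[needed] >= 0))
})

test_that("measure_suite on a toy 12-mer equals the brute-force record", {
  s <- "GGCGAAACGCCA"
  target <- rna_mfe(s, toy)$structure
  rec <- measure_suite(tibble::tibble(id = "x", seq = s), target$text,
                       engine = toy, site = 1:4)
  or <- toy_oracle_measures(s, target, toy)
  part <- toy_oracle_ensemble(s, toy)
  expect_equal(rec$ensemble_defect, or$defect, tolerance = 1e-9)
  expect_equal(rec$ebpd, or$ebpd, tolerance = 1e-9)
  expect_equal(rec$diversity_vienna, or$diversity_vienna, tolerance = 1e-9)
  expect_equal(rec$prob_target,
               exp(-(-nrow(target$pairs)) / toy$RT) / part$z,
               tolerance = 1e-9)
})
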