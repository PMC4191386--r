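make_aln <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  alignment_block(tibble::tibble(id = ids, aligned = rows))
}

test_that("map_columns_to_reference maps non-gap columns", {
  aln <- make_aln(c("ACGU", "AC-U"), ids = c("ref", "x"))
  m <- map_columns_to_reference(aln, "ref")
  expect_equal(m$column, 1:4)
  expect_equal(m$position, 1:4)
  aln <- make_aln(c("A-CG", "AACG"), ids = c("ref", "x"))
  m <- map_columns_to_reference(aln, "ref")
  expect_equal(m$column, c(1, 3, 4))
  expect_equal(m$position, 1:3)
  expect_error(map_columns_to_reference(aln, "missing"), "not found")
})

test_that("reference gaps reduce the mapped positions", {
  aln <- generate_synthetic_alignment(5, 20, seed = 9)
  rows <- aln$records$aligned
  gapped <- rows[1]
  substr(gapped, 3, 3) <- "-"
  substr(gapped, 7, 7) <- "-"
  substr(gapped, 11, 11) <- "-"
  substr(gapped, 18, 18) <- "-"
  aln2 <- make_aln(c(gapped, rows[-1]),
                   ids = c("ref", sprintf("x%d", seq_along(rows[-1]))))
  m <- map_columns_to_reference(aln2, "ref")
  expect_equal(nrow(m), 16)
  expect_false(any(c(3, 7, 11, 18) %in% m$column))
})

test_that("conservation_profile frequencies sum to one over covered positions", {
  aln <- make_aln(c("ACGU", "ACGU", "AC-U", "GCGU"),
                  ids = c("ref", "a", "b", "c"))
  prof <- conservation_profile(aln, "ref")
  expect_equal(prof$position, 1:4)
  expect_equal(rowSums(as.matrix(prof[, c("A", "C", "G", "U")])), rep(1, 4))
  expect_equal(prof$coverage, c(4L, 4L, 3L, 4L))
  expect_equal(prof$A[1], 3 / 4)
  expect_equal(prof$G[3], 1) # gaps excluded from the denominator
  prof_g <- conservation_profile(aln, "ref", gap_inclusive = TRUE)
  expect_equal(prof_g$G[3], 3 / 4)
})

test_that("conserved_positions applies the threshold with majority nucleotide", {
  prof <- tibble::tibble(
    position = 1:3, column = 1:3, ref_nt = c("A", "C", "U"), coverage = 1000L,
    A = c(0.97, 0.01, 0.25), C = c(0.01, 0.949, 0.25),
    G = c(0.01, 0.04, 0.25), U = c(0.01, 0.001, 0.25)
  )
  got <- conserved_positions(prof, 0.96)
  expect_equal(got$position, 1L)
  expect_equal(got$nt, "A")
  # 94.9% conserved column: excluded at 0.96, included at 0.94
  expect_equal(conserved_positions(prof, 0.94)$position, c(1L, 2L))
  # uniform column excluded at any threshold above 0.25
  expect_false(3 %in% conserved_positions(prof, 0.26)$position)
  expect_equal(conserved_positions(prof, "strict")$position, 1L)
})

test_that("planted conservation is recovered exactly (generator round trip)", {
  cmap <- tibble::tibble(position = c(2, 5, 9), nt = c("G", "A", "C"),
                         freq = c(1, 0.99, 0.98))
  aln <- generate_synthetic_alignment(800, 12, cmap, seed = 4)
  prof <- conservation_profile(aln, "REF")
  got <- conserved_positions(prof, 0.95)
  expect_equal(got$position, c(2L, 5L, 9L))
  expect_equal(got$nt, c("G", "A", "C"))
})

test_that("build_design_pattern composes not-codes, conserved and overrides", {
  expect_equal(build_design_pattern("ACGU")$codes, c("B", "D", "H", "V"))
  p <- build_design_pattern("ACGU", conserved = c(`2` = "C"),
                            overrides = c(`4` = "H"))
  expect_equal(paste(p$codes, collapse = ""), "BCHH")
  expect_error(build_design_pattern("ACGU", conserved = c(`2` = "C"),
                                    overrides = c(`2` = "H")),
               "both conserved and overridden")
  expect_error(build_design_pattern("ACGU", conserved = c(`9` = "C")),
               "within 1..4", fixed = TRUE)
})

test_that("the printed pattern is reproduced from the reconstructed reference", {
  conserved <- c(`6` = "G", `7` = "U", `22` = "C", `23` = "U", `24` = "G",
                 `25` = "A", `27` = "G", `28` = "A", `29` = "G", `44` = "C",
                 `45` = "G", `46` = "A", `47` = "A", `48` = "A", `49` = "C")
  p <- build_design_pattern(plmvd_reference(), conserved,
                            overrides = c(`8` = "H"))
  expect_equal(paste(p$codes, collapse = ""),
               paste(hammerhead_pattern()$codes, collapse = ""))
})

test_that("select_candidates filters, ranks, and breaks ties lexicographically", {
  recs <- hh_candidates() |>
    dplyr::inner_join(hh_kinetics(), by = "id") |>
    dplyr::mutate(gc = gc_percent(seq))
  # smallest ensemble defect overall -> HH8
  expect_equal(select_candidates(recs, "ens_def")$id, "HH8")
  # order statistic: second smallest
  expect_equal(select_candidates(recs, "ens_def", rank = 2)$id, "HH7")
  # maximization
  expect_equal(select_candidates(recs, "ens_def", direction = "max")$id,
               "HH6")
  # gc window filter (30-39% decade bin)
  in_bin <- select_candidates(recs, "ens_def", gc_window = c(30, 39),
                              rank = NULL)
  expect_true(all(in_bin$gc >= 30 & in_bin$gc < 40))
  # empty filtered set is an explicit empty result
  empty <- select_candidates(recs, "ens_def", gc_window = c(90, 99))
  expect_equal(nrow(empty), 0)
  # permutation invariance
  perm <- recs[sample(nrow(recs)), ]
  expect_equal(select_candidates(perm, "ens_def", rank = NULL)$id,
               select_candidates(recs, "ens_def", rank = NULL)$id)
  # deterministic lexicographic tie-break on equal objectives
  ties <- tibble::tibble(id = c("b", "a"), seq = c("GGUU", "AACC"),
                         value = c(1, 1))
  expect_equal(select_candidates(ties, "value")$id, "a")
})

test_that("prob_target bounds act as filters", {
  recs <- hh_candidates()[c(1, 9), ]
  recs <- dplyr::bind_cols(
    recs, tibble::tibble(prob_target = c(0.40, 0.18), score = c(2, 1)))
  expect_equal(select_candidates(recs, "score", prob_min = 0.4)$id, "HH1")
  expect_equal(select_candidates(recs, "score", prob_max = 0.2)$id, "HH9")
})
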