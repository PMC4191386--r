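toy <- rna_engine("toy")

test_that("design_problem validates lengths and structures", {
  expect_error(design_problem("((...))", "NNN"), "pattern length")
  expect_error(design_problem("((...))",
                              compatible_with = list("((....))")),
               "length")
  p <- design_problem("((...))")
  expect_equal(p$pattern$codes, rep("N", 7))
})

test_that("propagation restricts paired domains to complementable sets", {
  # A at position 1 forces U at its partner
  p <- design_problem("((...))", "ANNNNNN", engine = toy)
  prop <- propagate_domains(p)
  expect_false(prop$unsat)
  expect_equal(prop$domains[[7]], "U")
  # G allows C and U
  p <- design_problem("((...))", "GNNNNNN", engine = toy)
  expect_setequal(propagate_domains(p)$domains[[7]], c("C", "U"))
})

test_that("propagation certifies pair contradictions as UNSAT", {
  p <- design_problem("((...))", "ANNNNNA", engine = toy)
  prop <- propagate_domains(p)
  expect_true(prop$unsat)
  out <- prove_unsat(p, budget = 100)
  expect_equal(out$status, "UNSAT")
  expect_equal(out$nodes_explored, 0L) # zero search (and engine) effort
  expect_true(out$complete)
})

test_that("propagation reaches a fixed point through compatible structures", {
  # chained constraint: target pairs (1,7); compatible structure pairs (1,9)
  # with A fixed at 9 -> 1 must be U -> 7 must be A or G
  p <- design_problem("((...))..", "NNNNNNNNA",
                      compatible_with = list("(.......)"), engine = toy)
  prop <- propagate_domains(p)
  expect_false(prop$unsat)
  expect_equal(prop$domains[[1]], "U")
  expect_setequal(prop$domains[[7]], c("A", "G"))
})

test_that("enumeration equals brute force over the full space (toy)", {
  set.seed(31)
  targets <- c("((...))." , ".((...))", "((....))")
  for (tgt in targets) {
    prob <- design_problem(tgt, engine = toy)
    out <- enumerate_designs(prob, node_budget = 1e6)
    brute <- toy_brute_force_designs(prob)
    expect_equal(out$status, "SOLUTIONS")
    expect_true(out$complete)
    expect_identical(sort(out$solutions$seq), brute)
  }
})

test_that("enumeration honours random IUPAC patterns and GC windows", {
  set.seed(32)
  codes <- names(ribodesign:::IUPAC_DOMAINS)
  for (rep in 1:20) {
    n <- sample(7:9, 1)
    half <- (n - 4) %/% 2
    tgt <- paste0(strrep("(", half), strrep(".", n - 2 * half),
                  strrep(")", half))
    pattern <- paste(sample(codes, n, replace = TRUE), collapse = "")
    gc <- if (rep %% 2 == 0) sort(sample(0:100, 2)) else NULL
    prob <- design_problem(tgt, pattern, gc_window = gc, engine = toy)
    out <- enumerate_designs(prob, node_budget = 1e6)
    brute <- toy_brute_force_designs(prob)
    expect_true(out$complete)
    expect_identical(sort(out$solutions$seq), brute)
    expect_equal(out$status,
                 if (length(brute) > 0) "SOLUTIONS" else "UNSAT")
  }
})

test_that("compatibility and incompatibility constraints filter as defined", {
  tgt <- "((...)).."
  compat <- "(.......)" # 1 must also pair with 9
  incompat <- ".(.....)." # 2-8 pair must NOT be formable
  prob <- design_problem(tgt, compatible_with = list(compat),
                         incompatible_with = list(incompat), engine = toy)
  out <- enumerate_designs(prob, node_budget = 1e6)
  brute <- toy_brute_force_designs(prob)
  expect_identical(sort(out$solutions$seq), brute)
  expect_gt(nrow(out$solutions), 0)
  # every solution: can form (1,9), cannot form (2,8)
  ok_pair <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "CG", "GC", "GU", "UG")
  for (s in out$solutions$seq) {
    ch <- strsplit(s, "")[[1]]
    expect_true(ok_pair(ch[1], ch[9]))
    expect_false(ok_pair(ch[2], ch[8]))
  }
})

test_that("adding constraints never enlarges the solution set", {
  tgt <- "((...))."
  p0 <- design_problem(tgt, engine = toy)
  p1 <- design_problem(tgt, "SNNNNNNN", engine = toy)
  p2 <- design_problem(tgt, "SNNNNNNN", gc_window = c(40, 60), engine = toy)
  s0 <- enumerate_designs(p0, node_budget = 1e6)$solutions$seq
  s1 <- enumerate_designs(p1, node_budget = 1e6)$solutions$seq
  s2 <- enumerate_designs(p2, node_budget = 1e6)$solutions$seq
  expect_true(all(s1 %in% s0))
  expect_true(all(s2 %in% s1))
})

test_that("emission is deterministic and duplicate-free", {
  prob <- design_problem("((...)).", "NNNNNNNN", engine = toy)
  a <- enumerate_designs(prob, node_budget = 1e6)
  b <- enumerate_designs(prob, node_budget = 1e6)
  expect_identical(a$solutions, b$solutions)
  expect_identical(a$nodes_explored, b$nodes_explored)
  expect_false(anyDuplicated(a$solutions$seq) > 0)
})

test_that("a fixed full sequence whose MFE differs from the target is UNSAT", {
  s <- "GGGGGAAAACCCCC" # folds into (((((....)))))
  prob <- design_problem(".((((....)))).", s, engine = toy)
  out <- enumerate_designs(prob)
  expect_equal(out$status, "UNSAT")
  expect_true(out$complete)
  expect_equal(out$leaves_tested, 1L)
})

test_that("soundness: emitted sequences re-verify MFE equality independently", {
  prob <- design_problem("((....))", engine = toy)
  out <- enumerate_designs(prob, node_budget = 1e6)
  refold <- rna_mfe_batch(out$solutions$seq, toy)
  expect_true(all(refold == "((....))"))
})

test_that("max_solutions truncates the deterministic stream", {
  prob <- design_problem("((...))", max_solutions = 3, engine = toy)
  out <- enumerate_designs(prob, node_budget = 1e6)
  full <- enumerate_designs(design_problem("((...))", engine = toy),
                            node_budget = 1e6)
  expect_equal(out$status, "SOLUTIONS")
  expect_equal(nrow(out$solutions), 3)
  expect_identical(out$solutions$seq, full$solutions$seq[1:3])
})

test_that("budget exhaustion yields a resume token that continues the stream", {
  prob <- design_problem("((...))", engine = toy)
  full <- enumerate_designs(prob, node_budget = 1e6)$solutions$seq
  got <- character(0)
  token <- NULL
  for (round in 1:200) {
    out <- enumerate_designs(prob, node_budget = 300, leaf_batch = 32,
                             resume = token)
    got <- c(got, out$solutions$seq)
    if (out$status != "BUDGET_EXHAUSTED") break
    token <- out$resume
  }
  expect_equal(out$status, "SOLUTIONS")
  expect_identical(got, full)
})

test_that("the 54-nt problem at a small budget reports exhaustion soundly", {
  prob <- design_problem(hammerhead_target(), hammerhead_pattern(),
                         max_solutions = 5)
  out <- enumerate_designs(prob, node_budget = 500, leaf_batch = 128)
  expect_equal(out$status, "BUDGET_EXHAUSTED")
  expect_false(out$complete)
  expect_type(out$resume, "integer")
  # soundness holds for whatever was emitted (typically nothing at this scale)
  if (nrow(out$solutions) > 0) {
    expect_true(all(rna_mfe_batch(out$solutions$seq) ==
                      hammerhead_target()$text))
    expect_true(all(iupac_match(out$solutions$seq, hammerhead_pattern())))
  }
})

test_that("the G8 variant at a small budget is BUDGET_EXHAUSTED, not UNSAT", {
  codes <- hammerhead_pattern()$codes
  codes[8] <- "G"
  prob <- design_problem(hammerhead_target(),
                         paste(codes, collapse = ""), engine = toy)
  out <- prove_unsat(prob, budget = 2000)
  expect_equal(out$status, "BUDGET_EXHAUSTED")
  expect_false(out$complete)
})
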