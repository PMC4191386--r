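# Bitmask nucleotide domains: A=1, C=2, G=4, U=8.
NT_BIT <- c(A = 1L, C = 2L, G = 4L, U = 8L)
GC_MASK <- 6L

# partner sets under AU/UA/CG/GC/GU/UG: A~U, C~G, G~{C,U}, U~{A,G}
SINGLE_PARTNER <- c(8L, 4L, 10L, 5L)

PARTNER_MASK <- vapply(1:15, function(m) {
  bits <- which(bitwAnd(m, NT_BIT) > 0L)
  Reduce(bitwOr, SINGLE_PARTNER[bits], 0L)
}, integer(1))

MASK_TO_CODE <- c("A", "C", "M", "G", "R", "S", "V", "U",
                  "W", "Y", "H", "K", "D", "B", "N")

mask_from_code <- function(code) {
  vapply(IUPAC_DOMAINS[code],
         function(dom) sum(NT_BIT[dom]), integer(1), USE.NAMES = FALSE)
}

mask_size <- function(m) {
  vapply(m, function(x) sum(bitwAnd(x, NT_BIT) > 0L), integer(1))
}

#' Define an inverse folding design problem
#'
#' A design problem asks for all sequences that (a) match an IUPAC pattern,
#' (b) have GC content inside an optional window, (c) can form every base pair
#' of each `compatible_with` structure, (d) cannot form all pairs of any
#' `incompatible_with` structure, and (e) have the target as their MFE
#' structure under the chosen engine.
#'
#' @param target Target structure (dot-bracket or [parse_dotbracket()]).
#' @param pattern IUPAC constraint ([iupac_pattern()] or string); same length
#'   as the target. Default: unconstrained (`N` everywhere).
#' @param gc_window Optional `c(lo, hi)` in integer percent. The window is the
#'   contiguous bin `lo <= 100 (G+C)/n < hi + 1`, so consecutive decade
#'   windows (30-39, 40-49, ...) tile the range without gaps.
#' @param compatible_with,incompatible_with Lists of structures (same length
#'   as the target).
#' @param max_solutions Stop after this many solutions (default unbounded).
#' @param engine An [rna_engine()] used for the leaf MFE test.
#' @return Object of class `design_problem`.
#' @export
design_problem <- function(target, pattern = NULL, gc_window = NULL,
                           compatible_with = list(),
                           incompatible_with = list(),
                           max_solutions = Inf, engine = NULL) {
  target <- as_dotbracket(target)
  if (is.null(pattern)) {
    pattern <- iupac_pattern(strrep("N", target$n))
  } else if (!inherits(pattern, "iupac_pattern")) {
    pattern <- iupac_pattern(pattern)
  }
  if (length(pattern$codes) != target$n) {
    stop("pattern length ", length(pattern$codes), " != target length ",
         target$n, call. = FALSE)
  }
  compatible_with <- lapply(compatible_with, as_dotbracket)
  incompatible_with <- lapply(incompatible_with, as_dotbracket)
  for (s in c(compatible_with, incompatible_with)) {
    if (s$n != target$n) {
      stop("constraint structure length ", s$n, " != target length ",
           target$n, call. = FALSE)
    }
  }
  if (!is.null(gc_window)) {
    stopifnot(length(gc_window) == 2, gc_window[1] <= gc_window[2])
  }
  structure(
    list(target = target, pattern = pattern, gc_window = gc_window,
         compatible_with = compatible_with,
         incompatible_with = incompatible_with,
         max_solutions = max_solutions, engine = as_engine(engine)),
    class = "design_problem"
  )
}

#' @export
print.design_problem <- function(x, ...) {
  cat("<design_problem> n =", x$target$n, "\n")
  cat("  target :", x$target$text, "\n")
  cat("  pattern:", paste(x$pattern$codes, collapse = ""), "\n")
  if (!is.null(x$gc_window)) {
    cat("  gc     : [", x$gc_window[1], ",", x$gc_window[2], "] %\n")
  }
  if (length(x$compatible_with) > 0) {
    cat("  compatible_with:", length(x$compatible_with), "structure(s)\n")
  }
  if (length(x$incompatible_with) > 0) {
    cat("  incompatible_with:", length(x$incompatible_with), "structure(s)\n")
  }
  invisible(x)
}

# all complementarity arcs: target pairs plus every compatible structure's
problem_arcs <- function(problem) {
  pairs <- problem$target$pairs
  for (s in problem$compatible_with) pairs <- rbind(pairs, s$pairs)
  unique(pairs)
}

#' Constraint propagation over nucleotide domains
#'
#' Restricts every position's nucleotide domain to values that can still form
#' each required base pair (target pairs and every `compatible_with`
#' structure), iterating to a fixed point. Unsatisfiability (an emptied
#' domain) is a returned value, not an error.
#'
#' @param problem A [design_problem()].
#' @return List with `unsat` (logical), `domains` (list of per-position
#'   nucleotide sets) and `codes` (the narrowed IUPAC pattern string). When
#'   `unsat` is `TRUE` the domains are those at the point of failure.
#' @export
propagate_domains <- function(problem) {
  stopifnot(inherits(problem, "design_problem"))
  masks <- mask_from_code(problem$pattern$codes)
  arcs <- problem_arcs(problem)
  if (nrow(arcs) > 0) {
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(arcs))) {
        i <- arcs$i[k]; j <- arcs$j[k]
        ni <- bitwAnd(masks[i], PARTNER_MASK[masks[j]])
        nj <- bitwAnd(masks[j], PARTNER_MASK[masks[i]])
        if (ni == 0L || nj == 0L) {
          masks[i] <- ni; masks[j] <- nj
          return(list(unsat = TRUE, domains = domains_from_masks(masks),
                      codes = codes_from_masks(masks)))
        }
        if (ni != masks[i] || nj != masks[j]) changed <- TRUE
        masks[i] <- ni; masks[j] <- nj
      }
      if (!changed) break
    }
  }
  list(unsat = FALSE, domains = domains_from_masks(masks),
       codes = codes_from_masks(masks), masks = masks)
}

domains_from_masks <- function(masks) {
  lapply(masks, function(m) names(NT_BIT)[bitwAnd(m, NT_BIT) > 0L])
}

codes_from_masks <- function(masks) {
  paste(ifelse(masks == 0L, "-", MASK_TO_CODE[pmax(masks, 1L)]),
        collapse = "")
}

# does `seq` fail at least one pair of every incompatible structure?
passes_incompatibility <- function(ch, incompatible_with) {
  for (s in incompatible_with) {
    if (nrow(s$pairs) == 0) return(FALSE) # empty structure is always formable
    ok <- paste0(ch[s$pairs$i], ch[s$pairs$j]) %in%
      c("AU", "UA", "CG", "GC", "GU", "UG")
    if (all(ok)) return(FALSE)
  }
  TRUE
}

#' Complete enumeration of an inverse folding problem
#'
#' Depth-first branch-and-propagate search over the constrained sequence
#' space. Variable ordering: paired positions before unpaired, then smallest
#' propagated domain, then position index. Value ordering: A < C < G < U.
#' Every leaf surviving propagation, the GC window and the incompatibility
#' test is checked for MFE equality with the target through the engine
#' (batched). The emission order is therefore deterministic, duplicates are
#' structurally impossible, and when the search space is exhausted without a
#' solution the problem is provably unsatisfiable.
#'
#' @param problem A [design_problem()].
#' @param node_budget Maximum number of search-tree nodes to expand before
#'   giving up with status `BUDGET_EXHAUSTED` and a resume token.
#' @param leaf_batch Number of leaf sequences per batched MFE call.
#' @param resume Resume token from a previous `BUDGET_EXHAUSTED` outcome;
#'   continues the traversal where it stopped.
#' @return Object of class `search_outcome`: `status` (`"SOLUTIONS"`,
#'   `"UNSAT"` or `"BUDGET_EXHAUSTED"`), `solutions` (tibble with `seq`,
#'   `gc`), `nodes_explored`, `leaves_tested`, `complete` (whether the whole
#'   space was covered) and `resume` (token, or `NULL`).
#' @examples
#' p <- design_problem("((...))", "GNNNNNC", engine = rna_engine("toy"))
#' enumerate_designs(p, node_budget = 1e4)
#' @export
enumerate_designs <- function(problem, node_budget = 1e6, leaf_batch = 512,
                              resume = NULL) {
  stopifnot(inherits(problem, "design_problem"))
  prop <- propagate_domains(problem)
  n <- problem$target$n
  if (prop$unsat) {
    return(new_search_outcome("UNSAT", character(0), 0L, 0L, TRUE, NULL,
                              problem))
  }
  arcs <- problem_arcs(problem)
  partners <- lapply(seq_len(n), function(i) {
    c(arcs$j[arcs$i == i], arcs$i[arcs$j == i])
  })
  paired <- lengths(partners) > 0
  ord <- order(!paired, mask_size(prop$masks), seq_len(n))

  st <- new.env(parent = emptyenv())
  st$nodes <- 0L
  st$leaves <- 0L
  st$solutions <- character(0)
  st$batch <- vector("list", leaf_batch)
  st$nb <- 0L
  st$done <- FALSE        # max_solutions reached
  st$exhausted <- FALSE   # node budget spent
  st$token <- NULL
  st$path <- integer(n)   # chosen nucleotide bit per depth
  st$resuming <- !is.null(resume)

  gc_window <- problem$gc_window
  max_solutions <- problem$max_solutions
  target_text <- problem$target$text
  engine <- problem$engine
  incompat <- problem$incompatible_with
  nt_of_bit <- character(8)
  nt_of_bit[NT_BIT] <- names(NT_BIT)

  flush_batch <- function() {
    if (st$nb == 0) return(invisible())
    seqs <- unlist(st$batch[seq_len(st$nb)])
    st$nb <- 0L
    mfes <- rna_mfe_batch(seqs, engine)
    st$solutions <- c(st$solutions, seqs[mfes == target_text])
    if (length(st$solutions) >= max_solutions) st$done <- TRUE
    invisible()
  }

  descend <- function(depth, masks, gc_count) {
    if (st$done || st$exhausted) return(invisible())
    if (depth > n) {
      # interior pruning brackets the window; the leaf must satisfy it exactly
      if (!is.null(gc_window)) {
        g <- 100 * gc_count / n
        if (g < gc_window[1] || g >= gc_window[2] + 1) return(invisible())
      }
      ch <- nt_of_bit[masks]
      st$leaves <- st$leaves + 1L
      if (passes_incompatibility(ch, incompat)) {
        st$nb <- st$nb + 1L
        st$batch[[st$nb]] <- paste(ch, collapse = "")
        if (st$nb >= leaf_batch) flush_batch()
      }
      return(invisible())
    }
    p <- ord[depth]
    if (!is.null(gc_window)) {
      rest <- masks[ord[depth:n]]
      min_gc <- gc_count + sum(bitwAnd(rest, bitwNot(GC_MASK)) == 0L)
      max_gc <- gc_count + sum(bitwAnd(rest, GC_MASK) > 0L)
      if (100 * max_gc / n < gc_window[1] ||
          100 * min_gc / n >= gc_window[2] + 1) {
        return(invisible())
      }
    }
    for (b in NT_BIT) {
      if (bitwAnd(masks[p], b) == 0L) next
      if (st$resuming) {
        if (b < resume[depth]) next
        if (b > resume[depth]) st$resuming <- FALSE
      }
      if (st$nodes >= node_budget) {
        st$exhausted <- TRUE
        st$token <- c(if (depth > 1) st$path[seq_len(depth - 1)], b,
                      rep(0L, n - depth))
        return(invisible())
      }
      st$nodes <- st$nodes + 1L
      st$path[depth] <- b
      m2 <- masks
      m2[p] <- b
      ok <- TRUE
      for (q in partners[[p]]) {
        nm <- bitwAnd(m2[q], PARTNER_MASK[b])
        if (nm == 0L) { ok <- FALSE; break }
        m2[q] <- nm
      }
      if (ok) {
        descend(depth + 1L,
                m2,
                gc_count + as.integer(bitwAnd(b, GC_MASK) > 0L))
      }
      if (st$done || st$exhausted) return(invisible())
      st$resuming <- FALSE
    }
    invisible()
  }

  descend(1L, prop$masks, 0L)
  flush_batch()
  if (length(st$solutions) > max_solutions) {
    st$solutions <- st$solutions[seq_len(max_solutions)]
  }
  complete <- !st$exhausted && !st$done
  status <- if (st$exhausted) "BUDGET_EXHAUSTED"
            else if (length(st$solutions) > 0) "SOLUTIONS"
            else if (complete) "UNSAT"
            else "SOLUTIONS" # unreachable: done implies solutions
  new_search_outcome(status, st$solutions, st$nodes, st$leaves, complete,
                     st$token, problem)
}

new_search_outcome <- function(status, solutions, nodes, leaves, complete,
                               token, problem) {
  structure(
    list(
      status = status,
      solutions = tibble::tibble(seq = solutions, gc = gc_percent(solutions)),
      nodes_explored = nodes,
      leaves_tested = leaves,
      complete = complete,
      resume = token,
      problem = problem
    ),
    class = "search_outcome"
  )
}

#' @export
print.search_outcome <- function(x, ...) {
  cat("<search_outcome>", x$status, "|", nrow(x$solutions), "solution(s) |",
      x$nodes_explored, "nodes |", x$leaves_tested, "leaves",
      if (x$complete) "| space exhausted" else "", "\n")
  invisible(x)
}

#' Attempt an unsatisfiability proof
#'
#' Runs the complete enumeration with `max_solutions = 1` under a node
#' budget. `UNSAT` is returned only when the whole constrained space was
#' traversed without a solution; if the budget runs out first the outcome is
#' `BUDGET_EXHAUSTED` and carries a resume token (`$resume`) that a later
#' call can continue from.
#'
#' @inheritParams enumerate_designs
#' @param budget Node budget for the attempt.
#' @return A `search_outcome` (see [enumerate_designs()]).
#' @export
prove_unsat <- function(problem, budget = 1e6, resume = NULL) {
  problem$max_solutions <- 1
  enumerate_designs(problem, node_budget = budget, resume = resume)
}
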