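#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: the design problem, the
#' selection criteria, optional density-of-states screening, and provenance
#' settings. All randomness downstream flows from the single `seed`.
#'
#' @param target Target structure (dot-bracket string).
#' @param pattern IUPAC pattern (string; default unconstrained).
#' @param engine An [rna_engine()].
#' @param gc_window Optional `c(lo, hi)` percent window for the search.
#' @param max_solutions Enumeration cap.
#' @param node_budget Search node budget.
#' @param reference Optional reference sequence for discrepancy measures.
#' @param site Conserved-site positions for site-restricted measures
#'   (default [conserved_site()] for 54-nt targets, otherwise all positions).
#' @param criteria List of criteria; each a list with fields `objective`,
#'   and optionally `direction`, `gc_window`, `prob_min`, `prob_max`, `rank`
#'   (see [select_candidates()]).
#' @param dos `NULL`, or a list with optional `n_samples` (default 1000) to
#'   screen the top-ranked candidate with [sampled_density()].
#' @param seed Integer master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(target, pattern = NULL, engine = NULL,
                            gc_window = NULL, max_solutions = 50,
                            node_budget = 1e6, reference = NULL, site = NULL,
                            criteria = list(list(objective = "ensemble_defect")),
                            dos = NULL, seed = 1L) {
  structure(
    list(target = target, pattern = pattern, engine = as_engine(engine),
         gc_window = gc_window, max_solutions = max_solutions,
         node_budget = node_budget, reference = reference, site = site,
         criteria = criteria, dos = dos, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(name, quiet, expr) {
  if (!quiet) message("[ribodesign] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the design pipeline
#'
#' Executes design (complete enumeration) -> measure -> rank -> optional
#' density-of-states screen, writing TSV reports and a JSON provenance log
#' to `out_dir`. Outputs are deterministic for a fixed configuration; a
#' stage failure aborts with the stage name while earlier outputs are
#' retained on disk.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `outcome` (search), `measures`, `ranked`
#'   (one tibble per criterion), `dos` (or `NULL`) and `paths` of everything
#'   written.
#' @export
run_pipeline <- function(config, out_dir = tempfile("ribodesign-"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  outcome <- pipeline_stage("design", quiet, {
    problem <- design_problem(
      config$target, config$pattern, gc_window = config$gc_window,
      max_solutions = config$max_solutions, engine = config$engine
    )
    enumerate_designs(problem, node_budget = config$node_budget)
  })
  designs <- outcome$solutions
  designs$id <- sprintf("D%04d", seq_len(nrow(designs)))
  paths$designs <- file.path(out_dir, "designs.fasta")
  write_fasta(designs, paths$designs)

  measures <- pipeline_stage("measure", quiet, {
    if (nrow(designs) == 0) {
      tibble::tibble(id = character(0), seq = character(0))
    } else {
      target_db <- as_dotbracket(config$target)
      site <- config$site
      if (is.null(site)) {
        site <- if (target_db$n == 54) conserved_site() else
          seq_len(target_db$n)
      }
      ms <- measure_suite(designs[, c("id", "seq")], target_db,
                          engine = config$engine, site = site,
                          reference = config$reference)
      # in-report verification: by construction every design's MFE is the target
      ms$mfe_is_target <- rna_mfe_batch(ms$seq, config$engine) == target_db$text
      ms
    }
  })
  paths$measures <- file.path(out_dir, "measures.tsv")
  write_measures_tsv(measures, paths$measures)

  ranked <- pipeline_stage("rank", quiet, {
    if (nrow(measures) == 0) {
      # nothing to rank (e.g. UNSAT design stage): empty but valid report
      list(measures[0, ])
    } else {
      lapply(config$criteria, function(cr) {
        select_candidates(
          measures,
          objective = cr$objective,
          direction = cr$direction %||% "min",
          gc_window = cr$gc_window,
          prob_min = cr$prob_min,
          prob_max = cr$prob_max,
          rank = cr$rank %||% 1
        )
      })
    }
  })
  paths$ranked <- file.path(out_dir, "ranked.tsv")
  write_measures_tsv(dplyr::bind_rows(ranked), paths$ranked)

  dos_result <- NULL
  winners <- dplyr::bind_rows(ranked)
  if (!is.null(config$dos) && nrow(winners) > 0) {
    dos_result <- pipeline_stage("dos", quiet, {
      top <- winners$seq[1]
      ref <- rna_mfe(top, config$engine)$structure
      sampled_density(top, ref,
                      n_samples = config$dos$n_samples %||% 1000,
                      seed = config$seed, engine = config$engine)
    })
    paths$dos <- file.path(out_dir, "dos.tsv")
    write_measures_tsv(tibble::as_tibble(dos_result), paths$dos)
  }

  provenance <- list(
    package = "ribodesign",
    version = as.character(utils::packageVersion("ribodesign")),
    r_version = R.version.string,
    engine = config$engine[c("params", "backend", "temperature", "dangles")],
    seed = config$seed,
    target = as_dotbracket(config$target)$text,
    pattern = if (is.null(config$pattern)) NULL else
      paste(iupac_pattern(config$pattern)$codes, collapse = ""),
    gc_window = config$gc_window,
    max_solutions = config$max_solutions,
    node_budget = config$node_budget,
    status = outcome$status,
    nodes_explored = outcome$nodes_explored,
    n_solutions = nrow(designs),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  paths$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(provenance, paths$provenance, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)

  invisible(list(outcome = outcome, measures = measures, ranked = ranked,
                 dos = dos_result, paths = paths, out_dir = out_dir))
}
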