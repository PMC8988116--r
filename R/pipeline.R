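#' @title End-to-end pipeline orchestration
#' @description Runs simulate -> encode -> overlap -> order -> contigs ->
#'   evaluate with a single config, writing every intermediate artifact to a
#'   run directory so each stage can be re-run or inspected independently.
#' @name cli
NULL

#' Build a pipeline configuration
#'
#' @param coverage Target coverage of the simulated dataset.
#' @param error_pct Point-mutation percentage per read.
#' @param n_reads,read_len Simulated read count and pre-mutation length.
#' @param min_overlap,stride Overlap-detection parameters (see
#'   [max_shift_correlation()]).
#' @param solver `"classic"` (nearest neighbour + 2-opt) or `"qubo-sa"`
#'   (clustering + QUBO + simulated annealing).
#' @param A1,A2 QUBO penalty constants.
#' @param max_cluster Largest directly solved sub-problem for the hybrid
#'   solver.
#' @param n_experiments Repetitions of the stochastic solver, best-of
#'   reported.
#' @param threshold Optional explicit contig-split threshold; by default the
#'   coverage-informed threshold is used.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(coverage = 10, error_pct = 0, n_reads = 50,
                            read_len = 3000, min_overlap = 100, stride = 1,
                            solver = c("classic", "qubo-sa"), A1 = 1,
                            A2 = 1e7, max_cluster = 7, n_experiments = 5,
                            threshold = NULL, seed = 1) {
  solver <- match.arg(solver)
  structure(
    list(coverage = coverage, error_pct = error_pct, n_reads = n_reads,
         read_len = read_len, min_overlap = min_overlap, stride = stride,
         solver = solver, A1 = A1, A2 = A2, max_cluster = max_cluster,
         n_experiments = n_experiments, threshold = threshold, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' @param cfg A `pipeline_config`.
#' @param out_dir Run directory for artifacts (created if missing); `NULL`
#'   keeps everything in memory.
#' @param layout Optional pre-built `read_layout` (e.g. from external FASTA
#'   plus truth files); when given, the simulation stage is skipped.
#' @return Invisibly, a list with the layout, overlap and cost matrices,
#'   solution, contigs and the `evaluation_report`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, layout = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(layout)) {
    layout <- simulate_dataset_a(cfg$coverage, error_pct = cfg$error_pct,
                                 seed = cfg$seed, n_reads = cfg$n_reads,
                                 read_len = cfg$read_len)
  }
  om <- build_overlap_matrix(layout, min_overlap = cfg$min_overlap,
                             stride = cfg$stride)
  cost <- to_cost_matrix(om)
  sol <- if (cfg$solver == "classic") {
    solve_tsp_classic(cost)
  } else {
    solve_hybrid(cost, max_cluster = cfg$max_cluster, seed = cfg$seed + 2L,
                 n_experiments = cfg$n_experiments)
  }
  threshold <- if (is.null(cfg$threshold)) {
    coverage_threshold(cost, cfg$coverage)
  } else {
    cfg$threshold
  }
  contigs <- split_path(sol$path, cost, threshold)
  report <- evaluate_report(sol, cost, layout, threshold = threshold)
  result <- list(layout = layout, overlap = om, cost = cost, solution = sol,
                 contigs = contigs, report = report, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    write_fasta(layout, file.path(out_dir, "reads.fasta"))
    write_truth(layout, file.path(out_dir, "truth.tsv"),
                file.path(out_dir, "adjacencies.json"))
    write_matrix_tsv(om$rho, file.path(out_dir, "rho.tsv"))
    write_matrix_tsv(cost, file.path(out_dir, "cost.tsv"))
    write_solution_json(sol, file.path(out_dir, "path.json"),
                        ids = layout$reads$read_id)
    write_contigs_tsv(contigs, layout$reads$read_id,
                      file.path(out_dir, "contigs.tsv"))
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  invisible(result)
}
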