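#' @title Evaluation against the ground-truth layout
#' @description With synthetic reads the true position of every read is
#'   known, so each junction of the assembled chain can be labelled: an edge
#'   between two reads whose source intervals genuinely intersect is a
#'   correct overlap, anything else is a real break. For a circular source
#'   the closing edge between the chain's two ends is evaluated as well
#'   (the artificial vertex between them carries no sequence), so a perfect
#'   circular assembly of N reads recovers N true overlaps out of N
#'   evaluated edges.
#' @name evaluate
NULL

# Evaluated edges of a path: consecutive pairs, plus the wrap edge when the
# truth is circular. Returns a 2-column matrix of vertex indices.
.path_edges <- function(path, circular) {
  n <- length(path)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L))
  }
  e <- cbind(path[-n], path[-1L])
  if (circular) e <- rbind(e, c(path[n], path[1L]))
  e
}

#' Label the edges of a read-ordering path against the truth
#'
#' @param path Integer vertex vector (1-based read vertices in layout
#'   order).
#' @param truth A `read_layout` with the true adjacency set.
#' @return A list with `is_true` (logical per evaluated edge), `n_edges`,
#'   `correct` (edges that are genuine overlaps) and `real_breaks`
#'   (`n_edges - correct`).
#' @export
classify_edges <- function(path, truth) {
  stopifnot(inherits(truth, "read_layout"))
  ids <- truth$reads$read_id
  if (any(path < 1L | path > length(ids))) {
    stop("path contains unknown read vertices")
  }
  keys <- .adjacency_keys(truth$adjacencies)
  edges <- .path_edges(path, isTRUE(truth$circular))
  is_true <- if (nrow(edges) == 0L) logical(0) else
    vapply(seq_len(nrow(edges)), function(k) {
      paste(sort(c(ids[edges[k, 1L]], ids[edges[k, 2L]])),
            collapse = "|") %in% keys
    }, logical(1L))
  list(is_true = is_true, n_edges = length(is_true),
       correct = sum(is_true), real_breaks = sum(!is_true))
}

#' Fraction of evaluated edges that are genuine overlaps
#'
#' @param correct Number of correctly detected overlaps.
#' @param n_edges Number of evaluated edges (the reference count of
#'   overlaps a perfect chain would recover).
#' @return `correct / n_edges`, capped at 1; `NA` with a warning when
#'   `n_edges` is 0.
#' @export
accuracy_fraction <- function(correct, n_edges) {
  if (correct < 0 || n_edges < 0) stop("counts must be non-negative")
  if (n_edges == 0) {
    warning("no evaluated edges; accuracy undefined")
    return(NA_real_)
  }
  min(1, correct / n_edges)
}

#' Assemble one evaluation row
#'
#' Combines path cost, real and calculated contig breakpoints, correct and
#' incorrect overlap counts and accuracy into one record. "Incorrect
#' overlaps" counts edges that the threshold retained inside contigs even
#' though they are not genuine overlaps (false positives); "calculated"
#' breakpoints are the threshold cuts along the linear path.
#'
#' @param sol A `tsp_solution`.
#' @param cost The `cost_matrix`.
#' @param truth A `read_layout`.
#' @param coverage Mean coverage used for the threshold (ignored when
#'   `threshold` is given).
#' @param threshold Optional explicit cost threshold.
#' @return An object of class `evaluation_report` (a one-row data.frame with
#'   columns `path_cost`, `real_contig_breaks`, `calculated_contig_breaks`,
#'   `correct_overlaps`, `incorrect_overlaps`, `accuracy`).
#' @export
evaluate_report <- function(sol, cost, truth, coverage = NULL,
                            threshold = NULL) {
  stopifnot(inherits(sol, "tsp_solution"))
  if (is.null(threshold)) {
    if (is.null(coverage)) stop("supply 'coverage' or an explicit 'threshold'")
    threshold <- coverage_threshold(cost, coverage)
  }
  path <- sol$path
  cls <- classify_edges(path, truth)
  edges <- .path_edges(path, isTRUE(truth$circular))
  edge_costs <- if (nrow(edges) == 0L) numeric(0) else
    cost[cbind(edges[, 1L] + 1L, edges[, 2L] + 1L)]
  retained <- edge_costs <= threshold
  contigs <- split_path(path, cost, threshold)
  rep <- data.frame(
    path_cost = sol$cost,
    real_contig_breaks = cls$real_breaks,
    calculated_contig_breaks = attr(contigs, "breaks"),
    correct_overlaps = sum(retained & cls$is_true),
    incorrect_overlaps = sum(retained & !cls$is_true),
    accuracy = accuracy_fraction(sum(retained & cls$is_true), cls$n_edges),
    threshold = threshold
  )
  class(rep) <- c("evaluation_report", "data.frame")
  rep
}

#' Serialise an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep <- as.data.frame(obj)
  class(rep) <- c("evaluation_report", "data.frame")
  rep
}
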