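#' @title Splitting the TSP path into contigs
#' @description A near-optimal tour may place non-overlapping reads next to
#'   each other. Every consecutive edge of the path is therefore checked
#'   against a cost threshold; edges above it are declared breaks and the
#'   path is cut there, yielding contigs -- ordered lists of reads, each
#'   asserted to overlap its neighbour. Lowering the threshold can only
#'   increase the number of contigs while reducing the chance of retaining a
#'   false overlap.
#' @name contigs
NULL

#' Coverage-informed cost threshold
#'
#' At mean coverage `COV`, a read laid out on a circular source genuinely
#' overlaps about `COV - 1` other reads in each direction, i.e.
#' `2 * (COV - 1)` in total. Per read, the `2 * (COV - 1)`-th smallest
#' off-diagonal cost is taken -- the cost of its furthest genuine
#' neighbour -- and the threshold is a quantile (default: the median) of
#' these values across reads, times a safety factor.
#'
#' @param cost A `cost_matrix` (artificial vertex in row/column 1).
#' @param coverage Mean sequencing depth `COV >= 2`.
#' @param q Quantile of the pooled per-read values (default 0.5).
#' @param safety Multiplier applied to the quantile (default 1).
#' @return A non-negative scalar threshold.
#' @export
coverage_threshold <- function(cost, coverage, q = 0.5, safety = 1) {
  if (coverage < 2) {
    stop("'coverage' must be >= 2; pass an explicit threshold instead")
  }
  C <- unclass(cost)[-1L, -1L, drop = FALSE]
  N <- nrow(C)
  k <- min(2L * (as.integer(round(coverage)) - 1L), N - 1L)
  kth <- vapply(seq_len(N), function(r) {
    sort(C[r, -r])[k]
  }, numeric(1L))
  as.numeric(stats::quantile(kth, q, type = 1L)) * safety
}

#' Cut a read-ordering path at high-cost edges
#'
#' @param path Integer vertex vector (1-based read vertices, artificial
#'   vertex already removed).
#' @param cost A `cost_matrix`.
#' @param threshold Cost cutoff; edges with cost strictly above it are
#'   breaks.
#' @return A list of integer vectors (class `contig_set`), one per contig,
#'   preserving path order; attribute `breaks` holds the breakpoint count
#'   ("calculated contigs" is reported as this count, so a perfect
#'   single-contig path reports 0).
#' @export
split_path <- function(path, cost, threshold) {
  if (length(path) == 0L) {
    return(structure(list(), class = "contig_set", breaks = 0L))
  }
  if (threshold < 0) stop("'threshold' must be >= 0")
  n <- length(path)
  if (n == 1L) {
    return(structure(list(path), class = "contig_set", breaks = 0L))
  }
  edge_costs <- cost[cbind(path[-n] + 1L, path[-1L] + 1L)]
  cut_after <- which(edge_costs > threshold)
  bounds <- c(0L, cut_after, n)
  contigs <- lapply(seq_len(length(bounds) - 1L), function(k) {
    path[(bounds[k] + 1L):bounds[k + 1L]]
  })
  structure(contigs, class = "contig_set", breaks = length(cut_after),
            threshold = threshold)
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set: %d contigs (%d breakpoints), sizes: %s\n",
              length(x), attr(x, "breaks"),
              paste(lengths(x), collapse = ", ")))
  invisible(x)
}

#' Write contigs as a TSV manifest
#'
#' One row per read: `contig_id`, `rank` (position within the contig) and
#' `read_id`.
#'
#' @param contigs A `contig_set`.
#' @param ids Read ids indexed by vertex number.
#' @param path Output path.
#' @export
write_contigs_tsv <- function(contigs, ids, path) {
  rows <- do.call(rbind, lapply(seq_along(contigs), function(k) {
    data.frame(contig_id = sprintf("contig_%03d", k),
               rank = seq_along(contigs[[k]]),
               read_id = ids[contigs[[k]]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(contig_id = character(0), rank = integer(0),
                       read_id = character(0))
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
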