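#' @title Classical TSP heuristic: nearest neighbour + 2-opt
#' @description The read ordering is the Hamiltonian cycle of minimum cost on
#'   the integer cost matrix, starting and ending at the artificial vertex 0.
#'   A greedy nearest-neighbour construction followed by first-improvement
#'   2-opt local search stands in for a general-purpose solver; for the
#'   repeat-free, low-error instances targeted here it routinely reaches the
#'   zero-cost optimum.
#' @name tsp_classic
NULL

.check_cost_matrix <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost)) {
    stop("cost matrix must be square")
  }
  if (any(cost < 0)) stop("cost matrix must be non-negative")
  if (!isTRUE(all.equal(unclass(cost), t(unclass(cost)),
                        check.attributes = FALSE))) {
    stop("cost matrix must be symmetric")
  }
  invisible(TRUE)
}

.new_tsp_solution <- function(path, cost, solver) {
  cycle <- c(0L, path, 0L)
  structure(
    list(cycle = cycle, path = path, cost = tour_cost(cycle, cost),
         solver = solver),
    class = "tsp_solution"
  )
}

#' Total cost of a Hamiltonian cycle
#'
#' @param cycle Integer vertex vector starting and ending at 0 (the
#'   artificial vertex); vertices are 0-based, matching the cost matrix rows
#'   minus one.
#' @param cost A `cost_matrix` (or any square symmetric matrix whose first
#'   row/column is the artificial vertex).
#' @return The integer sum of consecutive edge costs, including the return
#'   edge.
#' @export
tour_cost <- function(cycle, cost) {
  n <- nrow(cost) - 1L
  if (cycle[1L] != 0L || cycle[length(cycle)] != 0L) {
    stop("cycle must start and end at the artificial vertex 0")
  }
  inner <- cycle[-c(1L, length(cycle))]
  if (length(inner) != n || !setequal(inner, seq_len(n)) ||
      anyDuplicated(inner)) {
    stop("cycle must visit every vertex exactly once")
  }
  idx <- cycle + 1L
  sum(cost[cbind(idx[-length(idx)], idx[-1L])])
}

#' Greedy nearest-neighbour tour from the artificial vertex
#'
#' From vertex 0, repeatedly moves to the cheapest unvisited vertex; ties are
#' broken by the lowest vertex index, making the construction deterministic.
#'
#' @param cost A `cost_matrix`.
#' @return A `tsp_solution` with fields `cycle`, `path` (the cycle without
#'   vertex 0, i.e. the read ordering) and `cost`.
#' @export
solve_nn <- function(cost) {
  .check_cost_matrix(cost)
  n <- nrow(cost) - 1L
  if (n < 1L) stop("need at least one read vertex")
  visited <- rep(FALSE, n)
  path <- integer(n)
  current <- 0L
  for (k in seq_len(n)) {
    cand <- which(!visited)
    nxt <- cand[which.min(cost[current + 1L, cand + 1L])]
    path[k] <- nxt
    visited[nxt] <- TRUE
    current <- nxt
  }
  .new_tsp_solution(path, cost, solver = "nn")
}

#' Improve a tour with first-improvement 2-opt
#'
#' Repeatedly reverses path segments whenever the exchange of the two cut
#' edges lowers the cycle cost, until a pass makes no improvement or
#' `max_passes` is reached. Vertex 0 stays the fixed start; the output cost
#' never exceeds the input cost.
#'
#' @param sol A `tsp_solution`.
#' @param cost The `cost_matrix` the solution was built on.
#' @param max_passes Maximum number of full scans (default 50).
#' @return An improved (or identical) `tsp_solution`.
#' @export
improve_2opt <- function(sol, cost, max_passes = 50) {
  stopifnot(inherits(sol, "tsp_solution"))
  path <- sol$path
  n <- length(path)
  if (n < 3L) return(sol)
  C <- function(a, b) cost[a + 1L, b + 1L]
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {
      prev <- if (i == 1L) 0L else path[i - 1L]
      for (j in (i + 1L):n) {
        nxt <- if (j == n) 0L else path[j + 1L]
        delta <- C(prev, path[j]) + C(path[i], nxt) -
          C(prev, path[i]) - C(path[j], nxt)
        if (delta < 0) {
          path[i:j] <- rev(path[i:j])
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  out <- .new_tsp_solution(path, cost, solver = paste0(sol$solver, "+2opt"))
  if (out$cost > sol$cost) sol else out
}

# Or-opt: relocate segments of length 1..3 (optionally reversed) to a
# cheaper position, first-improvement. Complements 2-opt, which cannot move
# a single vertex between two non-adjacent edges.
.improve_or_opt <- function(sol, cost, max_passes = 50) {
  path <- sol$path
  n <- length(path)
  if (n < 3L) return(sol)
  C <- function(a, b) cost[a + 1L, b + 1L]
  edge <- function(p, k) if (k == 0L) 0L else if (k > length(p)) 0L else p[k]
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (len in 1:3) {
      if (len >= n) next
      i <- 1L
      while (i + len - 1L <= n) {
        seg <- path[i:(i + len - 1L)]
        rest <- path[-(i:(i + len - 1L))]
        gain <- C(edge(path, i - 1L), path[i]) +
          C(path[i + len - 1L], edge(path, i + len)) -
          C(edge(path, i - 1L), edge(path, i + len))
        done <- FALSE
        for (j in 0:length(rest)) {
          a <- edge(rest, j)
          b <- edge(rest, j + 1L)
          for (s in list(seg, rev(seg))) {
            add <- C(a, s[1L]) + C(s[len], b) - C(a, b)
            if (add < gain) {
              path <- append(rest, s, after = j)
              improved <- TRUE
              done <- TRUE
              break
            }
          }
          if (done) break
        }
        i <- i + 1L
        n <- length(path)
      }
    }
    if (!improved) break
  }
  out <- .new_tsp_solution(path, cost, solver = paste0(sol$solver, "+oropt"))
  if (out$cost > sol$cost) sol else out
}

#' Classical solver: nearest neighbour plus 2-opt and Or-opt local search
#'
#' Alternates 2-opt edge exchanges with Or-opt segment relocations until
#' neither move type improves the tour.
#'
#' @inheritParams improve_2opt
#' @param cost A `cost_matrix`.
#' @return A `tsp_solution`.
#' @export
solve_tsp_classic <- function(cost, max_passes = 50) {
  sol <- solve_nn(cost)
  repeat {
    before <- sol$cost
    sol <- improve_2opt(sol, cost, max_passes = max_passes)
    sol <- .improve_or_opt(sol, cost, max_passes = max_passes)
    if (sol$cost >= before) break
  }
  sol$solver <- "nn+2opt+oropt"
  sol
}

#' @export
print.tsp_solution <- function(x, ...) {
  cat(sprintf("tsp_solution (%s): %d vertices, cost %g\n",
              x$solver, length(x$path), x$cost))
  invisible(x)
}

#' Serialise a TSP solution to JSON
#'
#' @param sol A `tsp_solution`.
#' @param path Output path.
#' @param ids Optional read ids (cost-matrix row names without the artificial
#'   vertex) recorded alongside the numeric ordering.
#' @export
write_solution_json <- function(sol, path, ids = NULL) {
  obj <- list(cycle = sol$cycle, path = sol$path, cost = sol$cost,
              solver = sol$solver)
  if (!is.null(ids)) obj$read_order <- ids[sol$path]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_solution_json
#' @export
read_solution_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(cycle = as.integer(obj$cycle), path = as.integer(obj$path),
         cost = obj$cost, solver = obj$solver,
         read_order = obj$read_order),
    class = "tsp_solution"
  )
}
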