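#' @title QUBO formulation of the TSP and a simulated-annealing surrogate
#' @description The TSP is cast as a quadratic unconstrained binary
#'   optimisation over N^2 one-hot position variables `x[i, n]` ("vertex i is
#'   visited n-th"), the input form for quantum annealers. The energy is
#'   `A1 * C + A2 * Q`: `C` collects the depot-out, depot-in and
#'   consecutive-position edge costs, and `Q` is the one-hot penalty
#'   `(1 - sum x)^2` for every vertex row and position column, which vanishes
#'   exactly on permutation matrices. A classical single-bit-flip Metropolis
#'   annealer samples the model in place of a QPU, and a clustering
#'   decomposition handles instances beyond the direct embedding limit
#'   (about 60 fully connected variables, i.e. N = 7, on the targeted
#'   annealer generation).
#' @name tsp_qubo
NULL

# variable index of x[vertex i (1..N), position n (1..N)]
.qv <- function(i, n, N) (i - 1L) * N + n

#' Build the TSP QUBO for a cost matrix with artificial depot
#'
#' @param cost A `cost_matrix`; row/column 1 is the artificial depot (the
#'   formulation's vertex N+1, our vertex 0).
#' @param A1 Weight of the tour-cost objective (default 1).
#' @param A2 Weight of the one-hot constraint penalty (default 1e7). With
#'   integer costs at most 1000, this makes every infeasible assignment more
#'   expensive than any feasible one.
#' @return An object of class `qubo_model`: list with `Q` (dense symmetric
#'   matrix, linear terms on the diagonal, halved pairwise coefficients off
#'   it), `offset`, `n_vertices`, `A1`, `A2`. The energy of a binary vector
#'   `x` is `x' Q x + offset`; for any feasible one-hot assignment it equals
#'   `A1` times the decoded tour cost.
#' @export
build_qubo <- function(cost, A1 = 1, A2 = 1e7) {
  .check_cost_matrix(cost)
  if (A1 <= 0 || A2 <= 0) stop("penalty constants must be positive")
  N <- nrow(cost) - 1L
  if (N < 2L) stop("need at least 2 read vertices")
  nv <- N * N
  Q <- matrix(0, nv, nv)
  C <- unclass(cost)

  # objective: depot-out (position 1), depot-in (position N) as linear terms
  for (i in seq_len(N)) {
    v1 <- .qv(i, 1L, N)
    vN <- .qv(i, N, N)
    Q[v1, v1] <- Q[v1, v1] + A1 * C[1L, i + 1L]
    Q[vN, vN] <- Q[vN, vN] + A1 * C[i + 1L, 1L]
  }
  # objective: consecutive positions n, n+1 over all vertex pairs
  for (n in seq_len(N - 1L)) {
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        if (i == j) next
        cij <- C[i + 1L, j + 1L]
        if (cij == 0) next
        v <- .qv(i, n, N); w <- .qv(j, n + 1L, N)
        Q[v, w] <- Q[v, w] + A1 * cij / 2
        Q[w, v] <- Q[w, v] + A1 * cij / 2
      }
    }
  }
  # one-hot penalties: (1 - sum x)^2 = 1 - sum x + 2 * sum_{pairs} x x
  groups <- c(
    lapply(seq_len(N), function(i) .qv(i, seq_len(N), N)),  # vertex rows
    lapply(seq_len(N), function(n) .qv(seq_len(N), n, N))   # position cols
  )
  for (grp in groups) {
    for (v in grp) Q[v, v] <- Q[v, v] - A2
    pairs <- grp
    for (a in seq_along(pairs)) {
      for (b in seq_along(pairs)) {
        if (a == b) next
        Q[pairs[a], pairs[b]] <- Q[pairs[a], pairs[b]] + A2
      }
    }
  }
  structure(
    list(Q = Q, offset = 2 * N * A2, n_vertices = N, A1 = A1, A2 = A2),
    class = "qubo_model"
  )
}

#' Energy of a binary assignment under a QUBO model
#'
#' @param model A `qubo_model`.
#' @param x Binary vector of length `n_vertices^2`.
#' @return `x' Q x + offset`.
#' @export
qubo_energy <- function(model, x) {
  stopifnot(inherits(model, "qubo_model"))
  x <- as.numeric(x)
  if (length(x) != nrow(model$Q)) stop("assignment length mismatch")
  as.numeric(x %*% model$Q %*% x) + model$offset
}

#' Sample a QUBO with single-bit-flip Metropolis simulated annealing
#'
#' Geometric cooling from `T0` (default: the largest coefficient magnitude)
#' to `Tend` over `n_sweeps` sweeps, restarted `n_restarts` times from
#' random states; the lowest-energy assignment ever visited is returned.
#'
#' @param model A `qubo_model`.
#' @param n_sweeps Sweeps per restart (default 1000).
#' @param n_restarts Independent restarts (default 10).
#' @param seed Optional integer seed.
#' @param T0,Tend Temperature schedule endpoints; `T0 = NULL` uses the
#'   largest coefficient magnitude of the model.
#' @return A list (class `sample_result`) with `assignment`, `energy` and
#'   `feasible` (all one-hot constraints satisfied).
#' @export
sa_sample <- function(model, n_sweeps = 1000, n_restarts = 10, seed = NULL,
                      T0 = NULL, Tend = 0.01) {
  stopifnot(inherits(model, "qubo_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(T0)) T0 <- max(abs(model$Q)) * 2  # off-diag entries are halved
  if (T0 <= 0) T0 <- 1
  res <- sa_anneal_cpp(model$Q, as.integer(n_sweeps),
                       as.integer(n_restarts), T0, Tend)
  x <- as.integer(res$x)
  structure(
    list(assignment = x, energy = res$energy + model$offset,
         feasible = .qubo_feasible(x, model$n_vertices)),
    class = "sample_result"
  )
}

.qubo_feasible <- function(x, N) {
  X <- matrix(x, nrow = N, byrow = TRUE)
  all(rowSums(X) == 1L) && all(colSums(X) == 1L)
}

#' Decode a QUBO sample into a tour
#'
#' The assignment is reshaped into the N x N vertex-by-position matrix. If
#' every row and column is one-hot the tour is read off directly; otherwise
#' the violated constraints are reported and, with `repair = TRUE`, a valid
#' permutation is reconstructed greedily: positions holding exactly one
#' otherwise-unused vertex are kept, then each free position is filled with
#' the unused vertex cheapest to reach from its predecessor.
#'
#' @param sample A `sample_result` (or a raw binary vector).
#' @param N Number of read vertices.
#' @param cost Optional `cost_matrix`, required for `repair = TRUE` and for
#'   the reported tour cost.
#' @param repair Repair infeasible samples instead of failing (default
#'   FALSE).
#' @return For feasible (or repaired) samples, a `tsp_solution` with an
#'   added `repairs` count; otherwise a list with `feasible = FALSE` and the
#'   violated constraint labels.
#' @export
decode_sample <- function(sample, N, cost = NULL, repair = FALSE) {
  x <- if (inherits(sample, "sample_result")) sample$assignment else
    as.integer(sample)
  if (length(x) != N * N) stop("assignment length must be N^2")
  X <- matrix(x, nrow = N, byrow = TRUE)  # rows: vertices, cols: positions
  rs <- rowSums(X); cs <- colSums(X)
  if (all(rs == 1L) && all(cs == 1L)) {
    path <- apply(X, 2L, which.max)
    sol <- if (is.null(cost)) {
      structure(list(cycle = c(0L, path, 0L), path = as.integer(path),
                     cost = NA_real_, solver = "qubo-sa"),
                class = "tsp_solution")
    } else {
      .new_tsp_solution(as.integer(path), cost, solver = "qubo-sa")
    }
    sol$repairs <- 0L
    return(sol)
  }
  violations <- c(
    sprintf("vertex_%d_visited_%d_times", which(rs != 1L), rs[rs != 1L]),
    sprintf("position_%d_filled_%d_times", which(cs != 1L), cs[cs != 1L])
  )
  if (!repair) {
    return(list(feasible = FALSE, violations = violations))
  }
  if (is.null(cost)) stop("repair requires the cost matrix")
  path <- rep(NA_integer_, N)
  used <- rep(FALSE, N)
  for (n in seq_len(N)) {   # keep unambiguous, unused placements
    if (cs[n] == 1L) {
      v <- which.max(X[, n])
      if (!used[v]) {
        path[n] <- v
        used[v] <- TRUE
      }
    }
  }
  repairs <- sum(is.na(path))
  for (n in which(is.na(path))) {
    prev <- if (n == 1L) 0L else path[n - 1L]
    prev <- if (is.na(prev)) 0L else prev
    free <- which(!used)
    v <- free[which.min(cost[prev + 1L, free + 1L])]
    path[n] <- v
    used[v] <- TRUE
  }
  sol <- .new_tsp_solution(path, cost, solver = "qubo-sa+repair")
  sol$repairs <- repairs
  sol
}

#' Solve a TSP instance directly through the QUBO + annealer route
#'
#' @inheritParams build_qubo
#' @inheritParams sa_sample
#' @return A `tsp_solution` (repaired if the best sample was infeasible).
#' @export
solve_qubo_direct <- function(cost, A1 = 1, A2 = 1e7, n_sweeps = 1000,
                              n_restarts = 10, seed = NULL) {
  model <- build_qubo(cost, A1 = A1, A2 = A2)
  s <- sa_sample(model, n_sweeps = n_sweeps, n_restarts = n_restarts,
                 seed = seed)
  decode_sample(s, model$n_vertices, cost = cost, repair = TRUE)
}

# ---- density-based decomposition --------------------------------------------

# Plain DBSCAN on a precomputed distance matrix. Noise points come back as
# singleton clusters so every vertex is always assigned.
.dbscan_dist <- function(D, eps, min_pts = 2L) {
  n <- nrow(D)
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    nb <- which(D[i, ] <= eps)
    if (length(nb) < min_pts) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue) > 0L) {
      q <- queue[1L]; queue <- queue[-1L]
      if (labels[q] == 0L) {
        labels[q] <- cl
        nbq <- which(D[q, ] <= eps)
        if (length(nbq) >= min_pts) queue <- union(queue, nbq[labels[nbq] == 0L])
      }
    }
  }
  for (i in which(labels == 0L)) {  # noise -> singletons
    cl <- cl + 1L
    labels[i] <- cl
  }
  labels
}

# Recursively partition vertex indices into clusters of size <= max_cluster,
# sweeping DBSCAN's eps over distance percentiles. The matrix has no
# coordinates, so costs act directly as distances. When no eps separates the
# vertices (typical when many exact-zero costs chain everything together),
# fall back to cutting a cheap nearest-neighbour traversal into consecutive
# chunks.
.cluster_vertices <- function(idx, D, max_cluster) {
  if (length(idx) <= max_cluster) return(list(idx))
  sub <- D[idx, idx, drop = FALSE]
  offs <- sub[upper.tri(sub)]
  for (q in seq(0.05, 0.95, by = 0.05)) {
    eps <- as.numeric(stats::quantile(offs, q, type = 1L))
    labels <- .dbscan_dist(sub, eps)
    sizes <- table(labels)
    if (length(sizes) >= 2L && max(sizes) < length(idx)) {
      parts <- split(idx, labels)
      return(unlist(lapply(parts, .cluster_vertices, D = D,
                           max_cluster = max_cluster),
                    recursive = FALSE))
    }
  }
  ord <- idx[.nn_order(sub)]
  split(ord, ceiling(seq_along(ord) / max_cluster))
}

# nearest-neighbour traversal order of a distance submatrix (local indices)
.nn_order <- function(D) {
  n <- nrow(D)
  visited <- rep(FALSE, n)
  ord <- integer(n)
  cur <- 1L
  for (k in seq_len(n)) {
    ord[k] <- cur
    visited[cur] <- TRUE
    if (k == n) break
    cand <- which(!visited)
    cur <- cand[which.min(D[cur, cand])]
  }
  ord
}

# Greedy cheapest-junction concatenation of sub-paths: repeatedly join the
# two path endpoints (any orientation) with the smallest connecting cost
# until a single path remains. The artificial vertex costs nothing from
# either end, so the merged chain anchors to it for free.
.merge_paths <- function(paths, cost) {
  while (length(paths) > 1L) {
    best <- NULL
    best_c <- Inf
    for (a in seq_along(paths)) {
      for (b in seq_along(paths)) {
        if (a == b) next
        ta <- paths[[a]][length(paths[[a]])]
        for (flip in c(FALSE, TRUE)) {
          hb <- if (flip) paths[[b]][length(paths[[b]])] else paths[[b]][1L]
          cc <- cost[ta + 1L, hb + 1L]
          if (cc < best_c) {
            best_c <- cc
            best <- list(a = a, b = b, flip = flip)
          }
        }
      }
    }
    pb <- paths[[best$b]]
    if (best$flip) pb <- rev(pb)
    paths[[best$a]] <- c(paths[[best$a]], pb)
    paths[[best$b]] <- NULL
  }
  paths[[1L]]
}

# one hybrid construction: cluster -> per-cluster QUBO solve -> greedy merge
.hybrid_construct <- function(cost, clusters, n_sweeps, n_restarts) {
  sub_paths <- lapply(clusters, function(cl) {
    if (length(cl) == 1L) return(cl)
    sub_cost <- .subproblem_cost(cost, cl)
    sol <- tryCatch(
      solve_qubo_direct(sub_cost, n_sweeps = n_sweeps,
                        n_restarts = n_restarts),
      error = function(e) NULL
    )
    if (is.null(sol)) sol <- solve_tsp_classic(sub_cost)  # logged fallback
    cl[sol$path]
  })
  .merge_paths(sub_paths, cost)
}

# cost submatrix for a vertex subset, with the artificial vertex retained as
# free endpoints so each cluster is solved as an open path
.subproblem_cost <- function(cost, vertices) {
  keep <- c(1L, vertices + 1L)
  sub <- unclass(cost)[keep, keep, drop = FALSE]
  structure(sub, class = c("cost_matrix", "matrix"),
            scale_max = attr(cost, "scale_max"))
}

#' Hybrid decomposition solver (clustering + QUBO sub-solves)
#'
#' Mirrors the CPU/QPU division of labour of decomposition-based annealer
#' tools: vertices are partitioned into clusters no larger than the direct
#' embedding limit, each cluster's TSP is solved through the QUBO +
#' simulated-annealing route, and the sub-paths are concatenated greedily at
#' their cheapest junctions. The construction is then iterated: the current
#' tour is re-cut into consecutive chunks at every possible offset, the
#' chunks re-solved and re-merged, and the best tour kept; the process stops
#' after one full iteration without improvement. The whole experiment is
#' repeated `n_experiments` times and the best tour is reported.
#'
#' @param cost A `cost_matrix`.
#' @param max_cluster Largest sub-problem solved directly (default 7, the
#'   N^2 <= 60 embedding limit).
#' @param seed Optional integer seed.
#' @param n_experiments Independent repetitions, best-of reported (default
#'   5).
#' @param n_sweeps,n_restarts Annealer schedule for each sub-solve.
#' @return A `tsp_solution` covering all reads.
#' @export
solve_hybrid <- function(cost, max_cluster = 7, seed = NULL,
                         n_experiments = 5, n_sweeps = 1000,
                         n_restarts = 10) {
  .check_cost_matrix(cost)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(cost) - 1L
  if (N <= max_cluster) {
    best <- NULL
    for (e in seq_len(n_experiments)) {
      sol <- solve_qubo_direct(cost, n_sweeps = n_sweeps,
                               n_restarts = n_restarts)
      if (is.null(best) || sol$cost < best$cost) best <- sol
    }
    best$solver <- "qubo-sa"
    return(best)
  }
  D <- unclass(cost)[-1L, -1L, drop = FALSE]
  clusters <- .cluster_vertices(seq_len(N), D, max_cluster)
  best <- NULL
  for (e in seq_len(n_experiments)) {
    path <- .hybrid_construct(cost, clusters, n_sweeps, n_restarts)
    sol <- .new_tsp_solution(path, cost, solver = "qubo-sa-hybrid")
    # outer improvement loop: terminate after one iteration with no change
    repeat {
      improved <- FALSE
      for (off in 0:(max_cluster - 1L)) {
        rotated <- if (off == 0L) sol$path else
          c(sol$path[-seq_len(off)], sol$path[seq_len(off)])
        chunks <- split(rotated, ceiling(seq_along(rotated) / max_cluster))
        cand_path <- .hybrid_construct(cost, chunks, n_sweeps, n_restarts)
        cand <- .new_tsp_solution(cand_path, cost,
                                  solver = "qubo-sa-hybrid")
        if (cand$cost < sol$cost) {
          sol <- cand
          improved <- TRUE
        }
        if (sol$cost == 0) break
      }
      if (!improved || sol$cost == 0) break
    }
    if (is.null(best) || sol$cost < best$cost) best <- sol
    if (best$cost == 0) break
  }
  best
}
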