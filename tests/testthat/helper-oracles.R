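# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately naive: enumeration, direct formula
# evaluation, brute force at tiny n.

# all permutations of 1..n as an n!-row matrix
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

# brute-force optimal cycle cost (artificial vertex 0 fixed as start)
brute_tsp_cost <- function(cost) {
  n <- nrow(cost) - 1L
  P <- perms(n)
  idx <- cbind(1L, P + 1L, 1L)
  costs <- apply(idx, 1L, function(r) {
    sum(cost[cbind(r[-length(r)], r[-1L])])
  })
  min(costs)
}

# random symmetric integer cost matrix with artificial vertex 0
rand_cost <- function(n, scale = 1000) {
  M <- matrix(sample(0:scale, (n + 1L)^2, replace = TRUE), n + 1L)
  M <- floor((M + t(M)) / 2)
  diag(M) <- 0
  M[1L, ] <- 0
  M[, 1L] <- 0
  structure(M, class = c("cost_matrix", "matrix"), scale_max = scale)
}

# exhaustive QUBO minimum over all 2^n_vars assignments (n_vars <= 16)
exhaustive_qubo_min <- function(model) {
  nv <- nrow(model$Q)
  stopifnot(nv <= 16L)
  states <- 0:(2^nv - 1L)
  X <- matrix(0L, length(states), nv)
  for (b in seq_len(nv)) X[, b] <- bitwAnd(bitwShiftR(states, b - 1L), 1L)
  min(rowSums((X %*% model$Q) * X) + model$offset)
}

# one-hot encoding of a path (vertex visited n-th) for energy-identity checks
path_to_assignment <- function(path) {
  N <- length(path)
  x <- integer(N * N)
  for (n in seq_len(N)) x[(path[n] - 1L) * N + n] <- 1L
  x
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small synthetic layout for unit tests (fast; full-size runs live in
# test-acceptance.R)
small_layout <- function(coverage = 5, error_pct = 0, seed = 7,
                         n_reads = 20, read_len = 300) {
  simulate_dataset_a(coverage, error_pct = error_pct, seed = seed,
                     n_reads = n_reads, read_len = read_len)
}
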