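test_that("pearson matches the correlation formula", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # zero-variance window carries no evidence of a relation
  expect_equal(pearson(c(2, 2, 2), c(1, 5, 9)), 0)
  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(1, 2), "length >= 2")
})

test_that("identical signals give rho 1 at shift 0", {
  sig <- encode_cumulated_phase(rand_dna(150))
  for (m in c("fft", "naive")) {
    res <- max_shift_correlation(sig, sig, min_overlap = 50, method = m)
    expect_equal(res$rho, 1.0, tolerance = 1e-9)
    expect_equal(res$shift, 0)
  }
})

test_that("error-free reads from one source correlate perfectly at the true shift", {
  set.seed(31)
  src <- rand_dna(400)
  a <- substring(src, 1, 200)
  b <- substring(src, 121, 320)  # b starts 120 bases into a, 80-base overlap
  res <- max_shift_correlation(encode_cumulated_phase(a),
                               encode_cumulated_phase(b),
                               min_overlap = 50)
  expect_equal(res$rho, 1.0, tolerance = 1e-9)
  expect_equal(res$shift, 120)
})

test_that("fast sliding correlation equals the naive per-shift oracle", {
  set.seed(32)
  for (i in 1:25) {
    la <- sample(60:200, 1)
    lb <- sample(60:200, 1)
    sa <- encode_cumulated_phase(rand_dna(la))
    sb <- encode_cumulated_phase(rand_dna(lb))
    fast <- max_shift_correlation(sa, sb, min_overlap = 20)
    naive <- max_shift_correlation(sa, sb, min_overlap = 20,
                                   method = "naive")
    expect_equal(fast$rho, naive$rho, tolerance = 1e-6)
    expect_equal(fast$shift, naive$shift)
  }
})

test_that("swapping the inputs negates the shift, coefficient unchanged", {
  set.seed(33)
  sa <- encode_cumulated_phase(rand_dna(150))
  sb <- encode_cumulated_phase(rand_dna(180))
  ab <- max_shift_correlation(sa, sb, min_overlap = 30)
  ba <- max_shift_correlation(sb, sa, min_overlap = 30)
  expect_equal(ab$rho, ba$rho, tolerance = 1e-9)
  expect_equal(ab$shift, -ba$shift)
})

test_that("stride with refinement recovers the exhaustive optimum nearby", {
  set.seed(34)
  src <- rand_dna(500)
  sa <- encode_cumulated_phase(substring(src, 1, 250))
  sb <- encode_cumulated_phase(substring(src, 101, 350))
  full <- max_shift_correlation(sa, sb, min_overlap = 50)
  strided <- max_shift_correlation(sa, sb, min_overlap = 50, stride = 7)
  expect_equal(strided$shift, full$shift)
  expect_equal(strided$rho, full$rho, tolerance = 1e-9)
})

test_that("min_overlap validation", {
  sig <- encode_cumulated_phase(rand_dna(50))
  expect_error(max_shift_correlation(sig, sig, min_overlap = 60),
               "exceeds")
  expect_error(max_shift_correlation(sig, sig, min_overlap = 1), ">= 2")
})

test_that("overlap matrix is symmetric with unit diagonal", {
  # 600 bp reads keep the weakest true overlap (120 bases) above min_overlap
  lay <- small_layout(coverage = 5, seed = 41, read_len = 600)
  om <- build_overlap_matrix(lay)
  expect_equal(diag(om$rho), rep(1, 20), ignore_attr = TRUE)
  expect_identical(om$rho, t(om$rho))
  expect_true(all(om$rho >= -1 - 1e-9 & om$rho <= 1 + 1e-9))
  expect_identical(om$shift, -t(om$shift))
  # true-adjacent error-free pairs correlate perfectly
  ids <- lay$reads$read_id
  for (k in seq_len(nrow(lay$adjacencies))) {
    i <- match(lay$adjacencies[k, 1], ids)
    j <- match(lay$adjacencies[k, 2], ids)
    expect_equal(om$rho[i, j], 1.0, tolerance = 1e-9)
  }
})

test_that("two identical reads give off-diagonal 1", {
  s <- rand_dna(200)
  om <- build_overlap_matrix(c(r1 = s, r2 = s))
  expect_equal(om$rho[1, 2], 1.0, tolerance = 1e-12)
})

test_that("encoding errors are reported with the read id", {
  expect_error(build_overlap_matrix(c(ok = "ACGT", broken = "ACXT")),
               "broken")
})

test_that("cost transform maps correlations to the integer range", {
  # raw transform endpoints: (1 - rho) * 1000
  expect_identical(phaseasm:::.raw_cost(1), 0)
  expect_identical(phaseasm:::.raw_cost(0), 1000)
  expect_identical(phaseasm:::.raw_cost(-1), 2000)
  # full matrix: rho {1, 0, -1} spans the raw range {0, 1000, 2000},
  # min-max scaled to {0, 500, 1000}
  rho <- diag(1, 3)
  rho[1, 2] <- rho[2, 1] <- 1
  rho[1, 3] <- rho[3, 1] <- 0
  rho[2, 3] <- rho[3, 2] <- -1
  dimnames(rho) <- list(letters[1:3], letters[1:3])
  om <- structure(list(rho = rho, shift = matrix(0, 3, 3),
                       min_overlap = 100, stride = 1),
                  class = "overlap_matrix")
  cost <- to_cost_matrix(om)
  expect_equal(dim(cost), c(4, 4))
  expect_true(all(cost[1, ] == 0) && all(cost[, 1] == 0))
  expect_true(all(diag(cost) == 0))
  expect_equal(cost["a", "b"], 0, ignore_attr = TRUE)
  expect_equal(cost["a", "c"], 500, ignore_attr = TRUE)
  expect_equal(cost["b", "c"], 1000, ignore_attr = TRUE)
  expect_true(all(cost == floor(cost)))
  # degenerate constant matrix
  rho2 <- diag(1, 3)
  rho2[upper.tri(rho2)] <- rho2[lower.tri(rho2)] <- 0.5
  om$rho <- rho2
  expect_warning(c2 <- to_cost_matrix(om), "identical")
  expect_true(all(c2 == 0))
})

test_that("matrix TSV round trip", {
  lay <- small_layout(seed = 42)
  om <- build_overlap_matrix(lay)
  cost <- to_cost_matrix(om)
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(cost, f)
  back <- read_matrix_tsv(f)
  expect_equal(unclass(cost), back, ignore_attr = TRUE)
  expect_identical(rownames(back), c("0", lay$reads$read_id))
})
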