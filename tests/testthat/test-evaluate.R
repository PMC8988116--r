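test_that("a path in true source order has only correct edges", {
  lay <- small_layout(coverage = 5, seed = 81)
  cls <- classify_edges(1:20, lay)
  expect_equal(cls$n_edges, 20)  # 19 consecutive + circular wrap
  expect_equal(cls$correct, 20)
  expect_equal(cls$real_breaks, 0)
})

test_that("edge classification matches an independent adjacency oracle", {
  lay <- small_layout(coverage = 5, seed = 82)
  ids <- lay$reads$read_id
  keys <- apply(lay$adjacencies, 1, function(p) paste(sort(p), collapse = "|"))
  set.seed(82)
  for (i in 1:5) {
    path <- sample(1:20)
    cls <- classify_edges(path, lay)
    edges <- cbind(path, c(path[-1], path[1]))  # consecutive + wrap
    oracle <- vapply(seq_len(nrow(edges)), function(k) {
      paste(sort(ids[edges[k, ]]), collapse = "|") %in% keys
    }, logical(1))
    expect_identical(cls$is_true, oracle)
    expect_equal(cls$correct + cls$real_breaks, cls$n_edges)
  }
  expect_error(classify_edges(c(1, 99), lay), "unknown")
})

test_that("joining two true-order blocks at a non-overlap creates one break each side", {
  # coverage 2: only consecutive reads overlap (1 neighbour per side)
  lay <- small_layout(coverage = 2, seed = 83)
  # blocks 1..10 and 11..20 in order: junctions 10-11 and wrap 20-1 are true,
  # so swapping the blocks' interiors creates breaks
  path <- c(1:10, 15:20, 11:14)
  cls <- classify_edges(path, lay)
  # oracle: count consecutive-pair violations directly
  edges <- cbind(path, c(path[-1], path[1]))
  d <- abs(edges[, 1] - edges[, 2])
  true_edge <- d == 1 | d == 19
  expect_equal(cls$real_breaks, sum(!true_edge))
  expect_gt(cls$real_breaks, 0)
})

test_that("random permutations score near zero under sparse adjacency", {
  lay <- small_layout(coverage = 2, seed = 84)  # adjacency density ~0.1
  set.seed(84)
  accs <- replicate(10, {
    cls <- classify_edges(sample(1:20), lay)
    cls$correct / cls$n_edges
  })
  expect_lt(mean(accs), 0.35)
})

test_that("accuracy fraction follows the recovered-overlap definition", {
  expect_equal(accuracy_fraction(45, 50), 0.90)
  expect_equal(accuracy_fraction(50, 50), 1.00)
  expect_equal(accuracy_fraction(0, 50), 0)
  expect_equal(accuracy_fraction(55, 50), 1.00)  # capped
  expect_warning(a <- accuracy_fraction(0, 0), "undefined")
  expect_true(is.na(a))
  expect_error(accuracy_fraction(-1, 10), "non-negative")
})

test_that("the report row matches a perfect error-free run", {
  lay <- small_layout(coverage = 5, seed = 85)
  om <- build_overlap_matrix(lay)
  cost <- to_cost_matrix(om)
  sol <- solve_tsp_classic(cost)
  rep <- evaluate_report(sol, cost, lay, coverage = 5)
  expect_equal(rep$path_cost, 0)
  expect_equal(rep$incorrect_overlaps, 0)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$real_contig_breaks, 0)
  expect_equal(rep$calculated_contig_breaks, 0)
})

test_that("reports are invariant to read relabelling", {
  lay <- small_layout(coverage = 5, seed = 86)
  om <- build_overlap_matrix(lay)
  cost <- to_cost_matrix(om)
  sol <- solve_tsp_classic(cost)
  rep1 <- evaluate_report(sol, cost, lay, coverage = 5)
  lay2 <- lay
  lay2$reads$read_id <- sprintf("other_%02d", 1:20)
  remap <- setNames(lay2$reads$read_id, lay$reads$read_id)
  lay2$adjacencies[] <- remap[lay$adjacencies]
  rep2 <- evaluate_report(sol, cost, lay2, coverage = 5)
  expect_equal(rep1$accuracy, rep2$accuracy)
  expect_equal(rep1$correct_overlaps, rep2$correct_overlaps)
})

test_that("a report recomputed from serialised artifacts matches memory", {
  lay <- small_layout(coverage = 5, seed = 87)
  om <- build_overlap_matrix(lay)
  cost <- to_cost_matrix(om)
  sol <- solve_tsp_classic(cost)
  rep <- evaluate_report(sol, cost, lay, coverage = 5)
  d <- tempfile()
  dir.create(d)
  write_matrix_tsv(cost, file.path(d, "cost.tsv"))
  write_solution_json(sol, file.path(d, "path.json"))
  write_truth(lay, file.path(d, "truth.tsv"), file.path(d, "adj.json"))
  cost2 <- structure(read_matrix_tsv(file.path(d, "cost.tsv")),
                     class = c("cost_matrix", "matrix"), scale_max = 1000)
  sol2 <- read_solution_json(file.path(d, "path.json"))
  truth2 <- read_truth(file.path(d, "truth.tsv"), file.path(d, "adj.json"))
  rep2 <- evaluate_report(sol2, cost2, truth2, coverage = 5)
  expect_equal(unclass(rep), unclass(rep2), ignore_attr = TRUE)
})
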