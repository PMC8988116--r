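test_that("generate_source produces uniform circular sequences", {
  src <- generate_source(10000, seed = 3)
  expect_s3_class(src, "source_sequence")
  expect_equal(src$length, 10000)
  expect_equal(nchar(src$sequence), 10000)
  expect_true(grepl("^[ACGT]+$", src$sequence))
  expect_true(src$circular)
  # all four bases present at plausible frequencies
  tab <- table(strsplit(src$sequence, "")[[1]])
  expect_setequal(names(tab), c("A", "C", "G", "T"))
  expect_true(all(tab > 2200) && all(tab < 2800))
  # determinism and boundary
  expect_identical(generate_source(10000, seed = 3)$sequence, src$sequence)
  expect_equal(nchar(generate_source(1, seed = 1)$sequence), 1)
  expect_error(generate_source(0), "positive")
})

test_that("extract_reads tiles the circle and records the true layout", {
  src <- generate_source(30000, seed = 5)
  lay <- extract_reads(src, n_reads = 50, read_len = 3000, overlap = 2400)
  expect_equal(nrow(lay$reads), 50)
  expect_true(all(nchar(lay$reads$sequence) == 3000))
  expect_equal(lay$reads$true_start, (0:49) * 600)
  # every read is an exact substring of the doubled source
  doubled <- paste0(src$sequence, src$sequence)
  for (r in seq_len(50)) {
    expect_identical(
      substring(doubled, lay$reads$true_start[r] + 1,
                lay$reads$true_start[r] + 3000),
      lay$reads$sequence[r]
    )
  }
  # adjacency oracle by direct circular-interval arithmetic:
  # reads i, j (starts 600 apart) intersect iff the circular start distance
  # is under 3000 in either direction
  expected_pairs <- 0L
  consecutive <- 0L
  for (i in 1:49) {
    for (j in (i + 1):50) {
      d0 <- ((j - i) * 600) %% 30000
      d <- min(d0, 30000 - d0)
      if (d < 3000) {
        expected_pairs <- expected_pairs + 1L
        if (d == 600) consecutive <- consecutive + 1L
      }
    }
  }
  expect_equal(nrow(lay$adjacencies), expected_pairs)
  expect_equal(expected_pairs, 200)  # 4 neighbours on each side
  expect_equal(consecutive, 50)      # consecutive circular adjacencies
})

test_that("extract_reads boundary cases", {
  src <- generate_source(100, seed = 2)
  one <- extract_reads(src, n_reads = 1, read_len = 20, overlap = 10)
  expect_equal(nrow(one$reads), 1)
  expect_equal(nrow(one$adjacencies), 0)
  # overlap = 0: consecutive reads touch but do not intersect
  lay0 <- extract_reads(src, n_reads = 5, read_len = 20, overlap = 0)
  expect_equal(nrow(lay0$adjacencies), 0)
  expect_error(extract_reads(src, 5, 20, 20), "overlap")
  expect_warning(extract_reads(src, 3, 20, 5), "close the circle")
})

test_that("mutate_reads applies the rounded event count per read", {
  src <- generate_source(6000, seed = 9)
  lay <- extract_reads(src, n_reads = 2, read_len = 3000, overlap = 0)
  # zero error: identity
  expect_identical(mutate_reads(lay, 0)$reads$sequence, lay$reads$sequence)
  # deletion-only: length drops by exactly round(1% of 3000) = 30
  del <- mutate_reads(lay, 1.0, weights = c(deletion = 1), seed = 1)
  expect_true(all(nchar(del$reads$sequence) == 2970))
  # insertion-only: length grows by 30
  ins <- mutate_reads(lay, 1.0, weights = c(insertion = 1), seed = 1)
  expect_true(all(nchar(ins$reads$sequence) == 3030))
  # substitution-only: length preserved, at most 30 mismatches
  sub <- mutate_reads(lay, 1.0, weights = c(substitution = 1), seed = 1)
  expect_true(all(nchar(sub$reads$sequence) == 3000))
  mm <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, lay$reads$sequence, sub$reads$sequence)
  expect_true(all(mm >= 1 & mm <= 30))
  # truth untouched by mutation
  expect_identical(del$reads$true_start, lay$reads$true_start)
  expect_identical(del$adjacencies, lay$adjacencies)
  expect_warning(mutate_reads(lay, 2.0), "1.5")
  expect_error(mutate_reads(lay, 1, weights = c(bogus = 1)), "weights")
})

test_that("simulate_dataset_a honours the coverage identity and seed", {
  lay <- simulate_dataset_a(coverage = 5, seed = 21)
  expect_equal(nrow(lay$reads), 50)
  expect_true(all(lay$reads$pre_mutation_length == 3000))
  expect_equal(50 * 3000 / lay$source_length, 5)
  lay2 <- simulate_dataset_a(coverage = 5, seed = 21)
  expect_identical(lay$reads$sequence, lay2$reads$sequence)
  expect_error(simulate_dataset_a(coverage = 7), "coverage")
})

test_that("FASTA round trip preserves ids and sequences", {
  lay <- small_layout(seed = 4)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(lay, fa)
  back <- read_fasta(fa)
  expect_identical(back$read_id, lay$reads$read_id)
  expect_identical(back$sequence, lay$reads$sequence)
  # empty file -> empty collection
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(nrow(read_fasta(empty)), 0)
  # strict mode rejects ambiguity codes, naming the record
  writeLines(c(">bad_rec", "ACGTNACGT"), fa)
  expect_error(read_fasta(fa), "bad_rec")
  # optional seeded mapping to concrete bases
  mapped <- read_fasta(fa, iupac_to_random = TRUE, seed = 1)
  expect_true(grepl("^[ACGT]+$", mapped$sequence))
  expect_equal(nchar(mapped$sequence), 9)
})

test_that("truth files round-trip the layout", {
  lay <- small_layout(seed = 6)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_truth(lay, tsv, js)
  back <- read_truth(tsv, js)
  expect_identical(back$reads$read_id, lay$reads$read_id)
  expect_identical(back$reads$true_start, lay$reads$true_start)
  expect_equal(back$source_length, lay$source_length)
  expect_identical(back$adjacencies, lay$adjacencies)
})
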