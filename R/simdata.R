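#' @title Synthetic long-read datasets with ground truth
#' @description Generate a random circular source sequence, tile it with
#'   fixed-length reads at a prescribed consecutive overlap, optionally
#'   mutate the reads with point mutations, and keep the true layout
#'   (start coordinates and the set of genuinely overlapping read pairs)
#'   for downstream evaluation.
#' @name simdata
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T")

#' Generate a random source sequence
#'
#' Bases are drawn i.i.d. uniformly from A, C, G, T, which makes repeated
#' regions vanishingly unlikely -- the pipeline assumes a repeat-free source.
#' The sequence is treated as circular (a cyclic buffer), so its beginning
#' and end are not distinguished.
#'
#' @param length Number of bases (>= 1).
#' @param seed Optional integer seed; the same seed reproduces the sequence.
#' @return An object of class `source_sequence`: a list with `sequence`
#'   (character string), `length` and `circular = TRUE`.
#' @export
generate_source <- function(length, seed = NULL) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1) {
    stop("'length' must be a positive integer")
  }
  length <- as.integer(length)
  if (!is.null(seed)) set.seed(seed)
  seq <- paste(sample(.DNA_ALPHABET, length, replace = TRUE), collapse = "")
  structure(
    list(sequence = seq, length = length, circular = TRUE),
    class = "source_sequence"
  )
}

# Circular interval intersection: do [s1, s1+l1) and [s2, s2+l2) intersect
# on a circle of size L? Touching endpoints do not count as intersection.
.circ_intersect <- function(s1, l1, s2, l2, L) {
  if (l1 + l2 >= L) return(TRUE)
  d <- (s2 - s1) %% L
  d < l1 || (L - d) < l2
}

# All unordered pairs of reads whose true intervals intersect on the circle
# (or on the line, for a linear source). Returns a 2-column character matrix
# of read ids, plus is used to key the truth set.
.true_adjacencies <- function(starts, lens, ids, L, circular = TRUE) {
  n <- length(starts)
  pairs <- list()
  k <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        hit <- if (circular) {
          .circ_intersect(starts[i], lens[i], starts[j], lens[j], L)
        } else {
          starts[i] < starts[j] + lens[j] && starts[j] < starts[i] + lens[i]
        }
        if (hit) {
          k <- k + 1L
          pairs[[k]] <- c(ids[i], ids[j])
        }
      }
    }
  }
  if (k == 0L) {
    matrix(character(0), ncol = 2L,
           dimnames = list(NULL, c("read1", "read2")))
  } else {
    m <- do.call(rbind, pairs)
    dimnames(m) <- list(NULL, c("read1", "read2"))
    m
  }
}

# Canonical "id1|id2" keys (sorted within pair) for set membership tests.
.adjacency_keys <- function(adj) {
  if (nrow(adj) == 0L) return(character(0))
  apply(adj, 1L, function(p) paste(sort(p), collapse = "|"))
}

#' Extract evenly spaced reads from a circular source
#'
#' Consecutive read starts are spaced `read_len - overlap` bases apart and
#' wrap around the circular source, so the requested `overlap` is the target
#' overlap between consecutive reads. If `n_reads` steps do not return
#' exactly to the origin a warning flags the residual wrap mismatch (the
#' layout is still produced; the last/first pair simply has a different
#' overlap).
#'
#' @param src A `source_sequence`.
#' @param n_reads Number of reads to extract.
#' @param read_len Read length in bases.
#' @param overlap Target overlap between consecutive reads
#'   (`0 <= overlap < read_len`).
#' @return An object of class `read_layout`: a list with `reads` (data.frame
#'   with columns `read_id`, `sequence`, `true_start`, `pre_mutation_length`),
#'   `source_length`, `circular`, `adjacencies` (2-column matrix of read-id
#'   pairs that genuinely overlap on the source) and `error_pct = 0`.
#' @export
extract_reads <- function(src, n_reads, read_len, overlap) {
  stopifnot(inherits(src, "source_sequence"))
  n_reads <- as.integer(n_reads)
  read_len <- as.integer(read_len)
  overlap <- as.integer(overlap)
  if (n_reads < 1L) stop("'n_reads' must be >= 1")
  if (overlap < 0L || overlap >= read_len) {
    stop("'overlap' must satisfy 0 <= overlap < read_len")
  }
  L <- src$length
  step <- read_len - overlap
  if (n_reads > 1L && (n_reads * step) %% L != 0L) {
    warning(sprintf(
      "n_reads * (read_len - overlap) = %d does not close the circle of length %d; last/first overlap differs from the target",
      n_reads * step, L
    ))
  }
  starts <- ((seq_len(n_reads) - 1L) * step) %% L
  # doubled sequence makes circular substring extraction trivial
  doubled <- paste0(src$sequence, src$sequence)
  if (read_len > 2L * L) stop("'read_len' exceeds twice the source length")
  seqs <- substring(doubled, starts + 1L, starts + read_len)
  ids <- sprintf("read_%03d", seq_len(n_reads))
  reads <- data.frame(
    read_id = ids,
    sequence = seqs,
    true_start = starts,
    pre_mutation_length = read_len,
    stringsAsFactors = FALSE
  )
  adj <- .true_adjacencies(starts, rep(read_len, n_reads), ids, L,
                           circular = src$circular)
  structure(
    list(reads = reads, source_length = L, circular = src$circular,
         adjacencies = adj, error_pct = 0),
    class = "read_layout"
  )
}

# One point-mutation event applied to a base vector at a uniform position.
# Substitutions always change the base; insertions/duplications lengthen and
# deletions shorten the read.
.apply_mutation <- function(bases, op) {
  n <- length(bases)
  pos <- sample.int(n, 1L)
  switch(op,
    substitution = {
      bases[pos] <- sample(setdiff(.DNA_ALPHABET, bases[pos]), 1L)
      bases
    },
    insertion = append(bases, sample(.DNA_ALPHABET, 1L), after = pos - 1L),
    deletion = if (n > 1L) bases[-pos] else bases,
    duplication = append(bases, bases[pos], after = pos)
  )
}

#' Introduce point mutations into the reads of a layout
#'
#' Per read, `round(error_pct / 100 * pre_mutation_length)` mutation events
#' are applied at uniformly random positions; each event is an insertion,
#' deletion, substitution or duplication chosen with the given relative
#' weights. Errors do not move reads: true start coordinates and the true
#' adjacency set are unchanged.
#'
#' @param layout A `read_layout`.
#' @param error_pct Percentage of bases mutated, in `[0, 100]`; values above
#'   1.5 trigger a warning because the pipeline assumes a low error rate.
#' @param weights Named non-negative weights for the four operators
#'   (`insertion`, `deletion`, `substitution`, `duplication`); equal by
#'   default.
#' @param seed Optional integer seed.
#' @return The layout with mutated read sequences and `error_pct` recorded.
#' @export
mutate_reads <- function(layout, error_pct,
                         weights = c(insertion = 1, deletion = 1,
                                     substitution = 1, duplication = 1),
                         seed = NULL) {
  stopifnot(inherits(layout, "read_layout"))
  if (!is.numeric(error_pct) || error_pct < 0) {
    stop("'error_pct' must be a non-negative percentage")
  }
  ops <- c("insertion", "deletion", "substitution", "duplication")
  if (is.null(names(weights)) || !all(names(weights) %in% ops) ||
      any(weights < 0) || sum(weights) <= 0) {
    stop("'weights' must be named non-negative weights for ",
         paste(ops, collapse = ", "), " with a positive sum")
  }
  w <- weights[ops]
  w[is.na(w)] <- 0
  if (error_pct > 1.5) {
    warning("error_pct above 1.5% violates the low-error assumption")
  }
  if (error_pct == 0) {
    layout$error_pct <- 0
    return(layout)
  }
  if (!is.null(seed)) set.seed(seed)
  for (r in seq_len(nrow(layout$reads))) {
    len0 <- layout$reads$pre_mutation_length[r]
    n_events <- round(error_pct / 100 * len0)
    if (n_events == 0L) next
    bases <- strsplit(layout$reads$sequence[r], "", fixed = TRUE)[[1L]]
    picked <- sample(ops, n_events, replace = TRUE, prob = w)
    for (op in picked) bases <- .apply_mutation(bases, op)
    layout$reads$sequence[r] <- paste(bases, collapse = "")
  }
  layout$error_pct <- error_pct
  layout
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper reproducing the reference experimental setup: 50 reads
#' of 3000 bp on a random circular source whose length is chosen so that
#' `n_reads * read_len / source_length` equals the requested coverage, with
#' evenly spaced starts and optional point mutations.
#'
#' @param coverage Target mean coverage (e.g. 5, 10 or 15).
#' @param error_pct Percentage of point mutations per read (0 to 1.5 for
#'   assumption-faithful runs).
#' @param seed Integer seed controlling source, layout and mutations.
#' @param n_reads,read_len Number and pre-mutation length of reads.
#' @return A `read_layout` (see [extract_reads()]) with a `coverage` field.
#' @export
simulate_dataset_a <- function(coverage, error_pct = 0, seed = 1,
                               n_reads = 50, read_len = 3000) {
  L <- n_reads * read_len / coverage
  if (L != round(L)) stop("coverage does not divide n_reads * read_len")
  L <- as.integer(L)
  step <- L / n_reads
  if (step != round(step)) {
    stop("source length is not a multiple of n_reads; choose a coverage ",
         "giving an integer start step")
  }
  src <- generate_source(L, seed = seed)
  layout <- extract_reads(src, n_reads, read_len, read_len - as.integer(step))
  layout <- mutate_reads(layout, error_pct, seed = seed + 1L)
  layout$coverage <- coverage
  layout
}

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings. `read_fasta()` validates that every
#' record uses only A, C, G, T (after uppercasing); with
#' `iupac_to_random = TRUE`, IUPAC ambiguity codes are replaced by a random
#' concrete base drawn from the code's meaning (seeded), otherwise any
#' non-ACGT symbol is rejected naming the offending record.
#'
#' @param path File path.
#' @param iupac_to_random Replace ambiguity codes by random concrete bases.
#' @param seed Seed for the ambiguity replacement.
#' @return `read_fasta()`: a data.frame with columns `read_id` and
#'   `sequence`.
#' @export
read_fasta <- function(path, iupac_to_random = FALSE, seed = NULL) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (iupac_to_random) {
    if (!is.null(seed)) set.seed(seed)
    iupac <- Biostrings::IUPAC_CODE_MAP
    for (i in seq_along(seqs)) {
      bases <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      amb <- which(!(bases %in% .DNA_ALPHABET))
      for (k in amb) {
        code <- iupac[[bases[k]]]
        if (is.null(code)) {
          stop(sprintf("record '%s' contains unknown symbol '%s'",
                       ids[i], bases[k]))
        }
        bases[k] <- sample(strsplit(code, "", fixed = TRUE)[[1L]], 1L)
      }
      seqs[i] <- paste(bases, collapse = "")
    }
  } else {
    ok <- grepl("^[ACGT]*$", seqs)
    if (!all(ok)) {
      stop(sprintf("record '%s' contains non-ACGT symbols; use iupac_to_random or clean the input",
                   ids[which(!ok)[1L]]))
    }
  }
  data.frame(read_id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' @param reads A data.frame with `read_id` and `sequence` columns, or a
#'   `read_layout`.
#' @rdname read_fasta
#' @export
write_fasta <- function(reads, path) {
  if (inherits(reads, "read_layout")) reads <- reads$reads
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$read_id
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Write and read ground-truth layout files
#'
#' The truth is serialised as a TSV of read coordinates
#' (`read_id`, `true_start`, `pre_mutation_length`, plus `source_length` and
#' `circular` repeated per row) and a JSON adjacency list of genuinely
#' overlapping read-id pairs.
#'
#' @param layout A `read_layout`.
#' @param tsv_path,json_path Output paths.
#' @return `read_truth()` reconstructs a `read_layout` without sequences.
#' @export
write_truth <- function(layout, tsv_path, json_path) {
  stopifnot(inherits(layout, "read_layout"))
  df <- layout$reads[, c("read_id", "true_start", "pre_mutation_length")]
  df$source_length <- layout$source_length
  df$circular <- layout$circular
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  adj <- apply(layout$adjacencies, 1L, function(p) as.list(p))
  jsonlite::write_json(
    lapply(seq_len(nrow(layout$adjacencies)), function(i) {
      unname(as.list(layout$adjacencies[i, ]))
    }),
    json_path, auto_unbox = TRUE
  )
  invisible(NULL)
}

#' @rdname write_truth
#' @export
read_truth <- function(tsv_path, json_path) {
  df <- read.table(tsv_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  adj_list <- jsonlite::read_json(json_path)
  adj <- if (length(adj_list) == 0L) {
    matrix(character(0), ncol = 2L,
           dimnames = list(NULL, c("read1", "read2")))
  } else {
    m <- t(vapply(adj_list, function(p) c(p[[1L]], p[[2L]]), character(2L)))
    dimnames(m) <- list(NULL, c("read1", "read2"))
    m
  }
  structure(
    list(
      reads = data.frame(read_id = df$read_id, sequence = NA_character_,
                         true_start = df$true_start,
                         pre_mutation_length = df$pre_mutation_length,
                         stringsAsFactors = FALSE),
      source_length = df$source_length[1L],
      circular = as.logical(df$circular[1L]),
      adjacencies = adj,
      error_pct = NA_real_
    ),
    class = "read_layout"
  )
}

#' @export
print.read_layout <- function(x, ...) {
  cat(sprintf(
    "read_layout: %d reads, source %d bp (%s), %d true overlap pairs, %.2f%% errors\n",
    nrow(x$reads), x$source_length,
    if (isTRUE(x$circular)) "circular" else "linear",
    nrow(x$adjacencies), x$error_pct
  ))
  invisible(x)
}
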