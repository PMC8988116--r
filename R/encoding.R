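#' @title Cumulated-phase encoding of DNA sequences
#' @description Map each base to a complex number (A: 1+j, C: -1-j, G: -1+j,
#'   T: 1-j), take the complex argument, and accumulate the arguments along
#'   the sequence. The running sum is the signal used for overlap detection:
#'   two reads sharing a substring produce signal windows that differ only by
#'   an additive constant, which Pearson correlation ignores.
#' @name encoding
NULL

# Complex arguments of the four base mappings, kept as integer multiples of
# pi/4 so the accumulation is exact integer arithmetic (no arctan calls) and
# the floating error of a signal value is one rounded product, independent
# of read length.
.phase_quarters <- c(
  A = 1L,   # arg(1 + j)  =  pi/4
  C = -3L,  # arg(-1 - j) = -3*pi/4
  G = 3L,   # arg(-1 + j) =  3*pi/4
  T = -1L   # arg(1 - j)  = -pi/4
)

#' Encode a DNA string as a cumulated-phase signal
#'
#' @param sequence A single non-empty character string over the alphabet
#'   A, C, G, T (case-insensitive).
#' @return A numeric vector of the same length as the sequence; element `k`
#'   is the sum of the complex arguments of the first `k` mapped bases.
#'   Consecutive differences are always one of `pi/4`, `-pi/4`, `3*pi/4`,
#'   `-3*pi/4`.
#' @examples
#' encode_cumulated_phase("ACGT")  # pi/4, -pi/2, pi/4, 0
#' @export
encode_cumulated_phase <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("'sequence' must be a single character string")
  }
  if (nchar(sequence) == 0L) {
    stop("'sequence' must be non-empty")
  }
  bases <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  q <- .phase_quarters[bases]
  if (anyNA(q)) {
    bad <- which(is.na(q))[1L]
    stop(sprintf("illegal symbol '%s' at position %d", bases[bad], bad))
  }
  cumsum(unname(q)) * (pi / 4)
}
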