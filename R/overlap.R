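#' @title Overlap detection via sliding-window Pearson correlation
#' @description For every pair of reads, the cumulated-phase signals are slid
#'   against each other and the Pearson correlation of the overlapping
#'   windows is computed for each shift; the maximum over shifts is the
#'   pair's overlap score. The fast path evaluates all shifts at once with
#'   FFT cross-products and prefix sums; a naive per-shift path is retained
#'   as an independent oracle.
#' @name overlap
NULL

#' Pearson correlation coefficient of two equal-length windows
#'
#' Standard product-moment correlation, `cov(X, Y) / (sd(X) sd(Y))`. A window
#' with zero standard deviation carries no evidence of a linear relation, so
#' the coefficient is defined as 0 in that case (avoiding division by zero).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A value in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("'x' and 'y' must have equal length")
  if (n < 2L) stop("windows must have length >= 2")
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  vx <- sum(dx * dx); vy <- sum(dy * dy)
  if (vx <= 0 || vy <= 0) return(0)
  r <- sum(dx * dy) / sqrt(vx * vy)
  max(-1, min(1, r))
}

# rho for every candidate shift, vectorised. Positive shift s means sigB
# starts s positions into sigA; the overlapping windows are
#   s >= 0:  a[(s+1)..(s+w)] vs b[1..w],  w = min(La - s, Lb)
#   s <  0:  a[1..w] vs b[(t+1)..(t+w)],  t = -s, w = min(Lb - t, La)
# `cc[s]` must hold the raw cross-product sum over the window, which the FFT
# provides for all shifts at once thanks to zero padding.
.rho_at_shifts <- function(shifts, cc_at, Pa, Pa2, Pb, Pb2, La, Lb) {
  s <- shifts
  w <- ifelse(s >= 0, pmin(La - s, Lb), pmin(Lb + s, La))
  Sxy <- cc_at(s)
  pos <- s >= 0
  t <- ifelse(pos, s, -s)
  Sx <- ifelse(pos, Pa[t + w + 1L] - Pa[t + 1L], Pa[w + 1L])
  Sx2 <- ifelse(pos, Pa2[t + w + 1L] - Pa2[t + 1L], Pa2[w + 1L])
  Sy <- ifelse(pos, Pb[w + 1L], Pb[t + w + 1L] - Pb[t + 1L])
  Sy2 <- ifelse(pos, Pb2[w + 1L], Pb2[t + w + 1L] - Pb2[t + 1L])
  num <- Sxy - Sx * Sy / w
  vx <- pmax(Sx2 - Sx^2 / w, 0)
  vy <- pmax(Sy2 - Sy^2 / w, 0)
  den <- sqrt(vx * vy)
  rho <- ifelse(den > 0, num / den, 0)
  pmax(-1, pmin(1, rho))
}

# Deterministic argmax: among shifts within 1e-12 of the maximum rho, prefer
# the smallest |shift|, then the positive one.
.pick_best_shift <- function(shifts, rho) {
  m <- max(rho)
  cand <- which(rho >= m - 1e-12)
  cand <- cand[order(abs(shifts[cand]), -sign(shifts[cand]))]
  best <- cand[1L]
  list(rho = rho[best], shift = shifts[best])
}

# Signal profile used by the fast path: centered values, prefix sums of
# values and squares (leading zero), and the length-n padded FFT.
.signal_profile <- function(sig, n) {
  c0 <- sig - mean(sig)
  list(
    centered = c0,
    P = c(0, cumsum(c0)),
    P2 = c(0, cumsum(c0 * c0)),
    fft = stats::fft(c(c0, rep(0, n - length(c0)))),
    len = length(c0)
  )
}

# Cross-products for all shifts from two cached FFTs (common pad length n,
# n >= La + Lb). cc(s) = sum_k a[s+k] b[k]; negative shifts wrap to the top.
.cross_products <- function(fftA, fftB, n) {
  Re(stats::fft(fftA * Conj(fftB), inverse = TRUE)) / n
}

.candidate_shifts <- function(La, Lb, min_overlap, stride) {
  full <- seq.int(-(Lb - min_overlap), La - min_overlap)
  if (stride <= 1L) return(list(coarse = full, full = full))
  list(coarse = full[seq.int(1L, length(full), by = stride)], full = full)
}

.max_shift_fft <- function(profA, profB, n, min_overlap, stride) {
  La <- profA$len; Lb <- profB$len
  cc <- .cross_products(profA$fft, profB$fft, n)
  cc_at <- function(s) cc[(s %% n) + 1L]
  cand <- .candidate_shifts(La, Lb, min_overlap, stride)
  rho <- .rho_at_shifts(cand$coarse, cc_at, profA$P, profA$P2,
                        profB$P, profB$P2, La, Lb)
  best <- .pick_best_shift(cand$coarse, rho)
  if (stride > 1L) {
    # refine around the best strided shift
    lo <- max(best$shift - (stride - 1L), min(cand$full))
    hi <- min(best$shift + (stride - 1L), max(cand$full))
    fine <- seq.int(lo, hi)
    rho_f <- .rho_at_shifts(fine, cc_at, profA$P, profA$P2,
                            profB$P, profB$P2, La, Lb)
    best <- .pick_best_shift(fine, rho_f)
  }
  best
}

#' Maximum Pearson correlation over all relative shifts of two signals
#'
#' @param sigA,sigB Numeric phase signals (see [encode_cumulated_phase()]).
#' @param min_overlap Minimum window length (bases) for a shift to be
#'   considered; tiny windows produce spurious coefficients near 1. Default
#'   100.
#' @param stride Evaluate every `stride`-th shift, then refine around the
#'   best one (default 1 = exhaustive; the FFT path makes stride > 1 rarely
#'   necessary).
#' @param method `"fft"` (prefix sums + FFT cross-products, O(L log L)) or
#'   `"naive"` (per-shift evaluation of the correlation formula, the test
#'   oracle).
#' @return A list with `rho` (maximum coefficient) and `shift`; a positive
#'   shift `s` means `sigB` starts `s` positions into `sigA`. Swapping the
#'   inputs negates the shift.
#' @export
max_shift_correlation <- function(sigA, sigB, min_overlap = 100, stride = 1,
                                  method = c("fft", "naive")) {
  method <- match.arg(method)
  La <- length(sigA); Lb <- length(sigB)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 2L) stop("'min_overlap' must be >= 2")
  if (min_overlap > La || min_overlap > Lb) {
    stop("'min_overlap' exceeds a signal length; no valid window exists")
  }
  stride <- max(1L, as.integer(stride))
  if (method == "naive") {
    shifts <- seq.int(-(Lb - min_overlap), La - min_overlap)
    rho <- vapply(shifts, function(s) {
      if (s >= 0) {
        w <- min(La - s, Lb)
        pearson(sigA[(s + 1L):(s + w)], sigB[1:w])
      } else {
        t <- -s
        w <- min(Lb - t, La)
        pearson(sigA[1:w], sigB[(t + 1L):(t + w)])
      }
    }, numeric(1L))
    return(.pick_best_shift(shifts, rho))
  }
  n <- stats::nextn(La + Lb)
  .max_shift_fft(.signal_profile(sigA, n), .signal_profile(sigB, n),
                 n, min_overlap, stride)
}

#' Pairwise maximum-correlation matrix for a set of reads
#'
#' Encodes every read, then fills a symmetric N x N matrix with the maximum
#' sliding-window Pearson coefficient for each unordered pair (diagonal 1),
#' together with the arg-max shift. Per-read FFTs are cached, so each pair
#' costs one complex multiply and one inverse FFT.
#'
#' @param reads A `read_layout`, a data.frame with `read_id`/`sequence`
#'   columns, or a named character vector of sequences.
#' @inheritParams max_shift_correlation
#' @return An object of class `overlap_matrix`: list with `rho` and `shift`
#'   matrices (dimnames = read ids) and the parameters used.
#' @export
build_overlap_matrix <- function(reads, min_overlap = 100, stride = 1) {
  if (inherits(reads, "read_layout")) reads <- reads$reads
  if (is.data.frame(reads)) {
    seqs <- reads$sequence
    ids <- reads$read_id
  } else {
    seqs <- as.character(reads)
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read_%03d", seq_along(seqs))
  }
  N <- length(seqs)
  if (N < 2L) stop("need at least 2 reads")
  sigs <- lapply(seq_len(N), function(i) {
    tryCatch(encode_cumulated_phase(seqs[i]),
             error = function(e) stop("read '", ids[i], "': ",
                                      conditionMessage(e)))
  })
  lens <- lengths(sigs)
  if (min_overlap > min(lens)) {
    stop("'min_overlap' exceeds the shortest read length")
  }
  n <- stats::nextn(2L * max(lens))
  profs <- lapply(sigs, .signal_profile, n = n)
  rho <- diag(1, N)
  shift <- matrix(0L, N, N)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      best <- .max_shift_fft(profs[[i]], profs[[j]], n, min_overlap, stride)
      rho[i, j] <- rho[j, i] <- best$rho
      shift[i, j] <- best$shift
      shift[j, i] <- -best$shift
    }
  }
  dimnames(rho) <- dimnames(shift) <- list(ids, ids)
  structure(
    list(rho = rho, shift = shift, min_overlap = min_overlap,
         stride = stride),
    class = "overlap_matrix"
  )
}

# (1 - rho) * 1000: correlation 1 -> 0, correlation 0 -> 1000,
# correlation -1 -> 2000. Applied before min-max scaling.
.raw_cost <- function(rho) (1 - rho) * 1000

# Half-up rounding (R's round() is banker's).
.round_half_up <- function(x) floor(x + 0.5)

#' Derive the integer TSP cost matrix with an artificial start vertex
#'
#' Off-diagonal entries are transformed as `(1 - rho) * 1000`, then min-max
#' scaled to `[0, scale_max]` and rounded to integers (TSP solvers here
#' operate on integer costs). An artificial vertex labelled `"0"` is
#' prepended with zero cost to and from every read, so the tour has a fixed,
#' meaningless start; removing it from the resulting Hamiltonian cycle
#' yields the read ordering.
#'
#' @param om An `overlap_matrix`.
#' @param scale_max Upper end of the integer cost range (default 1000).
#' @return An object of class `cost_matrix`: an `(N+1) x (N+1)` integer
#'   matrix, row/column 1 being the artificial vertex `"0"`, with attribute
#'   `scale_max`.
#' @export
to_cost_matrix <- function(om, scale_max = 1000) {
  stopifnot(inherits(om, "overlap_matrix"))
  rho <- om$rho
  N <- nrow(rho)
  v <- .raw_cost(rho)
  off <- upper.tri(v) | lower.tri(v)
  mn <- min(v[off]); mx <- max(v[off])
  if (mx == mn) {
    warning("all off-diagonal costs identical; scaled matrix is all zero")
    scaled <- matrix(0, N, N)
  } else {
    scaled <- .round_half_up((v - mn) / (mx - mn) * scale_max)
  }
  diag(scaled) <- 0
  cost <- matrix(0, N + 1L, N + 1L)
  cost[-1L, -1L] <- scaled
  read_ids <- rownames(rho)
  if (is.null(read_ids)) read_ids <- sprintf("read_%03d", seq_len(N))
  ids <- c("0", read_ids)
  dimnames(cost) <- list(ids, ids)
  structure(cost, class = c("cost_matrix", "matrix"), scale_max = scale_max)
}

#' Serialise matrices as TSV with a header of read ids
#'
#' @param m An `overlap_matrix` component (`$rho`) or a `cost_matrix`.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  write.table(as.data.frame(unclass(m)), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                   check.names = FALSE)
  as.matrix(df)
}
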