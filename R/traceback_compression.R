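# Bit-packed traceback storage.
#
# Instead of keeping one (k, r_prev) record per position for every (w, r)
# cell, the whole chain of a cell is concatenated into two 32-bit words:
# one holding the n sidechain-index fields, one holding the n
# predecessor-rank fields.  Field s of the index word is
# floor(log2(k_s)) + 1 bits wide; every field of the rank word is
# floor(log2(R)) + 1 bits wide.  Packing is possible only when the field
# widths sum to at most 32 bits in each word.
#
# Layout (fixed by this package; see docs/packing.md): position 0 sits at
# the least-significant end of each word and higher positions follow at
# increasing offsets.  Words are held in R doubles, which represent
# unsigned 32-bit values exactly, sidestepping the sign bit of R's native
# integer type.

#' Bits needed to store a sidechain index at a position
#'
#' A position offering `k_s` sidechains stores its chosen index in
#' `floor(log2(k_s)) + 1` bits — the bit length of `k_s` itself.  (For
#' exact powers of two this spends one bit more than the zero-based
#' indices strictly need; the width is kept as defined because the
#' feasibility inequalities and the packed word layout are stated in terms
#' of it.)
#'
#' @param k_s positive integer (vectorized) sidechain count(s).
#' @return integer bit count(s).
#' @examples
#' bits_for_sidechain(c(1, 3, 4))  # 1 2 3
#' @export
bits_for_sidechain <- function(k_s) {
  vapply(k_s, function(k) {
    k <- as.integer(k)
    if (is.na(k) || k < 1L) stop("sidechain count must be a positive integer")
    b <- 0L
    while (k > 0L) { k <- k %/% 2L; b <- b + 1L }
    b
  }, integer(1))
}

#' Can a traceback chain be packed into two 32-bit words?
#'
#' Checks the two packing constraints: the per-position sidechain-index
#' fields must fit one word, `sum_s floor(log2(k_s) + 1) <= 32`, and the
#' uniform predecessor-rank fields the other,
#' `n * floor(log2(R) + 1) <= 32`.
#'
#' @param K integer vector of per-position sidechain counts.
#' @param R number of ranks kept per state.
#' @return list with logical `eq1_ok` (index word fits), `eq2_ok` (rank
#'   word fits), and the bit totals `k_bits_total`, `r_bits_total`.
#' @examples
#' check_compression_feasible(rep(4, 10), R = 3)  # both fit: 30 and 20 bits
#' @export
check_compression_feasible <- function(K, R) {
  if (length(K) < 1L) stop("K must be nonempty")
  if (R < 1L) stop("R must be >= 1")
  k_bits <- sum(bits_for_sidechain(K))
  r_bits <- length(K) * bits_for_sidechain(R)
  list(eq1_ok = k_bits <= 32L, eq2_ok = r_bits <= 32L,
       k_bits_total = as.integer(k_bits), r_bits_total = as.integer(r_bits))
}

#' Pack a traceback chain into two 32-bit words
#'
#' Concatenates `n` `(k, r_prev)` records into one index word and one rank
#' word, position 0 at the least-significant bits.  Each `k` occupies
#' [bits_for_sidechain()] of its `k_s` bits; each `r_prev` occupies the
#' uniform `bits_for_sidechain(R)` bits.
#'
#' @param k integer vector of `n` zero-based sidechain indices.
#' @param r_prev integer vector of `n` zero-based predecessor ranks.
#' @param K per-position sidechain counts (defines the field widths).
#' @param R ranks per state (defines the rank field width).
#' @return object of class `packed_traceback`: list with `k_word` and
#'   `r_word`, doubles holding unsigned 32-bit values.
#' @examples
#' pt <- pack_traceback(k = 1, r_prev = 1, K = 2, R = 2)
#' pt$k_word  # 1
#' @export
pack_traceback <- function(k, r_prev, K, R) {
  n <- length(K)
  if (length(k) != n || length(r_prev) != n)
    stop("k and r_prev must hold one record per position")
  feas <- check_compression_feasible(K, R)
  if (!(feas$eq1_ok && feas$eq2_ok))
    stop(sprintf("packing infeasible: %d index bits / %d rank bits exceed 32",
                 feas$k_bits_total, feas$r_bits_total))
  k <- as.integer(k); r_prev <- as.integer(r_prev)
  k_width <- bits_for_sidechain(K)
  r_width <- bits_for_sidechain(R)
  if (any(k < 0L) || any(k >= 2^k_width))
    stop("sidechain index exceeds its field width")
  if (any(r_prev < 0L) || any(r_prev >= R) || any(r_prev >= 2^r_width))
    stop("predecessor rank exceeds its field width")
  k_offset <- c(0L, cumsum(k_width))[seq_len(n)]
  r_offset <- (seq_len(n) - 1L) * r_width
  structure(list(k_word = sum(k * 2^k_offset),
                 r_word = sum(r_prev * 2^r_offset)),
            class = "packed_traceback")
}

#' Unpack two 32-bit traceback words
#'
#' Exact inverse of [pack_traceback()] under the same layout parameters
#' `(K, R)`.
#'
#' @param packed a `packed_traceback` (or bare list with `k_word`,
#'   `r_word`).
#' @param K,R the layout parameters used at pack time.
#' @return list with integer vectors `k` and `r_prev`, one record per
#'   position.
#' @export
unpack_traceback <- function(packed, K, R) {
  n <- length(K)
  k_width <- bits_for_sidechain(K)
  r_width <- bits_for_sidechain(R)
  k_offset <- c(0L, cumsum(k_width))[seq_len(n)]
  r_offset <- (seq_len(n) - 1L) * r_width
  list(k = as.integer((packed$k_word %/% 2^k_offset) %% 2^k_width),
       r_prev = as.integer((packed$r_word %/% 2^r_offset) %% 2^r_width))
}

#' Traceback memory footprints and the saving from packing
#'
#' Without compression the traceback matrix needs one record per position
#' per cell, `8 * n * w_prime_max * R` bytes; packed into two words per
#' cell it needs `8 * w_prime_max * R` bytes regardless of `n`, a saving
#' of `100 * (1 - 1/n)` percent.
#'
#' @param n positions; @param R ranks; @param w_prime_max integer mass
#'   bound.
#' @return byte counts (doubles; these exceed integer range for realistic
#'   instances) or a percentage.
#' @examples
#' uncompressed_traceback_bytes(10, 3, 5e7) / compressed_traceback_bytes(3, 5e7)
#' traceback_saving_fraction(10)  # 90
#' @export
uncompressed_traceback_bytes <- function(n, R, w_prime_max) {
  stopifnot(n >= 0, R >= 0, w_prime_max >= 0)
  8 * n * w_prime_max * R
}

#' @rdname uncompressed_traceback_bytes
#' @export
compressed_traceback_bytes <- function(R, w_prime_max) {
  stopifnot(R >= 0, w_prime_max >= 0)
  8 * w_prime_max * R
}

#' @rdname uncompressed_traceback_bytes
#' @export
traceback_saving_fraction <- function(n) {
  stopifnot(n >= 1)
  100 * (1 - 1 / n)
}
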