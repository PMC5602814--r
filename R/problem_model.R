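# Domain types for scaffolds, mass peaks and explicit compounds.
#
# A scaffold configuration is the tuple (n, K, W, P): n substitutable
# positions, K the per-position sidechain counts, W the n x h matrix of
# sidechain masses (Da) and P the n x h matrix of attachment probabilities,
# with h = max(K) and all cells beyond k_s zero-padded.  Sidechain indices
# are zero-based throughout the public interface: the dynamic program, the
# traceback bit-packing and the brute-force oracle all operate on the index
# values themselves, so a single convention is kept end to end.

#' Construct a scaffold configuration
#'
#' Builds the `(n, K, W, P)` description of one configuration of a molecular
#' scaffold: for each substitutable position, the candidate sidechains with
#' their masses (Da) and attachment probabilities.  Ragged per-position
#' vectors are padded with zeros to `h = max(K)` columns; padded cells are
#' not legal sidechains and carry mass 0 and probability 0 by convention.
#'
#' Probabilities are only required to lie in `[0, 1]`; they need not sum to
#' one within a position, and the solver never renormalizes them.
#'
#' @param weights list of `n` numeric vectors; `weights[[s]][j]` is the mass
#'   in Da of the `j`-th candidate sidechain at position `s`.
#' @param probs list of `n` numeric vectors of the same shape as `weights`;
#'   attachment probabilities in `[0, 1]`.
#' @param scaffold_id character scalar identifying the scaffold.
#' @param config_index non-negative integer; which configuration of the
#'   scaffold this is (a scaffold may admit several sets of substitutable
#'   positions, each solved independently).
#' @param sidechain_labels optional list of `n` character vectors naming the
#'   sidechains (plumbing for reports; never used by the solver).
#' @return an object of class `scaffold_config`: a list with elements
#'   `scaffold_id`, `config_index`, `n`, `K`, `h`, `W`, `P`,
#'   `sidechain_labels`.
#' @examples
#' cfg <- scaffold_config(
#'   weights = list(c(1, 2), c(1, 2)),
#'   probs   = list(c(0.9, 0.1), c(0.8, 0.2)))
#' cfg$h
#' @export
scaffold_config <- function(weights, probs, scaffold_id = "scaffold",
                            config_index = 0L, sidechain_labels = NULL) {
  if (!is.list(weights) || !is.list(probs))
    stop("`weights` and `probs` must be lists of per-position vectors")
  if (length(weights) != length(probs))
    stop("`weights` and `probs` must have one vector per position")
  n <- length(weights)
  if (n < 1L) stop("a scaffold configuration needs at least one position")
  K <- vapply(weights, length, integer(1))
  if (any(K < 1L)) stop("every position needs at least one sidechain")
  if (!all(vapply(probs, length, integer(1)) == K))
    stop("`weights` and `probs` disagree on sidechain counts")
  h <- max(K)
  W <- matrix(0, n, h)
  P <- matrix(0, n, h)
  for (s in seq_len(n)) {
    W[s, seq_len(K[s])] <- as.numeric(weights[[s]])
    P[s, seq_len(K[s])] <- as.numeric(probs[[s]])
  }
  if (!is.null(sidechain_labels)) {
    if (length(sidechain_labels) != n ||
        !all(vapply(sidechain_labels, length, integer(1)) == K))
      stop("`sidechain_labels` must mirror the shape of `weights`")
  }
  structure(
    list(scaffold_id = as.character(scaffold_id),
         config_index = as.integer(config_index),
         n = n, K = as.integer(K), h = as.integer(h), W = W, P = P,
         sidechain_labels = sidechain_labels),
    class = "scaffold_config")
}

#' @export
print.scaffold_config <- function(x, ...) {
  cat(sprintf("<scaffold_config> %s [config %d]: n = %d positions, h = %d, K = %s\n",
              x$scaffold_id, x$config_index, x$n, x$h,
              paste(x$K, collapse = ",")))
  invisible(x)
}

#' Validate a scaffold configuration
#'
#' Checks the structural invariants of a configuration and returns a
#' character vector of human-readable violations (empty when the
#' configuration is valid).  Violations are reported, not raised, so a
#' batch run can log and skip bad records.
#'
#' Checked rules: `h = max(K)`; every mass non-negative; every probability
#' in `[0, 1]`; and the padding rule — for `j >= k_s` both `p[s, j]` and
#' `w[s, j]` must be zero (those cells are not sidechains).
#'
#' @param cfg a `scaffold_config` (or a bare list with the same fields).
#' @return character vector of violation descriptions; `character(0)` when
#'   all invariants hold.
#' @examples
#' cfg <- scaffold_config(list(c(1, 2)), list(c(0.5, 0.5)))
#' validate_scaffold(cfg)  # character(0)
#' @export
validate_scaffold <- function(cfg) {
  out <- character(0)
  n <- cfg$n; K <- cfg$K; h <- cfg$h; W <- cfg$W; P <- cfg$P
  if (length(K) != n)
    out <- c(out, sprintf("K has length %d but n = %d", length(K), n))
  if (h != max(K))
    out <- c(out, sprintf("h = %d but max(K) = %d", h, max(K)))
  if (!all(dim(W) == c(n, h)) || !all(dim(P) == c(n, h))) {
    out <- c(out, "W and P must both be n x h matrices")
    return(out)  # shape is broken; cellwise checks would be meaningless
  }
  for (s in seq_len(n)) {
    for (j in seq_len(h)) {
      w <- W[s, j]; p <- P[s, j]
      if (w < 0)
        out <- c(out, sprintf(
          "position %d sidechain %d: negative mass %g", s - 1L, j - 1L, w))
      if (p < 0 || p > 1)
        out <- c(out, sprintf(
          "position %d sidechain %d: probability %g outside [0,1]",
          s - 1L, j - 1L, p))
      if (j > K[s] && (p != 0 || w != 0))
        out <- c(out, sprintf(
          "position %d sidechain %d: padding rule violated (j >= k_s requires p = w = 0, got p = %g, w = %g)",
          s - 1L, j - 1L, p, w))
    }
  }
  out
}

#' Construct a mass peak
#'
#' A molecular-weight window `[w_min, w_max]` in Da derived from an LC-MS
#' peak, together with `D`, the number of mass decimal digits the
#' instrument resolution supports.  `D` controls the integerization of all
#' masses (multiplication by `10^D`) and thereby the size of the dynamic
#' programming table.
#'
#' @param w_min,w_max window bounds in Da, `w_max >= w_min >= 0`.
#' @param D non-negative integer count of decimal digits.
#' @return an object of class `mass_peak`.
#' @export
mass_peak <- function(w_min, w_max, D = 5L) {
  if (w_max < w_min) stop("invalid window: w_max < w_min")
  if (w_min < 0) stop("invalid window: w_min < 0")
  D <- as.integer(D)
  if (D < 0L) stop("D must be a non-negative integer")
  structure(list(w_min = as.numeric(w_min), w_max = as.numeric(w_max), D = D),
            class = "mass_peak")
}

#' @export
print.mass_peak <- function(x, ...) {
  cat(sprintf("<mass_peak> [%.*f, %.*f] Da, D = %d\n",
              x$D, x$w_min, x$D, x$w_max, x$D))
  invisible(x)
}

# Round to nearest integer, ties away from zero.  base::round() rounds
# half to even, which would not match the convention that inputs carrying
# at most D decimals integerize exactly.
int_round <- function(x) floor(x + 0.5)

#' Integerize a CSCCP instance
#'
#' Converts the mass window and the sidechain mass matrix to integers by
#' multiplying by `10^D` and rounding to nearest (ties away from zero).
#' The dynamic program indexes its table by these integer masses.  On
#' conforming inputs — masses written with at most `D` decimals — the
#' conversion is exact; a warning is recorded for any mass whose scaled
#' value is more than `1e-6` away from an integer, since such a mass loses
#' precision at this `D`.
#'
#' @param peak a `mass_peak`.
#' @param cfg a `scaffold_config`.
#' @return an object of class `csccp_problem`: `w_prime_min`, `w_prime_max`
#'   (integer window bounds in units of `10^-D` Da), `W_prime` (`n x h`
#'   integer-valued mass matrix), `D`, and `residual_warnings`, a character
#'   vector of the masses that did not scale exactly.
#' @examples
#' cfg  <- scaffold_config(list(c(1.5, 2)), list(c(0.5, 0.5)))
#' prob <- integerize(mass_peak(0, 4, D = 1), cfg)
#' prob$W_prime
#' @export
integerize <- function(peak, cfg) {
  if (peak$w_max < peak$w_min) stop("invalid window: w_max < w_min")
  scale <- 10^peak$D
  scaled <- cfg$W * scale
  W_prime <- int_round(scaled)
  resid <- abs(scaled - W_prime)
  warn <- character(0)
  bad <- which(resid > 1e-6, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    warn <- sprintf(
      "mass %g at position %d sidechain %d is not exact at D = %d (residual %.3g)",
      cfg$W[bad], bad[, 1] - 1L, bad[, 2] - 1L, peak$D, resid[bad])
    warning(sprintf(
      "%d sidechain mass(es) carry more than D = %d decimals; integerization rounds them",
      length(warn), peak$D))
  }
  structure(
    list(w_prime_min = int_round(peak$w_min * scale),
         w_prime_max = int_round(peak$w_max * scale),
         W_prime = W_prime, D = peak$D,
         residual_warnings = warn),
    class = "csccp_problem")
}

#' Evaluate an explicit compound
#'
#' For a selection of one sidechain per position, returns the compound's
#' total integerized sidechain mass `g(x) = sum_s w'[s, x_s]` and its
#' probability `f(x) = prod_s p[s, x_s]`.  Both are order-independent in
#' the positions; the probability is computed as a plain double-precision
#' product in the linear domain.
#'
#' @param cfg a `scaffold_config`.
#' @param selection integer vector of `n` zero-based sidechain indices,
#'   `0 <= selection[s] < k_s`.
#' @param D decimal digits used for integerization (default 0 returns the
#'   raw rounded masses).
#' @return list with `total_mass_int` (units of `10^-D` Da) and
#'   `probability`.
#' @examples
#' cfg <- scaffold_config(list(c(1, 2), c(1, 2)),
#'                        list(c(0.9, 0.1), c(0.8, 0.2)))
#' evaluate_compound(cfg, c(0, 1))  # mass 3, probability 0.18
#' @export
evaluate_compound <- function(cfg, selection, D = 0L) {
  selection <- as.integer(selection)
  if (length(selection) != cfg$n)
    stop("selection must pick one sidechain per position")
  if (any(selection < 0L) || any(selection >= cfg$K))
    stop(sprintf("selection out of range at position(s) %s",
                 paste(which(selection < 0L | selection >= cfg$K) - 1L,
                       collapse = ", ")))
  idx <- cbind(seq_len(cfg$n), selection + 1L)
  list(total_mass_int = sum(int_round(cfg$W[idx] * 10^D)),
       probability = prod(cfg$P[idx]))
}
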