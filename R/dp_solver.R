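# Two-phase top-R dynamic program for the CSCCP.
#
# Phase one fills, position by position, the cost layers c_{s,w,r}: the
# r-th highest probability over all partial compounds on positions 0..s
# whose integer sidechain mass is exactly w.  Only two layers (C-, C+) are
# live at a time (rolling buffers).  Phase two collects the final layer's
# cells inside the integerized window, ranks them, and backtracks each
# through the per-position traceback records (k, r_prev).
#
# Why top-R per state suffices (proof sketch, also covers distinctness):
# ranks at a state hold pairwise distinct selections — two entries with
# different k differ at the current position, two with the same k and
# different r_prev extend distinct predecessor selections (induction).
# If a compound is within the global top R under the deterministic order
# (prob desc, then mass asc, then last-position-first index order), each
# of its prefixes is within the top R at its own (s, w) state: any prefix
# displaced below rank R is dominated by R prefixes at the same state
# whose identical suffix extensions dominate the compound under the same
# order.  The brute-force oracle sorts by exactly this order, so DP and
# enumeration agree selection by selection.

# deterministic candidate order shared by every ranking step:
# probability descending, then sidechain index k ascending, then
# predecessor rank ascending.  Candidate columns are laid out k-major
# (column = k * R + r_prev), so "first maximum" scans implement the rule.

#' Update one DP state
#'
#' Computes the top-`R` ranked probabilities and traceback records for a
#' single state `(s, w)` from the previous position's layer.  For each
#' sidechain `k` at position `s` and each predecessor rank `r`, the
#' candidate probability is `p[s, k] * C_minus[w - w'[s, k], r]`;
#' candidates reaching below mass zero or extending an invalid (zero
#' probability) predecessor are skipped.  Survivors are ranked by
#' probability descending, ties broken by smaller `k`, then smaller
#' predecessor rank.
#'
#' @param cfg a `scaffold_config`.
#' @param problem a `csccp_problem` from [integerize()].
#' @param C_minus `(w_prime_max + 1) x R` matrix: the previous layer
#'   (`c_{s-1,.,.}`), or the base layer when `s = 0` (probability 1 at
#'   `w = 0`, rank 0; zero elsewhere).
#' @param s zero-based position index.
#' @param w integer mass, `0 <= w <= w_prime_max`.
#' @param R number of ranks to keep.
#' @return list with `prob` (numeric length `R`, zeros marking invalid
#'   ranks), `k` and `r_prev` (integer length `R`, zero-based, `NA` at
#'   invalid ranks).
#' @export
state_update <- function(cfg, problem, C_minus, s, w, R) {
  stopifnot(s >= 0, s < cfg$n, w >= 0, w <= problem$w_prime_max, R >= 1)
  ks <- cfg$K[s + 1L]
  cand_p <- numeric(0); cand_k <- integer(0); cand_r <- integer(0)
  for (k in 0:(ks - 1L)) {
    wk <- problem$W_prime[s + 1L, k + 1L]
    if (w - wk < 0) next
    p <- cfg$P[s + 1L, k + 1L]
    for (r in 0:(R - 1L)) {
      c_prev <- C_minus[w - wk + 1L, r + 1L]
      if (c_prev <= 0) next
      cand_p <- c(cand_p, p * c_prev)
      cand_k <- c(cand_k, k)
      cand_r <- c(cand_r, r)
    }
  }
  keep <- cand_p > 0
  cand_p <- cand_p[keep]; cand_k <- cand_k[keep]; cand_r <- cand_r[keep]
  prob <- numeric(R)
  kk <- rep(NA_integer_, R); rr <- rep(NA_integer_, R)
  if (length(cand_p) > 0) {
    o <- order(-cand_p, cand_k, cand_r)
    take <- seq_len(min(R, length(o)))
    prob[take] <- cand_p[o[take]]
    kk[take] <- cand_k[o[take]]
    rr[take] <- cand_r[o[take]]
  }
  list(prob = prob, k = kk, r_prev = rr)
}

#' Run the forward pass of the CSCCP dynamic program
#'
#' Fills the cost layers for positions `0 .. n-1` over integer masses
#' `0 .. w_prime_max` and `R` ranks, retaining per-position traceback.
#' The base (virtual) layer holds probability 1 at mass 0, rank 0, and is
#' invalid everywhere else.  After each position the current layer becomes
#' the previous one and older cost layers are discarded (rolling buffers),
#' unless `keep_all_C = TRUE` retains them for inspection.
#'
#' Two engines produce bit-identical tables: `"vectorized"` updates all
#' masses of a position at once (the serial analogue of the accelerator
#' design that assigns one thread per mass value) and is the default;
#' `"sequential"` loops over states calling [state_update()] and serves as
#' the reference path.
#'
#' Traceback is stored either as raw per-position `(k, r_prev)` layers
#' (`traceback = "raw"`) or packed into two 32-bit words per `(w, r)` cell
#' (`traceback = "packed"`, see [pack_traceback()]); the two modes yield
#' identical rankings.  Packed mode requires [check_compression_feasible()]
#' to pass.
#'
#' @param cfg a `scaffold_config`.
#' @param problem a `csccp_problem`.
#' @param R ranks to keep per state (default 3).
#' @param engine `"vectorized"` or `"sequential"`.
#' @param traceback `"raw"` or `"packed"`.
#' @param device optional [device_profile()]; when supplied, the instance
#'   is first classified with [classify_feasibility()] and refused if not
#'   feasible.  The constraint models a memory-limited accelerator and is
#'   advisory on a CPU: `force = TRUE` overrides it.
#' @param force logical; run even if the device model says infeasible.
#' @param keep_all_C retain every cost layer (diagnostics only).
#' @return an object of class `csccp_state`: the final layer `C_plus`, the
#'   penultimate `C_minus`, traceback storage, the layout parameters, and
#'   `stats` (counts of state updates and valid cells).
#' @export
dp_forward <- function(cfg, problem, R = 3L,
                       engine = c("vectorized", "sequential"),
                       traceback = c("raw", "packed"),
                       device = NULL, force = FALSE, keep_all_C = FALSE) {
  engine <- match.arg(engine)
  traceback <- match.arg(traceback)
  R <- as.integer(R)
  stopifnot(R >= 1L)
  if (!is.null(device) && !force) {
    verdict <- classify_feasibility(cfg, R, problem$D,
                                    problem$w_prime_max / 10^problem$D,
                                    device)
    if (verdict$category != "feasible")
      stop(sprintf("instance refused by device model: %s (use force = TRUE to override)",
                   verdict$category))
  }
  n <- cfg$n
  nw <- as.integer(problem$w_prime_max + 1)
  packed <- traceback == "packed"
  if (packed) {
    feas <- check_compression_feasible(cfg$K, R)
    if (!(feas$eq1_ok && feas$eq2_ok))
      stop("packed traceback infeasible: per-position fields exceed 32 bits")
    k_width <- bits_for_sidechain(cfg$K)
    k_offset <- c(0L, cumsum(k_width))[seq_len(n)]
    r_width <- bits_for_sidechain(R)
    r_offset <- (seq_len(n) - 1L) * r_width
    Kw_minus <- matrix(NA_real_, nw, R); Kw_minus[1L, 1L] <- 0
    Rw_minus <- matrix(NA_real_, nw, R); Rw_minus[1L, 1L] <- 0
  }
  C_minus <- matrix(0, nw, R)
  C_minus[1L, 1L] <- 1  # virtual layer s = -1: the empty selection, mass 0
  layers <- if (!packed) vector("list", n)
  C_history <- if (keep_all_C) list()
  # work counter: states updated at strictly positive mass.  The origin
  # column w = 0 only ever holds all-zero-mass selections and is excluded,
  # so the count scales exactly with w'_max = w_max * 10^D.
  updates <- 0

  for (s in seq_len(n)) {  # 1-based internally; position s-1 in DP terms
    ks <- cfg$K[s]
    if (engine == "vectorized") {
      m <- ks * R
      M <- matrix(0, nw, m)
      for (k in seq_len(ks)) {
        wk <- problem$W_prime[s, k]
        p <- cfg$P[s, k]
        if (p > 0 && wk < nw) {
          M[(wk + 1L):nw, ((k - 1L) * R + 1L):(k * R)] <-
            p * C_minus[seq_len(nw - wk), , drop = FALSE]
        }
      }
      C_plus <- matrix(0, nw, R)
      Lk <- matrix(NA_integer_, nw, R)
      Lr <- matrix(NA_integer_, nw, R)
      rows <- seq_len(nw)
      for (r in seq_len(R)) {
        j <- max.col(M, ties.method = "first")
        v <- M[cbind(rows, j)]
        ok <- v > 0
        if (!any(ok)) break
        C_plus[ok, r] <- v[ok]
        Lk[ok, r] <- (j[ok] - 1L) %/% R
        Lr[ok, r] <- (j[ok] - 1L) %% R
        M[cbind(which(ok), j[ok])] <- 0
      }
      updates <- updates + (nw - 1)
    } else {
      C_plus <- matrix(0, nw, R)
      Lk <- matrix(NA_integer_, nw, R)
      Lr <- matrix(NA_integer_, nw, R)
      for (w in 0:(nw - 1L)) {
        upd <- state_update(cfg, problem, C_minus, s - 1L, w, R)
        C_plus[w + 1L, ] <- upd$prob
        Lk[w + 1L, ] <- upd$k
        Lr[w + 1L, ] <- upd$r_prev
        if (w > 0L) updates <- updates + 1
      }
    }
    if (packed) {
      Kw_plus <- matrix(NA_real_, nw, R)
      Rw_plus <- matrix(NA_real_, nw, R)
      idx <- which(!is.na(Lk))
      if (length(idx) > 0) {
        w0 <- (idx - 1L) %% nw            # zero-based mass of the cell
        kv <- Lk[idx]; rv <- Lr[idx]
        wk <- problem$W_prime[cbind(s, kv + 1L)]
        pred <- cbind(w0 - wk + 1L, rv + 1L)
        Kw_plus[idx] <- Kw_minus[pred] + kv * 2^k_offset[s]
        Rw_plus[idx] <- Rw_minus[pred] + rv * 2^r_offset[s]
      }
      Kw_minus <- Kw_plus
      Rw_minus <- Rw_plus
    } else {
      layers[[s]] <- list(k = Lk, r_prev = Lr)
    }
    if (keep_all_C) C_history[[s]] <- C_plus
    C_prev <- C_minus
    C_minus <- C_plus
  }

  structure(
    list(C_plus = C_minus, C_minus = C_prev,
         layers = if (!packed) layers,
         k_words = if (packed) Kw_minus, r_words = if (packed) Rw_minus,
         traceback = traceback, engine = engine,
         n = n, K = cfg$K, R = R, problem = problem,
         C_history = C_history,
         stats = list(
           state_updates = updates,
           cells = as.numeric(n) * nw * R,
           valid_final_cells = sum(C_minus > 0))),
    class = "csccp_state")
}

#' @export
print.csccp_state <- function(x, ...) {
  cat(sprintf("<csccp_state> n = %d, R = %d, w'_max = %d, %s traceback, %d valid final cells\n",
              x$n, x$R, x$problem$w_prime_max, x$traceback,
              x$stats$valid_final_cells))
  invisible(x)
}

#' Rank the final DP layer inside the mass window
#'
#' Collects every valid cell `(w, r)` of the final cost layer with
#' `w_prime_min <= w <= w_prime_max`, sorts by probability descending
#' (ties: smaller mass, then smaller rank first) and returns at most `R`.
#'
#' @param table a `csccp_state` from [dp_forward()].
#' @param problem the `csccp_problem` (supplies the window bounds).
#' @param R maximum number of results.
#' @return data frame with zero-based columns `w` (integer mass), `r`
#'   (rank within its state) and `prob`; zero rows when no compound falls
#'   in the window.
#' @export
finalize_top_r <- function(table, problem, R = table$R) {
  C <- table$C_plus
  lo <- problem$w_prime_min; hi <- problem$w_prime_max
  empty <- data.frame(w = integer(0), r = integer(0), prob = numeric(0))
  if (lo > hi) return(empty)
  sub <- C[(lo + 1L):(hi + 1L), , drop = FALSE]
  idx <- which(sub > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  w <- lo + idx[, 1L] - 1L
  r <- idx[, 2L] - 1L
  p <- sub[idx]
  o <- order(-p, w, r)
  take <- o[seq_len(min(R, length(o)))]
  data.frame(w = as.integer(w[take]), r = as.integer(r[take]),
             prob = p[take])
}

#' Backtrack one final cell to its compound
#'
#' Recovers the sidechain selection behind a valid final cell `(w, r)`.
#' With raw traceback the chain `(k, r_prev)` is followed from position
#' `n-1` down to 0, subtracting each chosen sidechain's integer mass; the
#' walk must terminate at mass 0.  With packed traceback the full
#' selection is decoded directly from the cell's 32-bit index word.
#'
#' @param table a `csccp_state`.
#' @param w integer mass of the cell (zero-based).
#' @param r rank of the cell (zero-based).
#' @return integer vector of `n` zero-based sidechain indices.
#' @export
backtrack <- function(table, w, r) {
  if (table$C_plus[w + 1L, r + 1L] <= 0)
    stop(sprintf("cell (w = %d, r = %d) is invalid; nothing to backtrack", w, r))
  n <- table$n
  if (table$traceback == "packed") {
    rec <- unpack_traceback(
      list(k_word = table$k_words[w + 1L, r + 1L],
           r_word = table$r_words[w + 1L, r + 1L]),
      table$K, table$R)
    return(rec$k)
  }
  sel <- integer(n)
  for (s in n:1) {
    k <- table$layers[[s]]$k[w + 1L, r + 1L]
    r_prev <- table$layers[[s]]$r_prev[w + 1L, r + 1L]
    if (is.na(k))
      stop("corrupt traceback: invalid cell reached during backtrack")
    sel[s] <- k
    w <- w - table$problem$W_prime[s, k + 1L]
    if (w < 0) stop("corrupt traceback: mass underflow during backtrack")
    r <- r_prev
  }
  if (w != 0) stop("corrupt traceback: nonzero terminal mass")
  sel
}

#' Solve one CSCCP instance
#'
#' Finds the `R` most probable compounds generable on the scaffold
#' configuration whose total sidechain mass lies in the peak window:
#' integerizes the instance, runs the forward DP, ranks the final layer
#' inside the window and backtracks each result.  Fewer than `R` compounds
#' are returned when fewer exist; all returned probabilities are positive
#' and all masses lie in the window.
#'
#' @param cfg a `scaffold_config`.
#' @param peak a `mass_peak`.
#' @param R number of compounds to report (default 3).
#' @param ... passed to [dp_forward()] (`engine`, `traceback`, `device`,
#'   `force`).
#' @return data frame of class `csccp_result` with columns `rank`
#'   (zero-based), `probability`, `total_mass_int` (units `10^-D` Da),
#'   `total_mass` (Da) and `selection` (list column of zero-based index
#'   vectors).
#' @examples
#' cfg <- scaffold_config(list(c(1, 2), c(1, 2)),
#'                        list(c(0.9, 0.1), c(0.8, 0.2)))
#' solve_csccp(cfg, mass_peak(3, 3, D = 0), R = 3)
#' @export
solve_csccp <- function(cfg, peak, R = 3L, ...) {
  bad <- validate_scaffold(cfg)
  if (length(bad) > 0)
    stop(paste(c("invalid scaffold configuration:", bad), collapse = "\n  "))
  problem <- integerize(peak, cfg)
  table <- dp_forward(cfg, problem, R = R, ...)
  top <- finalize_top_r(table, problem, R)
  sel <- lapply(seq_len(nrow(top)),
                function(i) backtrack(table, top$w[i], top$r[i]))
  out <- data.frame(rank = seq_len(nrow(top)) - 1L,
                    probability = top$prob,
                    total_mass_int = top$w)
  out$total_mass <- out$total_mass_int / 10^peak$D
  out$selection <- sel
  class(out) <- c("csccp_result", "data.frame")
  out
}

#' Solve one CSCCP instance by exhaustive enumeration
#'
#' Verification oracle: enumerates every selection in
#' `[0, k_0 - 1] x ... x [0, k_{n-1} - 1]`, evaluates mass and probability
#' exactly as [evaluate_compound()] does, filters by the integerized
#' window and sorts by the solver's deterministic order — probability
#' descending, then total mass ascending, then sidechain indices compared
#' from the last position to the first.  Independent of every DP code
#' path.
#'
#' @param cfg a `scaffold_config`.
#' @param peak a `mass_peak`.
#' @param R number of compounds to report.
#' @param cap refuse instances with more than `cap` selections (default
#'   `1e6`).
#' @return data frame shaped like [solve_csccp()]'s result.
#' @export
brute_force_solve <- function(cfg, peak, R = 3L, cap = 1e6) {
  n_total <- prod(cfg$K)
  if (n_total > cap)
    stop(sprintf("instance has %g selections, above the enumeration cap %g",
                 n_total, cap))
  problem <- integerize(peak, cfg)
  grid <- do.call(expand.grid,
                  c(lapply(cfg$K, function(k) 0:(k - 1L)),
                    KEEP.OUT.ATTRS = FALSE))
  sel_mat <- as.matrix(grid)
  mass <- numeric(n_total)
  prob <- rep(1, n_total)
  for (s in seq_len(cfg$n)) {
    mass <- mass + problem$W_prime[s, sel_mat[, s] + 1L]
    prob <- prob * cfg$P[s, sel_mat[, s] + 1L]
  }
  keep <- prob > 0 & mass >= problem$w_prime_min & mass <= problem$w_prime_max
  sel_mat <- sel_mat[keep, , drop = FALSE]
  mass <- mass[keep]; prob <- prob[keep]
  # order shared with the DP: ties on (prob, mass) resolved by comparing
  # selection indices last position first (the order the DP's per-state
  # k-ascending / r_prev-ascending rule induces)
  key_cols <- lapply(rev(seq_len(cfg$n)), function(s) sel_mat[, s])
  o <- do.call(order, c(list(-prob, mass), key_cols))
  take <- o[seq_len(min(R, length(o)))]
  out <- data.frame(rank = seq_along(take) - 1L,
                    probability = prob[take],
                    total_mass_int = mass[take])
  out$total_mass <- out$total_mass_int / 10^peak$D
  out$selection <- lapply(take, function(i) as.integer(sel_mat[i, ]))
  class(out) <- c("csccp_result", "data.frame")
  out
}

#' @export
print.csccp_result <- function(x, ...) {
  cat(sprintf("<csccp_result> %d compound(s)\n", nrow(x)))
  if (nrow(x) > 0) {
    show <- data.frame(rank = x$rank,
                       probability = signif(x$probability, 6),
                       total_mass = x$total_mass,
                       selection = vapply(x$selection, paste,
                                          character(1), collapse = ","))
    print.data.frame(show, row.names = FALSE)
  }
  invisible(x)
}
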