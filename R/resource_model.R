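# Device resource accounting and feasibility classification.
#
# The DP was designed for a memory-limited accelerator: the two rolling
# cost buffers and the packed traceback each occupy 8 * w'_max * R bytes
# of global memory (w'_max = w_max * 10^D), 16 * R * w_max * 10^D in
# total, and the per-block ranking buffers live in a small shared memory.
# An instance is feasible when that footprint fits the device and the
# traceback chain packs into two 32-bit words.  On a CPU these limits are
# advisory — the solver can be forced past them — but the model is kept
# so that feasibility statistics over a scaffold database can be
# reproduced.
#
# The default profile models an NVIDIA Tesla K40c-class card.  Its global
# memory is taken as 11 440 MiB: the derived maximum-target-weight figures
# are consistent with that value (a nearby figure of 11 439 MB also
# circulates; the 1 MiB difference does not change any classification at
# the parameter scales of interest).

#' Describe a compute device
#'
#' @param global_memory_bytes device global memory (default 11 440 MiB, a
#'   Tesla K40c-class card).
#' @param shared_memory_bytes per-block shared memory (default 49 152 B =
#'   48 KiB).
#' @param max_threads_hw hardware cap on threads per block (default 1024).
#' @return object of class `device_profile`.
#' @export
device_profile <- function(global_memory_bytes = 11440 * 2^20,
                           shared_memory_bytes = 49152,
                           max_threads_hw = 1024L) {
  stopifnot(global_memory_bytes > 0, shared_memory_bytes > 0,
            max_threads_hw >= 1)
  structure(list(global_memory_bytes = global_memory_bytes,
                 shared_memory_bytes = shared_memory_bytes,
                 max_threads_hw = as.integer(max_threads_hw)),
            class = "device_profile")
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("<device_profile> %.0f MiB global, %d B shared, <= %d threads/block\n",
              x$global_memory_bytes / 2^20, x$shared_memory_bytes,
              x$max_threads_hw))
  invisible(x)
}

#' Global-memory footprint of the DP state
#'
#' The rolling cost buffers and the packed traceback words together need
#' `16 * R * w_max * 10^D` bytes of global memory.
#'
#' @param R ranks per state.
#' @param D mass decimal digits.
#' @param w_max mass cap in Da.
#' @return byte count (double).
#' @examples
#' state_memory_bytes(3, 5, 500) / 2^30   # 2.24 GiB
#' state_memory_bytes(10, 5, 500) / 2^30  # 7.45 GiB
#' @export
state_memory_bytes <- function(R, D, w_max) {
  stopifnot(R >= 0, D >= 0, w_max >= 0)
  16 * R * w_max * 10^D
}

#' Memory saved by rolling cost buffers
#'
#' Keeping only the previous and current cost layers instead of all `n`
#' saves `100 * (1 - 2/n)` percent of the cost-matrix memory.
#'
#' @param n positions, `n >= 2`.
#' @return percentage.
#' @examples
#' c_matrix_saving_fraction(10)  # 80
#' @export
c_matrix_saving_fraction <- function(n) {
  if (n < 2) stop("rolling buffers need n >= 2")
  100 * (1 - 2 / n)
}

#' Maximum target weight a device can handle
#'
#' The largest `w_max` (Da) whose DP state fits the device's global
#' memory: `floor(global_memory_bytes / (16 * R * 10^D))`.
#'
#' @param R ranks per state; @param D mass decimal digits.
#' @param device a [device_profile()].
#' @return integer number of Da.
#' @examples
#' max_target_weight(3, 5)   # 2499
#' max_target_weight(10, 5)  # 749
#' @export
max_target_weight <- function(R, D, device = device_profile()) {
  stopifnot(R >= 1, D >= 0)
  floor(device$global_memory_bytes / (16 * R * 10^D))
}

# largest power of two <= x (x >= 1)
largest_pow2_le <- function(x) {
  b <- 0L
  x <- floor(x)
  while (x > 1) { x <- x %/% 2; b <- b + 1L }
  2^b
}

#' Maximum threads per block for the ranking buffers
#'
#' Each thread ranks one mass value and needs an `h * R`-entry update
#' buffer at 8 bytes per entry in the block's shared memory.  The bound is
#' the largest power of two `T` with `T * h * R * 8 <=
#' shared_memory_bytes`, capped at the hardware thread limit.  Returns 0
#' when not even one thread's buffer fits (the instance cannot be
#' scheduled).
#'
#' @param R ranks per state; @param h maximum sidechains per position.
#' @param device a [device_profile()].
#' @return a power of two (or 0 when infeasible).
#' @examples
#' max_threads_per_block(3, 5)   # 256
#' max_threads_per_block(10, 10) # 32
#' @export
max_threads_per_block <- function(R, h, device = device_profile()) {
  stopifnot(R >= 1, h >= 1)
  cap <- device$shared_memory_bytes / (8 * h * R)
  if (cap < 1) return(0)
  min(largest_pow2_le(cap), device$max_threads_hw)
}

#' Classify the feasibility of one instance
#'
#' An instance `(cfg, R, D, w_max)` is feasible on a device when its DP
#' state fits the global memory and its traceback chain packs into two
#' 32-bit words; otherwise it is classified as
#' `insufficient_global_memory`, `compression_impossible`, or
#' `both_problems`.
#'
#' @param cfg a `scaffold_config`.
#' @param R ranks per state; @param D decimal digits; @param w_max mass
#'   cap in Da.
#' @param device a [device_profile()].
#' @return object of class `feasibility_verdict`: `category` plus a
#'   `detail` list with the violated quantities (`required_bytes`,
#'   `global_memory_bytes`, `k_bits_total`, `r_bits_total`, `eq1_ok`,
#'   `eq2_ok`).
#' @export
classify_feasibility <- function(cfg, R = 3L, D = 5L, w_max = 500,
                                 device = device_profile()) {
  required <- state_memory_bytes(R, D, w_max)
  mem_bad <- required > device$global_memory_bytes
  comp <- check_compression_feasible(cfg$K, R)
  comp_bad <- !(comp$eq1_ok && comp$eq2_ok)
  category <- if (mem_bad && comp_bad) "both_problems"
  else if (mem_bad) "insufficient_global_memory"
  else if (comp_bad) "compression_impossible"
  else "feasible"
  structure(list(category = category,
                 detail = list(required_bytes = required,
                               global_memory_bytes = device$global_memory_bytes,
                               k_bits_total = comp$k_bits_total,
                               r_bits_total = comp$r_bits_total,
                               eq1_ok = comp$eq1_ok, eq2_ok = comp$eq2_ok)),
            class = "feasibility_verdict")
}

#' @export
print.feasibility_verdict <- function(x, ...) {
  cat(sprintf("<feasibility_verdict> %s (needs %.3g B of %.3g B; %d index bits, %d rank bits)\n",
              x$category, x$detail$required_bytes,
              x$detail$global_memory_bytes,
              x$detail$k_bits_total, x$detail$r_bits_total))
  invisible(x)
}

#' Feasibility statistics over a configuration set
#'
#' Classifies every configuration at each requested `D` and tabulates the
#' share of feasible cases and the counts per failure category — the
#' database-level view of which scaffolds a device can process.
#'
#' @param configurations list of `scaffold_config` objects.
#' @param R ranks per state; @param w_max mass cap in Da.
#' @param D_values integer vector of decimal-digit settings to scan.
#' @param device a [device_profile()].
#' @return data frame with one row per `D`: `D`, `n_total`, `n_feasible`,
#'   `pct_feasible` (two decimals), and counts
#'   `insufficient_global_memory`, `compression_impossible`,
#'   `both_problems`, `n_infeasible`.
#' @export
feasibility_report <- function(configurations, R = 3L, w_max = 500,
                               D_values = 0:7, device = device_profile()) {
  if (length(configurations) < 1L) stop("need at least one configuration")
  cats <- c("feasible", "insufficient_global_memory",
            "compression_impossible", "both_problems")
  rows <- lapply(D_values, function(D) {
    verdicts <- vapply(configurations, function(cfg)
      classify_feasibility(cfg, R, D, w_max, device)$category, character(1))
    counts <- table(factor(verdicts, levels = cats))
    total <- length(verdicts)
    data.frame(D = D, n_total = total,
               n_feasible = as.integer(counts[["feasible"]]),
               pct_feasible = round(100 * counts[["feasible"]] / total, 2),
               insufficient_global_memory =
                 as.integer(counts[["insufficient_global_memory"]]),
               compression_impossible =
                 as.integer(counts[["compression_impossible"]]),
               both_problems = as.integer(counts[["both_problems"]]),
               n_infeasible = total - as.integer(counts[["feasible"]]))
  })
  do.call(rbind, rows)
}
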