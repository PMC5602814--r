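# Deterministic synthetic scaffolds and peaks.
#
# The generator emulates the structure of a natural-product scaffold
# database: a handful of substitutable positions, a few candidate
# sidechains per position (database-wide the typical maximum per scaffold
# is about four), sidechain masses written with a fixed number of decimal
# digits so integerization is exact by construction, and per-position
# attachment probabilities.  It makes every module testable offline; it
# does not emulate real sidechain chemistry or empirical mass
# distributions.

#' Describe a synthetic-scaffold generator
#'
#' Defaults model a small natural-product-like scaffold: 2-6 substitutable
#' positions, 1-4 candidate sidechains per position (so the typical `h`
#' matches the ~4 seen across real scaffold databases), sidechain masses
#' up to 45 Da written with two decimals (average total sidechain mass
#' then sits near the ~90 Da typical of such databases), and per-position
#' probabilities normalized to sum to one, the natural reading of
#' attachment frequencies.  `prob_mode = "uniform01"` instead leaves raw
#' uniform draws, exercising the weaker contract that probabilities are
#' only bounded by `[0, 1]`.
#'
#' @param n_range integer interval for the number of positions.
#' @param k_range integer interval for per-position sidechain counts.
#' @param weight_range mass interval in Da.
#' @param digits decimal digits masses are quantized to.
#' @param prob_mode `"normalized"` or `"uniform01"`.
#' @param seed integer seed or `NULL`.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_range = c(2L, 6L), k_range = c(1L, 4L),
                           weight_range = c(0, 45), digits = 2L,
                           prob_mode = c("normalized", "uniform01"),
                           seed = NULL) {
  prob_mode <- match.arg(prob_mode)
  stopifnot(length(n_range) == 2, n_range[1] >= 1, n_range[2] >= n_range[1],
            length(k_range) == 2, k_range[1] >= 1, k_range[2] >= k_range[1],
            length(weight_range) == 2, weight_range[1] >= 0,
            weight_range[2] >= weight_range[1], digits >= 0)
  structure(list(n_range = as.integer(n_range), k_range = as.integer(k_range),
                 weight_range = as.numeric(weight_range),
                 digits = as.integer(digits), prob_mode = prob_mode,
                 seed = seed),
            class = "generator_spec")
}

sample_interval <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

#' Generate one synthetic scaffold configuration
#'
#' Draws the number of positions, per-position sidechain counts, masses
#' (uniform in `weight_range`, rounded to `digits` decimals so
#' integerization at `D >= digits` is exact) and probabilities per
#' `prob_mode`.  The output always passes [validate_scaffold()], and the
#' same seed always yields the same configuration.
#'
#' @param spec a [generator_spec()].
#' @param seed overrides `spec$seed`; when neither is given the current
#'   RNG state is used.
#' @return a `scaffold_config`.
#' @examples
#' cfg <- generate_scaffold(generator_spec(seed = 1))
#' validate_scaffold(cfg)
#' @export
generate_scaffold <- function(spec = generator_spec(), seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- sample_interval(spec$n_range)
  K <- vapply(seq_len(n), function(s) sample_interval(spec$k_range),
              integer(1))
  weights <- lapply(K, function(k)
    round(stats::runif(k, spec$weight_range[1], spec$weight_range[2]),
          spec$digits))
  probs <- lapply(K, function(k) {
    p <- stats::runif(k)
    if (spec$prob_mode == "normalized") p / sum(p) else p
  })
  scaffold_config(weights, probs,
                  scaffold_id = sprintf("SYN-%s",
                                        if (is.null(seed)) "rng" else seed),
                  config_index = 0L)
}

#' Generate a mass peak guaranteed to match a configuration
#'
#' Picks a random selection on the configuration, takes its total
#' sidechain mass, and opens a window of a random half-width (quantized
#' to the generator's decimal digits) around it, clipped at zero.  By
#' construction at least one compound lies in the window, so every
#' generated `(cfg, peak)` pair is solvable.
#'
#' @param cfg a `scaffold_config`.
#' @param spec the [generator_spec()] (supplies `digits`).
#' @param half_width_range interval in Da for the random half-width.
#' @param seed optional seed; default uses the current RNG state (so a
#'   scaffold-then-peak sequence is reproducible from one upstream seed).
#' @return a `mass_peak` with `D = spec$digits`.
#' @export
generate_peak_for <- function(cfg, spec = generator_spec(),
                              half_width_range = c(0, 5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sel <- vapply(cfg$K, function(k) sample.int(k, 1L) - 1L, integer(1))
  mass <- sum(cfg$W[cbind(seq_len(cfg$n), sel + 1L)])
  hw <- round(stats::runif(1, half_width_range[1], half_width_range[2]),
              spec$digits)
  mass_peak(max(0, round(mass - hw, spec$digits)),
            round(mass + hw, spec$digits), D = spec$digits)
}
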