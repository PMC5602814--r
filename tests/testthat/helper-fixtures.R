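# Shared fixtures: the two-position running instance and the seeded
# random-instance factory used by the oracle-equivalence suites.

# two positions, masses {1,2} each, probabilities (0.9, 0.1) / (0.8, 0.2);
# the four compounds have (mass, prob) = (2, .72), (3, .18), (3, .08), (4, .02)
running_cfg <- function() {
  scaffold_config(list(c(1, 2), c(1, 2)),
                  list(c(0.9, 0.1), c(0.8, 0.2)))
}

# one seeded random (cfg, peak, R) instance; small enough for enumeration
oracle_instance <- function(i) {
  gspec <- generator_spec(
    n_range = c(1, 6), k_range = c(1, 5),
    weight_range = c(0, 15), digits = i %% 3, seed = i,
    prob_mode = if (i %% 4 == 0) "uniform01" else "normalized")
  cfg <- generate_scaffold(gspec)
  list(cfg = cfg,
       peak = generate_peak_for(cfg, gspec),
       R = c(1L, 3L, 8L)[i %% 3 + 1])
}

# full structural equality of two result tables: same compounds in the
# same order, probabilities to 1e-12
expect_same_result <- function(a, b, tol = 1e-12) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$total_mass_int, b$total_mass_int)
  expect_identical(a$selection, b$selection)
  expect_equal(a$probability, b$probability, tolerance = tol)
}
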