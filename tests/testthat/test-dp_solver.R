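# base layer shared by the state_update examples
base_layer <- function(nw, R) {
  C <- matrix(0, nw, R)
  C[1, 1] <- 1
  C
}

test_that("state_update ranks candidates and marks unreachable ranks invalid", {
  cfg <- running_cfg()
  prob <- integerize(mass_peak(0, 4, D = 0), cfg)
  C0 <- base_layer(5, 2)

  # at w = 2 only the mass-2 sidechain reaches the origin
  upd <- state_update(cfg, prob, C0, s = 0, w = 2, R = 2)
  expect_equal(upd$prob, c(0.1, 0))
  expect_identical(upd$k, c(1L, NA_integer_))
  expect_identical(upd$r_prev, c(0L, NA_integer_))

  # no sidechain mass divides w = 3 from the base layer
  upd3 <- state_update(cfg, prob, C0, s = 0, w = 3, R = 2)
  expect_equal(upd3$prob, c(0, 0))
  expect_true(all(is.na(upd3$k)))

  # equal probabilities: the smaller sidechain index takes rank 0
  tie <- scaffold_config(list(c(1, 1)), list(c(0.4, 0.4)))
  ptie <- integerize(mass_peak(0, 1, D = 0), tie)
  updt <- state_update(tie, ptie, base_layer(2, 2), s = 0, w = 1, R = 2)
  expect_identical(updt$k, c(0L, 1L))
  expect_equal(updt$prob, c(0.4, 0.4))
})

test_that("dp_forward fills the final layer as enumeration predicts", {
  # single compound
  one <- scaffold_config(list(10), list(0.5))
  p1 <- integerize(mass_peak(0, 10, D = 0), one)
  t1 <- dp_forward(one, p1, R = 2)
  expect_equal(t1$stats$valid_final_cells, 1)
  expect_equal(t1$C_plus[11, 1], 0.5)

  # running example: rank-0 probs at w = 2, 3, 4 and rank-1 at w = 3
  cfg <- running_cfg()
  p <- integerize(mass_peak(0, 4, D = 0), cfg)
  tab <- dp_forward(cfg, p, R = 2)
  expect_equal(tab$C_plus[3, 1], 0.72)
  expect_equal(tab$C_plus[4, 1], 0.18)
  expect_equal(tab$C_plus[5, 1], 0.02)
  expect_equal(tab$C_plus[4, 2], 0.08)

  # zero-probability scaffold annihilates every cell
  dead <- scaffold_config(list(c(1, 2)), list(c(0, 0)))
  pd <- integerize(mass_peak(0, 2, D = 0), dead)
  expect_equal(dp_forward(dead, pd, R = 2)$stats$valid_final_cells, 0)
})

test_that("finalize_top_r collects window cells in deterministic order", {
  cfg <- running_cfg()
  p33 <- integerize(mass_peak(3, 3, D = 0), cfg)
  tab <- dp_forward(cfg, p33, R = 2)
  top <- finalize_top_r(tab, p33, R = 2)
  expect_equal(top$w, c(3L, 3L))
  expect_equal(top$r, c(0L, 1L))
  expect_equal(top$prob, c(0.18, 0.08))

  # empty window between reachable masses
  p59 <- integerize(mass_peak(5, 9, D = 0), cfg)
  expect_equal(nrow(finalize_top_r(dp_forward(cfg, p59, R = 2), p59)), 0)

  p24 <- integerize(mass_peak(2, 4, D = 0), cfg)
  top1 <- finalize_top_r(dp_forward(cfg, p24, R = 1), p24, R = 1)
  expect_equal(top1$w, 2L)
  expect_equal(top1$prob, 0.72)
})

test_that("backtrack recovers the selection behind each cell", {
  cfg <- running_cfg()
  p <- integerize(mass_peak(0, 4, D = 0), cfg)
  tab <- dp_forward(cfg, p, R = 2)
  expect_identical(backtrack(tab, 3, 0), c(0L, 1L))
  expect_identical(backtrack(tab, 3, 1), c(1L, 0L))
  expect_error(backtrack(tab, 1, 0), "invalid")

  one <- scaffold_config(list(10), list(0.5))
  p1 <- integerize(mass_peak(0, 10, D = 0), one)
  expect_identical(backtrack(dp_forward(one, p1, R = 1), 10, 0), 0L)
})

test_that("backtracked selections re-evaluate to their cell's mass and probability", {
  for (i in 1:15) {
    inst <- oracle_instance(i)
    prob <- integerize(inst$peak, inst$cfg)
    tab <- dp_forward(inst$cfg, prob, R = inst$R)
    top <- finalize_top_r(tab, prob, inst$R)
    for (j in seq_len(nrow(top))) {
      sel <- backtrack(tab, top$w[j], top$r[j])
      ev <- evaluate_compound(inst$cfg, sel, D = inst$peak$D)
      expect_equal(ev$total_mass_int, as.numeric(top$w[j]))
      expect_equal(ev$probability, top$prob[j], tolerance = 1e-12)
    }
  }
})

test_that("solve_csccp matches the worked enumeration", {
  cfg <- running_cfg()
  res <- solve_csccp(cfg, mass_peak(3, 3, D = 0), R = 3)
  expect_equal(nrow(res), 2)
  expect_identical(res$selection, list(c(0L, 1L), c(1L, 0L)))
  expect_equal(res$probability, c(0.18, 0.08))
  expect_equal(res$rank, c(0L, 1L))

  # R = 1 over the whole mass range returns the argmax compound
  res1 <- solve_csccp(cfg, mass_peak(0, 4, D = 0), R = 1)
  expect_identical(res1$selection, list(c(0L, 0L)))
  expect_equal(res1$probability, 0.72)
})

test_that("brute_force_solve enumerates, filters and caps", {
  cube <- scaffold_config(rep(list(c(0, 1)), 3),
                          rep(list(c(0.5, 0.5)), 3))
  res <- brute_force_solve(cube, mass_peak(0, 3, D = 0), R = 8)
  expect_equal(nrow(res), 8)
  expect_equal(res$probability, rep(0.125, 8))

  expect_equal(nrow(brute_force_solve(cube, mass_peak(5, 9, D = 0), R = 3)), 0)
  expect_error(brute_force_solve(cube, mass_peak(0, 3, D = 0), R = 3, cap = 7),
               "cap")
})

test_that("solver equals the brute-force oracle on seeded random instances", {
  for (i in 1:60) {
    inst <- oracle_instance(i)
    a <- solve_csccp(inst$cfg, inst$peak, R = inst$R)
    b <- brute_force_solve(inst$cfg, inst$peak, R = inst$R)
    expect_same_result(a, b)
    expect_gte(nrow(a), 1)  # peak construction guarantees a hit
  }
})

test_that("returned compounds satisfy rank order, window and completeness", {
  for (i in 61:80) {
    inst <- oracle_instance(i)
    res <- solve_csccp(inst$cfg, inst$peak, R = inst$R)
    prob <- integerize(inst$peak, inst$cfg)
    expect_true(all(diff(res$probability) <= 1e-15))
    expect_true(all(res$total_mass_int >= prob$w_prime_min &
                      res$total_mass_int <= prob$w_prime_max))
    expect_true(all(res$probability > 0))
    # completeness: nothing the oracle can enumerate in the window beats
    # the last returned rank
    full <- brute_force_solve(inst$cfg, inst$peak, R = .Machine$integer.max,
                              cap = 1e6)
    if (nrow(res) < inst$R) {
      expect_equal(nrow(full), nrow(res))
    } else {
      extra <- full$probability[-seq_len(nrow(res))]
      if (length(extra) > 0)
        expect_lte(max(extra), res$probability[nrow(res)] + 1e-15)
    }
  }
})

test_that("vectorized and sequential engines build identical tables", {
  for (i in c(3, 6, 9, 12)) {  # whole-Da instances: exact at D = 0
    inst <- oracle_instance(i)
    # cap table size so the R-level reference loop stays cheap
    peak <- mass_peak(inst$peak$w_min, inst$peak$w_max, D = 0)
    prob <- integerize(peak, inst$cfg)
    a <- dp_forward(inst$cfg, prob, R = inst$R, engine = "vectorized")
    b <- dp_forward(inst$cfg, prob, R = inst$R, engine = "sequential")
    expect_identical(a$C_plus, b$C_plus)
    expect_identical(a$layers, b$layers)
  }
})

test_that("rolling buffers and full layer retention give the same result", {
  cfg <- running_cfg()
  p <- integerize(mass_peak(0, 4, D = 0), cfg)
  roll <- dp_forward(cfg, p, R = 2)
  kept <- dp_forward(cfg, p, R = 2, keep_all_C = TRUE)
  expect_identical(roll$C_plus, kept$C_plus)
  expect_identical(kept$C_history[[cfg$n]], kept$C_plus)
  expect_length(kept$C_history, cfg$n)
})

test_that("the device model refuses infeasible instances unless forced", {
  cfg <- running_cfg()
  peak <- mass_peak(0, 4, D = 0)
  tiny <- device_profile(global_memory_bytes = 64)
  expect_error(solve_csccp(cfg, peak, R = 3, device = tiny), "refused")
  res <- solve_csccp(cfg, peak, R = 3, device = tiny, force = TRUE)
  expect_gte(nrow(res), 1)
})
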