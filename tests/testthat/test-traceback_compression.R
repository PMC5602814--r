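test_that("field widths follow the bit-length rule", {
  expect_identical(bits_for_sidechain(1), 1L)
  expect_identical(bits_for_sidechain(3), 2L)
  expect_identical(bits_for_sidechain(4), 3L)
  expect_identical(bits_for_sidechain(c(2, 7, 8, 31, 32)),
                   c(2L, 3L, 4L, 5L, 6L))
  expect_error(bits_for_sidechain(0), "positive")
})

test_that("compression feasibility implements both word constraints", {
  f <- check_compression_feasible(rep(4, 10), R = 3)
  expect_true(f$eq1_ok && f$eq2_ok)
  expect_identical(f$k_bits_total, 30L)
  expect_identical(f$r_bits_total, 20L)

  # 17 single-sidechain positions overflow the rank word at R = 3
  f2 <- check_compression_feasible(rep(1, 17), R = 3)
  expect_true(f2$eq1_ok)
  expect_false(f2$eq2_ok)
  expect_identical(f2$r_bits_total, 34L)

  f3 <- check_compression_feasible(1, R = 1)
  expect_true(f3$eq1_ok && f3$eq2_ok)
})

test_that("feasibility verdicts match independently computed bit sums", {
  # independent oracle: bit length via the binary expansion from intToBits
  bitlen <- function(x) max(which(as.integer(intToBits(as.integer(x))) == 1L))
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:20, 1)
    K <- sample(1:12, n, replace = TRUE)
    R <- sample(1:10, 1)
    f <- check_compression_feasible(K, R)
    expect_identical(f$eq1_ok, sum(vapply(K, bitlen, integer(1))) <= 32)
    expect_identical(f$eq2_ok, n * bitlen(R) <= 32)
  }
})

test_that("pack and unpack are mutual inverses on worked examples", {
  pt <- pack_traceback(k = 1, r_prev = 1, K = 2, R = 2)
  expect_equal(pt$k_word, 1)
  expect_equal(pt$r_word, 1)

  z <- pack_traceback(k = c(0, 0, 0), r_prev = c(0, 0, 0),
                      K = c(2, 3, 4), R = 3)
  expect_equal(z$k_word, 0)
  expect_equal(z$r_word, 0)
  expect_identical(unpack_traceback(list(k_word = 0, r_word = 0),
                                    K = c(2, 3, 4), R = 3),
                   list(k = c(0L, 0L, 0L), r_prev = c(0L, 0L, 0L)))

  # single-position layout: the word is the masked field itself
  expect_identical(unpack_traceback(list(k_word = 5, r_word = 2),
                                    K = 7, R = 4)$k, 5L)

  expect_error(pack_traceback(k = 4, r_prev = 0, K = 2, R = 2),
               "field width")
  expect_error(pack_traceback(k = 0, r_prev = 2, K = 2, R = 2),
               "field width")
  expect_error(pack_traceback(k = rep(0, 17), r_prev = rep(0, 17),
                              K = rep(1, 17), R = 3),
               "infeasible")
})

test_that("pack/unpack round-trips 1000 random record sequences", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(1:10, 1)
    repeat {  # draw layouts until the 32-bit constraints hold
      K <- sample(1:8, n, replace = TRUE)
      R <- sample(1:8, 1)
      f <- check_compression_feasible(K, R)
      if (f$eq1_ok && f$eq2_ok) break
    }
    k <- vapply(K, function(ks) sample.int(ks, 1) - 1L, integer(1))
    r_prev <- sample.int(R, n, replace = TRUE) - 1L
    pt <- pack_traceback(k, r_prev, K, R)
    expect_lte(pt$k_word, 2^32 - 1)
    expect_lte(pt$r_word, 2^32 - 1)
    rec <- unpack_traceback(pt, K, R)
    expect_identical(rec$k, as.integer(k))
    expect_identical(rec$r_prev, as.integer(r_prev))
  }
})

test_that("solver results are identical in raw and packed traceback modes", {
  for (i in 1:20) {
    inst <- oracle_instance(i)
    raw <- solve_csccp(inst$cfg, inst$peak, R = inst$R, traceback = "raw")
    packed <- solve_csccp(inst$cfg, inst$peak, R = inst$R,
                          traceback = "packed")
    expect_same_result(raw, packed)
  }
})

test_that("traceback byte accounting matches the closed forms", {
  expect_equal(uncompressed_traceback_bytes(10, 3, 1000) /
                 compressed_traceback_bytes(3, 1000), 10)
  expect_equal(traceback_saving_fraction(10), 90)
  expect_equal(traceback_saving_fraction(1), 0)
  expect_equal(compressed_traceback_bytes(3, 5e7), 1.2e9)
  expect_equal(uncompressed_traceback_bytes(1, 3, 100),
               compressed_traceback_bytes(3, 100))
})
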