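test_that("lottery constructor enforces the distribution invariants", {
  expect_error(lottery(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_error(lottery(c(1, 2), c(1.2, -0.2)), "\\[0, 1\\]")
  expect_error(lottery(Inf, 1), "finite")
  expect_error(lottery(numeric(0), numeric(0)), "length")
  # duplicate outcomes are merged, zero-probability outcomes dropped
  l <- lottery(c(5, 5, 9, 2), c(0.25, 0.25, 0.5, 0))
  expect_equal(l$outcomes, c(5, 9))
  expect_equal(l$probs, c(0.5, 0.5))
})

test_that("CPC-format expansion covers the degenerate and shaped cases", {
  # degenerate shape: B is the plain two-outcome gamble
  p <- make_obs(1)
  p$hb <- 90; p$p_hb <- 0.05; p$lb <- 12
  b <- expand_problem(p)$lot_b[[1]]
  expect_equal(b$outcomes, c(12, 90))
  expect_equal(b$probs, c(0.95, 0.05))
  # sure option A when p_ha = 1
  p$p_ha <- 1
  a <- expand_problem(p)$lot_a[[1]]
  expect_equal(a$outcomes, p$ha)
  expect_equal(a$probs, 1)
})

test_that("symmetric expansion spreads pHb binomially around Hb", {
  p <- make_obs(1)
  p$hb <- 20; p$p_hb <- 0.6; p$lb <- 1
  p$lot_shape_b <- "symmetric"; p$lot_num_b <- 3L
  b <- expand_problem(p)$lot_b[[1]]
  high <- setdiff(b$outcomes, 1)
  expect_length(high, 3)
  expect_equal(sort(high), c(19, 20, 21))
  # summation oracle: the high branch carries exactly pHb, total mass 1
  expect_equal(sum(b$probs[b$outcomes != 1]), 0.6, tolerance = 1e-12)
  expect_equal(sum(b$probs), 1, tolerance = 1e-12)
  # binomial weights on the branch
  expect_equal(b$probs[b$outcomes %in% high], 0.6 * dbinom(0:2, 2, 0.5))
})

test_that("all lot-shape expansions preserve the conditional mean Hb", {
  cases <- tidyr::expand_grid(
    shape = c("symmetric", "right_skewed", "left_skewed"),
    num = c(3L, 5L, 7L)
  )
  for (i in seq_len(nrow(cases))) {
    p <- make_obs(1)
    p$hb <- 40; p$p_hb <- 0.35; p$lb <- 2
    p$lot_shape_b <- cases$shape[i]; p$lot_num_b <- cases$num[i]
    b <- expand_problem(p)$lot_b[[1]]
    expect_equal(lottery_ev(b), 0.35 * 40 + 0.65 * 2, tolerance = 1e-9)
    expect_equal(sum(b$probs), 1, tolerance = 1e-12)
  }
  expect_error(choicebias:::expand_lottery_b(10, 0.5, 1, "symmetric", 4), "odd")
  expect_error(choicebias:::expand_lottery_b(10, 0.5, 1, "none", 3), "lot_num 1")
  expect_error(choicebias:::expand_lottery_b(10, 0.5, 1, "weird", 1), "unknown")
})

test_that("survival probabilities reproduce the worked dominance example", {
  a <- worked_lottery_a()
  b <- worked_lottery_b()
  expect_equal(survival_prob(a, c(12, 14, 90, 96)), c(1.00, 0.95, 0.90, 0.90))
  expect_equal(survival_prob(b, c(12, 14, 90, 96)), c(1.00, 0.90, 0.90, 0.85))
  # any lottery pays at least its own minimum with certainty
  expect_equal(survival_prob(b, lottery_min(b)), 1)
})

test_that("dominance orders behave per definition and nest", {
  a <- worked_lottery_a()
  b <- worked_lottery_b()
  expect_identical(dominance(a, b, 1), 1L)
  expect_identical(dominance(b, a, 1), -1L)
  expect_identical(dominance(a, a, 1), 0L)
  expect_identical(dominance(a, a, 2), 0L)
  expect_identical(dominance(a, a, 3), 0L)
  # the classic risk-aversion case: sure 50 vs fair 0/100
  sure <- lottery(50, 1)
  risky <- lottery(c(0, 100), c(0.5, 0.5))
  expect_identical(dominance(sure, risky, 1), 0L)
  expect_identical(dominance(sure, risky, 2), 1L)
  expect_identical(dominance(sure, risky, 3), 1L)
})

test_that("dominance nesting holds on random problems", {
  ex <- expand_problem(tiny_problems(300, seed = 7))
  for (i in seq_len(nrow(ex))) {
    d1 <- dominance(ex$lot_a[[i]], ex$lot_b[[i]], 1)
    d2 <- dominance(ex$lot_a[[i]], ex$lot_b[[i]], 2)
    d3 <- dominance(ex$lot_a[[i]], ex$lot_b[[i]], 3)
    if (d1 != 0L) expect_identical(d2, d1)
    if (d2 != 0L) expect_identical(d3, d2)
  }
})

test_that("p_better matches exhaustive enumeration and coupling logic", {
  a <- worked_lottery_a()
  b <- worked_lottery_b()
  # brute-force oracle over all 3x3 outcome pairs (independent draws)
  pa <- a$probs; pb <- b$probs
  oracle <- 0
  for (i in 1:3) for (j in 1:3) {
    oracle <- oracle + pa[i] * pb[j] * sign(b$outcomes[j] - a$outcomes[i])
  }
  expect_equal(p_better(a, b, 0), oracle)
  expect_equal(oracle, -0.05)
  # identical independent lotteries are symmetric
  expect_equal(p_better(a, a, 0), 0)
  # B = A + 1 surely (comonotone coupling) always pays more
  shift <- lottery(a$outcomes + 1, a$probs)
  expect_equal(p_better(a, shift, 1), 1)
  # antimonotone coupling: u < .5 pairs A=0 with B=2, u > .5 pairs A=10 with B=1
  a2 <- lottery(c(0, 10), c(0.5, 0.5))
  b2 <- lottery(c(1, 2), c(0.5, 0.5))
  expect_equal(p_better(a2, b2, -1), 0)
  expect_equal(p_better(a2, b2, 0), 0) # B wins iff A = 0: half the mass each way
  # hand enumeration: B beats A exactly when A pays 1 (w.p. 0.75)
  a3 <- lottery(c(1, 4), c(0.75, 0.25))
  b3 <- lottery(c(2, 3), c(0.5, 0.5))
  expect_equal(p_better(a3, b3, 0), 0.75 - 0.25)
})
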