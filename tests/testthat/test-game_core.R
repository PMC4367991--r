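test_that("within-group simplification recovers (B, C) and preserves the Nash set", {
  # stag-hunt-shaped raw game: r = 3, s = 0, t = 1, p = 2
  raw <- bimatrix(rbind(c(3, 0), c(1, 2)), rbind(c(3, 1), c(0, 2)))
  bc <- simplify_within(raw)
  expect_equal(bc$B, -2)
  expect_equal(bc$C, 2)
  expect_identical(classify_dilemma(bc$B, bc$C), "stag_hunt")
  expect_identical(ne_profiles_oracle(raw), c("1 1", "2 2"))
  expect_identical(ne_profiles(enumerate_pure_nash(within_game(bc$B, bc$C))),
                   ne_profiles_oracle(raw))

  # identity when t = p = 0
  raw0 <- bimatrix(rbind(c(0.7, 0.4), c(0, 0)), rbind(c(0.7, 0), c(0.4, 0)))
  expect_equal(simplify_within(raw0), list(B = 0.4, C = 0.7))

  # the worked small-group-1 example: r = 0.1, s = 0.1, t = p = 0
  raw1 <- bimatrix(rbind(c(0.1, 0.1), c(0, 0)), rbind(c(0.1, 0), c(0.1, 0)))
  expect_equal(simplify_within(raw1), list(B = 0.1, C = 0.1))

  # non-symmetric input is rejected
  expect_error(simplify_within(random_between_raw()), "symmetric")
})

test_that("between-group simplification matches the printed parameterization", {
  # R1=2, S1=-1, T1=0, P1=0 / P2=0, S2=-1, T2=0, R2=2
  raw <- bimatrix(rbind(c(2, -1), c(0, 0)), rbind(c(0, -1), c(0, 2)))
  expect_equal(simplify_between(raw),
               list(B3 = -1, C3 = 2, B4 = -1, C4 = 2))

  zero <- bimatrix(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(simplify_between(zero), list(B3 = 0, C3 = 0, B4 = 0, C4 = 0))
})

test_that("simplification preserves the pure Nash set on random games", {
  set.seed(42)
  for (k in 1:1000) {
    raw <- random_within_raw()
    bc <- simplify_within(raw)
    expect_identical(
      ne_profiles(enumerate_pure_nash(within_game(bc$B, bc$C))),
      ne_profiles_oracle(raw))

    rawb <- random_between_raw()
    p <- simplify_between(rawb)
    expect_identical(
      ne_profiles(enumerate_pure_nash(between_game(p$B3, p$B4, p$C3, p$C4))),
      ne_profiles_oracle(rawb))
  }
})

test_that("dilemma classification follows the sign regime and its equilibria", {
  expect_identical(classify_dilemma(2, 1), "harmony")
  expect_identical(classify_dilemma(-1, -1), "prisoners_dilemma")
  expect_identical(classify_dilemma(1, -1), "snowdrift")
  expect_identical(classify_dilemma(-1, 2), "stag_hunt")
  expect_error(classify_dilemma(0, 1), "degenerate")
  expect_error(classify_dilemma(1, 0), "degenerate")

  # equilibrium structure implied by each class, on random magnitudes
  expected <- list(
    harmony = "1 1",                     # all preferred behavior
    prisoners_dilemma = "2 2",           # all the opposite
    snowdrift = c("1 2", "2 1"),         # coexistence
    stag_hunt = c("1 1", "2 2"))         # either, by initial condition
  set.seed(7)
  for (k in 1:200) {
    B <- stats::runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    C <- stats::runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    cls <- classify_dilemma(B, C)
    expect_identical(ne_profiles(enumerate_pure_nash(within_game(B, C))),
                     expected[[cls]])
  }
})

test_that("pure Nash enumeration handles unique, multiple and degenerate games", {
  ne <- enumerate_pure_nash(within_game(10, 10, preferred = 2))
  expect_equal(nrow(ne), 1L)
  expect_equal(unlist(ne[1, ]),
               c(row_behavior = 2, col_behavior = 2,
                 row_payoff = 10, col_payoff = 10))

  ne2 <- enumerate_pure_nash(between_game(B3 = -1, B4 = -1, C3 = 2, C4 = 2))
  expect_identical(ne_profiles(ne2), c("1 1", "2 2"))
  expect_equal(ne2$row_payoff[ne2$row_behavior == 1], 2)
  expect_equal(ne2$col_payoff[ne2$row_behavior == 1], 0)
  expect_equal(ne2$row_payoff[ne2$row_behavior == 2], 0)
  expect_equal(ne2$col_payoff[ne2$row_behavior == 2], 2)

  allzero <- bimatrix(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(nrow(enumerate_pure_nash(allzero)), 4L)
})

test_that("the cohesion ratio q agrees between the Nash-payoff and closed forms", {
  expect_equal(compute_q_general(game_set(c(2, 2, -1, -1, 1, 1, 2, 2))), 1)
  expect_equal(compute_q_closed(1, 1, 2, 2), 1)
  expect_equal(compute_q_general(game_set(c(2, 2, -1, -1, 1, 1/9, 2, 2/9))), 9)
  expect_equal(compute_q_closed(1, 1/9, 2, 2/9), 9)
  expect_equal(compute_q_closed(0.37, 0.37, 0.37, 0.37), 1)

  # fully symmetric parameter sets give q = 1 through the general path
  set.seed(11)
  for (k in 1:50) {
    b <- stats::rnorm(1); c1 <- stats::runif(1, 0.1, 5)
    b3 <- -stats::runif(1, 0.1, 5); c3 <- stats::runif(1, 0.1, 5)
    expect_equal(compute_q_general(game_set(c(b, b, b3, b3, c1, c1, c3, c3))), 1)
  }

  # oracle equivalence across the harmony-within / snowdrift-between regime
  set.seed(123)
  for (k in 1:1000) {
    p <- random_regime_params()
    gs <- game_set(p)
    expect_equal(compute_q_general(gs), compute_q_closed(gs),
                 tolerance = 1e-12)
  }

  # label-swap reciprocity of the closed form
  set.seed(5)
  for (k in 1:100) {
    cc <- stats::runif(4, 0.05, 4)
    expect_equal(compute_q_closed(cc[1], cc[2], cc[3], cc[4]) *
                   compute_q_closed(cc[2], cc[1], cc[4], cc[3]), 1,
                 tolerance = 1e-12)
  }

  expect_error(compute_q_closed(1, -1, 2, 1), "undefined")
})
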