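baseline_params <- c(2, 2, -1, -1, 1, 1, 2, 2)

test_that("population initialization honors f, the seed and binomial spread", {
  cfg <- lattice_config(L = 10, f = 1, seed = 3)
  st <- initialize_population(cfg)
  expect_true(all(st$group == 1L))

  # identical seed => bit-identical grids
  cfg2 <- lattice_config(L = 30, f = 0.4, seed = 99)
  expect_identical(initialize_population(cfg2), initialize_population(cfg2))

  # realized fraction within 3 binomial standard errors of nominal
  st100 <- initialize_population(lattice_config(L = 100, f = 0.5, seed = 17))
  expect_lt(abs(mean(st100$group == 1L) - 0.5), 0.015)
  expect_lt(abs(mean(st100$behavior == 1L) - 0.5), 0.015)

  expect_error(lattice_config(f = 1.2), "f must")
  expect_error(lattice_config(L = 1), "L must")
})

test_that("pairwise payoffs dispatch on the group pair with group 1 on the row axis", {
  gs <- game_set(baseline_params)
  # two group-1 players both on their preferred behavior: (C1, C1)
  expect_equal(pairwise_payoffs(gs, 1, 1, 1, 1),
               c(payoff_a = 1, payoff_b = 1))
  # cross-group mismatch on each one's preferred behavior: (B3, B4)
  expect_equal(pairwise_payoffs(gs, 1, 1, 2, 2),
               c(payoff_a = -1, payoff_b = -1))
  # argument order must not matter: group-2 caller, profile (2, 1)
  expect_equal(pairwise_payoffs(gs, 2, 1, 1, 2),
               c(payoff_a = 0, payoff_b = 0))
  # consistency of the swap for every label combination
  for (ga in 1:2) for (ba in 1:2) for (gb in 1:2) for (bb in 1:2)
    expect_equal(unname(pairwise_payoffs(gs, ga, ba, gb, bb)),
                 unname(rev(pairwise_payoffs(gs, gb, bb, ga, ba))))
})

test_that("accumulated payoffs equal the per-edge brute-force oracle", {
  gs <- game_set(baseline_params)

  # monomorphic group-1 / behavior-1 lattice: every site earns 4 * C1
  mono <- population_state(matrix(1L, 4, 4), matrix(1L, 4, 4))
  expect_true(all(accumulate_payoffs(mono, gs) == 4))

  # a lone group-1/behavior-1 site among group-2/behavior-2 neighbors: 4 * B3
  g <- matrix(2L, 5, 5); b <- matrix(2L, 5, 5)
  g[3, 3] <- 1L; b[3, 3] <- 1L
  lone <- population_state(g, b)
  expect_equal(accumulate_payoffs(lone, gs)[3, 3], -4)

  # random lattices against the explicit edge-sum oracle, both engines
  set.seed(31)
  for (k in 1:5) {
    st <- random_state(5)
    gsr <- game_set(stats::rnorm(8))
    oracle <- payoff_field_oracle(st, gsr)
    expect_equal(accumulate_payoffs(st, gsr, engine = "r"), oracle)
    expect_equal(accumulate_payoffs(st, gsr, engine = "cpp"), oracle)
  }
})

test_that("synchronous imitation copies the best candidate and keeps self on ties", {
  gs <- game_set(baseline_params)

  # monomorphic behavior grid is a fixed point whatever the payoffs
  set.seed(8)
  for (k in 1:5) {
    g <- matrix(sample(1:2, 9, TRUE), 3, 3)
    mono <- population_state(g, matrix(1L, 3, 3))
    upd <- synchronous_update(mono, accumulate_payoffs(mono, game_set(stats::rnorm(8))))
    expect_identical(upd$behavior, mono$behavior)
  }

  # hand-built 3x3 case: the center's strictly best neighbor plays behavior 2
  st <- population_state(matrix(1L, 3, 3),
                         rbind(c(1L, 2L, 1L), c(1L, 1L, 1L), c(1L, 1L, 1L)))
  pay <- matrix(0, 3, 3)
  pay[1, 2] <- 5        # northern neighbor of the center dominates
  upd <- synchronous_update(st, pay)
  expect_identical(upd$behavior[2, 2], 2L)

  # a strictly maximal focal player keeps its own behavior
  pay2 <- matrix(0, 3, 3); pay2[2, 2] <- 5
  st2 <- population_state(matrix(1L, 3, 3),
                          rbind(c(2L, 2L, 2L), c(2L, 1L, 2L), c(2L, 2L, 2L)))
  expect_identical(synchronous_update(st2, pay2)$behavior[2, 2], 1L)

  # all-tied payoffs: everyone keeps its behavior (self preference)
  st3 <- random_state(4, seed = 2)
  expect_identical(synchronous_update(st3, matrix(1, 4, 4))$behavior,
                   st3$behavior)
})

test_that("the compiled and reference engines produce identical dynamics", {
  set.seed(77)
  for (k in 1:5) {
    st <- random_state(8)
    gsr <- game_set(c(stats::rnorm(4), stats::runif(4, 0.1, 2)))
    conv <- convergence_spec(window = 20, average_window = 20, max_steps = 60)
    tr_r <- run_lattice(gsr, conv = conv, init = st, engine = "r")
    tr_c <- run_lattice(gsr, conv = conv, init = st, engine = "cpp")
    expect_identical(tr_r$rho1, tr_c$rho1)
    expect_identical(tr_r$rho1_g1, tr_c$rho1_g1)
    expect_identical(tr_r$final_state$behavior, tr_c$final_state$behavior)
    expect_identical(tr_r$converged_at, tr_c$converged_at)
  }
})

test_that("runs conserve the group grid, are deterministic and flag fixed points", {
  gs <- game_set(baseline_params)
  cfg <- lattice_config(L = 20, f = 0.3, seed = 5)
  conv <- convergence_spec(window = 50, average_window = 50, max_steps = 2000)

  tr <- run_lattice(gs, cfg, conv)
  expect_identical(tr$final_state$group, initialize_population(cfg)$group)
  tr_again <- run_lattice(gs, cfg, conv)
  expect_identical(tr$rho1, tr_again$rho1)
  expect_identical(tr$final_state$behavior, tr_again$final_state$behavior)

  # an all-behavior-2 start is already a fixed point: converged at step 0
  init <- population_state(initialize_population(cfg)$group,
                           matrix(2L, 20, 20))
  tr0 <- run_lattice(gs, conv = conv, init = init)
  expect_true(tr0$fixed_point)
  expect_identical(tr0$converged_at, 0L)
  expect_equal(tr0$steady_rho1, 0)
})

test_that("label-swapped runs mirror exactly, step for step", {
  # fluct_tol chosen strictly between attainable per-step deltas (multiples
  # of 1/400 on a 20 x 20 lattice) so both runs stop at the same step
  conv <- convergence_spec(fluct_tol = 0.013, window = 30,
                           average_window = 30, max_steps = 500)
  set.seed(13)
  for (params in list(baseline_params,
                      c(2, 2, -1, -1, 1, 1/3, 2, 2/3),
                      c(1, 2, -2, -1, 0.5, 1, 3, 2))) {
    st <- random_state(20, f = 0.35)
    tr <- run_lattice(game_set(params), conv = conv, init = st)
    tr_m <- run_lattice(game_set(swap_params(params)), conv = conv,
                        init = mirror_state(st))
    expect_identical(length(tr$rho1), length(tr_m$rho1))
    n <- length(st$group)
    # counts mirror exactly: n * rho1' = n - n * rho1 at every step
    expect_identical(round(tr_m$rho1 * n), n - round(tr$rho1 * n))
    expect_equal(tr_m$rho1_g1, 1 - tr$rho1_g2)
    expect_identical(tr_m$final_state$behavior, 3L - tr$final_state$behavior)
  }
})
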