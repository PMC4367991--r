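# Independent oracles, written against the definitions rather than the
# package internals.

# Pure Nash profiles of a 2x2 bimatrix via the max-based formulation: a
# profile is an equilibrium iff each player's payoff attains the maximum of
# its own payoffs over its strategies, holding the opponent fixed.
ne_profiles_oracle <- function(game) {
  A <- game$row_payoffs
  D <- game$col_payoffs
  out <- character(0)
  for (i in 1:2) for (j in 1:2) {
    if (A[i, j] == max(A[, j]) && D[i, j] == max(D[i, ]))
      out <- c(out, paste(i, j))
  }
  sort(out)
}

ne_profiles <- function(ne) sort(paste(ne$row_behavior, ne$col_behavior))

# Brute-force accumulated payoffs: explicit double loop over sites and the
# four neighbor offsets, payoffs from pairwise_payoffs one edge at a time.
payoff_field_oracle <- function(state, games) {
  g <- state$group; b <- state$behavior
  L <- nrow(g); M <- ncol(g)
  wrap <- function(k, n) ((k - 1) %% n) + 1
  total <- matrix(0, L, M)
  for (i in seq_len(L)) for (j in seq_len(M)) {
    for (off in list(c(-1, 0), c(0, 1), c(1, 0), c(0, -1))) {
      ni <- wrap(i + off[1], L); nj <- wrap(j + off[2], M)
      total[i, j] <- total[i, j] +
        pairwise_payoffs(games, g[i, j], b[i, j], g[ni, nj], b[ni, nj])[1]
    }
  }
  total
}

# Random symmetric within-group raw game [(r,r),(s,t);(t,s),(p,p)].
random_within_raw <- function() {
  v <- stats::rnorm(4)   # r, s, t, p
  A <- rbind(c(v[1], v[2]), c(v[3], v[4]))
  bimatrix(A, t(A))
}

# Random between-group raw game [(R1,P2),(S1,S2);(T1,T2),(P1,R2)].
random_between_raw <- function() {
  bimatrix(matrix(stats::rnorm(4), 2, 2), matrix(stats::rnorm(4), 2, 2))
}

# Random parameter set in the harmony-within / snowdrift-between regime.
random_regime_params <- function() {
  c(stats::runif(2, 0.1, 3),            # B1, B2 > 0
    -stats::runif(2, 0.1, 3),           # B3, B4 < 0
    stats::runif(4, 0.1, 3))            # C1..C4 > 0
}

random_state <- function(L, f = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  population_state(matrix(sample(1:2, L * L, TRUE, c(f, 1 - f)), L, L),
                   matrix(sample(1:2, L * L, TRUE), L, L))
}

# Label-swapped mirror of a state (group 1 <-> 2, behavior 1 <-> 2).
mirror_state <- function(state) {
  population_state(3L - state$group, 3L - state$behavior, state$step)
}

# Parameter vector with the two groups' roles exchanged.
swap_params <- function(p) p[c(2, 1, 4, 3, 6, 5, 8, 7)]
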