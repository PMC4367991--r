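#' Lattice simulation configuration
#'
#' @param L lattice side length; the population has `L * L` players on a
#'   square lattice with periodic boundary conditions.
#' @param f probability that a site belongs to small group 1 (group
#'   membership is fixed for the whole run).
#' @param init_behavior1_prob probability that a site starts with behavior 1.
#' @param seed integer seed; identical seeds give bit-identical populations
#'   and (the dynamics being deterministic) identical trajectories.
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(L = 100L, f = 0.5, init_behavior1_prob = 0.5,
                           seed = 1L) {
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("L must be an integer >= 2")
  if (!is.numeric(f) || is.na(f) || f < 0 || f > 1)
    stop("f must lie in [0, 1]")
  if (!is.numeric(init_behavior1_prob) || is.na(init_behavior1_prob) ||
      init_behavior1_prob < 0 || init_behavior1_prob > 1)
    stop("init_behavior1_prob must lie in [0, 1]")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L) stop("seed must be a non-negative integer")
  structure(list(L = L, f = f, init_behavior1_prob = init_behavior1_prob,
                 seed = seed),
            class = "lattice_config")
}

#' Initialize a population on the lattice
#'
#' Each site independently joins small group 1 with probability `f` and
#' starts with behavior 1 with probability `init_behavior1_prob` (i.i.d.
#' Bernoulli draws, so realized fractions fluctuate binomially around the
#' nominal values). Group labels never change afterwards.
#'
#' @param config a [lattice_config()].
#' @return An object of class `population_state`: a list with `group` and
#'   `behavior` (L x L integer matrices with entries in \{1, 2\}) and `step`
#'   (0 for a fresh population).
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "lattice_config"))
  L <- config$L
  set.seed(config$seed)
  group <- matrix(ifelse(stats::runif(L * L) < config$f, 1L, 2L), L, L)
  behavior <- matrix(
    ifelse(stats::runif(L * L) < config$init_behavior1_prob, 1L, 2L), L, L)
  population_state(group, behavior, step = 0L)
}

#' Construct a population state from explicit grids
#'
#' @param group,behavior L x L integer matrices with entries in \{1, 2\}.
#' @param step the step index the state corresponds to.
#' @return An object of class `population_state`.
#' @export
population_state <- function(group, behavior, step = 0L) {
  group <- as.matrix(group); storage.mode(group) <- "integer"
  behavior <- as.matrix(behavior); storage.mode(behavior) <- "integer"
  if (!identical(dim(group), dim(behavior)))
    stop("group and behavior grids must have identical dimensions")
  if (!all(group %in% c(1L, 2L)) || !all(behavior %in% c(1L, 2L)))
    stop("group and behavior labels must be 1 or 2")
  structure(list(group = group, behavior = behavior, step = as.integer(step)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  d <- dim(x$group)
  cat(sprintf("population on a %d x %d periodic lattice (step %d)\n",
              d[1], d[2], x$step))
  cat(sprintf("  group 1 fraction:    %.4f\n", mean(x$group == 1L)))
  cat(sprintf("  behavior 1 fraction: %.4f\n", mean(x$behavior == 1L)))
  invisible(x)
}

#' Pairwise payoff lookup table
#'
#' Builds the 2x2x2x2 array `tab[gA, bA, gB, bB]` giving player A's payoff
#' from one encounter, dispatching on the group pair: two group-1 players use
#' the within-group-1 game, two group-2 players the within-group-2 game, and
#' mixed pairs the between-group game with the group-1 player on the row
#' axis regardless of argument order.
#'
#' @param games a [game_set()].
#' @return A numeric array of dimension `c(2, 2, 2, 2)`.
#' @export
payoff_lookup <- function(games) {
  g <- interaction_games(games)
  tab <- array(0, dim = c(2, 2, 2, 2))
  for (bA in 1:2) for (bB in 1:2) {
    tab[1, bA, 1, bB] <- g$within1$row_payoffs[bA, bB]
    tab[2, bA, 2, bB] <- g$within2$row_payoffs[bA, bB]
    tab[1, bA, 2, bB] <- g$between$row_payoffs[bA, bB]
    # group-2 player against a group-1 opponent: column player of the
    # between-group game, whose own behavior indexes the column
    tab[2, bA, 1, bB] <- g$between$col_payoffs[bB, bA]
  }
  tab
}

#' Payoffs of a single pairwise encounter
#'
#' @param games a [game_set()].
#' @param group_a,behavior_a,group_b,behavior_b labels in \{1, 2\} for the
#'   two players.
#' @return Numeric vector `c(payoff_a, payoff_b)`.
#' @examples
#' gs <- game_set(c(2, 2, -1, -1, 1, 1, 2, 2))
#' pairwise_payoffs(gs, 1, 1, 2, 2)  # cross-group mismatch: (B3, B4)
#' @export
pairwise_payoffs <- function(games, group_a, behavior_a, group_b, behavior_b) {
  stopifnot(group_a %in% 1:2, behavior_a %in% 1:2,
            group_b %in% 1:2, behavior_b %in% 1:2)
  tab <- payoff_lookup(games)
  c(payoff_a = tab[group_a, behavior_a, group_b, behavior_b],
    payoff_b = tab[group_b, behavior_b, group_a, behavior_a])
}

# Periodic shift of a matrix: dr/dc move the *source* so that
# shift(m, -1, 0)[i, j] == m[i - 1, j] (the northern neighbor's value).
shift_torus <- function(m, dr, dc) {
  L <- nrow(m); M <- ncol(m)
  m[((seq_len(L) - 1 + dr) %% L) + 1, ((seq_len(M) - 1 + dc) %% M) + 1,
    drop = FALSE]
}

# Neighbor offsets in the fixed candidate order N, E, S, W.
.neighbor_offsets <- list(N = c(-1L, 0L), E = c(0L, 1L),
                          S = c(1L, 0L), W = c(0L, -1L))

#' Accumulate per-round payoffs over the four neighbors
#'
#' Every player plays one game against each of its four von Neumann
#' neighbors (north, east, south, west, periodic wrap) and sums the four
#' payoffs. Payoffs are recomputed from zero every round; nothing carries
#' over.
#'
#' @param state a [population_state()].
#' @param games a [game_set()].
#' @param engine `"cpp"` (compiled loop) or `"r"` (vectorized reference
#'   implementation); both produce identical results.
#' @return An L x L numeric matrix of accumulated payoffs.
#' @export
accumulate_payoffs <- function(state, games, engine = c("cpp", "r")) {
  stopifnot(inherits(state, "population_state"))
  engine <- match.arg(engine)
  tab <- payoff_lookup(games)
  if (engine == "cpp")
    return(.cpp_accumulate_payoffs(state$group, state$behavior, as.vector(tab)))
  g <- state$group; b <- state$behavior
  total <- matrix(0, nrow(g), ncol(g))
  for (off in .neighbor_offsets) {
    gn <- shift_torus(g, off[1], off[2])
    bn <- shift_torus(b, off[1], off[2])
    total <- total + tab[cbind(as.vector(g), as.vector(b),
                               as.vector(gn), as.vector(bn))]
  }
  total
}

#' Synchronous best-neighbor imitation update
#'
#' All players update at once: each adopts the behavior of the member of
#' \{self, N, E, S, W\} with the highest accumulated payoff this round. A
#' player that is itself (weakly) maximal keeps its behavior; among strictly
#' better tied neighbors the first in the fixed order N, E, S, W is copied,
#' so the update is fully deterministic. Group labels are untouched.
#'
#' @param state a [population_state()].
#' @param payoffs payoff matrix from [accumulate_payoffs()] on `state`.
#' @return The updated [population_state()] (step incremented).
#' @export
synchronous_update <- function(state, payoffs) {
  stopifnot(inherits(state, "population_state"),
            identical(dim(payoffs), dim(state$behavior)))
  b <- state$behavior
  cand_pay <- cbind(as.vector(payoffs),
                    vapply(.neighbor_offsets, function(off)
                      as.vector(shift_torus(payoffs, off[1], off[2])),
                      numeric(length(b))))
  cand_beh <- cbind(as.vector(b),
                    vapply(.neighbor_offsets, function(off)
                      as.vector(shift_torus(b, off[1], off[2])),
                      integer(length(b))))
  pick <- max.col(cand_pay, ties.method = "first")
  new_b <- matrix(cand_beh[cbind(seq_along(pick), pick)],
                  nrow(b), ncol(b))
  population_state(state$group, new_b, step = state$step + 1L)
}

#' Run the lattice dynamics with the convergence protocol
#'
#' Iterates payoff accumulation and synchronous imitation, recording the
#' behavior-1 fraction (population and per group) each step, until either
#' (a) an update leaves the behavior grid unchanged — an exact fixed point of
#' the deterministic dynamics, so the run is converged on the spot — or
#' (b) the fluctuation criterion of [detect_convergence()] fires, after which
#' the run continues for `average_window` further steps and the steady-state
#' fraction is their mean, or (c) `max_steps` is exhausted, in which case the
#' trajectory is flagged unconverged.
#'
#' @param games a [game_set()].
#' @param config a [lattice_config()]; ignored when `init` is given.
#' @param conv a [convergence_spec()].
#' @param init optional [population_state()] to start from instead of a
#'   seeded random initialization.
#' @param record_steps integer steps (1-based update counts; 0 = initial
#'   state) at which to keep a copy of the full state.
#' @param engine `"cpp"` or `"r"`.
#' @return An object of class `trajectory`; see [trajectory()].
#' @examples
#' gs <- game_set(c(2, 2, -1, -1, 1, 1, 2, 2))
#' tr <- run_lattice(gs, lattice_config(L = 20, f = 0.5, seed = 1),
#'                   conv = convergence_spec(window = 50, average_window = 50))
#' tr$steady_rho1
#' @export
run_lattice <- function(games, config = lattice_config(),
                        conv = convergence_spec(), init = NULL,
                        record_steps = integer(0), engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  state <- if (is.null(init)) initialize_population(config) else init
  stopifnot(inherits(state, "population_state"))
  group0 <- state$group
  tab <- payoff_lookup(games)
  record_steps <- sort(unique(as.integer(record_steps)))
  if (length(record_steps) && max(record_steps) > conv$max_steps)
    stop("record_steps beyond max_steps")

  rho1 <- mean(state$behavior == 1L)
  n1 <- sum(group0 == 1L); n2 <- length(group0) - n1
  rho1_g1 <- if (n1 > 0) sum(state$behavior == 1L & group0 == 1L) / n1 else NA_real_
  rho1_g2 <- if (n2 > 0) sum(state$behavior == 1L & group0 == 2L) / n2 else NA_real_
  snapshots <- list()
  if (0L %in% record_steps)
    snapshots[["0"]] <- encode_states(state)

  t <- 0L
  fixed_point <- FALSE
  converged_at <- NA_integer_
  steady <- NA_real_
  target <- NA_integer_  # step at which the averaging window completes

  advance <- function(k) {
    # advance k steps, appending fractions; returns TRUE on fixed point
    if (engine == "cpp") {
      res <- .cpp_simulate(group0, state$behavior, as.vector(tab), k)
      state$behavior <<- res$behavior
      state$step <<- state$step + res$steps_done
      rho1 <<- c(rho1, res$rho1)
      rho1_g1 <<- c(rho1_g1, res$rho1_g1)
      rho1_g2 <<- c(rho1_g2, res$rho1_g2)
      t <<- t + res$steps_done
      res$fixed_point
    } else {
      hit <- FALSE
      for (s in seq_len(k)) {
        prev <- state$behavior
        state <<- synchronous_update(state, accumulate_payoffs(state, games,
                                                               engine = "r"))
        b <- state$behavior
        rho1 <<- c(rho1, mean(b == 1L))
        rho1_g1 <<- c(rho1_g1,
                      if (n1 > 0) sum(b == 1L & group0 == 1L) / n1 else NA_real_)
        rho1_g2 <<- c(rho1_g2,
                      if (n2 > 0) sum(b == 1L & group0 == 2L) / n2 else NA_real_)
        t <<- t + 1L
        if (identical(b, prev)) { hit <- TRUE; break }
      }
      hit
    }
  }

  # chunk boundaries: stop exactly at requested snapshot steps
  chunk <- 200L
  while (t < conv$max_steps) {
    pending <- record_steps[record_steps > t]
    k <- min(chunk, conv$max_steps - t,
             if (length(pending)) pending[1] - t else Inf,
             if (!is.na(target)) target - t else Inf)
    hit <- advance(as.integer(k))
    if (t %in% record_steps)
      snapshots[[as.character(t)]] <- encode_states(state)
    if (hit) {
      fixed_point <- TRUE
      converged_at <- t - 1L  # state at t equals state at t - 1
      steady <- rho1[t + 1L]  # constant from here on; window mean is exact
      if (!length(record_steps[record_steps > t])) break
      # still need later snapshots: state is frozen, reuse it
      for (s in record_steps[record_steps > t]) {
        frozen <- state; frozen$step <- as.integer(s)
        snapshots[[as.character(s)]] <- encode_states(frozen)
      }
      break
    }
    if (is.na(target)) {
      ca <- detect_convergence(rho1, conv)
      if (!is.na(ca)) {
        converged_at <- ca
        target <- ca + conv$average_window
        if (target <= t) break
      }
    }
    if (!is.na(target) && t >= target) break
  }
  if (!is.na(converged_at) && !fixed_point) {
    if (converged_at + conv$average_window + 1L <= length(rho1)) {
      steady <- steady_state_average(rho1, converged_at, conv)
    } else {
      # criterion fired but the averaging window does not fit before
      # max_steps: treat as unconverged rather than average a short window
      converged_at <- NA_integer_
    }
  }

  trajectory(rho1 = rho1, rho1_g1 = rho1_g1, rho1_g2 = rho1_g2,
             converged_at = converged_at, steady_rho1 = steady,
             fixed_point = fixed_point,
             realized_f = n1 / length(group0),
             final_state = state, snapshots = snapshots,
             games = games, config = if (is.null(init)) config else NULL,
             conv = conv)
}
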