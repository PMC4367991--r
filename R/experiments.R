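#' Encode a population state as a single 4-state grid
#'
#' Combines group and behavior into one integer per site, following the
#' snapshot color convention: 0 = behavior 1 in group 1 (blue), 1 = behavior
#' 2 in group 1 (yellow), 2 = behavior 1 in group 2 (green), 3 = behavior 2
#' in group 2 (red).
#'
#' @param state a [population_state()].
#' @return An L x L integer matrix with entries in 0..3.
#' @export
encode_states <- function(state) {
  stopifnot(inherits(state, "population_state"))
  m <- 2L * (state$group - 1L) + (state$behavior - 1L)
  storage.mode(m) <- "integer"
  m
}

#' Replicated runs of one parameter point
#'
#' Runs `n_reps` independent replicates differing only in the seed
#' (`seed0 + 0, ..., seed0 + n_reps - 1`) and collects the steady-state
#' behavior-1 fractions.
#'
#' @param games a [game_set()].
#' @param config a [lattice_config()]; its seed is replaced per replicate.
#' @param conv a [convergence_spec()].
#' @param n_reps number of replicates.
#' @param seed0 seed of the first replicate.
#' @return A list with `mean_steady_rho1`, `reps` (a data.frame with one row
#'   per replicate: `replicate`, `seed`, `steady_rho1`, `converged`,
#'   `converged_at`, `realized_f`), and `n_unconverged`.
#' @export
run_replicates <- function(games, config = lattice_config(),
                           conv = convergence_spec(), n_reps = 10L,
                           seed0 = config$seed) {
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 1L)
  rows <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed0 + k - 1L)
    tr <- run_lattice(games, cfg, conv)
    rows[[k]] <- data.frame(replicate = k, seed = cfg$seed,
                            steady_rho1 = tr$steady_rho1,
                            converged = !is.na(tr$converged_at),
                            converged_at = tr$converged_at,
                            realized_f = tr$realized_f)
  }
  reps <- do.call(rbind, rows)
  list(mean_steady_rho1 = mean(reps$steady_rho1, na.rm = TRUE),
       reps = reps,
       n_unconverged = sum(!reps$converged))
}

#' Parameter scheme for varying the cohesion ratio q
#'
#' Holds the six fixed parameters `[B1, B2, B3, B4, C1, C3]` and derives a
#' full eight-parameter set for any `q > 0` through `C2 = C1 / q`,
#' `C4 = C3 / q`, which keeps the harmony-within / snowdrift-between regime
#' intact while setting `(C3 + C1) / (C4 + C2) = q` exactly.
#'
#' @param base numeric vector `c(B1, B2, B3, B4, C1, C3)`.
#' @return A function of `q` returning a [game_set()].
#' @examples
#' scheme <- q_scheme(c(2, 2, -1, -1, 1, 2))
#' unlist(scheme(9))
#' @export
q_scheme <- function(base = c(2, 2, -1, -1, 1, 2)) {
  base <- as.numeric(base)
  if (length(base) != 6L || !all(is.finite(base)))
    stop("base must be 6 finite numbers [B1,B2,B3,B4,C1,C3]")
  function(q) {
    if (!is.numeric(q) || q <= 0) stop("q must be positive")
    game_set(c(base[1:4], base[5], base[5] / q, base[6], base[6] / q))
  }
}

sweep_row <- function(f, q, param_set_id, res) {
  cbind(data.frame(f = f, q = q, param_set_id = param_set_id),
        res$reps[c("replicate", "seed", "steady_rho1", "converged")])
}

#' Sweep the group-1 fraction f at fixed parameters
#'
#' @param f_values probabilities to sweep.
#' @param games a [game_set()] (held fixed across the sweep).
#' @param config,conv,n_reps,seed0 protocol settings; replicate seeds are
#'   `seed0 + i * 1000 + k` for sweep point `i`.
#' @param param_set_id label stored in the result rows.
#' @return A `sweep_result` data.frame with one row per (f, replicate).
#' @export
sweep_f <- function(f_values, games, config = lattice_config(),
                    conv = convergence_spec(), n_reps = 10L, seed0 = 1L,
                    param_set_id = 1L) {
  stopifnot(all(f_values >= 0 & f_values <= 1))
  q <- compute_q_general(games)
  out <- vector("list", length(f_values))
  for (i in seq_along(f_values)) {
    cfg <- config
    cfg$f <- f_values[i]
    res <- run_replicates(games, cfg, conv, n_reps,
                          seed0 = seed0 + (i - 1L) * 1000L)
    out[[i]] <- sweep_row(f_values[i], q, param_set_id, res)
  }
  structure(do.call(rbind, out), class = c("sweep_result", "data.frame"))
}

#' Sweep the cohesion ratio q at fixed f
#'
#' @param q_values positive ratios to sweep.
#' @param scheme a [q_scheme()] deriving the parameter set for each q.
#' @param f group-1 fraction, held fixed.
#' @param config,conv,n_reps,seed0 protocol settings.
#' @param param_set_id label stored in the result rows.
#' @return A `sweep_result` data.frame with one row per (q, replicate).
#' @export
sweep_q <- function(q_values, scheme = q_scheme(), f = 0.5,
                    config = lattice_config(), conv = convergence_spec(),
                    n_reps = 10L, seed0 = 1L, param_set_id = 1L) {
  stopifnot(all(q_values > 0))
  out <- vector("list", length(q_values))
  cfg <- config
  cfg$f <- f
  for (i in seq_along(q_values)) {
    res <- run_replicates(scheme(q_values[i]), cfg, conv, n_reps,
                          seed0 = seed0 + (i - 1L) * 1000L)
    out[[i]] <- sweep_row(f, q_values[i], param_set_id, res)
  }
  structure(do.call(rbind, out), class = c("sweep_result", "data.frame"))
}

#' Full factorial sweep over f and q
#'
#' @param f_values,q_values grids for the two variables.
#' @param scheme a [q_scheme()].
#' @param config,conv,n_reps,seed0 protocol settings.
#' @return A `sweep_result` data.frame with `length(f_values) *
#'   length(q_values) * n_reps` rows.
#' @export
sweep_fq <- function(f_values, q_values, scheme = q_scheme(),
                     config = lattice_config(), conv = convergence_spec(),
                     n_reps = 10L, seed0 = 1L) {
  stopifnot(all(f_values >= 0 & f_values <= 1), all(q_values > 0))
  out <- list()
  i <- 0L
  for (q in q_values) {
    games <- scheme(q)
    for (f in f_values) {
      cfg <- config
      cfg$f <- f
      res <- run_replicates(games, cfg, conv, n_reps,
                            seed0 = seed0 + i * 1000L)
      out[[length(out) + 1L]] <- sweep_row(f, q, 1L, res)
      i <- i + 1L
    }
  }
  structure(do.call(rbind, out), class = c("sweep_result", "data.frame"))
}

#' Mean steady-state fraction per sweep point
#'
#' @param result a `sweep_result` from [sweep_f()], [sweep_q()] or
#'   [sweep_fq()].
#' @return A data.frame with one row per (f, q, param_set_id) and the
#'   replicate-mean `steady_rho1`.
#' @export
summarize_sweep <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  agg <- stats::aggregate(steady_rho1 ~ f + q + param_set_id, data = result,
                          FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  agg[order(agg$param_set_id, agg$q, agg$f), , drop = FALSE]
}

#' Capture lattice snapshots at selected steps
#'
#' Runs the dynamics and keeps the full 4-state grid (see [encode_states()])
#' at the requested steps (counting synchronous updates; 0 is the initial
#' state). The default steps follow the customary 1, 3, 100, 500 sequence.
#'
#' @param games a [game_set()].
#' @param config a [lattice_config()].
#' @param steps integer steps at which to capture.
#' @param conv a [convergence_spec()]; `max_steps` must cover the largest
#'   requested step.
#' @return Named list of integer grids (entries 0..3), one per step, plus
#'   the trajectory as attribute `"trajectory"`.
#' @export
capture_snapshots <- function(games, config = lattice_config(),
                              steps = c(1L, 3L, 100L, 500L),
                              conv = convergence_spec()) {
  steps <- as.integer(steps)
  if (any(steps < 0L)) stop("snapshot steps must be >= 0")
  if (any(steps > conv$max_steps))
    stop("snapshot step beyond the run length (max_steps)")
  tr <- run_lattice(games, config, conv, record_steps = steps)
  out <- tr$snapshots[as.character(steps)]
  attr(out, "trajectory") <- tr
  out
}

#' Count connected clusters of a value on the periodic lattice
#'
#' Connected components under 4-neighbor (von Neumann) adjacency with
#' periodic wrap. Used to check that a persistent minority behavior occupies
#' few contiguous clusters rather than scattered sites.
#'
#' @param grid an integer matrix.
#' @param value the cell value whose clusters are counted.
#' @return Number of connected components of cells equal to `value`.
#' @export
count_clusters <- function(grid, value) {
  L <- nrow(grid); M <- ncol(grid)
  sel <- grid == value
  lab <- matrix(0L, L, M)
  n_comp <- 0L
  for (start in which(sel)) {
    if (lab[start] != 0L) next
    n_comp <- n_comp + 1L
    queue <- start
    lab[start] <- n_comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% L + 1L
      j <- (cur - 1L) %/% L + 1L
      for (off in .neighbor_offsets) {
        ni <- (i - 1L + off[1] + L) %% L + 1L
        nj <- (j - 1L + off[2] + M) %% M + 1L
        ncur <- (nj - 1L) * L + ni
        if (sel[ncur] && lab[ncur] == 0L) {
          lab[ncur] <- n_comp
          queue <- c(queue, ncur)
        }
      }
    }
  }
  n_comp
}
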