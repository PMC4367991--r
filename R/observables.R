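#' Convergence-and-averaging protocol specification
#'
#' The measurement protocol: a run counts as converged at the first step `t`
#' such that the per-step fluctuation of the population behavior-1 fraction
#' stayed below `fluct_tol` for `window` consecutive steps ending at `t`;
#' the steady-state fraction is then the mean over the `average_window`
#' steps that follow.
#'
#' @param fluct_tol fluctuation tolerance (per-step absolute change in the
#'   behavior-1 fraction).
#' @param window number of consecutive quiet steps required.
#' @param average_window number of post-convergence steps averaged.
#' @param max_steps hard cap; a run that never converges is flagged.
#' @return An object of class `convergence_spec`.
#' @export
convergence_spec <- function(fluct_tol = 0.01, window = 500L,
                             average_window = 500L, max_steps = 20000L) {
  window <- as.integer(window)
  average_window <- as.integer(average_window)
  max_steps <- as.integer(max_steps)
  if (!is.numeric(fluct_tol) || fluct_tol <= 0)
    stop("fluct_tol must be positive")
  if (any(is.na(c(window, average_window, max_steps))) ||
      window < 1L || average_window < 1L || max_steps < 1L)
    stop("window, average_window and max_steps must be positive integers")
  structure(list(fluct_tol = fluct_tol, window = window,
                 average_window = average_window, max_steps = max_steps),
            class = "convergence_spec")
}

#' Trajectory of a lattice run
#'
#' @param rho1,rho1_g1,rho1_g2 behavior-1 fraction series (population,
#'   within group 1, within group 2); element `i` is the fraction at step
#'   `i - 1`, so the series start at the initial state (step 0).
#' @param converged_at step at which the convergence criterion fired, or
#'   `NA` if the run never converged.
#' @param steady_rho1 steady-state behavior-1 fraction (post-convergence
#'   average), or `NA`.
#' @param fixed_point whether the run ended in an exact fixed point.
#' @param realized_f realized group-1 fraction of the run.
#' @param final_state,snapshots,games,config,conv run metadata.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(rho1, rho1_g1, rho1_g2, converged_at, steady_rho1,
                       fixed_point = FALSE, realized_f = NA_real_,
                       final_state = NULL, snapshots = list(),
                       games = NULL, config = NULL, conv = NULL) {
  structure(list(rho1 = rho1, rho1_g1 = rho1_g1, rho1_g2 = rho1_g2,
                 converged_at = converged_at, steady_rho1 = steady_rho1,
                 fixed_point = fixed_point, realized_f = realized_f,
                 final_state = final_state, snapshots = snapshots,
                 games = games, config = config, conv = conv),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$rho1) - 1L
  cat(sprintf("lattice trajectory: %d steps, realized f = %.4f\n",
              n, x$realized_f))
  if (is.na(x$converged_at)) {
    cat("  NOT converged within the step budget\n")
  } else {
    cat(sprintf("  converged at step %d%s, steady-state rho1 = %.4f\n",
                x$converged_at,
                if (x$fixed_point) " (exact fixed point)" else "",
                x$steady_rho1))
  }
  invisible(x)
}

#' Fraction of behavior 1 in a population state
#'
#' @param state a [population_state()].
#' @param group optionally restrict to one small group (1 or 2).
#' @return The fraction of sites (of the group, if given) playing behavior 1.
#' @export
fraction_behavior1 <- function(state, group = NULL) {
  stopifnot(inherits(state, "population_state"))
  if (is.null(group)) return(mean(state$behavior == 1L))
  stopifnot(group %in% 1:2)
  sel <- state$group == group
  if (!any(sel)) return(NA_real_)
  mean(state$behavior[sel] == 1L)
}

#' Detect convergence of a behavior-fraction series
#'
#' Scans the per-step fluctuation (absolute change of the fraction from one
#' step to the next) and returns the first step `t` such that every
#' fluctuation in the `window` steps ending at `t` is below `fluct_tol`.
#'
#' @param rho1 numeric series; element `i` is the fraction at step `i - 1`.
#' @param spec a [convergence_spec()].
#' @return The convergence step (an integer), or `NA` if the criterion never
#'   fires within the series.
#' @export
detect_convergence <- function(rho1, spec = convergence_spec()) {
  stopifnot(inherits(spec, "convergence_spec"), length(rho1) >= 1L)
  d <- abs(diff(rho1))          # d[s] is the fluctuation at step s
  w <- spec$window
  if (length(d) < w) return(NA_integer_)
  quiet <- d < spec$fluct_tol
  # run length of consecutive quiet steps ending at each step
  streak <- 0L
  for (s in seq_along(quiet)) {
    streak <- if (quiet[s]) streak + 1L else 0L
    if (streak >= w) return(s)
  }
  NA_integer_
}

#' Steady-state average of a converged series
#'
#' Arithmetic mean of the fraction over the `average_window` steps following
#' the convergence step.
#'
#' @param rho1 numeric series (element `i` = step `i - 1`).
#' @param converged_at convergence step, e.g. from [detect_convergence()].
#' @param spec a [convergence_spec()].
#' @return The mean fraction.
#' @export
steady_state_average <- function(rho1, converged_at, spec = convergence_spec()) {
  stopifnot(inherits(spec, "convergence_spec"), !is.na(converged_at))
  idx <- converged_at + 1L + seq_len(spec$average_window)  # steps ca+1 .. ca+aw
  if (max(idx) > length(rho1))
    stop("series too short: extend the run ", max(idx) - length(rho1),
         " steps beyond the averaging window")
  mean(rho1[idx])
}

#' Stabilization step of a series
#'
#' The first step after which every subsequent per-step change stays below
#' `tol` through the end of the series; 0 for a series that never moves by
#' `tol` or more.
#'
#' @param rho1 numeric series (element `i` = step `i - 1`).
#' @param tol fluctuation tolerance.
#' @return An integer step index.
#' @export
stabilization_step <- function(rho1, tol = 0.01) {
  stopifnot(length(rho1) >= 1L, tol > 0)
  d <- abs(diff(rho1))
  big <- which(d >= tol)
  if (length(big) == 0L) 0L else big[length(big)]
}
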