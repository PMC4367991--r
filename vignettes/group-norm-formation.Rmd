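---
title: "Norm formation in group-structured lattice populations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norm formation in group-structured lattice populations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupgames)
```

## The model

`groupgames` simulates behavioral evolution in a population of `L * L`
players on a square lattice with periodic boundary conditions. Each player
carries two labels:

* a **group** label (small group 1 or 2), drawn once at initialization —
  each site joins group 1 independently with probability `f` — and frozen
  for the whole run;
* a **behavior** label (behavior 1 or 2), initially an independent coin flip
  (probability `init_behavior1_prob`, default 0.5), updated every round.

Group `k` *prefers* behavior `k`. The preference is not a bias in the update
rule; it is encoded entirely in the payoffs, which depend on the pair of
groups that meet:

* two group-1 players play the within-group-1 game
  `[(C1,C1),(B1,0);(0,B1),(0,0)]`,
* two group-2 players play the mirrored within-group-2 game
  `[(0,0),(0,B2);(B2,0),(C2,C2)]`,
* a mixed pair plays the between-group game
  `[(C3,0),(B3,B4);(0,0),(0,C4)]`, with the group-1 player on the row axis
  regardless of who is "focal".

These three matrices are the *equivalently simplified* forms of arbitrary
raw 2x2 games: subtracting from each player's payoff a constant that depends
only on the opponent's move changes no best response and no Nash
equilibrium, and reduces each game to two parameters. `simplify_within()`
and `simplify_between()` perform this reduction (`C = r - t`, `B = s - p`
for a symmetric within-group game `[(r,r),(s,t);(t,s),(p,p)]`, and
analogously per player for the between-group game); a property-style test
verifies on a thousand random games that the pure Nash set is identical
before and after.

The sign pattern of `(B, C)` classifies a within-group game
(`classify_dilemma()`): both negative is a prisoner's dilemma, both positive
a harmony game, `B > 0 > C` a snowdrift game, `B < 0 < C` a stag hunt.
Boundary games with `B = 0` or `C = 0` raise an error rather than receive an
arbitrary label, since the taxonomy is defined by strict inequalities. Note
that the taxonomy reads a game in *preference coordinates* (cooperating
means playing one's own preferred behavior); for the between-group game,
where the two players prefer different behaviors, the roles of `B` and `C`
swap, and the standard regime `C3, C4 > 0 > B3, B4` is an anti-coordination
(snowdrift) game with the two pure equilibria at mutual behavior 1 and
mutual behavior 2.

## The cohesion ratio q

A group whose internal harmony game has large payoffs loses more when a
member deviates from the internal equilibrium; it is more *cohesive*. The
relative degree of preference of group 1 is measured from the pure Nash
equilibria of the three games: the group-1 player's equilibrium payoffs,
summed over the within-group-1 and between-group games, divided by the
group-2 player's equilibrium payoffs summed over the within-group-2 and
between-group games (`compute_q_general()`). In the regime studied in the
simulations — harmony games inside both groups (`Ci, Bi > 0`, i = 1, 2) and
a snowdrift game between (`Ci > 0 > Bi`, i = 3, 4) — the within games have
unique equilibria with payoffs `(C1, C1)` and `(C2, C2)`, the between game
has the two pure equilibria `(C3, 0)` and `(0, C4)`, and the ratio collapses
to the closed form

    q = (C3 + C1) / (C4 + C2)

(`compute_q_closed()`). A property test checks the two routes agree to
1e-12 relative error on a thousand random parameter sets in the regime.

Two design choices deserve a note. First, the ratio uses **pure** equilibria
only: the closed form above follows from the pure-equilibrium sets, and
including the snowdrift game's mixed equilibrium would break it. Second,
equilibrium enumeration uses **weak** best responses (ties count), the
standard definition; it matters only on measure-zero parameter boundaries.

## Dynamics

Each round has two phases, both exactly deterministic:

1. **Payoff accumulation** (`accumulate_payoffs()`): every player plays one
   game against each of its four von Neumann neighbors (north, east, south,
   west; periodic wrap) and sums the four payoffs. Payoffs are recomputed
   from zero each round.
2. **Synchronous unconditional imitation** (`synchronous_update()`): every
   player simultaneously adopts the behavior of the highest-payoff member of
   `{self, N, E, S, W}`.

The candidate set includes the player itself: a player that is already the
(weak) payoff maximum of its neighborhood keeps its behavior. Excluding self
would force strictly-best players to switch, destroying the stable
monomorphic configurations the dynamics are supposed to settle into;
self-inclusion is the standard unconditional-imitation convention. Ties are
broken deterministically — self first, then the first of N, E, S, W — so a
trajectory is a pure function of the seed, the configuration and the
parameters. The package tests this determinism, the conservation of the
group grid, and an exact mirror symmetry: swapping all labels (group 1↔2,
behavior 1↔2) on the initial grids and exchanging the parameter roles
(`B1↔B2, C1↔C2, B3↔B4, C3↔C4`) reproduces, step for step, the label-swapped
trajectory, so `rho1'(t) = 1 - rho1(t)` exactly.

The inner loop is compiled (Rcpp); the exported R implementations of both
phases are retained as the reference, and a test checks the two engines
produce bit-identical trajectories.

## Measurement protocol

The observable is `rho1(t)`, the fraction of the population playing behavior
1 after `t` rounds (per-group fractions are recorded too, and satisfy the
weighted-sum identity with the realized group-1 fraction at every step).
A run is *converged* at the first step `t` such that the per-step
fluctuation `|rho1(s) - rho1(s-1)|` stayed below `fluct_tol = 0.01` for
`window = 500` consecutive steps ending at `t`; the steady-state fraction is
then the mean of `rho1` over the `average_window = 500` steps that follow
the detection window. Replicated experiments repeat this with consecutive
seeds (default `n_reps = 10`) and average.

Three operational choices were open and are fixed as follows:

* "Fluctuation" is read as the per-step absolute difference, the simplest
  reading; an alternative (deviation from a window mean) would change little
  because both vanish on the absorbing configurations that dominate.
* The averaging window *follows* the detection window rather than
  overlapping it.
* A hard cap `max_steps = 20000` flags (not fails) non-convergent runs, and
  a run whose detection fires too close to the cap for a full averaging
  window is reported as unconverged rather than averaged over a short
  window.

Because the dynamics are deterministic, a round that changes no behavior
fixes the configuration forever. `run_lattice()` therefore stops as soon as
an update leaves the grid unchanged, records the exact step, and takes the
(constant) current fraction as the steady state; the fluctuation criterion
is the fallback for runs that end in persistent small oscillations
(synchronous imitation admits period-2 "blinkers") rather than a fixed
point. This early exit changes no reported value — the averaging window of
a constant series is its constant — and makes sweeps cheap, since most runs
absorb within a few hundred steps.

`stabilization_step()` reports a complementary diagnostic: the first step
after which every subsequent per-step change stays below a tolerance. At
balanced group sizes (f = 0.5) and the default parameters the population
fraction hardly moves from step 1 on — a per-step change of 0.01 means 100
of 10,000 players switching at once — so the statistic is typically 0-2,
comfortably below the nominal "stable by about step 50" reading taken from
time-course figures.

## Experiments

* `sweep_f()`: steady state versus the group-1 share `f` at fixed
  parameters (the six bundled fixed-`q` parameter groups all have `q = 1`).
* `sweep_q()`: steady state versus `q` at fixed `f`. Following the published
  design, `q` is varied by rescaling only the group-2 cohesion payoffs,
  `C2 = C1 / q` and `C4 = C3 / q`, holding `[B1, B2, B3, B4, C1, C3]` fixed
  (`q_scheme()`); this hits the target ratio exactly and stays inside the
  harmony/snowdrift regime for every `q > 0`. Other parameterizations of the
  same `q` are out of scope.
* `sweep_fq()`: the full factorial surface.
* `capture_snapshots()`: the 4-state grid (group x behavior) at chosen
  steps, by convention 1, 3, 100 and 500 (steps count updates; 0 is the
  initial state), exported by `export_snapshot()` as a PNG (blue/yellow =
  behaviors 1/2 in group 1, green/red = behaviors 1/2 in group 2) plus a
  plain-text integer grid.

Replicate seeds are `seed0 + k` within a sweep point and offset by 1000
between points, all recorded in the output table and manifests, so any row
is reproducible in isolation.

A short demonstration at reduced size (a 30 x 30 lattice and a 100-step
protocol keep the vignette quick; published-scale experiments use L = 100
and the 500-step windows, which the acceptance script reruns):

```{r demo}
gs <- game_set(c(2, 2, -1, -1, 1, 1, 2, 2))
compute_q_closed(gs)

conv <- convergence_spec(window = 100, average_window = 100, max_steps = 5000)
tr <- run_lattice(gs, lattice_config(L = 30, f = 0.2, seed = 1), conv)
tr

sw <- sweep_f(c(0.1, 0.5, 0.9), gs, lattice_config(L = 30), conv,
              n_reps = 3, seed0 = 1)
summarize_sweep(sw)
```

The minority group's preferred behavior is driven out when `f` is small,
and the steady fraction rises with `f` — at equal cohesion the larger group
sets the norm.

## What the generator does and does not emulate

The initialization reproduces the study conditions: i.i.d. Bernoulli group
assignment with probability `f` (the "with probability f" wording; realized
fractions are recorded alongside the nominal value rather than forced by
shuffling an exact count) and i.i.d. 50/50 behaviors. Passing tests
therefore speak to this synthetic regime — independent spatial mixing of
groups, no geometry in the initial behavior field, fixed group membership,
exactly four neighbors. They do not speak to real crowds: correlated group
placement (families walk together), membership churn, heterogeneous degree,
or noisy/asynchronous decision rules are all outside the model.

## Numerical notes and limitations

* All state is integer; the only floating-point quantities are payoffs and
  fractions, and the two simulation engines are bit-compatible.
* With tolerance 0.01 and an `L = 100` lattice, per-step fluctuations are
  multiples of 1e-4, so the convergence comparison is far from
  representability issues. (One symmetry test on a 20 x 20 lattice uses a
  tolerance chosen strictly between attainable deltas so that a pair of
  mirrored runs cannot disagree at the boundary.)
* The pure-Nash enumeration is exhaustive over the four profiles of a 2x2
  game; n x n games and mixed equilibria are out of scope.
* `q` is undefined when the group-2 equilibrium payoffs sum to zero
  (`C2 + C4 = 0` in the closed form); both routes raise an error.
* Very long transients are cut off at `max_steps`; the flag is propagated
  into sweep tables as `converged = FALSE` rather than silently averaged.
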