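#' Construct a 2x2 bimatrix game
#'
#' A bimatrix holds the payoffs of a two-player game in which each player
#' chooses behavior 1 or behavior 2. `row_payoffs[i, j]` is the row player's
#' payoff when the row player plays behavior `i` and the column player plays
#' behavior `j`; `col_payoffs[i, j]` is the column player's payoff at the same
#' profile.
#'
#' @param row_payoffs 2x2 numeric matrix of row-player payoffs.
#' @param col_payoffs 2x2 numeric matrix of column-player payoffs.
#' @return An object of class `bimatrix`.
#' @examples
#' # mutual-cooperation harmony game
#' g <- bimatrix(rbind(c(1, 2), c(0, 0)), rbind(c(1, 0), c(2, 0)))
#' enumerate_pure_nash(g)
#' @export
bimatrix <- function(row_payoffs, col_payoffs) {
  row_payoffs <- as.matrix(row_payoffs)
  col_payoffs <- as.matrix(col_payoffs)
  if (!all(dim(row_payoffs) == c(2L, 2L)) || !all(dim(col_payoffs) == c(2L, 2L)))
    stop("a bimatrix needs two 2x2 payoff matrices")
  if (!all(is.finite(row_payoffs)) || !all(is.finite(col_payoffs)))
    stop("all payoffs must be finite")
  structure(list(row_payoffs = row_payoffs, col_payoffs = col_payoffs),
            class = "bimatrix")
}

#' @export
print.bimatrix <- function(x, ...) {
  cat("2x2 bimatrix game (row payoff, col payoff):\n")
  cells <- matrix(sprintf("(%g, %g)", x$row_payoffs, x$col_payoffs), 2, 2)
  dimnames(cells) <- list(c("behavior 1", "behavior 2"),
                          c("behavior 1", "behavior 2"))
  print(cells, quote = FALSE)
  invisible(x)
}

#' Simplified payoff parameter set for the three interaction games
#'
#' Bundles the eight payoff differences `B1..B4`, `C1..C4` that define the
#' three simplified interaction matrices of the model: the within-group-1
#' game, the between-group game (row player = group-1 member), and the
#' within-group-2 game. Group k prefers behavior k: its internal game rewards
#' mutual play of behavior k with `Ck` and unilateral play with `Bk`.
#'
#' @param params numeric vector of length 8 in the order
#'   `c(B1, B2, B3, B4, C1, C2, C3, C4)`.
#' @return An object of class `game_set`.
#' @examples
#' gs <- game_set(c(2, 2, -1, -1, 1, 1, 2, 2))
#' compute_q_closed(gs)
#' @export
game_set <- function(params) {
  params <- as.numeric(params)
  if (length(params) != 8L || !all(is.finite(params)))
    stop("params must be 8 finite numbers in the order [B1,B2,B3,B4,C1,C2,C3,C4]")
  names(params) <- c("B1", "B2", "B3", "B4", "C1", "C2", "C3", "C4")
  structure(as.list(params), class = "game_set")
}

#' @export
print.game_set <- function(x, ...) {
  cat("Simplified game set [B1,B2,B3,B4,C1,C2,C3,C4] =\n  [",
      paste(format(unlist(x), trim = TRUE), collapse = ", "), "]\n", sep = "")
  cat("within group 1:", classify_dilemma(x$B1, x$C1), "\n")
  cat("within group 2:", classify_dilemma(x$B2, x$C2), "\n")
  invisible(x)
}

#' Build the simplified within-group bimatrix
#'
#' Produces the internal game of one small group. For group 1 the preferred
#' behavior is 1 and the matrix is `[(C,C),(B,0);(0,B),(0,0)]`; for group 2
#' the preferred behavior is 2 and the matrix is the mirrored form
#' `[(0,0),(0,B);(B,0),(C,C)]`.
#'
#' @param B,C payoff differences of the simplified form.
#' @param preferred which behavior (1 or 2) the group prefers.
#' @return A [bimatrix()].
#' @export
within_game <- function(B, C, preferred = 1L) {
  if (preferred == 1L) {
    bimatrix(rbind(c(C, B), c(0, 0)), rbind(c(C, 0), c(B, 0)))
  } else if (preferred == 2L) {
    bimatrix(rbind(c(0, 0), c(B, C)), rbind(c(0, B), c(0, C)))
  } else stop("preferred must be 1 or 2")
}

#' Build the simplified between-group bimatrix
#'
#' Cross-group encounters, with the group-1 member on the row axis:
#' `[(C3,0),(B3,B4);(0,0),(0,C4)]`.
#'
#' @param B3,B4,C3,C4 payoff differences of the simplified form.
#' @return A [bimatrix()].
#' @export
between_game <- function(B3, B4, C3, C4) {
  bimatrix(rbind(c(C3, B3), c(0, 0)), rbind(c(0, B4), c(0, C4)))
}

#' The three interaction games of a parameter set
#'
#' @param games a [game_set()].
#' @return A list with elements `within1`, `between`, `within2`, each a
#'   [bimatrix()].
#' @export
interaction_games <- function(games) {
  stopifnot(inherits(games, "game_set"))
  list(within1 = within_game(games$B1, games$C1, preferred = 1L),
       between = between_game(games$B3, games$B4, games$C3, games$C4),
       within2 = within_game(games$B2, games$C2, preferred = 2L))
}

#' Equivalent simplification of a symmetric within-group game
#'
#' Takes a raw symmetric 2x2 game `[(r,r),(s,t);(t,s),(p,p)]` and subtracts
#' from each player's payoff a constant that depends only on the opponent's
#' choice (t when the opponent plays the preferred behavior, p otherwise).
#' Best responses, and therefore the pure Nash set, are unchanged; the game
#' collapses to the two parameters `B = s - p` and `C = r - t`.
#'
#' @param raw a [bimatrix()] with the symmetric within-group structure, i.e.
#'   `col_payoffs == t(row_payoffs)`.
#' @return A list with components `B` and `C`.
#' @examples
#' raw <- bimatrix(rbind(c(3, 0), c(1, 2)), rbind(c(3, 1), c(0, 2)))
#' simplify_within(raw)  # B = -2, C = 2: stag hunt
#' @export
simplify_within <- function(raw) {
  stopifnot(inherits(raw, "bimatrix"))
  if (!isTRUE(all.equal(raw$col_payoffs, t(raw$row_payoffs),
                        check.attributes = FALSE)))
    stop("raw game is not of the symmetric within-group structure ",
         "[(r,r),(s,t);(t,s),(p,p)]")
  A <- raw$row_payoffs
  list(B = A[1, 2] - A[2, 2], C = A[1, 1] - A[2, 1])
}

#' Equivalent simplification of the between-group game
#'
#' Takes the raw cross-group game `[(R1,P2),(S1,S2);(T1,T2),(P1,R2)]` (row
#' player = group-1 member) and removes opponent-choice-dependent constants
#' from both players' payoffs, yielding the four between-group parameters.
#' The pure Nash set is preserved.
#'
#' @param raw a [bimatrix()] with the between-group structure.
#' @return A list with components `B3 = S1 - P1`, `C3 = R1 - T1`,
#'   `B4 = S2 - P2`, `C4 = R2 - T2`.
#' @export
simplify_between <- function(raw) {
  stopifnot(inherits(raw, "bimatrix"))
  A <- raw$row_payoffs
  D <- raw$col_payoffs
  list(B3 = A[1, 2] - A[2, 2], C3 = A[1, 1] - A[2, 1],
       B4 = D[1, 2] - D[1, 1], C4 = D[2, 2] - D[2, 1])
}

#' Classify a simplified within-group game into its social dilemma
#'
#' The simplified form `[(C,C),(B,0);(0,B),(0,0)]` falls into one of four
#' dilemmas by the signs of B and C: both negative is a prisoner's dilemma
#' (unique equilibrium at mutual defection from the preferred behavior),
#' both positive a harmony game (unique equilibrium at mutual preferred
#' behavior), B positive / C negative a snowdrift game (two anti-coordination
#' equilibria) and B negative / C positive a stag hunt (two coordination
#' equilibria).
#'
#' @param B,C payoff differences of the simplified form; both must be
#'   nonzero (the boundary games are degenerate and unclassified).
#' @return One of `"prisoners_dilemma"`, `"harmony"`, `"snowdrift"`,
#'   `"stag_hunt"`.
#' @export
classify_dilemma <- function(B, C) {
  stopifnot(is.finite(B), is.finite(C))
  if (B == 0 || C == 0)
    stop("degenerate game: B = 0 or C = 0 lies on a classification boundary")
  if (B < 0 && C < 0) "prisoners_dilemma"
  else if (B > 0 && C > 0) "harmony"
  else if (B > 0 && C < 0) "snowdrift"
  else "stag_hunt"
}

#' Enumerate the pure-strategy Nash equilibria of a 2x2 bimatrix
#'
#' Checks all four pure profiles for mutual (weak) best responses: a profile
#' is an equilibrium when neither player can strictly gain by a unilateral
#' deviation. Ties count as equilibria.
#'
#' @param game a [bimatrix()].
#' @return An object of class `nash_set`: a data.frame with columns
#'   `row_behavior`, `col_behavior`, `row_payoff`, `col_payoff`, one row per
#'   equilibrium profile (possibly zero rows).
#' @examples
#' enumerate_pure_nash(within_game(B = 10, C = 10, preferred = 2))
#' @export
enumerate_pure_nash <- function(game) {
  stopifnot(inherits(game, "bimatrix"))
  A <- game$row_payoffs
  D <- game$col_payoffs
  out <- data.frame(row_behavior = integer(), col_behavior = integer(),
                    row_payoff = numeric(), col_payoff = numeric())
  for (i in 1:2) for (j in 1:2) {
    if (A[i, j] >= A[3 - i, j] && D[i, j] >= D[i, 3 - j])
      out[nrow(out) + 1L, ] <- list(i, j, A[i, j], D[i, j])
  }
  class(out) <- c("nash_set", class(out))
  out
}

#' @export
print.nash_set <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("no pure-strategy Nash equilibrium\n")
  } else {
    cat("pure-strategy Nash equilibria:\n")
    for (k in seq_len(nrow(x)))
      cat(sprintf("  (%d, %d) with payoffs (%g, %g)\n",
                  x$row_behavior[k], x$col_behavior[k],
                  x$row_payoff[k], x$col_payoff[k]))
  }
  invisible(x)
}

#' Relative degree of preference q from Nash-equilibrium payoffs
#'
#' The cohesion of small group 1 relative to small group 2, defined from the
#' pure Nash equilibria of the three interaction games: the numerator sums the
#' group-1 player's equilibrium payoffs over the within-group-1 and
#' between-group games; the denominator sums the group-2 player's equilibrium
#' payoffs over the within-group-2 and between-group games. q > 1 means group
#' 1 loses more by deviating from its equilibrium, i.e. coheres more strongly.
#'
#' @param games a [game_set()].
#' @return A single positive number.
#' @seealso [compute_q_closed()] for the closed form valid in the
#'   harmony-within / snowdrift-between regime.
#' @export
compute_q_general <- function(games) {
  g <- interaction_games(games)
  ne1 <- enumerate_pure_nash(g$within1)
  ne2 <- enumerate_pure_nash(g$between)
  ne3 <- enumerate_pure_nash(g$within2)
  num <- sum(ne1$row_payoff) + sum(ne2$row_payoff)
  den <- sum(ne3$row_payoff) + sum(ne2$col_payoff)
  if (den == 0)
    stop("q is undefined: group-2 equilibrium payoffs sum to zero")
  num / den
}

#' Relative degree of preference q, closed form
#'
#' In the regime where both internal games are harmony games and the
#' between-group game is a snowdrift game (all `Ci > 0`, `B1, B2 > 0`,
#' `B3, B4 < 0`), the Nash-payoff ratio reduces to
#' `q = (C3 + C1) / (C4 + C2)`.
#'
#' @param C1,C2,C3,C4 the four mutual-preference payoffs, or pass a
#'   [game_set()] as `C1` and leave the rest missing.
#' @return A single number.
#' @export
compute_q_closed <- function(C1, C2, C3, C4) {
  if (inherits(C1, "game_set")) {
    gs <- C1
    C1 <- gs$C1; C2 <- gs$C2; C3 <- gs$C3; C4 <- gs$C4
  }
  if (C4 + C2 == 0) stop("q is undefined: C4 + C2 = 0")
  (C3 + C1) / (C4 + C2)
}
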