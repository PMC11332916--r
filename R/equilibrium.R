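# Static analysis of the blossom game as a singleton congestion game with
# player-specific payoffs: Nash verification, greedy construction of
# preference-ordered equilibria, and exhaustive enumeration on tiny
# instances (the oracle for the constructive routine).

attendance_of <- function(assignment, n_days) {
  tabulate(assignment[assignment != HOME], nbins = n_days)
}

#' Total welfare of a static assignment
#'
#' @param assignment Integer vector over players: a day or [HOME].
#' @param m Numeric vector of preferences.
#' @param bloom A [bloom_profile].
#' @param z,c Capacity threshold and disappointment cost.
#' @return Sum of all players' utilities under [day_utility()] /
#'   [home_utility()].
#' @export
assignment_welfare <- function(assignment, m, bloom, z, c) {
  sum(assignment_utilities(assignment, m, bloom, z, c))
}

assignment_utilities <- function(assignment, m, bloom, z, c) {
  k <- as.numeric(bloom)
  att <- attendance_of(assignment, length(k))
  u <- numeric(length(assignment))
  vis <- assignment != HOME
  if (any(vis))
    u[vis] <- day_utility(m[vis], k[assignment[vis]], att[assignment[vis]], z, c)
  u
}

#' Test whether an assignment is a Nash equilibrium
#'
#' An assignment is a (pure) Nash equilibrium when no player can *strictly*
#' improve by a unilateral deviation: a visitor compares its utility against
#' staying home (0) and against joining any other day `d'` with anticipated
#' crowd `n(d') + 1`; a home player compares 0 against joining each day the
#' same way.  Ties never break an equilibrium.
#'
#' @inheritParams assignment_welfare
#' @return A list: `is_nash` (logical) and, when `FALSE`, `witness` — a
#'   list with the deviating `player`, its `target` (day or [HOME]), and
#'   the utility `gain`.
#' @examples
#' b <- default_bloom(19)
#' is_nash(c(10L), m = 2, bloom = b, z = 0.1, c = 1)$is_nash  # lone visitor
#' @export
is_nash <- function(assignment, m, bloom, z, c) {
  k <- as.numeric(bloom)
  n_days <- length(k)
  n <- length(assignment)
  att <- attendance_of(assignment, n_days)
  current <- assignment_utilities(assignment, m, bloom, z, c)

  # Anticipated utility of player i moving to day d: crowd att[d] + 1,
  # except that "moving" to the player's own day is not a deviation.
  crowd <- matrix(rep(att + 1L, each = n), nrow = n, ncol = n_days)
  value <- outer(m, k) / crowd
  dev <- ifelse(value >= z, value, -c)
  vis <- assignment != HOME
  if (any(vis)) dev[cbind(which(vis), assignment[vis])] <- -Inf

  tol <- 1e-12
  for (i in seq_len(n)) {
    best_day <- which.max(dev[i, ])
    best_day_u <- dev[i, best_day]
    home_u <- if (vis[i]) 0 else -Inf   # home is a deviation only for visitors
    best <- max(best_day_u, home_u)
    if (best > current[i] + tol) {
      target <- if (best_day_u >= home_u) as.integer(best_day) else HOME
      return(list(is_nash = FALSE,
                  witness = list(player = i, target = target,
                                 gain = best - current[i])))
    }
  }
  list(is_nash = TRUE, witness = NULL)
}

#' Greedy construction of a preference-ordered Nash equilibrium
#'
#' Players are processed in descending preference order (ties shuffled
#' randomly).  Each player is placed on the day that maximises its own
#' utility among *feasible* days — days where its arrival leaves every
#' current occupant, and the player itself, at or above the capacity
#' threshold; ties between equally good days are broken uniformly at
#' random.  A player with no feasible day stays home.  The filling of the
#' season until no one can be added without someone going negative yields
#' the winner-takes-all equilibria of the game; whether the constructed
#' equilibrium attains maximal welfare can be audited against
#' [enumerate_equilibria()] on small instances.
#'
#' @inheritParams assignment_welfare
#' @param fill `"best_day"` (default) places each player on its
#'   own-utility-maximising feasible day; `"peak_first"` places it on the
#'   feasible day of largest abundance.
#' @return Integer assignment vector (in the original player order).
#' @export
construct_optimal_ne <- function(m, bloom, z, c, fill = c("best_day", "peak_first")) {
  fill <- match.arg(fill)
  k <- as.numeric(bloom)
  n_days <- length(k)
  n <- length(m)
  ord <- order(-m, stats::runif(n))
  att <- integer(n_days)
  min_m <- rep(Inf, n_days)   # weakest occupant per day
  assignment <- rep(HOME, n)

  for (i in ord) {
    # adding player i to day d leaves everyone >= z iff the weakest of
    # (current occupants, i) clears the threshold at crowd att[d] + 1
    feasible <- pmin(min_m, m[i]) * k / (att + 1L) >= z
    if (!any(feasible)) next
    score <- if (fill == "best_day") m[i] * k / (att + 1L) else k
    score[!feasible] <- -Inf
    best <- which(score == max(score))
    d <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
    assignment[i] <- d
    att[d] <- att[d] + 1L
    min_m[d] <- min(min_m[d], m[i])
  }
  assignment
}

#' Exhaustively enumerate pure Nash equilibria
#'
#' Tests every one of the `(n_days + 1)^n` assignments of `n` players to
#' days-or-home with [is_nash()].  Intended as an oracle on tiny fixtures;
#' instances beyond `cap` assignments are rejected.
#'
#' @inheritParams assignment_welfare
#' @param cap Maximum number of assignments to enumerate (default `1e6`).
#' @return A list with one element per equilibrium, each a list holding
#'   `assignment` and `welfare`.
#' @examples
#' eqs <- enumerate_equilibria(m = c(1, 1), bloom = bloom_profile(c(1, 2)),
#'                             z = 0.1, c = 1)
#' length(eqs)
#' @export
enumerate_equilibria <- function(m, bloom, z, c, cap = 1e6) {
  n <- length(m)
  n_days <- length(bloom)
  n_assign <- (n_days + 1)^n
  if (n_assign > cap)
    stop(sprintf("instance has %.0f assignments, over the enumeration cap of %.0f",
                 n_assign, cap), call. = FALSE)
  out <- list()
  assignment <- rep(HOME, n)
  for (idx in seq_len(n_assign) - 1L) {
    rem <- idx
    for (j in seq_len(n)) {
      assignment[j] <- rem %% (n_days + 1L)
      rem <- rem %/% (n_days + 1L)
    }
    if (is_nash(assignment, m, bloom, z, c)$is_nash) {
      out[[length(out) + 1L]] <- list(
        assignment = as.integer(assignment),
        welfare = assignment_welfare(assignment, m, bloom, z, c))
    }
  }
  out
}
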