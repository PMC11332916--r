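# Decision rules: bloom-weighted initial draw, the local-knowledge and
# global-knowledge next-season updates, and the multiplicative learning decay.
# All rules are vectorised over agents; randomness comes from the calling
# R session's RNG stream (the engine manages named streams on top).

#' Bloom-weighted initial day choice
#'
#' Every agent's first choice is a day drawn with probability proportional
#' to the flower abundance, `P(d) = K(d) / sum(K)`; the home option is never
#' part of the initial draw.
#'
#' @param n Number of draws (one per agent).
#' @param bloom A [bloom_profile].
#' @return Integer vector of day indices.
#' @examples
#' set.seed(1)
#' table(initial_choice(1000, default_bloom(19)))
#' @export
initial_choice <- function(n, bloom) {
  k <- as.numeric(bloom)
  if (length(k) == 1L) return(rep(1L, n))
  sample.int(length(k), size = n, replace = TRUE, prob = k / sum(k))
}

#' Local-knowledge update rule
#'
#' Satisficing agents with strictly positive utility repeat their choice.
#' An agent with zero or negative utility (home-stayers included, since home
#' pays 0) stays home with probability `1 - p` and otherwise re-draws a
#' bloom-weighted day, exactly as in [initial_choice()]; home is excluded
#' from the re-draw itself.
#'
#' @param choice Integer vector of current choices (day or [HOME]).
#' @param utility Numeric vector of last-season utilities.
#' @param p Numeric vector of per-agent exploration probabilities.
#' @param bloom A [bloom_profile].
#' @return Integer vector of next-season choices.
#' @export
local_update <- function(choice, utility, p, bloom) {
  out <- as.integer(choice)
  unhappy <- which(utility <= 0)
  if (length(unhappy)) {
    explore <- stats::runif(length(unhappy)) < p[unhappy]
    out[unhappy] <- HOME
    ex <- unhappy[explore]
    if (length(ex)) out[ex] <- initial_choice(length(ex), bloom)
  }
  out
}

#' Global-knowledge (best-response) update rule
#'
#' As in [local_update()], a satisfied agent repeats its choice and a
#' dissatisfied agent stays home with probability `1 - p`.  With probability
#' `p`, instead of a blind re-draw, the agent uses the published attendance
#' of the previous season: for every day it anticipates the utility
#' `day_utility(m, K(d), n_last(d) + 1, z, c)` of joining that day (adding
#' itself to the remembered crowd), and picks a day attaining the maximum
#' anticipated utility, ties broken uniformly at random.  If no day has a
#' positive anticipated utility it stays home.
#'
#' With `subtract_self = TRUE` the agent first removes itself from the
#' remembered attendance of the day it actually attended, so the anticipated
#' crowd on its own day is `n_last(d)` rather than `n_last(d) + 1`.
#'
#' @inheritParams local_update
#' @param m Numeric vector of preferences.
#' @param last_attendance Integer vector of per-day attendance from the
#'   previous season.
#' @param z,c Capacity threshold and disappointment cost (see
#'   [day_utility()]).
#' @param subtract_self Logical; see Details.
#' @return Integer vector of next-season choices.
#' @export
global_update <- function(choice, utility, p, m, last_attendance, bloom,
                          z, c, subtract_self = FALSE) {
  out <- as.integer(choice)
  unhappy <- which(utility <= 0)
  if (!length(unhappy)) return(out)
  explore <- stats::runif(length(unhappy)) < p[unhappy]
  out[unhappy] <- HOME
  ex <- unhappy[explore]
  if (!length(ex)) return(out)

  k <- as.numeric(bloom)
  n_days <- length(k)
  n_ex <- length(ex)
  anticipated <- matrix(rep(last_attendance + 1, each = n_ex),
                        nrow = n_ex, ncol = n_days)
  if (subtract_self) {
    own <- choice[ex]
    attended <- own != HOME
    if (any(attended))
      anticipated[cbind(which(attended), own[attended])] <-
        last_attendance[own[attended]]
  }
  value <- outer(m[ex], k) / anticipated
  u <- ifelse(value >= z, value, -c)
  best <- max.col(u, ties.method = "random")
  best_u <- u[cbind(seq_len(n_ex), best)]
  out[ex] <- ifelse(best_u > 0, best, HOME)
  out
}

#' Multiplicative exploration decay
#'
#' After a strictly negative season the agent's exploration probability is
#' multiplied by the learning constant `L`; zero-utility (home) seasons
#' leave `p` untouched, so staying home several seasons in a row decays `p`
#' only once, after the failure that sent the agent home.  `L = 1` disables
#' learning.
#'
#' @param p Numeric vector of exploration probabilities in (0, 1].
#' @param last_utility Numeric vector of last-season utilities.
#' @param L Learning multiplier in (0, 1].
#' @return Updated probabilities: `p * L` where `last_utility < 0`, else `p`.
#' @examples
#' learning_update(0.5, last_utility = -1, L = 0.5)  # 0.25
#' learning_update(0.5, last_utility = 0, L = 0.5)   # 0.5
#' @export
learning_update <- function(p, last_utility, L) {
  ifelse(last_utility < 0, p * L, p)
}
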