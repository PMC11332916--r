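# Core domain objects for the blossom game: configuration, bloom profile,
# per-visit utility and single-season payoff accounting.

#' Sentinel value for the stay-at-home option
#'
#' Day choices are integers in `1:n_days`; `HOME` (`0L`) marks an agent that
#' stays out of the game for a season (or a bat that remains at its roost).
#'
#' @export
HOME <- 0L

#' Blossom game configuration
#'
#' Builds a validated configuration for [run_game()]. The defaults are the
#' reference study conditions: 2000 heterogeneous players on a 19-day season
#' with a triangular bloom peaking mid-season, capacity parameter `z = 0.1`,
#' exploration probability 0.5, learning multiplier 0.5, and 100 seasons.
#'
#' @param n_players Positive integer, number of agents (default 2000).
#' @param n_days Positive integer, length of the blossom season in days.
#' @param z Positive real; a visit succeeds iff `m * K(d) / n(d) >= z`.
#' @param pref_low,pref_high Bounds of the uniform preference draw; the
#'   preference `m` measures how much an agent values the visit. `pref_low`
#'   must be at least 1.
#' @param disappointment_cost Non-negative magnitude `c`; a failed visit
#'   yields utility `-c`.
#' @param p_init Initial exploration probability, in (0, 1].
#' @param learning_L Multiplier applied to `p` after each strictly negative
#'   season, in (0, 1]. `learning_L = 1` disables learning.
#' @param info_mode `"local"` (agents only know their own outcome) or
#'   `"global"` (agents know the full attendance vector of the last season).
#' @param n_seasons Positive integer, number of seasons to simulate.
#' @param turnover_fraction Fraction of the population replaced by fresh,
#'   memory-free agents at the start of each season after the first; in
#'   `[0, 1)`.
#' @param seed Integer RNG seed; a fixed seed makes a run bit-reproducible.
#' @param subtract_self If `TRUE`, a global-mode agent anticipating next
#'   season's crowding removes itself from the remembered attendance of its
#'   own previous day before adding itself back. Default `FALSE`: the agent
#'   adds itself to the remembered attendance of every day as-is.
#'
#' @return An object of class `blossom_config` (a named list).
#' @examples
#' cfg <- game_config(n_players = 100, n_seasons = 10, seed = 1)
#' cfg$z
#' @export
game_config <- function(n_players = 2000L,
                        n_days = 19L,
                        z = 0.1,
                        pref_low = 1,
                        pref_high = 3,
                        disappointment_cost = 1,
                        p_init = 0.5,
                        learning_L = 0.5,
                        info_mode = c("local", "global"),
                        n_seasons = 100L,
                        turnover_fraction = 0,
                        seed = 1L,
                        subtract_self = FALSE) {
  info_mode <- match.arg(info_mode)
  cfg <- list(
    n_players = as.integer(n_players),
    n_days = as.integer(n_days),
    z = as.numeric(z),
    pref_low = as.numeric(pref_low),
    pref_high = as.numeric(pref_high),
    disappointment_cost = as.numeric(disappointment_cost),
    p_init = as.numeric(p_init),
    learning_L = as.numeric(learning_L),
    info_mode = info_mode,
    n_seasons = as.integer(n_seasons),
    turnover_fraction = as.numeric(turnover_fraction),
    seed = as.integer(seed),
    subtract_self = isTRUE(subtract_self)
  )
  class(cfg) <- "blossom_config"
  validate_game_config(cfg)
}

validate_game_config <- function(cfg) {
  stop_if <- function(bad, msg) if (bad) stop(msg, call. = FALSE)
  stop_if(is.na(cfg$n_players) || cfg$n_players < 1L, "n_players must be a positive integer")
  stop_if(is.na(cfg$n_days) || cfg$n_days < 1L, "n_days must be a positive integer")
  stop_if(!is.finite(cfg$z) || cfg$z <= 0, "z must be positive")
  stop_if(cfg$pref_low < 1, "pref_low must be >= 1")
  stop_if(cfg$pref_high < cfg$pref_low, "pref_high must be >= pref_low")
  stop_if(cfg$disappointment_cost < 0, "disappointment_cost must be non-negative")
  stop_if(!is.finite(cfg$p_init) || cfg$p_init <= 0 || cfg$p_init > 1,
          "p_init must be in (0, 1]")
  stop_if(!is.finite(cfg$learning_L) || cfg$learning_L <= 0 || cfg$learning_L > 1,
          "learning_L must be in (0, 1]")
  stop_if(is.na(cfg$n_seasons) || cfg$n_seasons < 1L, "n_seasons must be a positive integer")
  stop_if(!is.finite(cfg$turnover_fraction) || cfg$turnover_fraction < 0 ||
            cfg$turnover_fraction >= 1, "turnover_fraction must be in [0, 1)")
  stop_if(is.na(cfg$seed), "seed must be an integer")
  cfg
}

#' @export
print.blossom_config <- function(x, ...) {
  cat(sprintf(
    "<blossom_config> N=%d, %d days, %d seasons, z=%g, p=%g, L=%g, mode=%s%s, seed=%d\n",
    x$n_players, x$n_days, x$n_seasons, x$z, x$p_init, x$learning_L,
    x$info_mode,
    if (x$turnover_fraction > 0) sprintf(", turnover=%g", x$turnover_fraction) else "",
    x$seed))
  invisible(x)
}

#' Bloom profile: per-day flower abundance
#'
#' `bloom_profile()` wraps a vector of strictly positive abundances
#' `K(d)`; `default_bloom()` builds the triangular profile
#' `K(i) = min(i, n_days + 1 - i)`, symmetric with a single interior
#' maximum (for a 19-day season, `K(10) = 10` and the abundances sum to 100).
#'
#' @param k Numeric vector of strictly positive per-day abundances.
#' @param n_days Positive integer season length.
#' @return An object of class `bloom_profile` (a numeric vector).
#' @examples
#' b <- default_bloom(19)
#' b[10]
#' sum(b)
#' @export
bloom_profile <- function(k) {
  k <- as.numeric(k)
  if (length(k) < 1L || anyNA(k) || any(k <= 0))
    stop("bloom profile must be a non-empty vector of positive abundances",
         call. = FALSE)
  structure(k, class = "bloom_profile")
}

#' @rdname bloom_profile
#' @export
default_bloom <- function(n_days) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L)
    stop("n_days must be a positive integer", call. = FALSE)
  i <- seq_len(n_days)
  bloom_profile(pmin(i, n_days + 1L - i))
}

#' Utility of a single visit
#'
#' A visitor with preference `m` on a day with abundance `k_d` shared among
#' `n_d` visitors (the visitor itself included) receives `m * k_d / n_d` when
#' that quantity is at least the capacity threshold `z`, and the
#' disappointment payoff `-c` otherwise.  The threshold is agent-specific:
#' on the same crowded day a high-`m` visitor may succeed while a low-`m`
#' visitor fails.  Staying home ([home_utility()]) always yields 0, so a
#' visit utility is never in the open interval `(-c, z)` excluding `-c`.
#'
#' All arguments are vectorised.
#'
#' @param m Preference(s), `>= 1`.
#' @param k_d Day abundance(s), positive.
#' @param n_d Attendance count(s), at least 1 (a chosen day always has at
#'   least its own chooser present).
#' @param z Capacity threshold, positive.
#' @param c Disappointment cost magnitude, non-negative.
#' @return Numeric vector of utilities.
#' @examples
#' day_utility(m = 2, k_d = 10, n_d = 40, z = 0.1, c = 1)   # 0.5
#' day_utility(m = 1, k_d = 10, n_d = 101, z = 0.1, c = 1)  # -1
#' @export
day_utility <- function(m, k_d, n_d, z, c) {
  if (any(n_d < 1L))
    stop("n_d must be >= 1: a chosen day counts its own chooser", call. = FALSE)
  v <- m * k_d / n_d
  ifelse(v >= z, v, -c)
}

#' @rdname day_utility
#' @export
home_utility <- function() 0

#' Score one season of the blossom game
#'
#' Tallies attendance, applies [day_utility()] to every visitor and
#' [home_utility()] to every home-stayer, and assembles a `season_record`.
#'
#' @param choices Integer vector of length `n_players`: a day in
#'   `1:cfg$n_days` or [HOME].
#' @param m Numeric vector of player preferences (same length as `choices`).
#' @param bloom A [bloom_profile] of length `cfg$n_days`.
#' @param cfg A [game_config()].
#' @param season Season index stored in the record.
#' @param prev_choices Previous season's choices, used to count changers;
#'   `NULL` for the first season (changers = 0 by convention).
#' @return A list with `utilities` (numeric vector) and `record`, a
#'   `season_record` with fields `season`, `attendance` (per-day counts),
#'   `home_count`, `mean_utility_by_day` (`NA` on empty days), `changers`,
#'   and `total_welfare`. `sum(attendance) + home_count == n_players` always.
#' @examples
#' cfg <- game_config(n_players = 3, n_days = 19, seed = 1)
#' b <- default_bloom(19)
#' season_payoffs(c(10L, 10L, 10L), m = c(1, 2, 3), bloom = b, cfg = cfg)$utilities
#' @export
season_payoffs <- function(choices, m, bloom, cfg, season = 1L,
                           prev_choices = NULL) {
  n <- cfg$n_players
  if (length(choices) != n)
    stop("choices must have one entry per player", call. = FALSE)
  if (length(bloom) != cfg$n_days)
    stop("bloom profile length must equal n_days", call. = FALSE)
  bad <- choices < 0L | choices > cfg$n_days | is.na(choices)
  if (any(bad))
    stop("choices must be HOME (0) or a day in 1..n_days", call. = FALSE)

  visiting <- choices != HOME
  attendance <- tabulate(choices[visiting], nbins = cfg$n_days)
  utilities <- numeric(n)
  if (any(visiting)) {
    d <- choices[visiting]
    utilities[visiting] <- day_utility(
      m = m[visiting], k_d = as.numeric(bloom)[d], n_d = attendance[d],
      z = cfg$z, c = cfg$disappointment_cost)
  }

  mean_by_day <- rep(NA_real_, cfg$n_days)
  if (any(visiting)) {
    sums <- vapply(split(utilities[visiting], factor(choices[visiting],
                                                     levels = seq_len(cfg$n_days))),
                   sum, numeric(1))
    occ <- attendance > 0L
    mean_by_day[occ] <- sums[occ] / attendance[occ]
  }

  changers <- if (is.null(prev_choices)) 0L else sum(choices != prev_choices)
  record <- structure(list(
    season = as.integer(season),
    attendance = attendance,
    home_count = sum(!visiting),
    mean_utility_by_day = mean_by_day,
    changers = as.integer(changers),
    total_welfare = sum(utilities)
  ), class = "season_record")
  list(utilities = utilities, record = record)
}
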