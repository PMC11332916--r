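# Waterhole variant: typed agents partitioning nightly visitation slots,
# with a same-type affinity term in the utility and local information only.

#' Sentinel for the stay-at-roost option
#' @export
ROOST <- 0L

#' Bat waterhole game configuration
#'
#' The waterhole game discretises the night into `n_slots` visitation slots
#' (minutes-after-sunset intervals).  Each bat belongs to one of `n_types`
#' species; its utility at a slot scales with the waterhole capacity `z`
#' (the maximum number of bats that can jointly access the water) and with
#' the fraction of same-type bats in the slot, so mixed slots are worse for
#' the minority type.  Information is local and learning is the same
#' multiplicative decay as in the blossom game.
#'
#' @param n_bats Positive integer, population size (default 500).
#' @param n_slots Positive integer, number of time slots (default 11).
#' @param n_types Positive integer, number of bat types (default 5).
#' @param type_proportions Numeric vector of length `n_types` summing to 1;
#'   default uniform. Bat `i`'s type is fixed at construction by these
#'   proportions (largest-remainder rounding, deterministic).
#' @param z Waterhole capacity in bats (default 60: eleven pure slots then
#'   hold 660 bats, so a 500-bat population fits while a 2000-bat population
#'   exceeds capacity).
#' @param c Energy-waste magnitude of a failed visit (default 1).
#' @param p_init,L Exploration probability and learning multiplier, as in
#'   [game_config()].
#' @param n_days Number of simulated days (default 100); the waterhole
#'   refills between days, so payoffs are independent across days given the
#'   choices.
#' @param seed Integer RNG seed.
#' @param type_term `"fraction"` (default) reads the same-type term of the
#'   utility as the *share* of slot attendance of the bat's own type;
#'   `"count"` reads it as the raw same-type count.
#' @return An object of class `bat_config`.
#' @export
bat_config <- function(n_bats = 500L,
                       n_slots = 11L,
                       n_types = 5L,
                       type_proportions = NULL,
                       z = 60,
                       c = 1,
                       p_init = 0.5,
                       L = 0.5,
                       n_days = 100L,
                       seed = 1L,
                       type_term = c("fraction", "count")) {
  type_term <- match.arg(type_term)
  if (is.null(type_proportions))
    type_proportions <- rep(1 / n_types, n_types)
  cfg <- list(
    n_bats = as.integer(n_bats),
    n_slots = as.integer(n_slots),
    n_types = as.integer(n_types),
    type_proportions = as.numeric(type_proportions),
    z = as.numeric(z),
    c = as.numeric(c),
    p_init = as.numeric(p_init),
    L = as.numeric(L),
    n_days = as.integer(n_days),
    seed = as.integer(seed),
    type_term = type_term
  )
  class(cfg) <- "bat_config"
  validate_bat_config(cfg)
}

validate_bat_config <- function(cfg) {
  stop_if <- function(bad, msg) if (bad) stop(msg, call. = FALSE)
  stop_if(is.na(cfg$n_bats) || cfg$n_bats < 1L, "n_bats must be a positive integer")
  stop_if(is.na(cfg$n_slots) || cfg$n_slots < 1L, "n_slots must be a positive integer")
  stop_if(is.na(cfg$n_types) || cfg$n_types < 1L, "n_types must be a positive integer")
  stop_if(cfg$n_types > cfg$n_bats, "n_types must not exceed n_bats")
  stop_if(length(cfg$type_proportions) != cfg$n_types,
          "type_proportions must have one entry per type")
  stop_if(any(cfg$type_proportions < 0) ||
            abs(sum(cfg$type_proportions) - 1) > 1e-8,
          "type_proportions must be non-negative and sum to 1")
  stop_if(!is.finite(cfg$z) || cfg$z <= 0, "z must be positive")
  stop_if(cfg$c < 0, "c must be non-negative")
  stop_if(cfg$p_init <= 0 || cfg$p_init > 1, "p_init must be in (0, 1]")
  stop_if(cfg$L <= 0 || cfg$L > 1, "L must be in (0, 1]")
  stop_if(is.na(cfg$n_days) || cfg$n_days < 1L, "n_days must be a positive integer")
  cfg
}

#' @export
print.bat_config <- function(x, ...) {
  cat(sprintf(
    "<bat_config> %d bats, %d slots, %d types, z=%g, p=%g, L=%g, %d days, seed=%d\n",
    x$n_bats, x$n_slots, x$n_types, x$z, x$p_init, x$L, x$n_days, x$seed))
  invisible(x)
}

#' Utility of one bat's waterhole visit
#'
#' A bat in a slot attended by `n_d` bats, `n_same` of which share its type
#' (itself included), receives `(z / n_d) * (n_same / n_d)` when that value
#' is at least 1, and `-c` otherwise — crowding beyond the waterhole
#' capacity `z`, or being too small a minority, makes the trip a waste of
#' energy.  A bat at its roost receives 0.  With `type_term = "count"` the
#' same-type term is the raw count `n_same` instead of the share.
#'
#' Vectorised over all count arguments.
#'
#' @param n_d Slot attendance, at least 1.
#' @param n_same Same-type attendance, between 1 and `n_d`.
#' @param z Waterhole capacity in bats.
#' @param c Energy-waste magnitude.
#' @param type_term `"fraction"` or `"count"`; see [bat_config()].
#' @return Numeric vector of utilities.
#' @examples
#' bat_utility(n_d = 10, n_same = 10, z = 20, c = 1)  # 2.0
#' bat_utility(n_d = 30, n_same = 15, z = 20, c = 1)  # -1
#' @export
bat_utility <- function(n_d, n_same, z, c, type_term = "fraction") {
  if (any(n_d < 1L))
    stop("n_d must be >= 1: a chosen slot counts its own chooser", call. = FALSE)
  if (any(n_same < 1L) || any(n_same > n_d))
    stop("n_same must satisfy 1 <= n_same <= n_d (the bat counts itself)",
         call. = FALSE)
  term <- if (identical(type_term, "count")) n_same else n_same / n_d
  v <- (z / n_d) * term
  ifelse(v >= 1, v, -c)
}

# Deterministic type assignment by largest-remainder apportionment.
assign_types <- function(n, proportions) {
  quota <- n * proportions
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  rep(seq_along(proportions), times = counts)
}

#' Run the bat waterhole game
#'
#' Day 1 assigns every bat a uniformly random slot (never the roost).  A bat
#' with positive utility repeats its slot; otherwise it stays at the roost
#' with probability `1 - p` and re-draws a uniform slot with probability
#' `p`.  Exploration decays as in [learning_update()] after each strictly
#' negative day.
#'
#' @param cfg A [bat_config()].
#' @return A `tpg_run` (with `kind = "bats"`) whose extra fields are
#'   `types` (per-bat type), `slot_types` (a days x slots x types count
#'   array), and whose `final_players` data frame carries a `type` column.
#'   `attendance` is the days x slots matrix; roost counts are
#'   `n_bats - rowSums(attendance)`.
#' @examples
#' res <- run_bat_game(bat_config(n_bats = 50, n_days = 20, seed = 3))
#' slot_dominance(final_slot_types(res))
#' @export
run_bat_game <- function(cfg) {
  validate_bat_config(cfg)
  n <- cfg$n_bats
  streams <- rng_streams(cfg$seed, c("init", "choices"))

  type <- assign_types(n, cfg$type_proportions)
  p <- rep(cfg$p_init, n)
  choice <- with_stream(streams, "init", sample.int(cfg$n_slots, n, replace = TRUE))
  n_negative <- integer(n)

  records <- vector("list", cfg$n_days)
  changer_series <- integer(cfg$n_days)
  attendance <- matrix(0L, cfg$n_days, cfg$n_slots)
  utility_history <- matrix(NA_real_, cfg$n_days, n)
  choices_history <- matrix(NA_integer_, cfg$n_days, n)
  slot_types <- array(0L, dim = c(cfg$n_days, cfg$n_slots, cfg$n_types))
  utilities <- numeric(n)
  prev_choice <- NULL

  for (t in seq_len(cfg$n_days)) {
    if (t > 1L) {
      choice <- with_stream(streams, "choices", {
        out <- choice
        unhappy <- which(utilities <= 0)
        if (length(unhappy)) {
          explore <- stats::runif(length(unhappy)) < p[unhappy]
          out[unhappy] <- ROOST
          ex <- unhappy[explore]
          if (length(ex)) out[ex] <- sample.int(cfg$n_slots, length(ex),
                                                replace = TRUE)
        }
        out
      })
    }

    visiting <- choice != ROOST
    tally <- matrix(0L, cfg$n_slots, cfg$n_types)
    if (any(visiting)) {
      tt <- table(factor(choice[visiting], levels = seq_len(cfg$n_slots)),
                  factor(type[visiting], levels = seq_len(cfg$n_types)))
      tally <- matrix(as.integer(tt), cfg$n_slots, cfg$n_types)
    }
    slot_att <- rowSums(tally)
    utilities <- numeric(n)
    if (any(visiting)) {
      vi <- which(visiting)
      utilities[vi] <- bat_utility(
        n_d = slot_att[choice[vi]],
        n_same = tally[cbind(choice[vi], type[vi])],
        z = cfg$z, c = cfg$c, type_term = cfg$type_term)
    }

    mean_by_slot <- rep(NA_real_, cfg$n_slots)
    if (any(visiting)) {
      vi <- which(visiting)
      sums <- vapply(split(utilities[vi],
                           factor(choice[vi], levels = seq_len(cfg$n_slots))),
                     sum, numeric(1))
      occ <- slot_att > 0
      mean_by_slot[occ] <- sums[occ] / slot_att[occ]
    }

    n_negative <- n_negative + as.integer(utilities < 0)
    p <- learning_update(p, utilities, cfg$L)

    changer_series[t] <- if (is.null(prev_choice)) 0L else
      sum(choice != prev_choice)
    records[[t]] <- structure(list(
      season = t,
      attendance = as.integer(slot_att),
      home_count = sum(!visiting),
      mean_utility_by_day = mean_by_slot,
      changers = changer_series[t],
      total_welfare = sum(utilities)
    ), class = "season_record")
    attendance[t, ] <- as.integer(slot_att)
    utility_history[t, ] <- utilities
    choices_history[t, ] <- choice
    slot_types[t, , ] <- tally
    prev_choice <- choice
  }

  structure(list(
    config = cfg,
    records = records,
    changer_series = changer_series,
    attendance = attendance,
    utility_history = utility_history,
    choices_history = choices_history,
    slot_types = slot_types,
    types = type,
    final_players = data.frame(
      id = seq_len(n), type = type, m = NA_real_, p = p,
      choice = choice, last_utility = utilities, n_negative = n_negative),
    kind = "bats"
  ), class = "tpg_run")
}

#' Final-day slot-by-type tally
#'
#' @param result A bat-game `tpg_run`.
#' @param day Day index; defaults to the final day.
#' @return Integer matrix, slots x types.
#' @export
final_slot_types <- function(result, day = dim(result$slot_types)[1]) {
  matrix(result$slot_types[day, , ],
         nrow = dim(result$slot_types)[2],
         ncol = dim(result$slot_types)[3])
}

#' Per-slot type dominance
#'
#' For each occupied slot, the attendance share of its most common type and
#' of its two most common types; empty slots are `NA`.
#'
#' @param tally Integer matrix, slots x types (see [final_slot_types()]).
#' @return Data frame with columns `slot`, `n`, `dominance`, `top2_share`.
#' @examples
#' slot_dominance(rbind(c(6, 4, 0), c(10, 0, 0), c(0, 0, 0)))
#' @export
slot_dominance <- function(tally) {
  n_slots <- nrow(tally)
  out <- data.frame(slot = seq_len(n_slots),
                    n = as.integer(rowSums(tally)),
                    dominance = NA_real_,
                    top2_share = NA_real_)
  for (s in seq_len(n_slots)) {
    if (out$n[s] > 0L) {
      shares <- sort(tally[s, ], decreasing = TRUE) / out$n[s]
      out$dominance[s] <- shares[1]
      out$top2_share[s] <- sum(shares[seq_len(min(2L, length(shares)))])
    }
  }
  out
}
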