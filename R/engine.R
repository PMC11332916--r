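# Season loop for the blossom game: synchronous updates, named RNG streams,
# turnover, and convergence diagnostics over the recorded season history.

# --- named RNG streams -------------------------------------------------------
# One master seed deterministically spawns independent sub-streams so that,
# e.g., enabling turnover draws from its own stream and does not perturb the
# stream driving the agents' choices.

rng_streams <- function(seed, names) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, length(names))
  states <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    set.seed(subseeds[i])
    assign(names[i], get(".Random.seed", envir = globalenv()), envir = states)
  }
  states
}

with_stream <- function(streams, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  res <- force(expr)
  assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  res
}

# --- turnover ----------------------------------------------------------------

#' Replace part of the population with fresh agents
#'
#' `ceiling(fraction * n)` players chosen uniformly without replacement are
#' replaced by memory-free entrants: a fresh preference drawn uniformly from
#' `[pref_low, pref_high]`, exploration probability reset to `p_init`, a
#' bloom-weighted initial day, and no utility history.  The population size
#' is unchanged.
#'
#' @param players Player data frame with columns `id`, `m`, `p`, `choice`,
#'   `last_utility`, `n_negative` (as in a run result's `final_players`).
#' @param fraction Fraction to replace, in `[0, 1)`.
#' @param cfg A [game_config()].
#' @param bloom A [bloom_profile]; defaults to [default_bloom()].
#' @return The player data frame with replaced rows, plus a logical column
#'   `fresh` flagging the entrants.
#' @export
apply_turnover <- function(players, fraction, cfg,
                           bloom = default_bloom(cfg$n_days)) {
  n <- nrow(players)
  players$fresh <- FALSE
  n_rep <- ceiling(fraction * n)
  if (n_rep == 0L) return(players)
  idx <- sample.int(n, n_rep)
  players$m[idx] <- stats::runif(n_rep, cfg$pref_low, cfg$pref_high)
  players$p[idx] <- cfg$p_init
  players$choice[idx] <- initial_choice(n_rep, bloom)
  players$last_utility[idx] <- NA_real_
  players$n_negative[idx] <- 0L
  players$fresh[idx] <- TRUE
  players
}

# --- main loop ---------------------------------------------------------------

#' Run the blossom game
#'
#' Simulates `cfg$n_seasons` seasons of the temporal partitioning game.
#' Season 1 gives every agent a bloom-weighted initial day.  Each later
#' season applies, in order: population turnover (if configured), the
#' decision rule of the configured information mode — synchronously, using
#' only the previous season's outcomes — and then payoffs; exploration
#' probabilities decay via [learning_update()] after each season's payoffs.
#' A fixed seed makes the whole run bit-reproducible.
#'
#' @param cfg A [game_config()].
#' @param bloom A [bloom_profile]; defaults to the triangular
#'   [default_bloom()] profile.
#' @return An object of class `tpg_run`: a list with `config`, `bloom`,
#'   `records` (one `season_record` per season), `changer_series`,
#'   `attendance` (seasons x days matrix), `utility_history` and
#'   `choices_history` (seasons x players matrices), and `final_players`
#'   (data frame with `id`, `m`, `p`, `choice`, `last_utility`,
#'   `n_negative`).
#' @examples
#' res <- run_game(game_config(n_players = 50, n_seasons = 20, seed = 7))
#' res$changer_series
#' @export
run_game <- function(cfg, bloom = default_bloom(cfg$n_days)) {
  validate_game_config(cfg)
  if (length(bloom) != cfg$n_days)
    stop("bloom profile length must equal n_days", call. = FALSE)
  n <- cfg$n_players
  streams <- rng_streams(cfg$seed, c("init", "choices", "turnover"))

  players <- with_stream(streams, "init", data.frame(
    id = seq_len(n),
    m = stats::runif(n, cfg$pref_low, cfg$pref_high),
    p = rep(cfg$p_init, n),
    choice = initial_choice(n, bloom),
    last_utility = NA_real_,
    n_negative = 0L,
    fresh = FALSE
  ))

  records <- vector("list", cfg$n_seasons)
  changer_series <- integer(cfg$n_seasons)
  attendance <- matrix(0L, cfg$n_seasons, cfg$n_days)
  utility_history <- matrix(NA_real_, cfg$n_seasons, n)
  choices_history <- matrix(NA_integer_, cfg$n_seasons, n)
  last_attendance <- NULL
  prev_choices <- NULL

  for (t in seq_len(cfg$n_seasons)) {
    if (t > 1L) {
      if (cfg$turnover_fraction > 0)
        players <- with_stream(streams, "turnover",
          apply_turnover(players, cfg$turnover_fraction, cfg, bloom))
      sitting <- which(!players$fresh)  # entrants keep their fresh draw
      players$choice[sitting] <- with_stream(streams, "choices", {
        if (cfg$info_mode == "local") {
          local_update(players$choice[sitting], players$last_utility[sitting],
                       players$p[sitting], bloom)
        } else {
          global_update(players$choice[sitting], players$last_utility[sitting],
                        players$p[sitting], players$m[sitting],
                        last_attendance, bloom,
                        z = cfg$z, c = cfg$disappointment_cost,
                        subtract_self = cfg$subtract_self)
        }
      })
    }

    sp <- season_payoffs(players$choice, players$m, bloom, cfg,
                         season = t, prev_choices = prev_choices)
    players$last_utility <- sp$utilities
    players$n_negative <- players$n_negative + as.integer(sp$utilities < 0)
    players$p <- learning_update(players$p, sp$utilities, cfg$learning_L)
    players$fresh <- FALSE

    records[[t]] <- sp$record
    changer_series[t] <- sp$record$changers
    attendance[t, ] <- sp$record$attendance
    utility_history[t, ] <- sp$utilities
    choices_history[t, ] <- players$choice
    last_attendance <- sp$record$attendance
    prev_choices <- players$choice
  }

  structure(list(
    config = cfg,
    bloom = bloom,
    records = records,
    changer_series = changer_series,
    attendance = attendance,
    utility_history = utility_history,
    choices_history = choices_history,
    final_players = players[setdiff(names(players), "fresh")],
    kind = "blossom"
  ), class = "tpg_run")
}

#' @export
print.tpg_run <- function(x, ...) {
  n_seasons <- length(x$records)
  cat(sprintf("<tpg_run:%s> %d agents, %d %s\n", x$kind,
              nrow(x$final_players), n_seasons,
              if (x$kind == "blossom") "seasons" else "days"))
  cat(sprintf("  final changers: %d; final mean utility: %.3f\n",
              x$changer_series[n_seasons],
              mean(x$utility_history[n_seasons, ])))
  invisible(x)
}

# --- diagnostics -------------------------------------------------------------

#' Per-season mean utility of visitors
#'
#' Mean utility over the agents that visited (i.e. did not stay home) in
#' each season; `NA` for seasons with no visitors.
#'
#' @param result A `tpg_run`.
#' @return Numeric vector, one entry per season.
#' @export
visitor_mean_utility <- function(result) {
  vapply(result$records, function(r) {
    nv <- sum(r$attendance)
    if (nv == 0L) NA_real_ else r$total_welfare / nv
  }, numeric(1))
}

#' Which days are congested beyond all repair
#'
#' A day is flagged congested in a given season when its attendance exceeds
#' the level at which even the keenest possible visitor fails, i.e.
#' `n(d) > pref_high * K(d) / z`.  Useful for measuring the full-information
#' oscillation, where days alternate between over-threshold crowds and
#' near-empty seasons.
#'
#' @param result A `tpg_run`.
#' @param season Season index.
#' @return Logical vector over days.
#' @export
congested_days <- function(result, season) {
  cfg <- result$config
  result$attendance[season, ] > cfg$pref_high * as.numeric(result$bloom) / cfg$z
}

#' Convergence diagnostics for a run
#'
#' Summarises the season history: *strong convergence* means no agent
#' changed its choice over the trailing `window` seasons (an absorbing
#' visitor set); the *weak trend* is the mean changer fraction over the
#' trailing window divided by the mean over the first `window` seasons
#' (values well below 1 indicate a decaying change rate, 0 a frozen run).
#'
#' @param result A `tpg_run`.
#' @param window Number of seasons in the leading/trailing windows; must be
#'   less than the number of seasons.
#' @return A list of class `convergence_report`: `strong_converged`,
#'   `weak_trend`, `mean_utility_late` (mean visitor utility over the
#'   trailing window), `visitor_pref_mean` and `home_pref_mean` (mean
#'   preference of final-season visitors and home-stayers).
#' @export
diagnose <- function(result, window = 20L) {
  n_seasons <- length(result$records)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window >= n_seasons)
    stop("window must be a positive integer smaller than the number of seasons",
         call. = FALSE)
  n <- nrow(result$final_players)
  frac <- result$changer_series / n
  late <- (n_seasons - window + 1L):n_seasons
  early <- seq_len(window)
  early_mean <- mean(frac[early])
  late_mean <- mean(frac[late])
  weak_trend <- if (early_mean == 0) {
    if (late_mean == 0) 0 else Inf
  } else late_mean / early_mean

  final <- result$final_players
  visiting <- final$choice != HOME
  structure(list(
    strong_converged = all(result$changer_series[late] == 0L),
    weak_trend = weak_trend,
    mean_utility_late = mean(visitor_mean_utility(result)[late], na.rm = TRUE),
    visitor_pref_mean = if (any(visiting)) mean(final$m[visiting]) else NA_real_,
    home_pref_mean = if (any(!visiting)) mean(final$m[!visiting]) else NA_real_
  ), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<convergence_report> strong=%s, weak_trend=%.4f\n",
    "  mean visitor utility (late): %.4f\n",
    "  mean preference: visitors %.3f vs home %.3f\n"),
    x$strong_converged, x$weak_trend, x$mean_utility_late,
    x$visitor_pref_mean, x$home_pref_mean))
  invisible(x)
}

#' Plot the attendance history of a run
#'
#' Season-by-season attendance traces for a subset of days (blossom game)
#' or slots (bat game), plus the home/roost count.
#'
#' @param x A `tpg_run`.
#' @param days Day (or slot) indices to trace; defaults to an evenly spread
#'   subset of at most five.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.tpg_run <- function(x, days = NULL, ...) {
  n_days <- ncol(x$attendance)
  if (is.null(days))
    days <- unique(round(seq(1, n_days, length.out = min(5, n_days))))
  home <- vapply(x$records, function(r) r$home_count, integer(1))
  graphics::matplot(cbind(x$attendance[, days, drop = FALSE], home),
                    type = "l", lty = 1,
                    xlab = if (x$kind == "blossom") "season" else "day",
                    ylab = "attendance", ...)
  graphics::legend("topright",
                   legend = c(paste(if (x$kind == "blossom") "day" else "slot",
                                    days), "home"),
                   col = seq_len(length(days) + 1), lty = 1, cex = 0.8)
  invisible(x)
}
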