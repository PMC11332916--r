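# Shared helpers: tiny configurations and an independent brute-force
# Nash checker used as an oracle against the package's is_nash().

quick_cfg <- function(...) {
  game_config(n_players = 50L, n_seasons = 20L, seed = 1L, ...)
}

changer_frac <- function(result) {
  result$changer_series / result$config$n_players
}

# Naive Nash check: recompute every deviation payoff from scratch with
# plain loops, independent of the vectorised implementation.
is_nash_oracle <- function(assignment, m, k, z, c) {
  n <- length(assignment)
  n_days <- length(k)
  payoff <- function(a, i) {
    if (a[i] == 0L) return(0)
    n_d <- sum(a == a[i])
    v <- m[i] * k[a[i]] / n_d
    if (v >= z) v else -c
  }
  for (i in seq_len(n)) {
    base <- payoff(assignment, i)
    for (target in 0:n_days) {
      if (target == assignment[i]) next
      alt <- assignment
      alt[i] <- target
      if (payoff(alt, i) > base + 1e-12) return(FALSE)
    }
  }
  TRUE
}
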