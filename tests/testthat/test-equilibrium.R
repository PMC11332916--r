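test_that("nash verification matches hand-worked micro-games", {
  b <- default_bloom(19)
  # lone player on the peak day: no improving deviation anywhere
  expect_true(is_nash(c(10L), m = 2, bloom = b, z = 0.1, c = 1)$is_nash)
  # everyone home is never an equilibrium: any day alone pays m*K/1 >= z
  r <- is_nash(rep(HOME, 4), m = c(1, 1, 2, 3), bloom = b, z = 0.1, c = 1)
  expect_false(r$is_nash)
  expect_gt(r$witness$gain, 0)
  expect_true(r$witness$target %in% 1:19)
})

test_that("enumeration recovers the hand-enumerated equilibria of a 1-player game", {
  # one player, two days with K = (1, 2): day 1 is dominated by day 2,
  # home is dominated by either day, so {day 2} is the unique equilibrium
  b <- bloom_profile(c(1, 2))
  eqs <- enumerate_equilibria(m = 1, bloom = b, z = 0.1, c = 1)
  expect_length(eqs, 1)
  expect_equal(eqs[[1]]$assignment, 2L)
  expect_equal(eqs[[1]]$welfare, 2)
  # with z = 1.5 day 1 fails outright; day 2 is still the only equilibrium
  eqs2 <- enumerate_equilibria(m = 1, bloom = b, z = 1.5, c = 1)
  expect_length(eqs2, 1)
  expect_equal(eqs2[[1]]$assignment, 2L)
  expect_error(enumerate_equilibria(m = rep(1, 8), bloom = default_bloom(19),
                                    z = 0.1, c = 1, cap = 1e6), "cap")
})

test_that("is_nash agrees with an independent brute-force oracle", {
  set.seed(31)
  k <- c(1, 2.5, 1)
  m <- c(3, 2.4, 2, 1.5, 1.2, 1)
  for (rep in 1:60) {
    a <- as.integer(sample(0:3, 6, replace = TRUE))
    expect_equal(is_nash(a, m, bloom_profile(k), z = 1, c = 1)$is_nash,
                 is_nash_oracle(a, m, k, z = 1, c = 1),
                 info = paste(a, collapse = ","))
  }
})

test_that("greedy construction places by preference and parks the overflow home", {
  b <- default_bloom(19)
  set.seed(17)
  a2 <- construct_optimal_ne(m = c(3, 1), bloom = b, z = 0.1, c = 1)
  expect_true(all(a2 != HOME))
  u2 <- assignment_welfare(a2, c(3, 1), b, z = 0.1, c = 1)
  expect_gt(u2, 0)
  expect_true(is_nash(a2, c(3, 1), b, z = 0.1, c = 1)$is_nash)

  # identical preferences beyond capacity: one day of K = 1 at z = 0.5
  # supports two unit-preference players; the rest must stay home
  b1 <- bloom_profile(1)
  a5 <- construct_optimal_ne(m = rep(1, 5), bloom = b1, z = 0.5, c = 1)
  expect_equal(sum(a5 != HOME), 2L)
  expect_true(is_nash(a5, rep(1, 5), b1, z = 0.5, c = 1)$is_nash)
})

test_that("constructed equilibria verify and the welfare audit is honest", {
  for (nm in c("lone", "tiny-ne", "boundary")) {
    fx <- make_fixture(nm)
    cfg <- fx$cfg
    set.seed(23)
    ne <- construct_optimal_ne(fx$players$m, fx$bloom, cfg$z,
                               cfg$disappointment_cost)
    expect_true(is_nash(ne, fx$players$m, fx$bloom, cfg$z,
                        cfg$disappointment_cost)$is_nash,
                info = nm)
    eqs <- enumerate_equilibria(fx$players$m, fx$bloom, cfg$z,
                                cfg$disappointment_cost)
    welfares <- vapply(eqs, `[[`, numeric(1), "welfare")
    w <- assignment_welfare(ne, fx$players$m, fx$bloom, cfg$z,
                            cfg$disappointment_cost)
    # the constructed assignment is among the enumerated equilibria
    expect_true(any(vapply(eqs, function(e)
      identical(e$assignment, ne), logical(1))), info = nm)
    expect_lte(w, max(welfares) + 1e-12)
  }
})

test_that("preference-ordered filling is not always the social optimum", {
  # six players, K = (1, 2.5, 1), z = 1: the greedy equilibrium (welfare 9)
  # is beaten by an equilibrium that sends the two keenest players to the
  # poor days and packs the rich day (welfare 9.31667)
  fx <- make_fixture("tiny-ne")
  cfg <- fx$cfg
  eqs <- enumerate_equilibria(fx$players$m, fx$bloom, cfg$z,
                              cfg$disappointment_cost)
  welfares <- vapply(eqs, `[[`, numeric(1), "welfare")
  best <- eqs[[which.max(welfares)]]
  expect_equal(best$welfare, 9.316667, tolerance = 1e-6)
  # the optimum spreads the two keenest players onto the poor days (the
  # mirror-image assignment is welfare-equivalent) and sends player 6 home
  expect_true(all(sort(best$assignment[1:2]) == c(1L, 3L)))
  expect_equal(best$assignment[3:6], c(2L, 2L, 2L, HOME))
  set.seed(23)
  ne <- construct_optimal_ne(fx$players$m, fx$bloom, cfg$z,
                             cfg$disappointment_cost)
  expect_equal(assignment_welfare(ne, fx$players$m, fx$bloom, cfg$z,
                                  cfg$disappointment_cost), 9)
})

test_that("winner-takes-all: home players in any equilibrium see no entry", {
  for (nm in c("tiny-ne", "boundary")) {
    fx <- make_fixture(nm)
    cfg <- fx$cfg
    k <- as.numeric(fx$bloom)
    eqs <- enumerate_equilibria(fx$players$m, fx$bloom, cfg$z,
                                cfg$disappointment_cost)
    for (e in eqs) {
      home <- which(e$assignment == HOME)
      if (!length(home)) next
      att <- tabulate(e$assignment[e$assignment != HOME], length(k))
      for (h in home) {
        antic <- day_utility(fx$players$m[h], k, att + 1, cfg$z,
                             cfg$disappointment_cost)
        expect_true(all(antic < 0), info = nm)
      }
    }
  }
})
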