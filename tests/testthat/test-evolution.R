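test_that("Fermi probability matches its closed form and saturates safely", {
  expect_equal(fermi_probability(5, 5, 0.1), 0.5)
  expect_equal(fermi_probability(5, 5, 1), 0.5)
  expect_equal(fermi_probability(0, 10, 0.1), 1 / (1 + exp(-100)),
               tolerance = 1e-15)
  expect_equal(fermi_probability(10, 0, 0.1), 1 / (1 + exp(100)))
  expect_lt(fermi_probability(10, 0, 0.1), 1e-43)
  # saturated limits do not overflow
  expect_equal(fermi_probability(1e6, 0, 0.1), 0)
  expect_equal(fermi_probability(0, 1e6, 0.1), 1)
  expect_error(fermi_probability(1, 2, 0), "beta")
})

test_that("pij + pji = 1 and pij decreases in the resource gap", {
  set.seed(1)
  ri <- runif(200, -50, 50)
  rj <- runif(200, -50, 50)
  beta <- runif(200, 0.01, 1)
  pij <- fermi_probability(ri, rj, beta)
  pji <- fermi_probability(rj, ri, beta)
  expect_true(all(pij >= 0 & pij <= 1))
  expect_equal(pij + pji, rep(1, 200))
  # strict monotonicity along an increasing gap grid (within the range
  # where the probability is not saturated to machine 0/1)
  gaps <- seq(-1.5, 1.5, by = 0.25)
  pr <- fermi_probability(gaps, 0, 0.1)
  expect_true(all(diff(pr) < 0))
  # saturated tails are weakly monotone
  wide <- fermi_probability(seq(-50, 50, by = 1), 0, 0.1)
  expect_true(all(diff(wide) <= 0))
})

test_that("imitation keeps expected strategy counts when resources are equal", {
  p <- risk_params(N = 100, a = 10, n = 10)
  set.seed(99)
  st <- withr::with_seed(99, initialize_population(p))
  st$resources <- rep(3, 100)
  drift <- replicate(400, {
    out <- learning_step(st, p)
    tabulate(out$strategies, 4L)
  })
  # each comparison is a fair coin; mean counts stay at the input counts
  expect_equal(rowMeans(drift), tabulate(st$strategies, 4L), tolerance = 0.08)
})

test_that("imitation is absorbing on monomorphic populations and near-certain
           for a pauper meeting a tycoon", {
  p <- risk_params(N = 10, a = 1, n = 10)
  mono <- structure(list(strategies = rep(2L, 10), resources = runif(10),
                         round_index = 0L), class = "population_state")
  out <- learning_step(mono, p)
  expect_equal(out$strategies, rep(2L, 10))

  p2 <- risk_params(N = 2, a = 1, n = 2)
  duo <- structure(list(strategies = c(4L, 1L), resources = c(0, 10),
                        round_index = 0L), class = "population_state")
  copies <- replicate(200, learning_step(duo, p2)$strategies[1])
  expect_true(all(copies == 1L))  # p = 1/(1+e^{-100})
})

test_that("mutation changes exactly round(alpha * N) individuals", {
  p <- risk_params(alpha = 0.05)
  set.seed(5)
  st <- initialize_population(p)
  for (i in 1:50) {
    out <- mutation_step(st, p)
    changed <- sum(out$strategies != st$strategies)
    expect_identical(changed, 5L)
    expect_true(all(out$strategies %in% match(p$strategy_set, STRATEGIES)))
  }
  # alpha = 0 is the identity
  p0 <- risk_params(alpha = 0)
  expect_identical(mutation_step(st, p0)$strategies, st$strategies)
  # two strategies: a mutated individual must flip to the other one
  p2 <- risk_params(alpha = 0.1, strategy_set = c("C", "D"))
  st2 <- withr::with_seed(8, initialize_population(p2))
  out2 <- mutation_step(st2, p2)
  flipped <- which(out2$strategies != st2$strategies)
  expect_length(flipped, 10)
  expect_true(all(out2$strategies[flipped] + st2$strategies[flipped] == 5L))
})

test_that("initial strategies are uniform over the allowed set", {
  p <- risk_params()
  counts <- Reduce(`+`, lapply(1:50, function(s) {
    tabulate(withr::with_seed(s, initialize_population(p))$strategies, 4L)
  }))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
  pcd <- risk_params(strategy_set = c("C", "D"))
  st <- withr::with_seed(1, initialize_population(pcd))
  expect_true(all(st$strategies %in% c(1L, 4L)))
})

test_that("both engines are bit-identical and runs are reproducible", {
  for (opts in list(list(),
                    list(peer_regime = "one_act"),
                    list(partner_scope = "subgroup"),
                    list(failure_rule = "debts",
                         learning_input = "cumulative"))) {
    p <- do.call(quick_params, c(list(rounds = 100, stable_window = 20), opts))
    a <- run_simulation(p, seed = 7, engine = "cpp")
    b <- run_simulation(p, seed = 7, engine = "r")
    expect_identical(a$series, b$series)
    expect_identical(a$final_state, b$final_state)
  }
  p <- quick_params()
  expect_identical(run_simulation(p, seed = 3)$series,
                   run_simulation(p, seed = 3)$series)
  expect_false(identical(run_simulation(p, seed = 3)$series,
                         run_simulation(p, seed = 4)$series))
})

test_that("run series respects population accounting", {
  p <- quick_params(strategy_set = c("C", "D"))
  run <- run_simulation(p, seed = 11)
  s <- run$series
  expect_true(all(s$n_C + s$n_CP + s$n_PP + s$n_D == p$N))
  expect_true(all(s$n_CP == 0L & s$n_PP == 0L))
  # no punishers: every punishment ledger entry is zero
  expect_true(all(s$central_loss == 0 & s$central_cost == 0 &
                    s$peer_loss == 0 & s$peer_cost == 0))
  expect_true(all(s$successes >= 0 & s$successes <= p$a))
})

test_that("the caller's RNG stream is left untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(run_simulation(quick_params(), seed = 1))
  expect_identical(.Random.seed, before)
})
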