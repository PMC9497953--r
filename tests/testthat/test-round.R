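p0 <- risk_params(t1 = 5, t2 = 2.5, U = 25)

test_that("contribution stage endows everyone and charges collaborators", {
  sg <- c(rep("C", 3), rep("CP", 2), rep("PP", 2), rep("D", 3))
  out <- apply_contributions(sg, p0)
  expect_equal(out$balances, c(rep(5, 7), rep(10, 3)))
  expect_equal(out$total_contribution, 35)

  allD <- apply_contributions(rep("D", 10), p0)
  expect_equal(allD$balances, rep(10, 10))
  expect_equal(allD$total_contribution, 0)

  allC <- apply_contributions(rep("C", 10), p0)
  expect_equal(allC$total_contribution, 50)
})

test_that("central punishment fires only when the pool reaches its threshold", {
  sg <- c("CP", "CP", "D", "D", "D")
  b <- apply_contributions(sg, p0)$balances
  out <- apply_central_punishment(b, sg, p0)
  expect_true(out$institution_established)   # 2 * 2 >= 4
  expect_equal(out$balances, c(3, 3, 5, 5, 5))
  expect_equal(out$central_loss, 15)
  expect_equal(out$central_cost, 4)

  # one CP: cost is sunk but no punishment
  sg2 <- c("CP", "D", "D", "D", "D")
  b2 <- apply_contributions(sg2, p0)$balances
  out2 <- apply_central_punishment(b2, sg2, p0)
  expect_false(out2$institution_established)
  expect_equal(out2$balances, c(3, rep(10, 4)))
  expect_equal(out2$central_loss, 0)
  expect_equal(out2$central_cost, 2)

  # no defectors: institution established, nothing to dock
  sg3 <- c("CP", "CP", "CP", "C", "C")
  b3 <- apply_contributions(sg3, p0)$balances
  out3 <- apply_central_punishment(b3, sg3, p0)
  expect_true(out3$institution_established)
  expect_equal(out3$central_cost, 6)
  expect_equal(out3$central_loss, 0)
})

test_that("pairwise peer punishment is all-against-all", {
  p <- update_params(p0, t2 = 2, w2 = 1)
  sg <- c("PP", "PP", "PP", "D", "D")
  b <- apply_contributions(sg, p)$balances
  out <- apply_peer_punishment(b, sg, p)
  expect_equal(out$balances, c(3, 3, 3, 4, 4))  # PP: 5-2, D: 10-6
  expect_equal(out$peer_loss, 12)
  expect_equal(out$peer_cost, 6)

  none <- apply_peer_punishment(rep(10, 5), rep("D", 5), p)
  expect_equal(none$balances, rep(10, 5))
  expect_equal(none$peer_loss, 0)

  p65 <- update_params(p0, t2 = 6.5)
  single <- apply_peer_punishment(c(5, 10), c("PP", "D"), p65)
  expect_equal(single$balances, c(4, 3.5))
})

test_that("one-act peer punishment charges each punisher once", {
  p <- update_params(p0, t2 = 2, peer_regime = "one_act")
  sg <- c("PP", "PP", "PP", "D", "D")
  b <- apply_contributions(sg, p)$balances
  out <- apply_peer_punishment(b, sg, p)
  expect_equal(out$balances, c(4, 4, 4, 7, 7))  # PP: 5-1, D: 10 - 2*3/2
  expect_equal(out$peer_loss, 6)
  expect_equal(out$peer_cost, 3)
  # no defectors present: no act, no cost
  quiet <- apply_peer_punishment(rep(5, 3), rep("PP", 3), p)
  expect_equal(quiet$balances, rep(5, 3))
  expect_equal(quiet$peer_cost, 0)
})

test_that("risk threshold is inclusive and failure forfeits everything", {
  p <- update_params(p0, U = 15)
  kept <- resolve_risk(c(5, 5, 5), 15, p)
  expect_true(kept$success)
  expect_equal(kept$balances, c(5, 5, 5))

  lost <- resolve_risk(c(5, 5, 10, -3), 10, p)
  expect_false(lost$success)
  expect_equal(lost$balances, rep(0, 4))

  p35 <- update_params(p0, U = 35)
  expect_true(resolve_risk(rep(5, 7), 35, p35)$success)

  # under the debts rule a negative balance survives the wipe
  pd <- update_params(p, failure_rule = "debts")
  debt <- resolve_risk(c(5, -3), 10, pd)
  expect_equal(debt$balances, c(0, -3))
})

test_that("play_round reproduces the hand-traced mixed subgroup", {
  p <- risk_params(N = 10, a = 1, n = 10, t1 = 5, t2 = 2, U = 35)
  fx <- make_fixture(list(c(C = 3, CP = 2, PP = 2, D = 3)), p)
  out <- play_round(fx$state, fx$assignment, p)
  led <- out$ledger
  expect_true(led$success)
  expect_true(led$institution_established)
  expect_equal(led$total_contribution, 35)
  expect_equal(led$central_loss, 15)
  expect_equal(led$central_cost, 4)
  expect_equal(led$peer_loss, 12)   # 2 * 2 * 3
  expect_equal(led$peer_cost, 6)
  # C = 5, CP = 3, PP = 10-5-3 = 2, D = 10-5-4 = 1
  expect_equal(out$state$resources,
               c(rep(5, 3), rep(3, 2), rep(2, 2), rep(1, 3)))
  # purity: identical inputs give identical outputs
  again <- play_round(fx$state, fx$assignment, p)
  expect_identical(again$ledger, led)
  expect_identical(again$state$resources, out$state$resources)
})

test_that("ledger identities and balance formula hold on random subgroups", {
  set.seed(42)
  for (regime in c("pairwise", "one_act")) {
    p <- risk_params(N = 10, a = 1, n = 10,
                     t1 = sample(seq(2, 9.5, 0.5), 1),
                     t2 = 6.5, w2 = 1,
                     U = sample(c(15, 25, 35), 1),
                     peer_regime = regime)
    for (i in 1:500) {
      sg <- random_subgroup(10)
      fx <- make_fixture(list(table(factor(sg, levels = STRATEGIES))[
        c("C", "CP", "PP", "D")]), p)
      out <- play_round(fx$state, fx$assignment, p)
      led <- out$ledger
      oracle <- oracle_subgroup(STRATEGIES[fx$state$strategies], p)
      expect_equal(out$state$resources, oracle$balances)
      expect_equal(led$success, oracle$success)
      expect_equal(led$institution_established, oracle$institution)
      expect_equal(led$n_C + led$n_CP + led$n_PP + led$n_D, 10)
      expect_equal(led$institution_established,
                   p$w1 * led$n_CP >= p$w)
      expect_equal(led$central_loss,
                   if (led$institution_established) p$t1 * led$n_D else 0)
      expect_equal(led$central_cost, p$w1 * led$n_CP)
      if (regime == "pairwise") {
        expect_equal(led$peer_loss, p$t2 * led$n_PP * led$n_D)
        expect_equal(led$peer_cost, (p$w2 / p$t2) * led$peer_loss)
      } else {
        acts <- if (led$n_D > 0) led$n_PP else 0
        expect_equal(led$peer_loss, p$t2 * acts)
        expect_equal(led$peer_cost, p$w2 * acts)
      }
      if (!led$success) {
        expect_equal(sum(out$state$resources), 0)
      }
    }
  }
})

test_that("fixtures validate composition", {
  p <- risk_params(N = 20, a = 2, n = 10, U = 15)
  expect_error(make_fixture(list(c(C = 10)), p), "one element per subgroup")
  expect_error(make_fixture(list(c(C = 9), c(D = 10)), p), "sum")
  fx <- make_fixture(list(c(C = 10), c(D = 10)), p)
  expect_equal(as.vector(table(fx$state$strategies)), c(10L, 10L))
})
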