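# short-run parameter sets used across tests; model constants stay at the
# canonical defaults unless a test overrides them
quick_params <- function(...) {
  args <- utils::modifyList(
    list(rounds = 200, stable_window = 50, replicates = 2), list(...)
  )
  do.call(risk_params, args)
}

# random subgroup strategy vector (labels), optionally forcing composition
random_subgroup <- function(n = 10) {
  sample(c("C", "CP", "PP", "D"), n, replace = TRUE)
}

# independent brute-force recomputation of one subgroup's final balances,
# following the round rules member by member (used as the oracle against
# the staged pipeline)
oracle_subgroup <- function(strategies, p) {
  n_cp <- sum(strategies == "CP")
  n_pp <- sum(strategies == "PP")
  n_d <- sum(strategies == "D")
  inst <- p$w1 * n_cp >= p$w
  total <- p$u * sum(strategies != "D")
  bal <- vapply(strategies, function(s) {
    b <- p$m
    if (s != "D") b <- b - p$u
    if (s == "CP") b <- b - p$w1
    if (s == "PP" && n_d > 0) {
      b <- b - if (p$peer_regime == "one_act") p$w2 else p$w2 * n_d
    }
    if (s == "D") {
      if (inst) b <- b - p$t1
      if (n_pp > 0) {
        b <- b - if (p$peer_regime == "one_act") p$t2 * n_pp / n_d else p$t2 * n_pp
      }
    }
    b
  }, numeric(1), USE.NAMES = FALSE)
  success <- total >= p$U
  if (!success) {
    bal <- if (p$failure_rule == "debts") pmin(bal, 0) else rep(0, length(bal))
  }
  list(balances = bal, success = success, total = total,
       institution = inst)
}
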