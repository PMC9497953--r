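# One game round, subgroup by subgroup:
#   endowment -> contribution -> central punishment -> peer punishment
#   -> threshold risk resolution.
# All four stage functions are pure and operate on a single subgroup, so a
# hand-traced example can be checked stage by stage.

as_codes <- function(strategies) {
  if (is.character(strategies)) strategy_codes(strategies) else as.integer(strategies)
}

#' Endowment and contribution stage for one subgroup
#'
#' Every member starts the round with the endowment `m`; each collaborator
#' (`C`, `CP`, `PP`) then pays the contribution `u` toward the common pot,
#' defectors pay nothing.
#'
#' @param strategies Strategy labels (or integer codes) of one subgroup.
#' @param p A [risk_params()] object.
#' @return A list with `balances` (numeric, per member) and
#'   `total_contribution` (units).
#' @examples
#' apply_contributions(c("C", "C", "D"), risk_params())
#' @export
apply_contributions <- function(strategies, p) {
  s <- as_codes(strategies)
  collab <- s != 4L
  balances <- rep(p$m, length(s)) - p$u * collab
  list(balances = balances, total_contribution = p$u * sum(collab))
}

#' Central (pool) punishment stage for one subgroup
#'
#' Each `CP` member pays `w1` into the institution pool unconditionally
#' (the cost is sunk).  If the subgroup pool reaches the establishment
#' threshold (`w1 * n_CP >= w`), the institution docks every defector `t1`,
#' exactly once per round.
#'
#' @param balances Member balances after [apply_contributions()].
#' @param strategies Strategy labels (or codes) of the subgroup.
#' @param p A [risk_params()] object.
#' @return A list with updated `balances`, `institution_established`
#'   (logical), `central_loss` (total units docked from defectors) and
#'   `central_cost` (total units paid by CP members).
#' @examples
#' st <- c("CP", "CP", "D", "D", "D")
#' b <- apply_contributions(st, risk_params())$balances
#' apply_central_punishment(b, st, risk_params())
#' @export
apply_central_punishment <- function(balances, strategies, p) {
  s <- as_codes(strategies)
  n_cp <- sum(s == 2L)
  n_d <- sum(s == 4L)
  established <- p$w1 * n_cp >= p$w - EPS
  balances[s == 2L] <- balances[s == 2L] - p$w1
  if (established) balances[s == 4L] <- balances[s == 4L] - p$t1
  list(balances = balances,
       institution_established = established,
       central_loss = if (established) p$t1 * n_d else 0,
       central_cost = p$w1 * n_cp)
}

#' Peer punishment stage for one subgroup
#'
#' Many-to-many sanctioning.  Under the default `"pairwise"` regime every
#' `PP` member punishes every defector in the subgroup once: a defector
#' loses `t2` per punisher (`t2 * n_PP` in total) and each punisher pays
#' `w2` per defector (`w2 * n_D` in total).  Under `"one_act"` each
#' punisher performs a single act per round (cost `w2`, only when a
#' defector is present) whose effect is spread evenly over the defectors
#' (`t2 * n_PP / n_D` lost by each).
#'
#' @inheritParams apply_central_punishment
#' @return A list with updated `balances`, `peer_loss` and `peer_cost`
#'   (`t2 * n_PP * n_D` and `w2 * n_PP * n_D` under `"pairwise"`;
#'   `t2 * n_PP` and `w2 * n_PP` under `"one_act"` when defectors are
#'   present).
#' @examples
#' st <- c("PP", "PP", "PP", "D", "D")
#' b <- apply_contributions(st, risk_params())$balances
#' apply_peer_punishment(b, st, risk_params())
#' @export
apply_peer_punishment <- function(balances, strategies, p) {
  s <- as_codes(strategies)
  n_pp <- sum(s == 3L)
  n_d <- sum(s == 4L)
  if (identical(p$peer_regime, "one_act")) {
    if (n_d > 0L) {
      balances[s == 3L] <- balances[s == 3L] - p$w2
      balances[s == 4L] <- balances[s == 4L] - p$t2 * n_pp / n_d
    }
    acts <- if (n_d > 0L) n_pp else 0L
  } else {
    balances[s == 3L] <- balances[s == 3L] - p$w2 * n_d
    balances[s == 4L] <- balances[s == 4L] - p$t2 * n_pp
    acts <- n_pp * n_d
  }
  list(balances = balances,
       peer_loss = p$t2 * acts,
       peer_cost = p$w2 * acts)
}

#' Threshold risk resolution for one subgroup
#'
#' If the subgroup's total contribution reaches the risk threshold `U`
#' (inclusive), the risk is withstood and balances are kept.  Otherwise the
#' subgroup fails and every member loses all resources.  Under
#' `failure_rule = "zero"` every balance becomes exactly 0, including
#' balances that punishment had driven negative; under `"debts"` a member
#' loses only what they hold, so negative balances persist.
#'
#' @param balances Member balances after the punishment stages.
#' @param total_contribution Total units contributed by the subgroup.
#' @param p A [risk_params()] object.
#' @return A list with `success` (logical) and final `balances`.
#' @examples
#' resolve_risk(c(5, 5, 10), 10, risk_params(U = 15))
#' @export
resolve_risk <- function(balances, total_contribution, p) {
  success <- total_contribution >= p$U - EPS
  if (!success) {
    balances <- if (identical(p$failure_rule, "debts")) {
      pmin(balances, 0)
    } else {
      rep(0, length(balances))
    }
  }
  list(success = success, balances = balances)
}

#' Play one full round
#'
#' Applies, subgroup by subgroup, the complete round pipeline:
#' [apply_contributions()], [apply_central_punishment()],
#' [apply_peer_punishment()], [resolve_risk()].  Strategies are left
#' untouched (learning and mutation happen between rounds); resources are
#' replaced by the end-of-round balances.
#'
#' @param state A `"population_state"`.
#' @param assignment A `"subgroup_assignment"` from
#'   [partition_into_subgroups()] or [make_fixture()].
#' @param p A [risk_params()] object.
#' @return A list with `state` (updated, `round_index` incremented),
#'   `ledger`, a tibble with one row per subgroup (strategy counts,
#'   `total_contribution`, `institution_established`, `central_loss`,
#'   `central_cost`, `peer_loss`, `peer_cost`, `success`), and
#'   `pre_risk_balances`, the per-member balances before risk resolution
#'   (these can be negative under heavy punishment).
#' @examples
#' p <- risk_params(N = 10, a = 1, n = 10, t2 = 2, U = 35)
#' fx <- make_fixture(list(c(C = 3, CP = 2, PP = 2, D = 3)), p)
#' play_round(fx$state, fx$assignment, p)$ledger
#' @export
play_round <- function(state, assignment, p) {
  validate_params(p)
  resources <- numeric(p$N)
  pre_risk <- numeric(p$N)
  rows <- vector("list", p$a)
  for (g in seq_len(p$a)) {
    members <- assignment[g, ]
    s <- state$strategies[members]
    contrib <- apply_contributions(s, p)
    cen <- apply_central_punishment(contrib$balances, s, p)
    peer <- apply_peer_punishment(cen$balances, s, p)
    risk <- resolve_risk(peer$balances, contrib$total_contribution, p)
    resources[members] <- risk$balances
    pre_risk[members] <- peer$balances
    rows[[g]] <- tibble::tibble(
      subgroup = g,
      n_C = sum(s == 1L), n_CP = sum(s == 2L),
      n_PP = sum(s == 3L), n_D = sum(s == 4L),
      total_contribution = contrib$total_contribution,
      institution_established = cen$institution_established,
      central_loss = cen$central_loss, central_cost = cen$central_cost,
      peer_loss = peer$peer_loss, peer_cost = peer$peer_cost,
      success = risk$success
    )
  }
  list(
    state = new_population_state(state$strategies, resources,
                                 state$round_index + 1L),
    ledger = dplyr::bind_rows(rows),
    pre_risk_balances = pre_risk
  )
}
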