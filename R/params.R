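#' Strategy labels of the game
#'
#' The four strategies, in canonical order: `C` (collaborator, no
#' punishment), `CP` (collaborator supporting the central punishment
#' institution), `PP` (collaborator enforcing peer punishment) and `D`
#' (defector / free-rider, the target of both punishment types).  Integer
#' strategy codes throughout the package index into this vector.
#'
#' @format A character vector of length 4.
#' @export
STRATEGIES <- c("C", "CP", "PP", "D")

# numeric tolerance for threshold comparisons on real-valued resources
EPS <- 1e-9

#' Game parameters for the risk-resistant collective-action model
#'
#' Bundles every model constant and run control of the threshold
#' public-goods game with punishment.  Each round, `N = a * n` individuals
#' receive an endowment `m`, are partitioned at random into `a` subgroups of
#' size `n`, and collaborators (strategies `C`, `CP`, `PP`) contribute `u`
#' toward their subgroup's risk threshold `U`.  `CP` players additionally
#' pay `w1` into a pool; if the subgroup pool reaches `w`, a central
#' institution docks every defector `t1` once.  Every `PP` player punishes
#' every defector in the subgroup (`t2` docked per punisher, at cost `w2`
#' per act).  A subgroup whose total contribution falls short of `U` fails
#' and all its members lose everything.  Between rounds, strategies evolve
#' by Fermi imitation with temperature `beta` and mutation at rate `alpha`.
#'
#' @param N Population size. Must equal `a * n`.
#' @param a Number of subgroups per round.
#' @param n Subgroup size.
#' @param m Per-round endowment (resource units).
#' @param u Contribution cost paid by each collaborator (units, `u <= m`).
#' @param w1 Pool contribution paid by each CP player (units).
#' @param w Pool threshold to establish the central institution (units).
#' @param w2 Cost of one act of peer punishment (units, `w2 <= t2`).
#' @param t1 Central punishment intensity: units docked from each defector
#'   when the institution is established.
#' @param t2 Peer punishment intensity: units docked from a defector per
#'   punishing PP player.
#' @param U Risk-resistance threshold: total subgroup contribution needed
#'   to withstand the risk (units).
#' @param beta Fermi learning temperature, in (0, 1]. Small values make
#'   imitation nearly deterministic toward the richer partner.
#' @param alpha Mutation rate, in [0, 1]; `round(alpha * N)` individuals
#'   mutate each round.
#' @param strategy_set Character subset of `c("C", "CP", "PP", "D")` with at
#'   least two elements; restricts both initialization and mutation.
#' @param rounds Number of rounds per run.
#' @param stable_window Number of trailing rounds treated as the
#'   evolutionary stable state for summary statistics.
#' @param replicates Default number of replicate runs in sweeps.
#' @param peer_regime How peer punishment acts are counted. `"pairwise"`
#'   (default): every PP member punishes every defector in the subgroup,
#'   paying `w2` per defector, and each defector loses `t2` per punisher.
#'   `"one_act"`: each PP member performs a single punishment act per
#'   round (cost `w2`, only when a defector is present) whose `t2` effect
#'   is spread evenly over the subgroup's defectors.
#' @param failure_rule What a failed subgroup's members lose. `"zero"`
#'   (default) sets every member's balance to exactly 0, erasing even
#'   punishment-induced debts; `"debts"` zeroes only positive holdings, so
#'   a balance that punishment drove negative persists.
#' @param learning_input Which balance the Fermi comparison uses:
#'   `"cumulative"` (default) compares accumulated holdings, which grow
#'   while an individual's subgroups keep succeeding and are wiped by a
#'   failure; `"round"` compares the current round's end-of-round balance
#'   only.
#' @param partner_scope `"population"` (default) draws imitation partners
#'   from the whole population; `"subgroup"` restricts them to the current
#'   round's subgroup.
#' @param rate_basis `"members"` (default) counts every member of a
#'   successful subgroup toward the collaboration rate; `"collaborators"`
#'   counts only the contributing members.
#' @param seed Optional default seed for [run_simulation()].
#'
#' @return A validated list of class `"risk_params"`.
#' @examples
#' p <- risk_params(t1 = 5, t2 = 2.5, U = 25)
#' p
#' @seealso [run_simulation()], [validate_params()]
#' @export
risk_params <- function(N = 100, a = 10, n = 10,
                        m = 10, u = 5,
                        w1 = 2, w = 4, w2 = 1,
                        t1 = 5, t2 = 2.5, U = 25,
                        beta = 0.1, alpha = 0.05,
                        strategy_set = STRATEGIES,
                        rounds = 3000, stable_window = 500,
                        replicates = 20,
                        peer_regime = c("pairwise", "one_act"),
                        failure_rule = c("zero", "debts"),
                        learning_input = c("round", "cumulative"),
                        partner_scope = c("population", "subgroup"),
                        rate_basis = c("members", "collaborators"),
                        seed = NULL) {
  p <- list(
    N = as.integer(N), a = as.integer(a), n = as.integer(n),
    m = as.numeric(m), u = as.numeric(u),
    w1 = as.numeric(w1), w = as.numeric(w), w2 = as.numeric(w2),
    t1 = as.numeric(t1), t2 = as.numeric(t2), U = as.numeric(U),
    beta = as.numeric(beta), alpha = as.numeric(alpha),
    strategy_set = as.character(strategy_set),
    rounds = as.integer(rounds),
    stable_window = as.integer(stable_window),
    replicates = as.integer(replicates),
    peer_regime = match.arg(peer_regime),
    failure_rule = match.arg(failure_rule),
    learning_input = match.arg(learning_input),
    partner_scope = match.arg(partner_scope),
    rate_basis = match.arg(rate_basis),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(p) <- "risk_params"
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model parameters and returns
#' the object unchanged if all hold; otherwise raises an error naming the
#' offending field.
#'
#' @param p A `"risk_params"` object (or compatible list).
#' @return `p`, invisibly unchanged, if valid.
#' @export
validate_params <- function(p) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
    }
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("N", "a", "n", "m", "u", "w1", "w", "w2", "t1", "t2", "U",
              "beta", "alpha", "rounds", "stable_window", "replicates")) {
    chk(num1(p[[f]]), f, "must be a single finite number")
  }
  chk(p$N >= 2, "N", "population must have at least 2 individuals")
  chk(p$N == p$a * p$n, "N", sprintf("N must equal a * n (%d != %d * %d)",
                                     p$N, p$a, p$n))
  for (f in c("m", "u", "w1", "w", "w2", "t1", "t2", "U")) {
    chk(p[[f]] >= 0, f, "must be non-negative")
  }
  chk(p$u <= p$m, "u", "contribution cannot exceed the endowment m")
  chk(p$beta > 0 && p$beta <= 1, "beta", "must lie in (0, 1]")
  chk(p$alpha >= 0 && p$alpha <= 1, "alpha", "must lie in [0, 1]")
  chk(p$w2 <= p$t2, "w2", "peer punishment cost w2 cannot exceed its intensity t2")
  chk(p$rounds >= 1, "rounds", "must be at least 1")
  chk(p$stable_window >= 1 && p$stable_window <= p$rounds,
      "stable_window", "must lie in [1, rounds]")
  chk(p$replicates >= 1, "replicates", "must be at least 1")
  chk(p$peer_regime %in% c("pairwise", "one_act"), "peer_regime",
      "must be \"pairwise\" or \"one_act\"")
  chk(p$failure_rule %in% c("zero", "debts"), "failure_rule",
      "must be \"zero\" or \"debts\"")
  chk(p$learning_input %in% c("round", "cumulative"), "learning_input",
      "must be \"round\" or \"cumulative\"")
  chk(length(p$strategy_set) >= 2 && !anyDuplicated(p$strategy_set) &&
        all(p$strategy_set %in% STRATEGIES),
      "strategy_set", "must be >= 2 distinct labels from {C, CP, PP, D}")
  invisible(p)
}

#' @export
print.risk_params <- function(x, ...) {
  cat("<risk_params>\n")
  cat(sprintf("  population   N = %d  (%d subgroups of %d)\n", x$N, x$a, x$n))
  cat(sprintf("  economy      m = %g, u = %g, U = %g\n", x$m, x$u, x$U))
  cat(sprintf("  central      w1 = %g, w = %g, t1 = %g\n", x$w1, x$w, x$t1))
  cat(sprintf("  peer         w2 = %g, t2 = %g\n", x$w2, x$t2))
  cat(sprintf("  evolution    beta = %g, alpha = %g, strategies = {%s}\n",
              x$beta, x$alpha, paste(x$strategy_set, collapse = ", ")))
  cat(sprintf("  run          rounds = %d, stable_window = %d, replicates = %d\n",
              x$rounds, x$stable_window, x$replicates))
  invisible(x)
}

# internal: strategy labels -> integer codes 1..4 (C, CP, PP, D)
strategy_codes <- function(labels) {
  codes <- match(labels, STRATEGIES)
  if (anyNA(codes)) {
    stop("unknown strategy label(s): ",
         paste(labels[is.na(codes)], collapse = ", "), call. = FALSE)
  }
  as.integer(codes)
}

# internal: sorted integer codes of the allowed strategy set
set_codes <- function(p) sort(strategy_codes(p$strategy_set))
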