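# Between-round dynamics: Fermi pairwise imitation and mutation.
# Draw accounting matters here: the compiled engine replays exactly the
# same runif sequence, which is what makes the two engines comparable
# bit-for-bit in tests.

#' Fermi imitation probability
#'
#' Probability that individual *i*, holding resources `ri`, adopts the
#' strategy of individual *j* holding `rj`:
#' `p = 1 / (1 + exp((ri - rj) / beta))`.  Poorer individuals imitate
#' richer ones with probability approaching 1; the temperature `beta` sets
#' how sharply the probability switches around `ri = rj`.  Saturates to 0
#' or 1 without overflow for large resource gaps.
#'
#' @param ri,rj Resource balances (vectorized).
#' @param beta Learning temperature, must be positive.
#' @return Imitation probabilities in `[0, 1]`.
#' @examples
#' fermi_probability(5, 5, 0.1)    # 0.5
#' fermi_probability(0, 10, 0.1)   # ~1
#' @export
fermi_probability <- function(ri, rj, beta) {
  if (!is.numeric(beta) || any(beta <= 0)) {
    stop("invalid parameter `beta`: must be positive", call. = FALSE)
  }
  # exp() overflows to Inf for large gaps; 1/(1+Inf) = 0 is the correct limit
  1 / (1 + exp((ri - rj) / beta))
}

#' Synchronous Fermi imitation step
#'
#' Each individual independently draws one model partner uniformly from
#' the other `N - 1` individuals (or from its own subgroup when
#' `p$partner_scope == "subgroup"`), and adopts that partner's strategy
#' with the Fermi probability computed from this round's resource
#' balances.  All comparisons use the pre-learning strategy vector and all
#' adoptions are applied simultaneously; resources are unchanged.
#' Consumes exactly `2 * N` uniform draws.
#'
#' @param state A `"population_state"` holding end-of-round resources.
#' @param p A [risk_params()] object (supplies `beta` and
#'   `partner_scope`).
#' @param assignment The round's `"subgroup_assignment"`; required only
#'   for subgroup-scoped partner selection.
#' @return The updated `"population_state"`.
#' @export
learning_step <- function(state, p, assignment = NULL) {
  N <- length(state$strategies)
  if (N < 2L) stop("learning requires at least 2 individuals", call. = FALSE)
  u_partner <- runif(N)
  u_coin <- runif(N)
  old <- state$strategies
  if (p$partner_scope == "subgroup") {
    if (is.null(assignment)) {
      stop("subgroup-scoped learning needs the round's `assignment`",
           call. = FALSE)
    }
    group_of <- integer(N)
    group_of[as.vector(t(assignment))] <- rep(seq_len(p$a), each = p$n)
    partner <- integer(N)
    for (i in seq_len(N)) {
      members <- assignment[group_of[i], ]
      others <- members[members != i]
      partner[i] <- others[floor(u_partner[i] * length(others)) + 1L]
    }
  } else {
    j0 <- floor(u_partner * (N - 1))            # 0 .. N-2
    j0 <- j0 + (j0 >= seq_len(N) - 1L)          # skip self
    partner <- as.integer(j0) + 1L
  }
  pij <- fermi_probability(state$resources, state$resources[partner], p$beta)
  adopt <- u_coin < pij
  new_strat <- ifelse(adopt, old[partner], old)
  new_population_state(new_strat, state$resources, state$round_index)
}

#' Mutation step
#'
#' Exactly `round(alpha * N)` distinct individuals, chosen uniformly
#' without replacement, each switch to a strategy drawn uniformly from the
#' allowed set minus their current strategy.  All other individuals are
#' unchanged.  Consumes `N + round(alpha * N)` uniform draws when the
#' mutation count is positive, none otherwise.
#'
#' @param state A `"population_state"`.
#' @param p A [risk_params()] object (supplies `alpha` and
#'   `strategy_set`).
#' @return The updated `"population_state"`.
#' @export
mutation_step <- function(state, p) {
  N <- length(state$strategies)
  k <- round(p$alpha * N)
  if (k == 0) return(state)
  set <- set_codes(p)
  if (length(set) < 2L) {
    stop("mutation requires at least 2 strategies in `strategy_set`",
         call. = FALSE)
  }
  chosen <- order(runif(N))[seq_len(k)]
  u_new <- runif(k)
  strat <- state$strategies
  for (idx in seq_len(k)) {
    i <- chosen[idx]
    alts <- set[set != strat[i]]
    strat[i] <- alts[floor(u_new[idx] * length(alts)) + 1L]
  }
  new_population_state(strat, state$resources, state$round_index)
}
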