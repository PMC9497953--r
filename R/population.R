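#' Initialize a population
#'
#' Draws each individual's strategy independently and uniformly from
#' `p$strategy_set`, sets all resource balances to zero, and stamps the
#' state with round index 0.  Consumes exactly `N` uniform draws from the
#' current RNG stream.
#'
#' @param p A [risk_params()] object.
#' @return A list of class `"population_state"` with elements `strategies`
#'   (integer codes into `c("C","CP","PP","D")`), `resources` (numeric,
#'   units) and `round_index`.
#' @examples
#' set.seed(1)
#' st <- initialize_population(risk_params())
#' table(STRATEGIES[st$strategies])
#' @export
initialize_population <- function(p) {
  validate_params(p)
  set <- set_codes(p)
  # floor(u * s) + 1 rather than sample(): the compiled engine replays the
  # identical draw sequence, so the two engines agree bit-for-bit
  idx <- floor(runif(p$N) * length(set)) + 1L
  new_population_state(set[idx], numeric(p$N), 0L)
}

new_population_state <- function(strategies, resources, round_index) {
  structure(
    list(strategies = as.integer(strategies),
         resources = as.numeric(resources),
         round_index = as.integer(round_index)),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> N = %d, round %d\n",
              length(x$strategies), x$round_index))
  print(table(strategy = factor(STRATEGIES[x$strategies], levels = STRATEGIES)))
  invisible(x)
}

#' Tidy a population state
#'
#' @param x A `"population_state"`.
#' @param ... Unused.
#' @return A tibble with one row per individual: `id`, `strategy`,
#'   `resources`.
#' @export
tidy.population_state <- function(x, ...) {
  tibble::tibble(
    id = seq_along(x$strategies),
    strategy = STRATEGIES[x$strategies],
    resources = x$resources
  )
}

#' Randomly partition the population into subgroups
#'
#' Draws a uniformly random partition of the `N` individuals into `a`
#' disjoint blocks of size `n` (a random permutation chopped into
#' consecutive blocks).  Consumes exactly `N` uniform draws.
#'
#' @param p A [risk_params()] object.
#' @return An integer matrix of class `"subgroup_assignment"` with `a` rows
#'   (subgroups) and `n` columns holding individual indices.
#' @examples
#' set.seed(1)
#' partition_into_subgroups(risk_params())[1, ]
#' @export
partition_into_subgroups <- function(p) {
  validate_params(p)
  perm <- order(runif(p$N))
  structure(matrix(perm, nrow = p$a, ncol = p$n, byrow = TRUE),
            class = "subgroup_assignment")
}

#' Build a deterministic population fixture
#'
#' Constructs a population with an exactly specified strategy composition
#' per subgroup, together with the block-identity subgroup assignment
#' (individuals `1..n` form subgroup 1, and so on).  Useful for worked
#' examples and unit tests where the random partition would obscure the
#' arithmetic.
#'
#' @param counts A list with one element per subgroup, each a named numeric
#'   vector of strategy counts, e.g. `c(C = 3, CP = 2, PP = 2, D = 3)`.
#'   Each must sum to `p$n`, and `length(counts)` must equal `p$a`.
#' @param p A [risk_params()] object.
#' @return A list with elements `state` (a `"population_state"` with zero
#'   resources) and `assignment` (a `"subgroup_assignment"`).
#' @examples
#' p <- risk_params(N = 10, a = 1, n = 10, U = 35)
#' fx <- make_fixture(list(c(C = 3, CP = 2, PP = 2, D = 3)), p)
#' STRATEGIES[fx$state$strategies]
#' @export
make_fixture <- function(counts, p) {
  validate_params(p)
  if (length(counts) != p$a) {
    stop(sprintf("`counts` must have one element per subgroup (%d), got %d",
                 p$a, length(counts)), call. = FALSE)
  }
  strat <- integer(0)
  for (g in seq_along(counts)) {
    cnt <- counts[[g]]
    if (is.null(names(cnt)) || !all(names(cnt) %in% STRATEGIES)) {
      stop("each count vector must be named with strategy labels", call. = FALSE)
    }
    if (sum(cnt) != p$n) {
      stop(sprintf("subgroup %d counts sum to %g, expected n = %d",
                   g, sum(cnt), p$n), call. = FALSE)
    }
    strat <- c(strat, rep(strategy_codes(names(cnt)), times = cnt))
  }
  assignment <- structure(
    matrix(seq_len(p$N), nrow = p$a, ncol = p$n, byrow = TRUE),
    class = "subgroup_assignment"
  )
  list(state = new_population_state(strat, numeric(p$N), 0L),
       assignment = assignment)
}
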