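#' Run one seeded multi-round simulation
#'
#' Executes `p$rounds` rounds of the risk-resistant game: each round the
#' population is endowed and randomly partitioned, every subgroup plays the
#' contribution / punishment / risk pipeline ([play_round()]), then
#' strategies update by synchronous Fermi imitation ([learning_step()])
#' followed by mutation ([mutation_step()]).  The run is fully reproducible
#' from `(p, seed)`; the caller's RNG state is left untouched.
#'
#' The default engine is compiled C++; `engine = "r"` runs the identical
#' process composed from the exported R operations.  Both engines consume
#' the same random draw sequence, so they return bit-identical results for
#' the same seed.
#'
#' @param p A [risk_params()] object.
#' @param seed Integer seed (defaults to `p$seed`).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return An object of class `"risk_run"`: a list with `params`, `seed`,
#'   `engine`, `series` (a tibble with one row per round: strategy counts
#'   at play time, `successes`, `succ_collaborators`, and round-aggregated
#'   punishment `central_loss`, `central_cost`, `peer_loss`, `peer_cost`)
#'   and `final_state`.
#' @examples
#' run <- run_simulation(risk_params(rounds = 200, stable_window = 50), seed = 1)
#' glance(run)
#' @export
run_simulation <- function(p, seed = p$seed, engine = c("cpp", "r")) {
  validate_params(p)
  engine <- match.arg(engine)
  if (is.null(seed)) {
    stop("a `seed` is required (pass it or set it in risk_params())",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  out <- withr::with_seed(seed, {
    state <- initialize_population(p)
    if (engine == "cpp") {
      raw <- sim_run_cpp(
        list(N = p$N, a = p$a, n = p$n, m = p$m, u = p$u,
             w1 = p$w1, w = p$w, w2 = p$w2, t1 = p$t1, t2 = p$t2,
             U = p$U, beta = p$beta, rounds = p$rounds,
             mut_k = as.integer(round(p$alpha * p$N)),
             subgroup_scope = identical(p$partner_scope, "subgroup"),
             keep_debts = identical(p$failure_rule, "debts"),
             cumulative = identical(p$learning_input, "cumulative"),
             peer_one_act = identical(p$peer_regime, "one_act"),
             strategy_set = set_codes(p)),
        state$strategies
      )
      list(
        counts = raw$counts,
        successes = raw$successes,
        succ_collaborators = raw$succ_collaborators,
        ledger = raw$ledger,
        final_state = new_population_state(raw$final_strategies,
                                           raw$final_resources, p$rounds)
      )
    } else {
      sim_run_r(p, state)
    }
  })
  series <- tibble::tibble(
    round = seq_len(p$rounds),
    n_C = out$counts[, 1], n_CP = out$counts[, 2],
    n_PP = out$counts[, 3], n_D = out$counts[, 4],
    successes = as.integer(out$successes),
    succ_collaborators = as.integer(out$succ_collaborators),
    central_loss = out$ledger[, 1], central_cost = out$ledger[, 2],
    peer_loss = out$ledger[, 3], peer_cost = out$ledger[, 4]
  )
  structure(
    list(params = p, seed = seed, engine = engine,
         series = series, final_state = out$final_state),
    class = "risk_run"
  )
}

# pure-R engine: composes the exported per-round operations; consumes the
# same draw sequence as the compiled engine
sim_run_r <- function(p, state) {
  T_ <- p$rounds
  counts <- matrix(0L, T_, 4)
  successes <- integer(T_)
  scol <- integer(T_)
  ledger <- matrix(0, T_, 4)
  wealth <- numeric(p$N)
  for (r in seq_len(T_)) {
    counts[r, ] <- tabulate(state$strategies, 4L)
    assignment <- partition_into_subgroups(p)
    played <- play_round(state, assignment, p)
    led <- played$ledger
    successes[r] <- sum(led$success)
    scol[r] <- sum((led$n_C + led$n_CP + led$n_PP)[led$success])
    ledger[r, ] <- c(sum(led$central_loss), sum(led$central_cost),
                     sum(led$peer_loss), sum(led$peer_cost))
    # accumulated holdings: grow while the member's subgroups succeed,
    # wiped ("zero") or capped at remaining debt ("debts") on failure
    member_success <- logical(p$N)
    member_success[as.vector(t(assignment))] <- rep(led$success, each = p$n)
    wealth <- ifelse(member_success,
                     wealth + played$pre_risk_balances,
                     if (identical(p$failure_rule, "debts")) {
                       pmin(wealth + played$pre_risk_balances, 0)
                     } else {
                       0
                     })
    learn_res <- if (identical(p$learning_input, "cumulative")) {
      wealth
    } else {
      played$state$resources
    }
    learned <- learning_step(
      new_population_state(played$state$strategies, learn_res,
                           played$state$round_index),
      p, assignment
    )
    state <- new_population_state(learned$strategies,
                                  played$state$resources,
                                  played$state$round_index)
    state <- mutation_step(state, p)
  }
  list(counts = counts, successes = successes, succ_collaborators = scol,
       ledger = ledger,
       final_state = new_population_state(state$strategies, state$resources,
                                          T_))
}

#' @export
print.risk_run <- function(x, ...) {
  p <- x$params
  cat(sprintf("<risk_run> %d rounds, seed %d, engine %s\n",
              p$rounds, x$seed, x$engine))
  cat(sprintf("  t1 = %g, t2 = %g, U = %g, strategies = {%s}\n",
              p$t1, p$t2, p$U, paste(p$strategy_set, collapse = ", ")))
  cat(sprintf("  stable-window collaboration rate: %.3f\n",
              collaboration_rate(x, window = "stable")))
  invisible(x)
}

#' Tidy the per-round time series of a run
#'
#' @param x A `"risk_run"`.
#' @param ... Unused.
#' @return A tibble with one row per round: strategy counts, success
#'   counts, punishment ledger aggregates, and the per-round
#'   `collaboration` rate.
#' @export
tidy.risk_run <- function(x, ...) {
  p <- x$params
  dplyr::mutate(x$series,
                collaboration = .data$successes * p$n / p$N)
}

#' One-row summary of a run on its stable window
#'
#' @param x A `"risk_run"`.
#' @param ... Unused.
#' @return The [summarize_run()] tibble computed on the stable window.
#' @export
glance.risk_run <- function(x, ...) {
  summarize_run(x, window = "stable")
}

#' Plot the strategy-share and collaboration trajectories of a run
#'
#' @param object A `"risk_run"`.
#' @param ... Unused.
#' @return A ggplot: per-round population shares of the four strategies
#'   plus the collaboration rate.
#' @export
autoplot.risk_run <- function(object, ...) {
  p <- object$params
  df <- tidy(object) |>
    dplyr::mutate(C = .data$n_C / p$N, CP = .data$n_CP / p$N,
                  PP = .data$n_PP / p$N, D = .data$n_D / p$N) |>
    dplyr::select("round", "C", "CP", "PP", "D", "collaboration") |>
    tidyr::pivot_longer(-"round", names_to = "series", values_to = "share")
  ggplot2::ggplot(df, ggplot2::aes(.data$round, .data$share,
                                   colour = .data$series)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "round", y = "population share / rate",
                  colour = NULL,
                  title = sprintf("t1 = %g, t2 = %g, U = %g",
                                  p$t1, p$t2, p$U)) +
    ggplot2::theme_minimal()
}
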