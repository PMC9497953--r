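# Summary statistics over a window of rounds: collaboration rate,
# punishment enhancement, cost-benefit ratios, resource wastage.

# resolve a window argument into round indices
#   "stable" -> trailing stable_window rounds; "all" -> every round;
#   integer vector -> used as is
window_rounds <- function(run, window) {
  T_ <- run$params$rounds
  if (is.character(window)) {
    window <- match.arg(window, c("stable", "all"))
    if (window == "stable") {
      return(seq.int(T_ - run$params$stable_window + 1L, T_))
    }
    return(seq_len(T_))
  }
  window <- as.integer(window)
  if (length(window) == 0L) stop("empty window", call. = FALSE)
  if (any(window < 1L | window > T_)) {
    stop("window must lie within 1..rounds", call. = FALSE)
  }
  window
}

#' Collaboration rate of a run
#'
#' The fraction of individuals who withstood the risk, averaged over a
#' window of rounds.  With the default basis every member of a successful
#' subgroup counts (defectors shelter under their subgroup's success);
#' `basis = "collaborators"` counts only the contributing members.
#'
#' @param run A `"risk_run"`.
#' @param window `"stable"` (trailing `stable_window` rounds, default),
#'   `"all"`, or an integer vector of round indices.
#' @param basis `"members"` or `"collaborators"`; defaults to the run's
#'   `rate_basis` parameter.
#' @return A fraction in `[0, 1]`.
#' @export
collaboration_rate <- function(run, window = "stable",
                               basis = run$params$rate_basis) {
  rows <- window_rounds(run, window)
  p <- run$params
  basis <- match.arg(basis, c("members", "collaborators"))
  if (basis == "members") {
    mean(run$series$successes[rows] * p$n / p$N)
  } else {
    mean(run$series$succ_collaborators[rows] / p$N)
  }
}

#' Enhancement of collaboration by one punishment type
#'
#' The signed difference between the collaboration rate of a full
#' four-strategy run and that of a matched run with the punishment type of
#' interest removed from the strategy set (reduced set `{C, D, PP}` when
#' isolating central punishment, `{C, D, CP}` for peer punishment).
#' Positive values mean the punishment promoted collaboration; negative
#' values mean it suppressed it.
#'
#' @param rate_full Collaboration rate with all four strategies.
#' @param rate_reduced Collaboration rate of the matched reduced-set run.
#' @return `rate_full - rate_reduced`.
#' @export
enhancement <- function(rate_full, rate_reduced) {
  stopifnot(all(rate_full >= 0 & rate_full <= 1, na.rm = TRUE),
            all(rate_reduced >= 0 & rate_reduced <= 1, na.rm = TRUE))
  rate_full - rate_reduced
}

#' Cost-benefit ratios of the two punishment types
#'
#' For each punishment type, the average resources docked per defector
#' divided by the average cost paid per punisher, pooled over the window
#' (sums of numerators and denominators are aggregated across rounds and
#' subgroups before dividing, so rounds without defectors or punishers do
#' not produce 0/0 terms):
#' \deqn{CBR_{central} = \frac{\sum central\_loss / \sum n_D}
#'                            {\sum central\_cost / \sum n_{CP}}, \quad
#'       CBR_{peer} = \frac{\sum peer\_loss / \sum n_D}
#'                         {\sum peer\_cost / \sum n_{PP}}.}
#' A ratio is `NA` when its punisher count or the defector count sums to
#' zero over the window.
#'
#' @param run A `"risk_run"`.
#' @param window As in [collaboration_rate()]; `"stable"` gives the
#'   evolutionary-stable-state ratio, `"all"` the whole-process ratio.
#' @return A named list with `cbr_central` and `cbr_peer`.
#' @export
cost_benefit_ratios <- function(run, window = "stable") {
  rows <- window_rounds(run, window)
  s <- run$series[rows, ]
  nD <- sum(s$n_D); nCP <- sum(s$n_CP); nPP <- sum(s$n_PP)
  cbr_central <- if (nD > 0 && nCP > 0 && sum(s$central_cost) > 0) {
    (sum(s$central_loss) / nD) / (sum(s$central_cost) / nCP)
  } else {
    NA_real_
  }
  cbr_peer <- if (nD > 0 && nPP > 0 && sum(s$peer_cost) > 0) {
    (sum(s$peer_loss) / nD) / (sum(s$peer_cost) / nPP)
  } else {
    NA_real_
  }
  list(cbr_central = cbr_central, cbr_peer = cbr_peer)
}

#' Difference between peer and central cost-benefit ratios
#'
#' `cbr_peer - cbr_central`, both computed from the same four-strategy run
#' at the run's punishment intensities.  `NA` if either ratio is
#' undefined on the window.
#'
#' @inheritParams cost_benefit_ratios
#' @return A signed difference, or `NA`.
#' @export
cbr_difference <- function(run, window = "stable") {
  r <- cost_benefit_ratios(run, window)
  r$cbr_peer - r$cbr_central
}

#' Resource wastage
#'
#' The average amount contributed per subgroup beyond what the risk
#' required: mean over window rounds and subgroups of the subgroup's total
#' contribution, minus the threshold `U`.  Negative values mean the group
#' on average failed to raise enough.
#'
#' @inheritParams cost_benefit_ratios
#' @return Wastage `k` in resource units.
#' @export
resource_wastage <- function(run, window = "stable") {
  rows <- window_rounds(run, window)
  p <- run$params
  s <- run$series[rows, ]
  n_collab <- s$n_C + s$n_CP + s$n_PP
  mean(p$u * n_collab / p$a) - p$U
}

#' Waste zone of a wastage value
#'
#' Deterministic zoning of the wastage `k` (in units of resources; the
#' cutpoints 3 and 6 are fractions of one extra collaborator's
#' contribution): `k < 0` insufficient contribution, `0 <= k < 3` no
#' waste, `3 <= k < 6` slight waste, `k >= 6` waste.
#'
#' @param k Wastage value(s) from [resource_wastage()].
#' @return A character vector of zone labels.
#' @examples
#' waste_zone(c(-2, 0, 5, 6))
#' @export
waste_zone <- function(k) {
  stopifnot(is.numeric(k), all(is.finite(k)))
  dplyr::case_when(
    k < 0 ~ "insufficient",
    k < 3 ~ "none",
    k < 6 ~ "slight",
    TRUE ~ "waste"
  )
}

#' Summary statistics of a run on a window
#'
#' @inheritParams cost_benefit_ratios
#' @return A one-row tibble: `collaboration_rate`, strategy shares
#'   (`share_C` .. `share_D`), `cbr_central`, `cbr_peer`,
#'   `cbr_difference`, `wastage_k`, `wastage_zone`.
#' @examples
#' run <- run_simulation(risk_params(rounds = 200, stable_window = 50), seed = 1)
#' summarize_run(run)
#' @export
summarize_run <- function(run, window = "stable") {
  rows <- window_rounds(run, window)
  p <- run$params
  s <- run$series[rows, ]
  cbr <- cost_benefit_ratios(run, window)
  k <- resource_wastage(run, window)
  tibble::tibble(
    collaboration_rate = collaboration_rate(run, window),
    share_C = mean(s$n_C) / p$N,
    share_CP = mean(s$n_CP) / p$N,
    share_PP = mean(s$n_PP) / p$N,
    share_D = mean(s$n_D) / p$N,
    cbr_central = cbr$cbr_central,
    cbr_peer = cbr$cbr_peer,
    cbr_difference = cbr$cbr_peer - cbr$cbr_central,
    wastage_k = k,
    wastage_zone = waste_zone(k)
  )
}
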