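---
title: "A threshold public-goods game with central and peer punishment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A threshold public-goods game with central and peer punishment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskgame)
library(dplyr)
```

## The model

`riskgame` simulates a collective-risk social dilemma: a population of
`N = a n` agents is re-partitioned every round into `a` subgroups of size
`n`, each subgroup must jointly raise a contribution threshold `U`, and a
subgroup that falls short fails — **every** member of a failed subgroup
loses all resources.  Individual payoffs are therefore a segmented
function of the subgroup's collaboration, unlike the linear public-goods
game: below the threshold everything is lost, above it nothing more is
gained.

Each agent holds one of four strategies:

* `C` — collaborator: contributes `u` toward the threshold;
* `CP` — collaborator who additionally pays `w1` into a sanctioning pool;
  if the subgroup's pool reaches `w` (`w1 n_CP >= w`), a central
  institution is established and docks every defector `t1`, once per
  round;
* `PP` — collaborator who punishes peers: every `PP` punishes every
  defector in the subgroup, paying `w2` per act and docking the target
  `t2` (`w2 <= t2`);
* `D` — defector: contributes nothing, the target of both sanctions.

A round proceeds subgroup by subgroup: endowment `m` → contributions →
central punishment → peer punishment → threshold resolution
(`sum u >= U`, inclusive).  Between rounds strategies evolve by
synchronous pairwise imitation with the Fermi rule
$$p_{ij} = \frac{1}{1 + e^{(r_i - r_j)/\beta}},$$
where $r_i$ is the agent's end-of-round balance and $\beta$ the learning
temperature, followed by mutation: exactly `round(alpha N)` distinct
agents resample a strategy uniformly from the allowed set minus their
current one.

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| `N, a, n` | population, subgroups, subgroup size | 100, 10, 10 | agents |
| `m` | per-round endowment | 10 | resources |
| `u` | contribution | 5 | resources |
| `w1, w` | pool payment per CP, institution threshold | 2, 4 | resources |
| `t1` | central punishment intensity | swept 2–9.5 | resources |
| `w2` | cost of one peer-punishment act | 1 | resources |
| `t2` | peer punishment intensity | swept 1–6.5 | resources |
| `U` | risk threshold | 15 / 25 / 35 | resources |
| `beta` | Fermi temperature | 0.1 | resources |
| `alpha` | mutation rate | 0.05 | — |

With `u = 5` and `n = 10` the three risk levels require 3, 5 and 7
collaborators per subgroup.  The canonical fixed points used when one
intensity is swept — `t2 = 2.5` and `t1 = 5` — satisfy
`t1 : t2 = w1 : w2`, which makes the two punishment types
cost-comparable.

`beta = 0.1` makes imitation nearly deterministic toward the richer
partner once balances differ by a unit or more; `alpha = 0.05` keeps a
constant inflow of five mutants per round, which sets the floor share of
any strategy under strong selection.

## Run length, windows and replication

The strategy dynamics reach a statistically stationary regime within a
few hundred rounds at these parameter values.  Runs default to
`rounds = 3000` with summary statistics taken on the trailing
`stable_window = 500` rounds ("stable state"); whole-run windows
(`window = "all"`) give the in-process statistics.  Sweeps default to 20
replicate seeds per cell (10 for the three-strategy-set enhancement
experiment, whose cost is roughly ninefold).  A stationarity check —
the first and second half of the stable window differing in
collaboration rate by well under 0.05 on average — holds across the
default grid.

## Summary statistics

* **Collaboration rate** — the fraction of agents belonging to subgroups
  that met the threshold, averaged over a window.  The default counts
  every member of a successful subgroup, including its defectors, because
  resisting the risk shelters the whole subgroup; `basis =
  "collaborators"` restricts to contributing members.
* **Enhancement** — the paired difference between the four-strategy
  collaboration rate and a matched run whose strategy set drops one
  punishment type (`{C, D, PP}` isolates central punishment, `{C, D,
  CP}` peer punishment).  Matched means the runs share replicate seeds;
  see below.
* **Cost–benefit ratio (CBR)** — resources docked per defector divided by
  cost paid per punisher, pooled over the window before dividing (a
  ratio of sums, not a mean of per-round ratios, so rounds without
  defectors or punishers contribute no 0/0 terms).  Whenever defined,
  the peer ratio obeys the closed form
  `cbr_peer = (t2 / w2) (sum n_PP / sum n_D)`, and
  `cbr_central <= t1 / w1` with equality exactly when every defector sat
  in an institution-established subgroup.
* **Resource wastage** — `k` = mean subgroup contribution minus `U`,
  zoned as insufficient (`k < 0`), none (`0 <= k < 3`), slight
  (`3 <= k < 6`) and waste (`k >= 6`).  `k` is defined at subgroup level
  because the zone cutpoints are fractions of one extra collaborator's
  `u = 5` contribution and would be unreachable per capita.

```{r metrics-demo}
p <- risk_params(t1 = 5, t2 = 2.5, U = 25, rounds = 600, stable_window = 200)
run <- run_simulation(p, seed = 1)
glance(run)
```

## Design decisions

Several mechanics are underdetermined by the verbal model description;
the package fixes them as follows and exposes the live alternatives as
`risk_params()` options so their effect can be measured rather than
argued.

* **Institution scope.**  The sanctioning pool is per subgroup
  (`w1 n_CP` summed within the subgroup): punishment executes on the
  subgroup's defectors and all other mechanics are subgroup-local.  The
  `CP` payment is sunk — it is an upfront investment, paid whether or
  not the pool reaches `w`.
* **Punishment multiplicities.**  Central punishment hits each defector
  once per round.  Peer punishment is all-against-all by default
  (`peer_regime = "pairwise"`); `"one_act"` instead charges each
  punisher a single `w2` per round, with the `t2` effect spread over the
  subgroup's defectors.  Pairwise reproduces the reference behaviour of
  the model clearly better across the sweep experiments and is the
  default.
* **Failure rule.**  "Losing everything" is implemented as set-to-zero,
  including balances that punishment had driven negative
  (`failure_rule = "zero"`); the alternative `"debts"` lets negative
  balances persist.  The two differ little in practice because heavily
  negative balances arise only under strong punishment in failing
  subgroups.
* **Learning.**  Partners are drawn from the whole population
  (`partner_scope = "population"`); the subgroup-scoped alternative
  collapses collaboration at these parameter values because failed
  subgroups degenerate into all-zero coin-flip comparisons.  The Fermi
  comparison uses the current round's end-of-round balance
  (`learning_input = "round"`).  Comparing accumulated holdings
  (`"cumulative"`) makes wealth differences dominated by how long ago an
  agent's subgroup last failed, which turns imitation into age-biased
  neutral drift and washes out every intensity trend — it is retained
  only as a sensitivity switch.  Updates are synchronous against the
  frozen end-of-round snapshot, one partner draw per agent per round,
  and learning precedes mutation.
* **Numerics.**  Resources are real-valued (intensities take half-unit
  values); threshold comparisons (`>= w`, `>= U`) are inclusive and use
  a `1e-9` slack so that sums of halves compare exactly.  The Fermi
  probability saturates to machine 0/1 for large gaps instead of
  overflowing.  `round(alpha N)` uses banker's rounding for non-integral
  products.

## Reproducibility and seeds

Every run is a pure function of `(params, seed)`.  The default engine is
compiled C++; a pure-R engine composed from the exported per-round
operations consumes the identical uniform-draw sequence, and the test
suite asserts bit-identical output across engines — an end-to-end check
that the compiled fast path implements exactly the documented process.

Sweeps derive per-row seeds as `(base_seed + i * 2654435761) mod 2^31`,
a bijection in the row index, so seeds are reproducible and guaranteed
distinct.  In the enhancement experiment, seeds depend only on
`(U, replicate)`: the full-strategy run and both reduced runs of a cell
share a seed, making the subtraction a paired comparison, and a reduced
run is computed once per value of the intensities it actually depends on
and reused across the orthogonal axis (its collaboration rate is
constant in the excluded intensity by construction).

## What the simulations do and do not show

The generator emulates the stated game exactly: well-mixed random
re-grouping, four pure strategies, synchronous imitation, uniform
mutation.  It does not model spatial or network structure, persistent
group membership, antisocial punishment (punishers targeting
collaborators), the two paradoxical defector-punisher strategies, or
heterogeneous endowments — conclusions from these simulations transfer
to real risk-sharing settings only insofar as those ingredients do not
dominate.  Punisher strategies are second-order altruists here: in every
payoff-monotone imitation dynamic they pay for a benefit shared by all
collaborators, so their stationary shares sit near the
mutation–selection floor.  Consequently the simulated stable-state
cost–benefit ratios of punishment are conservative relative to accounts
in which punisher shares stay elevated.
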