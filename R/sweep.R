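# Sweep orchestration over punishment intensities, risk thresholds and
# strategy sets, with reproducible per-row seeds and tidy output.

#' Update a parameter set
#'
#' Returns a revalidated copy of `p` with the named fields replaced.
#'
#' @param p A [risk_params()] object.
#' @param ... Named fields to replace (e.g. `t1 = 8`,
#'   `strategy_set = c("C", "D")`).
#' @return A validated `"risk_params"` object.
#' @export
update_params <- function(p, ...) {
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  validate_params(p)
  p
}

#' Sweep specification
#'
#' Describes a full factorial sweep over punishment intensities, risk
#' thresholds and strategy sets.  The default grids are the model's
#' canonical ranges: `t1` from 2 to 9.5 and `t2` from 1 to 6.5 in steps of
#' 0.5, `U` in `{15, 25, 35}`.
#'
#' @param t1_values,t2_values Numeric grids of punishment intensities.
#' @param U_values Numeric grid of risk thresholds.
#' @param strategy_sets List of strategy subsets, each a character vector.
#' @param replicates Replicate runs per grid cell.
#' @param base_seed Integer root seed; every row's seed derives from it.
#' @param rounds,stable_window Optional overrides of the run length and
#'   trailing stable window.
#' @return A list of class `"sweep_spec"`.
#' @export
sweep_spec <- function(t1_values = seq(2, 9.5, by = 0.5),
                       t2_values = seq(1, 6.5, by = 0.5),
                       U_values = c(15, 25, 35),
                       strategy_sets = list(STRATEGIES),
                       replicates = 20, base_seed = 1L,
                       rounds = NULL, stable_window = NULL) {
  stopifnot(all(t1_values >= 0), all(t2_values >= 0), all(U_values >= 0),
            replicates >= 1, length(strategy_sets) >= 1)
  structure(
    list(t1_values = t1_values, t2_values = t2_values, U_values = U_values,
         strategy_sets = strategy_sets,
         replicates = as.integer(replicates),
         base_seed = as.integer(base_seed),
         rounds = rounds, stable_window = stable_window),
    class = "sweep_spec"
  )
}

#' Derive a replicate seed from a base seed
#'
#' Deterministic, collision-free seed for row `i` of a sweep:
#' multiplication by an odd constant is a bijection mod 2^31, so distinct
#' indices always map to distinct seeds (exact in double arithmetic since
#' `i * c < 2^53`).
#'
#' @param base_seed Integer root seed.
#' @param i Positive integer index (replicate or grid-row number).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(base_seed, i) {
  as.integer((as.double(base_seed) + as.double(i) * 2654435761) %% 2^31)
}

set_label <- function(set) paste(set, collapse = "+")

# apply sweep-level overrides and one grid row to a params object
cell_params <- function(p, t1, t2, U, set, spec) {
  args <- list(t1 = t1, t2 = t2, U = U, strategy_set = set)
  if (!is.null(spec$rounds)) args$rounds <- spec$rounds
  if (!is.null(spec$stable_window)) args$stable_window <- spec$stable_window
  do.call(update_params, c(list(p), args))
}

#' Run a full factorial sweep
#'
#' Runs [run_simulation()] for every combination in the spec's
#' `t1 x t2 x U x strategy_set x replicate` grid and summarizes each run
#' on its stable window.  Deterministic given `spec$base_seed`: each row's
#' seed derives from the base seed and the row's position in the grid, and
#' all row seeds are distinct.
#'
#' @param spec A [sweep_spec()].
#' @param p A [risk_params()] template supplying all non-swept parameters.
#' @return A tibble with one row per grid cell and replicate: `t1`, `t2`,
#'   `U`, `strategy_set`, `replicate`, `seed`, and the [summarize_run()]
#'   columns.
#' @examples
#' spec <- sweep_spec(t1_values = 5, t2_values = 2.5, U_values = 25,
#'                    replicates = 2, rounds = 200, stable_window = 50)
#' run_sweep(spec, risk_params())
#' @export
run_sweep <- function(spec, p = risk_params()) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- tidyr::expand_grid(
    t1 = spec$t1_values, t2 = spec$t2_values, U = spec$U_values,
    set = spec$strategy_sets, replicate = seq_len(spec$replicates)
  )
  purrr::pmap(
    list(grid$t1, grid$t2, grid$U, grid$set, grid$replicate,
         seq_len(nrow(grid))),
    function(t1, t2, U, set, replicate, i) {
      seed <- derive_seed(spec$base_seed, i)
      pc <- tryCatch(
        cell_params(p, t1, t2, U, set, spec),
        error = function(e) {
          stop(sprintf("sweep cell (t1=%g, t2=%g, U=%g, set=%s): %s",
                       t1, t2, U, set_label(set), conditionMessage(e)),
               call. = FALSE)
        }
      )
      run <- run_simulation(pc, seed = seed)
      dplyr::bind_cols(
        tibble::tibble(t1 = t1, t2 = t2, U = U,
                       strategy_set = set_label(set),
                       replicate = replicate, seed = seed),
        summarize_run(run, window = "stable")
      )
    }
  ) |>
    dplyr::bind_rows()
}

#' Collaboration rate along one punishment intensity, with baseline
#'
#' Sweeps one punishment intensity while the other stays at its canonical
#' fixed value (`t2 = 2.5` when sweeping `t1`, `t1 = 5` when sweeping
#' `t2`; the fixed points satisfy `t1 = 2 t2` so the two punishment types
#' are cost-comparable, `t1 : t2 = w1 : w2`).  A `{C, D}`-only baseline at
#' the same risk threshold is included, seed-matched to the sweep: within
#' a replicate, every intensity value and the baseline share one seed, so
#' comparisons against the baseline are paired.
#'
#' @param p A [risk_params()] template.
#' @param U Risk threshold for the whole experiment.
#' @param axis `"t1"` or `"t2"`: which intensity varies.
#' @param values Grid for the varying intensity (defaults to the canonical
#'   range of that axis).
#' @param replicates,base_seed Replication controls.
#' @return A tibble like [run_sweep()]'s; baseline rows carry
#'   `strategy_set = "C+D"` and `NA` intensities.
#' @export
intensity_sweep <- function(p = risk_params(), U = 25,
                            axis = c("t1", "t2"), values = NULL,
                            replicates = p$replicates, base_seed = 1L) {
  axis <- match.arg(axis)
  if (is.null(values)) {
    values <- if (axis == "t1") seq(2, 9.5, by = 0.5) else seq(1, 6.5, by = 0.5)
  }
  rows <- list()
  for (rep in seq_len(replicates)) {
    seed <- derive_seed(base_seed, rep)
    for (v in values) {
      pc <- if (axis == "t1") {
        update_params(p, t1 = v, t2 = 2.5, U = U, strategy_set = STRATEGIES)
      } else {
        update_params(p, t1 = 5, t2 = v, U = U, strategy_set = STRATEGIES)
      }
      run <- run_simulation(pc, seed = seed)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(t1 = pc$t1, t2 = pc$t2, U = U,
                       strategy_set = set_label(pc$strategy_set),
                       replicate = rep, seed = seed),
        summarize_run(run, window = "stable")
      )
    }
    pb <- update_params(p, U = U, strategy_set = c("C", "D"))
    base_run <- run_simulation(pb, seed = seed)
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(t1 = NA_real_, t2 = NA_real_, U = U,
                     strategy_set = "C+D", replicate = rep, seed = seed),
      summarize_run(base_run, window = "stable")
    )
  }
  dplyr::bind_rows(rows)
}

#' Punishment enhancement surfaces over the intensity grid
#'
#' For every `(t1, t2, U)` cell, runs the full four-strategy game and the
#' two reduced games that drop one punishment type (`{C, D, PP}` to
#' isolate central punishment, `{C, D, CP}` to isolate peer punishment),
#' and reports the paired differences of stable-window collaboration
#' rates.  Within a replicate all runs share one seed (derived from
#' `(U, replicate)` only), so the subtraction is paired; a reduced run is
#' computed once per value of the intensities it actually depends on and
#' reused across the orthogonal axis.
#'
#' @param p A [risk_params()] template.
#' @param t1_values,t2_values,U_values Sweep grids.
#' @param replicates,base_seed Replication controls.
#' @return A tibble of class `"enhancement_table"`: one row per
#'   `(t1, t2, U)` with replicate-averaged `rate_full`,
#'   `rate_no_central`, `rate_no_peer`, `enhancement_central`
#'   (`rate_full - rate_no_central`) and `enhancement_peer`
#'   (`rate_full - rate_no_peer`).
#' @export
enhancement_sweep <- function(p = risk_params(),
                              t1_values = seq(2, 9.5, by = 0.5),
                              t2_values = seq(1, 6.5, by = 0.5),
                              U_values = c(15, 25, 35),
                              replicates = p$replicates, base_seed = 1L) {
  cache <- new.env(parent = emptyenv())
  rate_of <- function(pc, seed, key) {
    if (is.null(cache[[key]])) {
      cache[[key]] <- collaboration_rate(run_simulation(pc, seed = seed),
                                         window = "stable")
    }
    cache[[key]]
  }
  grid <- tidyr::expand_grid(t1 = t1_values, t2 = t2_values, U = U_values)
  out <- purrr::pmap(grid, function(t1, t2, U) {
    full <- nc <- np <- numeric(replicates)
    for (rep in seq_len(replicates)) {
      seed <- derive_seed(base_seed, match(U, U_values) * 10000L + rep)
      full[rep] <- rate_of(
        update_params(p, t1 = t1, t2 = t2, U = U, strategy_set = STRATEGIES),
        seed, sprintf("full|%g|%g|%g|%d", t1, t2, U, rep))
      nc[rep] <- rate_of(
        update_params(p, t1 = t1, t2 = t2, U = U,
                      strategy_set = c("C", "D", "PP")),
        seed, sprintf("nocentral|%g|%g|%d", t2, U, rep))
      np[rep] <- rate_of(
        update_params(p, t1 = t1, t2 = t2, U = U,
                      strategy_set = c("C", "D", "CP")),
        seed, sprintf("nopeer|%g|%g|%d", t1, U, rep))
    }
    tibble::tibble(
      t1 = t1, t2 = t2, U = U, replicates = replicates,
      rate_full = mean(full), rate_no_central = mean(nc),
      rate_no_peer = mean(np),
      enhancement_central = mean(enhancement(full, nc)),
      enhancement_peer = mean(enhancement(full, np))
    )
  }) |>
    dplyr::bind_rows()
  class(out) <- c("enhancement_table", class(out))
  out
}

#' Heatmaps of the punishment enhancement surfaces
#'
#' @param object An `"enhancement_table"` from [enhancement_sweep()].
#' @param ... Unused.
#' @return A ggplot of the central and peer enhancement surfaces over
#'   `(t1, t2)`, faceted by punishment type and risk threshold.
#' @export
autoplot.enhancement_table <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object,
    c("enhancement_central", "enhancement_peer"),
    names_to = "punishment", names_prefix = "enhancement_",
    values_to = "enhancement"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t1, .data$t2,
                                   fill = .data$enhancement)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(ggplot2::vars(.data$punishment),
                        ggplot2::vars(.data$U), labeller = "label_both") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "central intensity t1", y = "peer intensity t2",
                  fill = "enhancement") +
    ggplot2::theme_minimal()
}

#' Write a sweep table with a metadata sidecar
#'
#' Writes the table as CSV (RFC 4180: header row, UTF-8, `.` decimal
#' separator, missing values empty) or JSON lines, plus a
#' `<path>.meta.json` sidecar recording the full parameter set, sweep
#' controls, base seed and package version.
#'
#' @param table A tibble (e.g. from [run_sweep()]).
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @param p,spec Optional [risk_params()] / [sweep_spec()] recorded in the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = c("csv", "jsonl"),
                          p = NULL, spec = NULL) {
  format <- match.arg(format)
  if (nrow(table) == 0L) stop("refusing to write an empty table", call. = FALSE)
  if (format == "csv") {
    readr::write_csv(table, path, na = "")
  } else {
    writeLines(vapply(seq_len(nrow(table)), function(i) {
      jsonlite::toJSON(as.list(table[i, ]), auto_unbox = TRUE, digits = NA,
                       na = "null")
    }, character(1)), path)
  }
  meta <- list(
    artifact = "riskgame",
    version = as.character(utils::packageVersion("riskgame")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = if (is.null(p)) NULL else unclass(p),
    sweep = if (is.null(spec)) NULL else unclass(spec),
    base_seed = if (is.null(spec)) NULL else spec$base_seed,
    rows = nrow(table)
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
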