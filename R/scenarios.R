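# Scenario drivers: bind simulator, measurement and fitting into the named
# analyses. Each driver accepts reduced replication (n_reps) for desk-scale
# runs; defaults are the canonical study conditions (N = 100, 10000 events,
# 1000 reps).

new_scenario_result <- function(...) {
  structure(list(...), class = "scenario_result")
}

#' Variant-preference scenario (direct bias)
#'
#' Runs the variant-preference rule with the preferred variant redrawn each
#' repetition, and builds the pooled acquisition curve for variant A plus
#' the two preference strata (runs where A is preferred: the slope-1 line;
#' runs where B is preferred: the slope-`p_less` line). With `start_mode =
#' "both"` produces the full six-panel layout (fixed-half and
#' uniform-increment rows).
#'
#' @param start_mode `"fixed_half"`, `"uniform_increments"`, or `"both"`.
#' @param pooling Which curves drive the reported verdicts: `"pooled"`,
#'   `"by_preference"`, or `"both"` (all curves are always computed).
#' @param p_less Less-preferred copying probability.
#' @param n,n_events,n_reps,base_seed,bin_width Study conditions.
#' @param freq_spec,out_spec Measurement conventions (defaults:
#'   current-state frequency, copy-event outcome).
#' @return A `scenario_result` with `panels`: per start mode, the pooled
#'   and stratified curves, their fit comparisons, and the stratified
#'   linear slopes.
#' @export
scenario_variant_preference <- function(start_mode = c("fixed_half",
                                                       "uniform_increments",
                                                       "both"),
                                        pooling = c("both", "pooled",
                                                    "by_preference"),
                                        p_less = 0.2, n = 100L,
                                        n_events = 10000L, n_reps = 1000L,
                                        base_seed = 1L, bin_width = 0.01,
                                        freq_spec =
                                          frequency_spec("individual_state"),
                                        out_spec =
                                          outcome_spec("copy_event")) {
  start_mode <- match.arg(start_mode)
  pooling <- match.arg(pooling)
  modes <- if (start_mode == "both") {
    c("fixed_half", "uniform_increments")
  } else {
    start_mode
  }
  panels <- list()
  for (m in seq_along(modes)) {
    sc <- scenario_config(
      scenario = paste0("variant_preference/", modes[m]),
      n = n, n_events = n_events, n_reps = n_reps, start_mode = modes[m],
      rule = "variant_preference", p_less = p_less, bin_width = bin_width,
      base_seed = base_seed + (m - 1L) * n_reps
    )
    batch <- run_batch(sc)
    pref <- batch_info(batch)$preferred_variant
    pooled <- curve_from_runs(batch, "A", freq_spec, out_spec, bin_width)
    strata <- curve_from_runs(batch, "A", freq_spec, out_spec, bin_width,
                              strata = paste0("preferred_", pref))
    cmp_pooled <- suppressWarnings(compare_fits(pooled))
    cmp_strata <- lapply(strata, function(cv)
      suppressWarnings(compare_fits(cv)))
    slopes <- vapply(strata, function(cv)
      fit_linear(cv)$coefficients[["slope"]], numeric(1))
    panels[[modes[m]]] <- list(
      config = sc, pooled_curve = pooled, strata_curves = strata,
      pooled_comparison = cmp_pooled, strata_comparisons = cmp_strata,
      strata_slopes = slopes
    )
  }
  verdicts <- do.call(rbind, lapply(names(panels), function(nm) {
    data.frame(start_mode = nm, curve = "pooled",
               better = panels[[nm]]$pooled_comparison$better,
               relative_fit = panels[[nm]]$pooled_comparison$relative_fit,
               stringsAsFactors = FALSE)
  }))
  new_scenario_result(scenario = "variant_preference", panels = panels,
                      verdicts = verdicts, pooling = pooling,
                      base_seed = base_seed)
}

#' Demonstrator-subgroup scenario (model bias)
#'
#' Everyone copies a random member of a fixed subgroup of size `dm`.
#' Reports the pooled curve and fits plus the near-boundary slopes of the
#' curve (weighted linear fits over the outer 15% of the frequency range),
#' which flag the horizontal flattening that post-fixation certainty
#' produces near frequencies 0 and 1.
#'
#' @param start_mode Start regime.
#' @param dm Subgroup size.
#' @inheritParams scenario_variant_preference
#' @return A `scenario_result` with `curve`, `comparison`, `edge_slopes`.
#' @export
scenario_demonstrator_subgroup <- function(start_mode = c("fixed_half",
                                                          "uniform_increments",
                                                          "rare"),
                                           dm = 5L, n = 100L,
                                           n_events = 10000L,
                                           n_reps = 1000L, base_seed = 1L,
                                           bin_width = 0.01,
                                           freq_spec =
                                             frequency_spec("individual_state"),
                                           out_spec =
                                             outcome_spec("copy_event")) {
  start_mode <- match.arg(start_mode)
  sc <- scenario_config(
    scenario = paste0("demonstrator_subgroup/", start_mode),
    n = n, n_events = n_events, n_reps = n_reps, start_mode = start_mode,
    rule = "demonstrator_subgroup", dm = dm, bin_width = bin_width,
    base_seed = base_seed
  )
  batch <- run_batch(sc)
  curve <- curve_from_runs(batch, "A", freq_spec, out_spec, bin_width)
  cmp <- suppressWarnings(compare_fits(curve))
  edge_slope <- function(lo, hi) {
    nz <- curve$counted > 0L & curve$bin_centre >= lo &
      curve$bin_centre <= hi
    if (sum(nz) < 2L) return(NA_real_)
    sub <- curve[nz, ]
    w <- sub$counted
    xb <- sum(w * sub$bin_centre) / sum(w)
    yb <- sum(w * sub$probability) / sum(w)
    sum(w * (sub$bin_centre - xb) * (sub$probability - yb)) /
      sum(w * (sub$bin_centre - xb)^2)
  }
  new_scenario_result(
    scenario = "demonstrator_subgroup", config = sc, curve = curve,
    comparison = cmp,
    edge_slopes = c(low = edge_slope(0, 0.15), high = edge_slope(0.85, 1)),
    verdicts = data.frame(start_mode = start_mode, dm = dm,
                          better = cmp$better,
                          relative_fit = cmp$relative_fit,
                          stringsAsFactors = FALSE),
    base_seed = base_seed
  )
}

#' Subgroup-size boundary scan
#'
#' Runs the demonstrator-subgroup scenario at fixed 50/50 starts across a
#' grid of subgroup sizes and reports, per size, which model fits better
#' and the largest size at which the sigmoid wins (`0` when it never
#' does).
#'
#' @param n Population size.
#' @param dm_grid Subgroup sizes to test.
#' @inheritParams scenario_variant_preference
#' @return A `scenario_result` with `table` (one row per `dm`) and
#'   `largest_sigmoid_dm`.
#' @export
scenario_dm_boundary <- function(n = 100L, dm_grid = c(5L, 10L, 20L, 50L),
                                 n_events = 10000L, n_reps = 1000L,
                                 base_seed = 1L, bin_width = 0.01) {
  if (any(dm_grid < 1L) || any(dm_grid > n)) {
    stop("dm_grid must lie within [1, n]")
  }
  rows <- lapply(seq_along(dm_grid), function(i) {
    res <- scenario_demonstrator_subgroup(
      start_mode = "fixed_half", dm = dm_grid[i], n = n,
      n_events = n_events, n_reps = n_reps,
      base_seed = base_seed + (i - 1L) * n_reps, bin_width = bin_width
    )
    data.frame(dm = dm_grid[i],
               r2_linear = res$comparison$linear$r_squared,
               r2_sigmoid = if (res$comparison$sigmoid_ok)
                 res$comparison$sigmoid$r_squared else NA_real_,
               relative_fit = res$comparison$relative_fit,
               better = res$comparison$better,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  winners <- tab$dm[tab$better == "sigmoid"]
  new_scenario_result(
    scenario = "dm_boundary", table = tab,
    largest_sigmoid_dm = if (length(winners)) max(winners) else 0L,
    base_seed = base_seed
  )
}

#' Frequency-measure comparison on neutral copying
#'
#' Identical random-copy runs, measured three ways: current population
#' state, full behaviour history, and a recent-history window (default the
#' last 10 behaviours, complete windows only). The state and windowed
#' measures recover the linear neutral relationship; the full history does
#' not.
#'
#' @param window_T Window length for the windowed measure.
#' @inheritParams scenario_variant_preference
#' @return A `scenario_result` with `curves` and `comparisons` (named
#'   `individual_state`, `behaviour_full_history`, `behaviour_window`) and
#'   a `verdicts` table.
#' @export
scenario_measurement_comparison <- function(n = 100L, n_events = 10000L,
                                            n_reps = 1000L, window_T = 10L,
                                            base_seed = 1L,
                                            bin_width = 0.01,
                                            out_spec =
                                              outcome_spec("copy_event")) {
  sc <- scenario_config(
    scenario = "measurement_comparison", n = n, n_events = n_events,
    n_reps = n_reps, start_mode = "fixed_half", rule = "random_copy",
    window_T = window_T, bin_width = bin_width, base_seed = base_seed
  )
  batch <- run_batch(sc)
  specs <- list(
    individual_state = frequency_spec("individual_state"),
    behaviour_full_history = frequency_spec("behaviour_full_history"),
    behaviour_window = frequency_spec("behaviour_window",
                                      window_T = window_T)
  )
  curves <- lapply(specs, function(fs)
    curve_from_runs(batch, "A", fs, out_spec, bin_width))
  comparisons <- lapply(curves, function(cv)
    suppressWarnings(compare_fits(cv)))
  new_scenario_result(
    scenario = "measurement_comparison", config = sc, curves = curves,
    comparisons = comparisons,
    verdicts = data.frame(
      measure = names(comparisons),
      better = vapply(comparisons, `[[`, "", "better"),
      relative_fit = vapply(comparisons, `[[`, 0, "relative_fit"),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    base_seed = base_seed
  )
}

#' Window-size sweep on neutral copying
#'
#' The baseline random-copy scenario measured with behaviour-frequency
#' windows swept across a log-spaced grid, with the crossover window at
#' which the sigmoid fit overtakes the linear fit.
#'
#' @param window_grid Window sizes (default [default_window_grid()]).
#' @inheritParams scenario_variant_preference
#' @param burn_in Burn-in policy for the sweep (default `use_partial`; see
#'   [window_sweep()]).
#' @return A `scenario_result` with `sweep` and `crossover`.
#' @export
scenario_window_sweep <- function(window_grid = NULL, n = 100L,
                                  n_events = 10000L, n_reps = 1000L,
                                  base_seed = 1L, bin_width = 0.01,
                                  burn_in = "use_partial",
                                  out_spec = outcome_spec("copy_event")) {
  if (is.null(window_grid)) window_grid <- default_window_grid(n_events)
  if (any(window_grid < 1L) || any(window_grid > n_events)) {
    stop("window_grid must lie within [1, n_events]")
  }
  sc <- scenario_config(
    scenario = "window_sweep", n = n, n_events = n_events, n_reps = n_reps,
    start_mode = "fixed_half", rule = "random_copy",
    bin_width = bin_width, base_seed = base_seed
  )
  batch <- run_batch(sc)
  sweep <- window_sweep(batch, window_grid, "A", out_spec, burn_in,
                        bin_width)
  new_scenario_result(
    scenario = "window_sweep", config = sc, sweep = sweep,
    crossover = crossover_window(sweep), base_seed = base_seed
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$scenario, "\n")
  if (!is.null(x$verdicts)) {
    print(x$verdicts)
  }
  if (!is.null(x$table)) {
    print(x$table)
    cat("largest sigmoid-winning dm:", x$largest_sigmoid_dm, "\n")
  }
  if (!is.null(x$crossover)) {
    cat("crossover window:", x$crossover, "\n")
  }
  invisible(x)
}
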