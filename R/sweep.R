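#' Linear-vs-sigmoid comparison across history-window sizes
#'
#' For each window size T, recomputes the windowed behaviour frequency for
#' every event of every run, pools the events into one acquisition curve,
#' and compares the count-weighted linear and sigmoid fits. T = 0 means the
#' full behaviour history.
#'
#' The sweep defaults to `burn_in = "use_partial"` so that window sizes
#' approaching the run length remain measurable and converge smoothly to
#' the full-history measure (a window of T = n_events would have no
#' complete-window events at all).
#'
#' @param batch A `copy_run_batch`.
#' @param windows Ascending vector of window sizes (0 = full history).
#' @param variant Tracked variant.
#' @param out_spec Outcome convention (default `copy_event`).
#' @param burn_in Burn-in policy for partial windows.
#' @param bin_width Curve bin width.
#' @param sigmoid_form Passed to [fit_sigmoid()].
#' @return Class `window_sweep`: a data frame with one row per window:
#'   `window`, `r2_linear`, `r2_sigmoid`, `relative_fit`, `better`,
#'   `sigmoid_ok`.
#' @export
window_sweep <- function(batch, windows, variant = "A",
                         out_spec = outcome_spec("copy_event"),
                         burn_in = "use_partial", bin_width = 0.01,
                         sigmoid_form = "logistic2") {
  windows <- as.integer(windows)
  if (!length(windows)) stop("windows must be nonempty")
  if (is.unsorted(windows)) stop("windows must be sorted ascending")
  # Hoist everything window-independent out of the T loop.
  labels <- lapply(batch, function(r) r$events$focal_after)
  oc <- lapply(batch, function(r)
    event_outcome(r$events, variant, out_spec))
  counted0 <- unlist(lapply(oc, `[[`, "counted"), use.names = FALSE)
  success0 <- unlist(lapply(oc, `[[`, "success"), use.names = FALSE)

  rows <- lapply(windows, function(Tw) {
    x <- unlist(lapply(labels, function(l)
      window_frequencies(l, Tw, variant, burn_in)), use.names = FALSE)
    counted <- counted0 & !is.na(x)
    curve <- build_curve(x, counted, success0 & counted, bin_width,
                         meta = list(variant = variant, window = Tw))
    cmp <- suppressWarnings(compare_fits(curve, sigmoid_form))
    data.frame(
      window = Tw,
      r2_linear = cmp$linear$r_squared,
      r2_sigmoid = if (cmp$sigmoid_ok) cmp$sigmoid$r_squared else NA_real_,
      relative_fit = cmp$relative_fit,
      better = cmp$better,
      sigmoid_ok = cmp$sigmoid_ok,
      stringsAsFactors = FALSE
    )
  })
  structure(do.call(rbind, rows),
            class = c("window_sweep", "data.frame"))
}

#' Crossover window of a sweep
#'
#' The smallest sampled window size at which the sigmoid fit overtakes the
#' linear fit (`relative_fit < 0`) *and* stays ahead at every larger
#' sampled window. Windows whose sigmoid fit was unavailable count as
#' linear-better.
#'
#' @param sweep A [window_sweep()] table.
#' @return The crossover window size, or `NA` if the linear fit wins
#'   everywhere.
#' @export
crossover_window <- function(sweep) {
  if (!nrow(sweep)) stop("sweep table is empty")
  neg <- !is.na(sweep$relative_fit) & sweep$relative_fit < 0
  # suffix of all-negative rows
  run_ok <- rev(cumprod(rev(neg))) == 1
  if (!any(run_ok)) return(NA_integer_)
  sweep$window[which(run_ok)[1L]]
}

#' Default log-spaced window grid
#'
#' About 30 log-spaced window sizes from 1 to `n_events`, always including
#' 10 and 2000 (the benchmark sizes of the window analyses).
#'
#' @param n_events Run length (grid upper end).
#' @param length_out Approximate number of grid points.
#' @return Sorted integer vector.
#' @export
default_window_grid <- function(n_events = 10000L, length_out = 30L) {
  g <- round(exp(seq(log(1), log(n_events), length.out = length_out)))
  sort(unique(as.integer(c(g, 10L, 2000L))))
}
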