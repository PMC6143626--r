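#' Frequency-measure specification
#'
#' The competing conventions for "how common is variant X at this event":
#' the proportion of individuals currently exhibiting it
#' (`individual_state`), the proportion of X among all behaviours performed
#' so far in the run (`behaviour_full_history`), or among the last
#' `window_T` performed behaviours (`behaviour_window`).
#'
#' @param source One of `"individual_state"`, `"behaviour_full_history"`,
#'   `"behaviour_window"`.
#' @param window_T Window length in behavioural observations (>= 1), used
#'   by `behaviour_window`.
#' @param exclude_focal_from_state Drop the focal individual from both
#'   numerator and denominator of the state count.
#' @param exclude_own_history Drop the focal's own performances from the
#'   behaviour stream before counting (supported by the scalar
#'   [history_frequency()] only).
#' @param burn_in `"skip_until_full_window"`: windowed frequencies are
#'   undefined while fewer than `window_T` behaviours exist (such events are
#'   excluded from curves); `"use_partial"`: use however many exist.
#' @return An object of class `frequency_spec`.
#' @export
frequency_spec <- function(source = c("individual_state",
                                      "behaviour_full_history",
                                      "behaviour_window"),
                           window_T = 10L,
                           exclude_focal_from_state = FALSE,
                           exclude_own_history = FALSE,
                           burn_in = c("skip_until_full_window",
                                       "use_partial")) {
  source <- match.arg(source)
  burn_in <- match.arg(burn_in)
  window_T <- as.integer(window_T)
  if (source == "behaviour_window" && (is.na(window_T) || window_T < 1L)) {
    stop("window_T must be >= 1 for behaviour_window")
  }
  structure(
    list(source = source, window_T = window_T,
         exclude_focal_from_state = isTRUE(exclude_focal_from_state),
         exclude_own_history = isTRUE(exclude_own_history),
         burn_in = burn_in),
    class = "frequency_spec"
  )
}

#' Adoption-outcome specification
#'
#' Which events count toward an acquisition curve and what counts as a
#' "success" for a tracked variant X:
#' \describe{
#'   \item{copy_event}{Every event with a demonstrator counts; success iff
#'     the demonstrated variant was X and the copy succeeded. Retaining X
#'     against a B demonstration is *not* a success — this is the
#'     convention behind the slope-1 / slope-pLess component lines.}
#'   \item{end_state}{Every event with a demonstrator counts; success iff
#'     the focal ends the event exhibiting X (retention counts). This is
#'     the convention of the closed-form direct-bias model.}
#'   \item{exposure_conditional}{Only events whose demonstrated variant is X
#'     count; success iff the focal ends the event exhibiting X.}
#' }
#'
#' @param convention One of `"copy_event"`, `"end_state"`,
#'   `"exposure_conditional"`.
#' @return An object of class `outcome_spec`.
#' @export
outcome_spec <- function(convention = c("copy_event", "end_state",
                                        "exposure_conditional")) {
  structure(list(convention = match.arg(convention)), class = "outcome_spec")
}

#' The behaviour stream of a run
#'
#' One performed behaviour per copying event: the focal's post-event
#' variant. The demonstrator's displayed variant stays in the event log, so
#' the alternative reading is always computable.
#'
#' @param run A `copy_run`.
#' @return Class `behaviour_stream`: list with `labels` ("A"/"B" per event)
#'   and `performer` (focal index per event).
#' @export
behaviour_stream <- function(run) {
  structure(list(labels = run$events$focal_after,
                 performer = run$events$focal),
            class = "behaviour_stream")
}

#' Individual-state frequency of a variant
#'
#' @param state A [population_state()] as it stands immediately before the
#'   event.
#' @param variant "A" or "B".
#' @param spec A [frequency_spec()] (only the `exclude_focal_from_state`
#'   flag is consulted).
#' @param focal Focal index, needed when excluding the focal.
#' @return Fraction in \[0, 1\].
#' @export
individual_frequency <- function(state, variant = "A",
                                 spec = frequency_spec("individual_state"),
                                 focal = NULL) {
  hits <- state$variants == variant
  if (spec$exclude_focal_from_state) {
    if (is.null(focal)) stop("focal needed when exclude_focal_from_state")
    hits <- hits[-focal]
  }
  mean(hits)
}

#' Behaviour-history frequency of a variant
#'
#' Computes the proportion of `variant` among the stream entries preceding
#' an event: all of them (`behaviour_full_history`) or the last
#' `min(window_T, length)` (`behaviour_window`). The stream passed in is the
#' prior history; an empty stream (first event) is undefined, as is a
#' partial window under `skip_until_full_window`.
#'
#' @param stream A [behaviour_stream()] holding the events so far.
#' @param variant "A" or "B".
#' @param spec A [frequency_spec()] with a history source.
#' @param focal Focal index (used by `exclude_own_history`).
#' @return Fraction in \[0, 1\], or `NA` when undefined.
#' @export
history_frequency <- function(stream, variant = "A", spec, focal = NULL) {
  stopifnot(spec$source %in% c("behaviour_full_history", "behaviour_window"))
  labels <- stream$labels
  if (spec$exclude_own_history) {
    if (is.null(focal)) stop("focal needed when exclude_own_history")
    labels <- labels[stream$performer != focal]
  }
  len <- length(labels)
  if (len == 0L) return(NA_real_)
  if (spec$source == "behaviour_window") {
    if (len < spec$window_T && spec$burn_in == "skip_until_full_window") {
      return(NA_real_)
    }
    labels <- labels[seq.int(max(1L, len - spec$window_T + 1L), len)]
  }
  mean(labels == variant)
}

#' Windowed behaviour frequencies for every event of a run (vectorized)
#'
#' For event e, the frequency of `variant` among the last
#' `min(window, e - 1)` stream entries (all of them when `window = 0`,
#' meaning full history). Event 1 is always `NA`; under
#' `skip_until_full_window`, so is every event with fewer than `window`
#' predecessors.
#'
#' @param labels Character vector of performed behaviours ("A"/"B"), in
#'   event order.
#' @param window Window length; 0 (or `Inf`) = full history.
#' @param variant Tracked variant.
#' @param burn_in See [frequency_spec()].
#' @return Numeric vector, one value (or `NA`) per event.
#' @export
window_frequencies <- function(labels, window = 0L, variant = "A",
                               burn_in = c("skip_until_full_window",
                                           "use_partial")) {
  burn_in <- match.arg(burn_in)
  a <- as.integer(labels == variant)
  E <- length(a)
  cs0 <- c(0L, cumsum(a))
  n_prior <- 0:(E - 1L)
  if (is.infinite(window) || window == 0L) {
    x <- cs0[n_prior + 1L] / n_prior
  } else {
    w <- pmin.int(window, n_prior)
    x <- (cs0[n_prior + 1L] - cs0[n_prior - w + 1L]) / w
    if (burn_in == "skip_until_full_window") x[n_prior < window] <- NA_real_
  }
  x[n_prior == 0L] <- NA_real_
  x
}

#' Classify events under an outcome convention (vectorized)
#'
#' @param events Event data frame (rows from a `copy_run` log, or the
#'   pooled log from [collect_events()]).
#' @param variant Tracked variant, "A" or "B".
#' @param spec An [outcome_spec()].
#' @return Data frame with logical columns `counted` and `success`
#'   (`success` implies `counted`). No-demonstrator events are never
#'   counted.
#' @export
event_outcome <- function(events, variant = "A", spec = outcome_spec()) {
  has_demo <- !is.na(events$demo_variant)
  out <- switch(spec$convention,
    copy_event = list(
      counted = has_demo,
      success = has_demo & events$demo_variant == variant &
        events$copy_succeeded
    ),
    end_state = list(
      counted = has_demo,
      success = has_demo & events$focal_after == variant
    ),
    exposure_conditional = {
      counted <- has_demo & events$demo_variant == variant
      list(counted = counted, success = counted &
             events$focal_after == variant)
    }
  )
  out$success[is.na(out$success)] <- FALSE
  data.frame(counted = out$counted, success = out$success)
}

#' Measure a batch of runs for curve building
#'
#' Computes, for every event of every run, the requested frequency measure
#' `x` and the outcome flags, pooled across runs. Events with undefined
#' frequency are marked uncounted.
#'
#' @param batch A `copy_run_batch` (or list of `copy_run`s).
#' @param variant Tracked variant.
#' @param freq_spec A [frequency_spec()].
#' @param out_spec An [outcome_spec()].
#' @return Data frame: `run_id`, `x`, `counted`, `success`.
#' @export
measure_runs <- function(batch, variant = "A",
                         freq_spec = frequency_spec("individual_state"),
                         out_spec = outcome_spec("copy_event")) {
  if (freq_spec$exclude_own_history) {
    stop("exclude_own_history is supported only by history_frequency()")
  }
  xs <- lapply(batch, function(run) {
    ev <- run$events
    if (freq_spec$source == "individual_state") {
      x <- if (variant == "A") ev$freq_state else 1 - ev$freq_state
      if (freq_spec$exclude_focal_from_state) {
        n <- run$initial_state$n_individuals
        x <- (x * n - (ev$focal_before == variant)) / (n - 1L)
      }
      x
    } else {
      win <- if (freq_spec$source == "behaviour_full_history") 0L else
        freq_spec$window_T
      window_frequencies(ev$focal_after, win, variant, freq_spec$burn_in)
    }
  })
  oc <- lapply(batch, function(run) event_outcome(run$events, variant,
                                                  out_spec))
  n_ev <- vapply(batch, function(r) nrow(r$events), integer(1))
  x <- unlist(xs, use.names = FALSE)
  counted <- unlist(lapply(oc, `[[`, "counted"), use.names = FALSE)
  success <- unlist(lapply(oc, `[[`, "success"), use.names = FALSE)
  counted <- counted & !is.na(x)
  success <- success & counted
  data.frame(run_id = rep.int(seq_along(batch), n_ev),
             x = x, counted = counted, success = success)
}
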