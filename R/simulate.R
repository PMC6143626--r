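#' Run a sequence of copying events
#'
#' The generative core: a sequential, asynchronous loop in which each event
#' picks a focal individual uniformly at random, selects a demonstrator
#' according to the rule, applies the rule, and appends a fully populated
#' event record. Runs continue past fixation (absorbed populations keep
#' producing no-change events). Randomness is drawn from R's global RNG;
#' callers seed it (see [run_batch()]).
#'
#' @param initial A [population_state()]. Must carry a preferred variant for
#'   the variant-preference rule and a nonempty subgroup for the
#'   demonstrator-subgroup rule.
#' @param config A [rule_config()].
#' @param n_events Number of copying events (>= 1; default 10000).
#' @return An object of class `copy_run`: a list with `events` (a data frame
#'   with one row per event: `event_index`, `focal`, `demonstrator`,
#'   `demo_variant`, `focal_before`, `focal_after`, `copy_succeeded`,
#'   `freq_state` — the variant-A frequency among individuals immediately
#'   before the event), `initial_state`, `final_state`, `config`, `n_events`,
#'   and `seed` (filled in by [run_batch()], otherwise `NA`).
#'
#' @details For the conformist reference rule `demonstrator` is recorded as
#'   `NA` (there are several) and `demo_variant` is the majority variant of
#'   the sample. Events whose demonstrator candidate set is empty (e.g.
#'   `dm = 1` with the focal the sole member and self-copying disallowed)
#'   record `NA` demonstrator and variant, `NA` `copy_succeeded`, and leave
#'   the focal unchanged; downstream outcome conventions never count them.
#' @export
run_events <- function(initial, config, n_events = 10000L) {
  stopifnot(inherits(initial, "population_state"),
            inherits(config, "rule_config"))
  n_events <- as.integer(n_events)
  if (is.na(n_events) || n_events < 1L) stop("n_events must be >= 1")
  rule <- config$rule
  if (rule == "variant_preference" && is.na(initial$preferred_variant)) {
    stop("variant_preference rule needs a preferred_variant in the state")
  }
  if (rule == "demonstrator_subgroup" && !length(initial$subgroup_ids)) {
    stop("demonstrator_subgroup rule needs a nonempty subgroup in the state")
  }
  if (rule == "demonstrator_subgroup" &&
      length(initial$subgroup_ids) > initial$n_individuals) {
    stop("dm cannot exceed the population size")
  }

  n <- initial$n_individuals
  v <- as.integer(initial$variants == "A") # 1 = A, 0 = B
  nA <- sum(v)
  allow_self <- config$allow_self_as_demonstrator

  focal <- sample.int(n, n_events, replace = TRUE)
  demo <- integer(n_events)
  dv <- integer(n_events)   # demonstrated variant (NA for conformist / none)
  fb <- integer(n_events)
  fa <- integer(n_events)
  succ <- logical(n_events)
  fqA <- integer(n_events)  # count of A before the event

  if (rule == "random_copy") {
    u <- stats::runif(n_events)
    if (allow_self) {
      d_all <- as.integer(floor(u * n)) + 1L
    } else {
      j <- as.integer(floor(u * (n - 1L))) + 1L
      d_all <- j + (j >= focal)
    }
    for (e in seq_len(n_events)) {
      f <- focal[e]; d <- d_all[e]
      dvv <- v[d]; fbb <- v[f]
      fqA[e] <- nA
      if (dvv != fbb) { v[f] <- dvv; nA <- nA + dvv - fbb }
      demo[e] <- d; dv[e] <- dvv; fb[e] <- fbb; fa[e] <- dvv
    }
    succ[] <- TRUE
  } else if (rule == "variant_preference") {
    pref <- as.integer(initial$preferred_variant == "A")
    p_less <- config$p_less
    u <- stats::runif(n_events)
    uc <- stats::runif(n_events)
    if (allow_self) {
      d_all <- as.integer(floor(u * n)) + 1L
    } else {
      j <- as.integer(floor(u * (n - 1L))) + 1L
      d_all <- j + (j >= focal)
    }
    for (e in seq_len(n_events)) {
      f <- focal[e]; d <- d_all[e]
      dvv <- v[d]; fbb <- v[f]
      fqA[e] <- nA
      s <- dvv == pref || uc[e] < p_less
      if (s && dvv != fbb) { v[f] <- dvv; nA <- nA + dvv - fbb }
      demo[e] <- d; dv[e] <- dvv; fb[e] <- fbb; fa[e] <- v[f]; succ[e] <- s
    }
  } else if (rule == "demonstrator_subgroup") {
    S <- initial$subgroup_ids
    dm <- length(S)
    pos_in_S <- integer(n); pos_in_S[S] <- seq_len(dm) # 0 = not a member
    u <- stats::runif(n_events)
    for (e in seq_len(n_events)) {
      f <- focal[e]
      k <- pos_in_S[f]
      if (k > 0L && !allow_self) {
        if (dm == 1L) { # sole member copying itself: no demonstrator
          fqA[e] <- nA
          demo[e] <- NA_integer_; dv[e] <- NA_integer_
          fb[e] <- v[f]; fa[e] <- v[f]; succ[e] <- NA
          next
        }
        j <- as.integer(floor(u[e] * (dm - 1L))) + 1L
        d <- S[j + (j >= k)]
      } else {
        d <- S[as.integer(floor(u[e] * dm)) + 1L]
      }
      dvv <- v[d]; fbb <- v[f]
      fqA[e] <- nA
      if (dvv != fbb) { v[f] <- dvv; nA <- nA + dvv - fbb }
      demo[e] <- d; dv[e] <- dvv; fb[e] <- fbb; fa[e] <- dvv; succ[e] <- TRUE
    }
  } else { # conformist_reference
    k <- config$conformist_sample
    if (k >= n) stop("conformist_sample must be smaller than the population")
    half <- k / 2
    for (e in seq_len(n_events)) {
      f <- focal[e]
      if (allow_self) {
        d3 <- sample.int(n, k)
      } else {
        s3 <- sample.int(n - 1L, k)
        d3 <- s3 + (s3 >= f)
      }
      dvv <- as.integer(sum(v[d3]) > half) # majority variant of the sample
      fbb <- v[f]
      fqA[e] <- nA
      if (dvv != fbb) { v[f] <- dvv; nA <- nA + dvv - fbb }
      demo[e] <- NA_integer_; dv[e] <- dvv; fb[e] <- fbb; fa[e] <- dvv
      succ[e] <- TRUE
    }
  }

  lab <- c("B", "A")
  events <- data.frame(
    event_index = seq_len(n_events),
    focal = focal,
    demonstrator = demo,
    demo_variant = lab[dv + 1L],
    focal_before = lab[fb + 1L],
    focal_after = lab[fa + 1L],
    copy_succeeded = succ,
    freq_state = fqA / n,
    stringsAsFactors = FALSE
  )
  final <- population_state(lab[v + 1L],
                            preferred_variant = initial$preferred_variant,
                            subgroup_ids = initial$subgroup_ids)
  structure(
    list(events = events, initial_state = initial, final_state = final,
         config = config, n_events = n_events, seed = NA_integer_,
         p0 = NA_real_),
    class = "copy_run"
  )
}

#' Replay a run's event log
#'
#' Reconstructs the population trajectory from the recorded events, checking
#' at every step that `focal_before` and `freq_state` match the
#' reconstructed state, and that the reconstructed final state equals the
#' recorded one.
#'
#' @param run A `copy_run`.
#' @return `TRUE` invisibly; errors on any mismatch.
#' @export
replay_run <- function(run) {
  v <- as.integer(run$initial_state$variants == "A")
  n <- length(v)
  ev <- run$events
  fa <- as.integer(ev$focal_after == "A")
  fb <- as.integer(ev$focal_before == "A")
  nA <- sum(v)
  for (e in seq_len(nrow(ev))) {
    f <- ev$focal[e]
    if (v[f] != fb[e]) stop("replay mismatch: focal_before at event ", e)
    if (nA != round(ev$freq_state[e] * n)) {
      stop("replay mismatch: freq_state at event ", e)
    }
    nA <- nA + fa[e] - v[f]
    v[f] <- fa[e]
  }
  if (!identical(c("B", "A")[v + 1L], run$final_state$variants)) {
    stop("replay mismatch: final state")
  }
  invisible(TRUE)
}

#' Run replicate simulations for a scenario
#'
#' Replicates [run_events()] with mutually independent runs whose seeds are
#' derived deterministically from `base_seed` (run i uses
#' `base_seed + i - 1`). Per-run initial frequencies follow the scenario's
#' start mode; for the variant-preference rule the preferred variant is
#' randomly selected at the beginning of each repetition unless the scenario
#' fixes it; for the subgroup rule the subgroup is redrawn each repetition.
#'
#' Start modes:
#' \describe{
#'   \item{fixed_half}{`p0 = 0.5` in every run.}
#'   \item{uniform_increments}{`p0` sweeps the grid 0, 0.001, ..., 1.000,
#'     thinned evenly when `n_reps` < 1001 (1001 reps visit every value).}
#'   \item{rare}{`p0` drawn uniformly from \{0.01, ..., 0.10\} per run:
#'     small but nonzero, so the tracked variant can occasionally spread.}
#' }
#'
#' @param scenario A [scenario_config()].
#' @param n_reps,base_seed Optional overrides of the scenario's values.
#' @return A list of `copy_run` objects, class `copy_run_batch`.
#' @export
run_batch <- function(scenario, n_reps = NULL, base_seed = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (is.null(n_reps)) n_reps <- scenario$n_reps
  if (is.null(base_seed)) base_seed <- scenario$base_seed
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be >= 1")
  cfg <- rule_config(scenario$rule, p_less = scenario$p_less,
                     dm = scenario$dm,
                     conformist_sample = scenario$conformist_sample,
                     allow_self_as_demonstrator =
                       scenario$allow_self_as_demonstrator)
  p0_grid <- if (scenario$start_mode == "uniform_increments") {
    grid <- seq(0, 1, by = 0.001)
    grid[round(seq(1, length(grid), length.out = n_reps))]
  }
  runs <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    seed_i <- as.integer(base_seed + i - 1L)
    set.seed(seed_i)
    p0 <- switch(scenario$start_mode,
      fixed_half = 0.5,
      uniform_increments = p0_grid[i],
      rare = sample(seq(0.01, 0.10, by = 0.01), 1L)
    )
    preferred <- NA_character_
    if (scenario$rule == "variant_preference") {
      preferred <- if (is.na(scenario$preferred_variant)) {
        sample(c("A", "B"), 1L)
      } else {
        scenario$preferred_variant
      }
    }
    subgroup <- integer(0)
    if (scenario$rule == "demonstrator_subgroup") {
      subgroup <- sort(sample.int(scenario$n, scenario$dm))
    }
    initial <- init_population(scenario$n, p0, mode = scenario$init_mode,
                               preferred_variant = preferred,
                               subgroup_ids = subgroup)
    run <- run_events(initial, cfg, scenario$n_events)
    run$seed <- seed_i
    run$p0 <- p0
    runs[[i]] <- run
  }
  structure(runs, class = "copy_run_batch",
            scenario = scenario, base_seed = as.integer(base_seed))
}

#' Pool the event logs of a batch into one data frame
#'
#' @param batch A `copy_run_batch` (or plain list of `copy_run`s).
#' @return The row-bound event data frame with a leading `run_id` column.
#' @export
collect_events <- function(batch) {
  cols <- names(batch[[1L]]$events)
  out <- lapply(stats::setNames(cols, cols), function(cl) {
    unlist(lapply(batch, function(r) r$events[[cl]]), use.names = FALSE)
  })
  n_ev <- vapply(batch, function(r) nrow(r$events), integer(1))
  out <- c(list(run_id = rep.int(seq_along(batch), n_ev)), out)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Per-run metadata of a batch
#'
#' @param batch A `copy_run_batch`.
#' @return Data frame with one row per run: `run_id`, `seed`, `p0`,
#'   `preferred_variant`, `final_freq_a`.
#' @export
batch_info <- function(batch) {
  data.frame(
    run_id = seq_along(batch),
    seed = vapply(batch, function(r) r$seed, integer(1)),
    p0 = vapply(batch, function(r) r$p0, numeric(1)),
    preferred_variant = vapply(batch, function(r)
      r$initial_state$preferred_variant, character(1)),
    final_freq_a = vapply(batch, function(r)
      mean(r$final_state$variants == "A"), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.copy_run <- function(x, ...) {
  cat("<copy_run>", x$config$rule, "|", x$n_events, "events | freq(A):",
      format(mean(x$initial_state$variants == "A"), digits = 3), "->",
      format(mean(x$final_state$variants == "A"), digits = 3), "\n")
  invisible(x)
}

#' @export
print.copy_run_batch <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat("<copy_run_batch>", length(x), "runs |", sc$rule, "| start:",
      sc$start_mode, "| base_seed:", attr(x, "base_seed"), "\n")
  invisible(x)
}
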