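#' Scenario configuration
#'
#' The full parameterization of one experiment: population and replication
#' sizes, starting conditions, learning rule and its parameters, and the
#' measurement conventions. Defaults are the canonical study conditions:
#' populations of 100 individuals, 10000 copying events per run, 1000
#' replicate runs, 50/50 binomial starts, `p_less = 0.2`, `dm = 5`,
#' current-state frequency, copy-event outcomes, 0.01-wide bins.
#'
#' @param scenario Free-text scenario name.
#' @param n Population size (>= 2).
#' @param n_events Copying events per run (>= 1).
#' @param n_reps Replicate runs (>= 1).
#' @param start_mode `"fixed_half"`, `"uniform_increments"` or `"rare"`
#'   (see [run_batch()]).
#' @param init_mode `"binomial"` or `"exact_round"` (see
#'   [init_population()]).
#' @param rule,p_less,dm,conformist_sample,allow_self_as_demonstrator See
#'   [rule_config()].
#' @param preferred_variant Fix the preferred variant ("A"/"B") across
#'   runs; `NA` redraws it uniformly each repetition.
#' @param variant Tracked variant for curves.
#' @param freq_source,window_T,burn_in See [frequency_spec()].
#' @param outcome See [outcome_spec()].
#' @param bin_width Curve bin width.
#' @param base_seed Integer seed from which all per-run seeds derive.
#' @return Class `scenario_config` (a validated named list).
#' @export
scenario_config <- function(scenario = "custom",
                            n = 100L,
                            n_events = 10000L,
                            n_reps = 1000L,
                            start_mode = c("fixed_half",
                                           "uniform_increments", "rare"),
                            init_mode = c("binomial", "exact_round"),
                            rule = c("random_copy", "variant_preference",
                                     "demonstrator_subgroup",
                                     "conformist_reference"),
                            p_less = 0.2,
                            dm = 5L,
                            conformist_sample = 3L,
                            allow_self_as_demonstrator = FALSE,
                            preferred_variant = NA_character_,
                            variant = "A",
                            freq_source = c("individual_state",
                                            "behaviour_full_history",
                                            "behaviour_window"),
                            window_T = 10L,
                            burn_in = c("skip_until_full_window",
                                        "use_partial"),
                            outcome = c("copy_event", "end_state",
                                        "exposure_conditional"),
                            bin_width = 0.01,
                            base_seed = 1L) {
  chk_count <- function(x, nm, min) {
    x <- as.integer(x)
    if (length(x) != 1L || is.na(x) || x < min) {
      stop("invalid config: ", nm, " must be an integer >= ", min)
    }
    x
  }
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("invalid config: ", nm, " must lie in [0, 1]")
    }
    as.numeric(x)
  }
  out <- list(
    scenario = as.character(scenario),
    n = chk_count(n, "n", 2L),
    n_events = chk_count(n_events, "n_events", 1L),
    n_reps = chk_count(n_reps, "n_reps", 1L),
    start_mode = match.arg(start_mode),
    init_mode = match.arg(init_mode),
    rule = match.arg(rule),
    p_less = chk_prob(p_less, "p_less"),
    dm = chk_count(dm, "dm", 1L),
    conformist_sample = chk_count(conformist_sample, "conformist_sample",
                                  3L),
    allow_self_as_demonstrator = isTRUE(allow_self_as_demonstrator),
    preferred_variant = as.character(preferred_variant),
    variant = as.character(variant),
    freq_source = match.arg(freq_source),
    window_T = chk_count(window_T, "window_T", 1L),
    burn_in = match.arg(burn_in),
    outcome = match.arg(outcome),
    bin_width = chk_prob(bin_width, "bin_width"),
    base_seed = chk_count(base_seed, "base_seed", 0L)
  )
  if (out$dm > out$n) stop("invalid config: dm must be <= n")
  if (out$conformist_sample >= out$n) {
    stop("invalid config: conformist_sample must be < n")
  }
  if (out$conformist_sample %% 2L == 0L) {
    stop("invalid config: conformist_sample must be odd")
  }
  if (!is.na(out$preferred_variant) &&
      !out$preferred_variant %in% c("A", "B")) {
    stop("invalid config: preferred_variant must be \"A\", \"B\" or NA")
  }
  if (!out$variant %in% c("A", "B")) {
    stop("invalid config: variant must be \"A\" or \"B\"")
  }
  nb <- 1 / out$bin_width
  if (abs(nb - round(nb)) > 1e-9) {
    stop("invalid config: bin_width must divide 1 evenly")
  }
  structure(out, class = "scenario_config")
}

#' Load and validate a scenario configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) file whose keys are
#' [scenario_config()] arguments. Unknown keys are rejected by name;
#' missing keys take the canonical defaults.
#'
#' @param path Path to the config file.
#' @return A validated `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use yaml or json)")
  )
  if (!is.list(vals)) stop("config file must hold a mapping of keys")
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  vals <- lapply(vals, function(v) if (is.null(v)) NA else v)
  do.call(scenario_config, vals)
}

#' Serialize a scenario configuration
#'
#' Writes the config as YAML or JSON (by extension), in canonical field
#' order so that load -> save -> load is the identity.
#'
#' @param config A `scenario_config`.
#' @param path Destination (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  ext <- tolower(tools::file_ext(path))
  vals <- unclass(config)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(vals, path)
  } else if (ext == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    stop("unsupported config format: .", ext)
  }
  invisible(path)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$scenario, "\n")
  cat("  rule:", x$rule, "| N =", x$n, "| events =", x$n_events,
      "| reps =", x$n_reps, "| start:", x$start_mode, "\n")
  cat("  measure:", x$freq_source, "| outcome:", x$outcome,
      "| seed:", x$base_seed, "\n")
  invisible(x)
}
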