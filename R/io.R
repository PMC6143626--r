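# CSV/JSON writers for the fixed schemas, plus the output manifest.
# Numbers are written with full (15 significant digit) precision so tables
# round-trip exactly and repeated writes are byte-identical.

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.15g", x))
}

write_table_csv <- function(df, path) {
  out <- df
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- fmt_num(out[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a batch's event logs to CSV
#'
#' One row per event with the fixed column set `run_id`, `event_index`,
#' `focal`, `demonstrator`, `demo_variant`, `focal_before`, `focal_after`,
#' `copy_succeeded`, `freq_state`, `freq_history_full`,
#' `freq_history_window` (window of `window_T`, complete windows only);
#' missing values are written as `NA`. Scenario parameters go to a JSON
#' sidecar next to the CSV.
#'
#' @param batch A `copy_run_batch` (or single `copy_run`).
#' @param path Destination CSV path.
#' @param window_T Window used for the `freq_history_window` column.
#' @param variant Variant whose frequencies are recorded.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(batch, path, window_T = 10L, variant = "A") {
  if (inherits(batch, "copy_run")) batch <- list(batch)
  ev <- collect_events(batch)
  full <- unlist(lapply(batch, function(r)
    window_frequencies(r$events$focal_after, 0L, variant)),
    use.names = FALSE)
  win <- unlist(lapply(batch, function(r)
    window_frequencies(r$events$focal_after, window_T, variant,
                       "skip_until_full_window")), use.names = FALSE)
  ev$freq_history_full <- full
  ev$freq_history_window <- win
  write_table_csv(ev, path)
  sc <- attr(batch, "scenario")
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- list(window_T = window_T, variant = variant,
               n_runs = length(batch),
               seeds = vapply(batch, function(r) r$seed, integer(1)))
  if (!is.null(sc)) meta$scenario <- unclass(sc)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read an event-log CSV
#'
#' @param path CSV written by [write_event_log()].
#' @return The event data frame; the JSON sidecar, if present, is attached
#'   as attribute `"meta"`.
#' @export
read_event_log <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(demo_variant = "character",
                                       focal_before = "character",
                                       focal_after = "character"))
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar)) {
    attr(ev, "meta") <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  }
  ev
}

#' Write / read an acquisition curve as CSV
#'
#' Columns: `bin_lo`, `bin_centre`, `counted`, `successes`, `probability`
#' (all bins, empty ones with `NA` probability).
#'
#' @param curve An `acquisition_curve`.
#' @param path CSV path.
#' @return `path` invisibly ([write_curve_csv()]); the reconstructed
#'   `acquisition_curve` ([read_curve_csv()]).
#' @export
write_curve_csv <- function(curve, path) {
  write_table_csv(as.data.frame(curve), path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("acquisition_curve", "data.frame"),
            bin_width = df$bin_centre[2] - df$bin_centre[1], meta = list())
}

#' Write a window-sweep table as CSV
#'
#' Columns: `window`, `r2_linear`, `r2_sigmoid`, `relative_fit`, `better`,
#' `sigmoid_ok`.
#'
#' @param sweep A [window_sweep()] table.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  write_table_csv(as.data.frame(sweep), path)
}

fit_to_list <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(model = fit$model, coefficients = as.list(fit$coefficients),
       r_squared = fit$r_squared, converged = fit$converged,
       n_bins = fit$n_bins)
}

comparison_to_list <- function(cmp) {
  list(linear = fit_to_list(cmp$linear), sigmoid = fit_to_list(cmp$sigmoid),
       relative_fit = cmp$relative_fit, better = cmp$better,
       sigmoid_ok = cmp$sigmoid_ok)
}

#' Write a scenario result to an output directory
#'
#' Serializes every curve to CSV, every fit comparison to JSON, the sweep
#' table (if any) to CSV, the configuration to JSON, and optionally figure
#' PNGs, then writes `manifest.json` recording the package version, base
#' seed, configuration hash and an md5 checksum per output file. On any
#' write failure the partial outputs created by this call are removed.
#'
#' @param result A `scenario_result`.
#' @param dir Output directory (created, with a notice, if missing).
#' @param figures Also render figure PNGs for the curves/sweep.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(result, dir, figures = FALSE) {
  stopifnot(inherits(result, "scenario_result"))
  if (!dir.exists(dir)) {
    message("creating output directory: ", dir)
    dir.create(dir, recursive = TRUE)
  }
  written <- character(0)
  emit <- function(fun, name, ...) {
    path <- file.path(dir, name)
    fun(..., path)
    written <<- c(written, path)
    path
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  curves <- list()
  comps <- list()
  walk_panel <- function(prefix, obj) {
    if (inherits(obj, "acquisition_curve")) {
      curves[[prefix]] <<- obj
    } else if (inherits(obj, "fit_comparison")) {
      comps[[prefix]] <<- obj
    } else if (is.list(obj) && !inherits(obj, "scenario_config")) {
      for (nm in names(obj)) {
        walk_panel(if (nzchar(prefix)) paste(prefix, nm, sep = "_") else nm,
                   obj[[nm]])
      }
    }
  }
  walk_panel("", unclass(result))
  for (nm in names(curves)) {
    emit(write_curve_csv, paste0("curve_", nm, ".csv"), curves[[nm]])
  }
  if (length(comps)) {
    path <- file.path(dir, "fits.json")
    jsonlite::write_json(lapply(comps, comparison_to_list), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
    written <- c(written, path)
  }
  if (!is.null(result$sweep)) {
    emit(write_sweep_csv, "sweep.csv", result$sweep)
  }
  if (!is.null(result$table)) {
    emit(write_table_csv, "table.csv", result$table)
  }
  cfg_path <- NULL
  if (!is.null(result$config)) {
    cfg_path <- emit(save_config, "config.json", result$config)
  }
  if (figures) {
    for (nm in names(curves)) {
      f <- file.path(dir, paste0("curve_", nm, ".png"))
      grDevices::png(f, width = 900, height = 700, res = 120)
      tryCatch(plot_curve(curves[[nm]], comps[[nm]]),
               finally = grDevices::dev.off())
      written <- c(written, f)
    }
    if (!is.null(result$sweep)) {
      f <- file.path(dir, "sweep.png")
      grDevices::png(f, width = 900, height = 700, res = 120)
      tryCatch(plot_sweep(result$sweep),
               finally = grDevices::dev.off())
      written <- c(written, f)
    }
  }
  checksums <- tools::md5sum(written)
  names(checksums) <- basename(names(checksums))
  manifest <- list(
    package = "conformsim",
    version = as.character(utils::packageVersion("conformsim")),
    scenario = result$scenario,
    base_seed = result$base_seed,
    config_hash = if (!is.null(cfg_path))
      unname(tools::md5sum(cfg_path)) else NA_character_,
    files = as.list(checksums),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
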