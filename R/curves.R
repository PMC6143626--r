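#' Build a binned acquisition curve
#'
#' Bins counted events by their frequency measure into left-closed,
#' right-open bins of equal width partitioning \[0, 1\] (the final bin is
#' closed, so a frequency of exactly 1 lands in the last bin), and records
#' per-bin counted totals, success totals, and the adoption probability
#' successes / counted (undefined for empty bins).
#'
#' @param x Frequency measure per event, in \[0, 1\].
#' @param counted,success Logical vectors as from [event_outcome()] /
#'   [measure_runs()]; only counted events contribute.
#' @param bin_width Bin width; must divide 1 evenly (default 0.01, the
#'   natural k/N resolution at N = 100).
#' @param meta Optional named list stored as metadata (variant, specs,
#'   stratum labels, ...).
#' @return Class `acquisition_curve`: a data frame with one row per bin
#'   (`bin_lo`, `bin_centre`, `counted`, `successes`, `probability`), with
#'   `bin_width` and `meta` attributes.
#' @export
build_curve <- function(x, counted = NULL, success, bin_width = 0.01,
                        meta = list()) {
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("bin_width must divide 1 evenly")
  nb <- as.integer(round(nb))
  if (is.null(counted)) counted <- rep.int(TRUE, length(x))
  x <- x[counted]
  success <- success[counted]
  if (!length(x)) stop("empty curve: no counted events supplied")
  if (anyNA(x)) stop("counted events must carry a defined frequency")
  if (min(x) < 0 || max(x) > 1) stop("frequencies must lie in [0, 1]")
  idx <- pmin.int(as.integer(floor(x / bin_width)), nb - 1L) + 1L
  cnt <- tabulate(idx, nbins = nb)
  suc <- tabulate(idx[success], nbins = nb)
  prob <- ifelse(cnt > 0L, suc / cnt, NA_real_)
  out <- data.frame(
    bin_lo = (seq_len(nb) - 1L) * bin_width,
    bin_centre = (seq_len(nb) - 0.5) * bin_width,
    counted = cnt,
    successes = suc,
    probability = prob
  )
  structure(out, class = c("acquisition_curve", "data.frame"),
            bin_width = bin_width, meta = meta)
}

#' Acquisition curve(s) straight from a batch of runs
#'
#' Convenience wrapper: [measure_runs()] then [build_curve()], optionally
#' stratified by a per-run label (e.g. which variant was preferred, or the
#' start regime).
#'
#' @param batch A `copy_run_batch`.
#' @param variant Tracked variant.
#' @param freq_spec,out_spec Measurement conventions.
#' @param bin_width Bin width.
#' @param strata Optional character vector of per-run labels (one per run);
#'   when supplied, one curve is returned per label.
#' @return A single `acquisition_curve`, or a named list of them when
#'   `strata` is supplied.
#' @export
curve_from_runs <- function(batch, variant = "A",
                            freq_spec = frequency_spec("individual_state"),
                            out_spec = outcome_spec("copy_event"),
                            bin_width = 0.01, strata = NULL) {
  m <- measure_runs(batch, variant, freq_spec, out_spec)
  meta0 <- list(variant = variant, freq_source = freq_spec$source,
                window_T = freq_spec$window_T,
                convention = out_spec$convention)
  if (is.null(strata)) {
    return(build_curve(m$x, m$counted, m$success, bin_width, meta0))
  }
  stopifnot(length(strata) == length(batch))
  lab <- strata[m$run_id]
  out <- lapply(stats::setNames(nm = sort(unique(strata))), function(s) {
    sel <- lab == s
    build_curve(m$x[sel], m$counted[sel], m$success[sel], bin_width,
                c(meta0, list(stratum = s)))
  })
  out
}

#' @export
print.acquisition_curve <- function(x, ...) {
  nz <- x$counted > 0L
  cat("<acquisition_curve>", sum(nz), "nonempty bins (width",
      attr(x, "bin_width"), ") |", sum(x$counted), "events,",
      sum(x$successes), "successes\n")
  m <- attr(x, "meta")
  if (length(m)) {
    cat("  ", paste(names(m), unlist(lapply(m, format)), sep = "=",
                    collapse = " | "), "\n")
  }
  invisible(x)
}
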