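# Shared fixtures: everything is generated in code at test time.

# A population with an exact variant-A count.
exact_state <- function(n = 100L, k_a = 50L, ...) {
  population_state(rep(c("A", "B"), c(k_a, n - k_a)), ...)
}

# Small replicated batch for pipeline tests.
small_batch <- function(rule = "random_copy", n_reps = 20L,
                        n_events = 500L, base_seed = 42L, ...) {
  run_batch(scenario_config(rule = rule, n_reps = n_reps,
                            n_events = n_events, base_seed = base_seed,
                            ...))
}

# Fabricate an acquisition curve with prescribed per-bin probabilities and
# weights (for fitting tests with exactly known geometry).
synthetic_curve <- function(x, y, w = rep(1000L, length(x))) {
  bw <- 1 / length(x)
  suc <- as.integer(round(y * w))
  structure(
    data.frame(bin_lo = x - bw / 2, bin_centre = x, counted = as.integer(w),
               successes = suc, probability = suc / w),
    class = c("acquisition_curve", "data.frame"),
    bin_width = bw, meta = list()
  )
}

# Count-weighted linear slope of a curve restricted to a frequency band.
band_slope <- function(cv, lo, hi) {
  nz <- cv$counted > 0 & cv$bin_centre >= lo & cv$bin_centre <= hi
  sub <- cv[nz, ]
  w <- sub$counted
  xb <- sum(w * sub$bin_centre) / sum(w)
  yb <- sum(w * sub$probability) / sum(w)
  sum(w * (sub$bin_centre - xb) * (sub$probability - yb)) /
    sum(w * (sub$bin_centre - xb)^2)
}

# Per-event-value (unbinned) adoption probabilities: group counted events
# by their exact frequency value. Used where the frequency measure takes
# exactly k/N values and binning would blur the last bin.
pointwise_curve <- function(x, counted, success) {
  x <- x[counted]
  success <- success[counted]
  cnt <- tapply(rep(1L, length(x)), x, sum)
  suc <- tapply(as.integer(success), x, sum)
  data.frame(p = as.numeric(names(cnt)), n = as.vector(cnt),
             phat = as.vector(suc) / as.vector(cnt))
}
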