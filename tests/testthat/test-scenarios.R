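test_that("scenario reruns with one base seed are byte-identical on disk", {
  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  r1 <- scenario_demonstrator_subgroup(n_reps = 5, n_events = 300,
                                       base_seed = 91)
  r2 <- scenario_demonstrator_subgroup(n_reps = 5, n_events = 300,
                                       base_seed = 91)
  suppressMessages({
    m1 <- write_outputs(r1, d1)
    m2 <- write_outputs(r2, d2)
  })
  expect_identical(m1$files, m2$files)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("variant preference with p_less = 1 degenerates to neutral copying", {
  vp <- scenario_variant_preference("uniform_increments", p_less = 1,
                                    n_reps = 60, n_events = 2000,
                                    base_seed = 93)
  panel <- vp$panels$uniform_increments
  expect_identical(panel$pooled_comparison$better, "linear")
  slope <- fit_linear(panel$pooled_curve)$coefficients[["slope"]]
  rc <- small_batch("random_copy", n_reps = 60, n_events = 2000,
                    base_seed = 94, start_mode = "uniform_increments")
  slope_rc <- fit_linear(curve_from_runs(rc))$coefficients[["slope"]]
  expect_lt(abs(slope - 1), 0.05)
  expect_lt(abs(slope_rc - slope), 0.05)
})

test_that("a whole-population subgroup is just random copying", {
  res <- scenario_demonstrator_subgroup(dm = 100, n_reps = 60,
                                        n_events = 2000, base_seed = 95)
  expect_identical(res$comparison$better, "linear")
  expect_lt(abs(fit_linear(res$curve)$coefficients[["slope"]] - 1), 0.05)
})

test_that("a lone self-copying broadcaster drives a near-step curve", {
  res <- scenario_demonstrator_subgroup(
    dm = 1, n_reps = 60, n_events = 2000, base_seed = 96,
    start_mode = "fixed_half"
  )
  # with self-copying disallowed the sole member freezes; allow it instead
  sc <- scenario_config(rule = "demonstrator_subgroup", dm = 1,
                        allow_self_as_demonstrator = TRUE, n_reps = 60,
                        n_events = 2000, base_seed = 97)
  b <- run_batch(sc)
  # every run fixes on its broadcaster's initial variant
  fixed <- vapply(b, function(r) {
    broadcaster <- r$initial_state$subgroup_ids
    all(r$final_state$variants ==
          r$initial_state$variants[broadcaster])
  }, logical(1))
  expect_true(all(fixed))
  # the pooled curve saturates: adoption ~0 below 0.5 and ~1 above
  cv <- curve_from_runs(b)
  lo <- cv$counted > 0 & cv$bin_centre < 0.3
  hi <- cv$counted > 0 & cv$bin_centre > 0.7
  expect_lt(stats::weighted.mean(cv$probability[lo], cv$counted[lo]), 0.1)
  expect_gt(stats::weighted.mean(cv$probability[hi], cv$counted[hi]), 0.9)
  expect_s3_class(res, "scenario_result")
})

test_that("scenario verdict tables trace back to their curves and fits", {
  res <- scenario_measurement_comparison(n_reps = 5, n_events = 400,
                                         base_seed = 98)
  expect_identical(res$verdicts$measure, names(res$comparisons))
  for (nm in res$verdicts$measure) {
    expect_identical(res$verdicts$better[res$verdicts$measure == nm],
                     res$comparisons[[nm]]$better)
    expect_s3_class(res$curves[[nm]], "acquisition_curve")
  }
})
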