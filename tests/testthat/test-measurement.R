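test_that("individual-state frequency counts heads, with optional focal exclusion", {
  st <- exact_state(100, 60)
  expect_equal(individual_frequency(st, "A"), 0.6)
  expect_equal(individual_frequency(st, "B"), 0.4)
  spec <- frequency_spec("individual_state", exclude_focal_from_state = TRUE)
  expect_equal(individual_frequency(st, "A", spec, focal = 1L), 59 / 99)
  all_a <- exact_state(10, 10)
  expect_equal(individual_frequency(all_a, "A"), 1)
  expect_equal(individual_frequency(all_a, "B"), 0)
})

test_that("history frequency honours source, window and burn-in", {
  stream <- structure(list(labels = c("A", "B", "A", "A"),
                           performer = c(1L, 2L, 1L, 3L)),
                      class = "behaviour_stream")
  full <- frequency_spec("behaviour_full_history")
  expect_equal(history_frequency(stream, "A", full), 0.75)
  win3 <- frequency_spec("behaviour_window", window_T = 3)
  expect_equal(history_frequency(stream, "A", win3), 2 / 3)
  win10 <- frequency_spec("behaviour_window", window_T = 10)
  short <- structure(list(labels = c("A", "B"), performer = c(1L, 2L)),
                     class = "behaviour_stream")
  expect_true(is.na(history_frequency(short, "A", win10)))
  win10p <- frequency_spec("behaviour_window", window_T = 10,
                           burn_in = "use_partial")
  expect_equal(history_frequency(short, "A", win10p), 0.5)
  empty <- structure(list(labels = character(0), performer = integer(0)),
                     class = "behaviour_stream")
  expect_true(is.na(history_frequency(empty, "A", full)))
  own <- frequency_spec("behaviour_full_history", exclude_own_history = TRUE)
  expect_equal(history_frequency(stream, "A", own, focal = 1L), 0.5)
})

test_that("vectorized window frequencies agree with the scalar definition", {
  set.seed(31)
  labels <- sample(c("A", "B"), 60, replace = TRUE)
  for (Tw in c(1L, 3L, 10L, 0L)) {
    for (bi in c("skip_until_full_window", "use_partial")) {
      xv <- window_frequencies(labels, Tw, "A", bi)
      spec <- if (Tw == 0L) {
        frequency_spec("behaviour_full_history", burn_in = bi)
      } else {
        frequency_spec("behaviour_window", window_T = Tw, burn_in = bi)
      }
      xs <- vapply(seq_along(labels), function(e) {
        stream <- structure(list(labels = labels[seq_len(e - 1L)],
                                 performer = rep(1L, e - 1L)),
                            class = "behaviour_stream")
        history_frequency(stream, "A", spec)
      }, numeric(1))
      expect_equal(xv, xs)
    }
  }
  # a window spanning the whole stream equals the full-history measure
  expect_equal(window_frequencies(labels, length(labels), "A",
                                  "use_partial"),
               window_frequencies(labels, 0L, "A"))
})

test_that("outcome conventions count and score events as defined", {
  ev <- data.frame(
    demo_variant = c("B", "A", "B", NA),
    focal_before = c("A", "A", "B", "A"),
    focal_after = c("A", "A", "B", "A"),
    copy_succeeded = c(FALSE, TRUE, TRUE, NA)
  )
  ce <- event_outcome(ev, "A", outcome_spec("copy_event"))
  # retaining A against a B demonstration is counted but is not a copy of A
  expect_identical(ce$counted, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(ce$success, c(FALSE, TRUE, FALSE, FALSE))
  es <- event_outcome(ev, "A", outcome_spec("end_state"))
  # ...but the end-state convention scores that retention as a success
  expect_identical(es$success, c(TRUE, TRUE, FALSE, FALSE))
  ec <- event_outcome(ev, "A", outcome_spec("exposure_conditional"))
  expect_identical(ec$counted, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(ec$success, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("outcome invariants hold on simulated events", {
  b <- small_batch("variant_preference", n_reps = 4, n_events = 400)
  ev <- collect_events(b)
  for (conv in c("copy_event", "end_state", "exposure_conditional")) {
    oc <- event_outcome(ev, "A", outcome_spec(conv))
    expect_true(all(oc$counted[oc$success]))
  }
  # end_state: exactly one of the two variants succeeds per counted event
  sa <- event_outcome(ev, "A", outcome_spec("end_state"))
  sb <- event_outcome(ev, "B", outcome_spec("end_state"))
  expect_true(all((sa$success + sb$success)[sa$counted] == 1L))
  # copy_event under random copying: success(A) iff the demonstrator showed A
  br <- small_batch("random_copy", n_reps = 4, n_events = 400)
  evr <- collect_events(br)
  ocr <- event_outcome(evr, "A", outcome_spec("copy_event"))
  expect_identical(ocr$success, evr$demo_variant == "A")
})
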