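test_that("a uniform population is absorbing under every rule", {
  set.seed(21)
  for (rule in c("random_copy", "variant_preference",
                 "demonstrator_subgroup", "conformist_reference")) {
    st <- population_state(
      rep("A", 50),
      preferred_variant = if (rule == "variant_preference") "B" else NA,
      subgroup_ids = if (rule == "demonstrator_subgroup") 1:5 else
        integer(0)
    )
    run <- run_events(st, rule_config(rule, p_less = 0.2), 1000L)
    expect_true(all(run$final_state$variants == "A"))
    expect_true(all(run$events$focal_before == "A"))
    expect_true(all(run$events$focal_after == "A"))
  }
})

test_that("neutral copying conserves expected variant frequency", {
  # Martingale property of drift: mean final frequency across replicates
  # stays at p0 (to within 3 SE of the replicate spread).
  finals <- vapply(seq_len(500), function(i) {
    set.seed(3000 + i)
    run <- run_events(init_population(100, 0.3), rule_config("random_copy"),
                      2000L)
    mean(run$final_state$variants == "A")
  }, numeric(1))
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.3), 3 * se)
})

test_that("small demonstrator subgroups drift to fixation within a run", {
  set.seed(23)
  n_fixed <- 0L
  for (i in seq_len(400)) {
    st <- init_population(100, 0.5, subgroup_ids = sort(sample.int(100, 5)))
    run <- run_events(st, rule_config("demonstrator_subgroup", dm = 5),
                      10000L)
    sub <- run$final_state$variants[run$final_state$subgroup_ids]
    n_fixed <- n_fixed + (length(unique(sub)) == 1L)
  }
  expect_gte(n_fixed / 400, 0.99)
})

test_that("once the subgroup fixes, subgroup demonstrations are deterministic", {
  set.seed(24)
  st <- init_population(100, 0.5, subgroup_ids = sort(sample.int(100, 5)))
  run <- run_events(st, rule_config("demonstrator_subgroup", dm = 5),
                    10000L)
  S <- st$subgroup_ids
  # reconstruct the subgroup composition through time
  v <- st$variants
  sub_uniform_from <- NA_integer_
  fixed_variant <- NA_character_
  ev <- run$events
  for (e in seq_len(nrow(ev))) {
    if (is.na(sub_uniform_from) && length(unique(v[S])) == 1L) {
      sub_uniform_from <- e
      fixed_variant <- v[S[1]]
    }
    v[ev$focal[e]] <- ev$focal_after[e]
  }
  expect_false(is.na(sub_uniform_from))
  late <- ev[ev$event_index >= sub_uniform_from & !is.na(ev$demonstrator), ]
  expect_true(all(late$demo_variant == fixed_variant))
})

test_that("replaying the event log reproduces the recorded states", {
  set.seed(25)
  for (rule in c("random_copy", "variant_preference",
                 "demonstrator_subgroup", "conformist_reference")) {
    st <- init_population(
      50, 0.4,
      preferred_variant = if (rule == "variant_preference") "A" else NA,
      subgroup_ids = if (rule == "demonstrator_subgroup")
        sort(sample.int(50, 5)) else integer(0)
    )
    run <- run_events(st, rule_config(rule), 2000L)
    expect_true(replay_run(run))
  }
})

test_that("batches are bit-identical under a fixed base seed", {
  b1 <- small_batch(n_reps = 5, n_events = 200)
  b2 <- small_batch(n_reps = 5, n_events = 200)
  expect_identical(collect_events(b1), collect_events(b2))
  expect_identical(batch_info(b1), batch_info(b2))
})

test_that("uniform-increment starts sweep the 0.1% grid exactly", {
  sc <- scenario_config(start_mode = "uniform_increments", n_reps = 1001,
                        n_events = 1, base_seed = 5)
  b <- run_batch(sc)
  expect_equal(batch_info(b)$p0, seq(0, 1, by = 0.001))
})

test_that("the preferred variant is drawn evenly across repetitions", {
  sc <- scenario_config(rule = "variant_preference", n_reps = 1000,
                        n_events = 1, base_seed = 6)
  pref <- batch_info(run_batch(sc))$preferred_variant
  expect_true(all(pref %in% c("A", "B")))
  expect_lt(abs(sum(pref == "A") - 500), 3 * sqrt(250))
})

test_that("a lone self-excluded subgroup member produces no-change events", {
  set.seed(26)
  st <- population_state(c("A", "B", "B", "A", "B"), subgroup_ids = 2L)
  run <- run_events(st, rule_config("demonstrator_subgroup", dm = 1), 500L)
  ev <- run$events
  own <- ev$focal == 2L
  expect_true(all(is.na(ev$demonstrator[own])))
  expect_true(all(is.na(ev$demo_variant[own])))
  expect_identical(ev$focal_after[own], ev$focal_before[own])
  # everyone else copies the broadcaster
  expect_true(all(ev$demonstrator[!own] == 2L))
  # and the population converges to the broadcaster's variant
  expect_true(all(run$final_state$variants == "B"))
})
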