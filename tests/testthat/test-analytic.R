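test_that("the direct-bias probability matches hand-computed cases", {
  # absorbing endpoints
  expect_equal(prob_adopt_a(0, 0.3, 0.8), 0)
  expect_equal(prob_adopt_a(1, 0.3, 0.8), 1)
  # an even preference mix gives the identity line
  expect_equal(prob_adopt_a(0.3, 0.7, 0.5), 0.3)
  # all-prefer-A at q = 0.2: 1.8 p - 0.8 p^2 evaluated at p = 0.5
  expect_equal(prob_adopt_a(0.5, 0.2, 1), 0.7)
  expect_error(prob_adopt_a(1.2, 0.5, 0.5), "domain")
})

test_that("the direct-bias probability is a monotone map of [0,1]^3 into [0,1]", {
  g <- seq(0, 1, by = 0.05)
  grid <- expand.grid(p = g, q = g, r = g)
  vals <- prob_adopt_a(grid$p, grid$q, grid$r)
  expect_true(all(vals >= 0 & vals <= 1))
  # non-decreasing in p for every (q, r)
  for (q in c(0, 0.2, 0.5, 1)) {
    for (r in c(0, 0.3, 0.5, 1)) {
      expect_true(all(diff(prob_adopt_a(g, q, r)) >= -1e-12))
    }
  }
})

test_that("the special cases collapse to the known shapes", {
  p <- seq(0, 1, by = 0.01)
  expect_equal(prob_adopt_a(p, 0.3, 0.5), p)     # even mix
  expect_equal(prob_adopt_a(p, 1, 0.8), p)       # no bias
  concave <- prob_adopt_a(p, 0.2, 1)             # r-shaped
  expect_true(all(diff(diff(concave)) < 1e-12))
  convex <- prob_adopt_a(p, 0.2, 0)
  expect_true(all(diff(diff(convex)) > -1e-12))
})

test_that("the regime-union curve reproduces its branch arithmetic", {
  cu <- regime_union_curve(0.2)
  expect_equal(cu$prob[cu$p == 0.25], 0.1)   # p^2 + (1-p) p q
  expect_equal(cu$prob[cu$p == 0.75], 0.9)   # 1.8 p - 0.8 p^2
  expect_identical(sum(cu$p == 0.5), 2L)     # both branch values at 0.5
  ident <- regime_union_curve(1)
  expect_equal(ident$prob, ident$p)          # no artefact without bias
})

test_that("mixtures of lines hit their endpoints and constant-weight case", {
  g <- seq(0, 1, by = 0.1)
  m <- mixture_of_lines(1, 0.2, w = function(x) rep(0.5, length(x)),
                        grid = g)
  expect_equal(m$y, 0.6 * g)
  expect_equal(mixture_of_lines(1, 0.2, w = 1, grid = g)$y, g)
  expect_equal(mixture_of_lines(1, 0.2, w = 0, grid = g)$y, 0.2 * g)
  expect_error(mixture_of_lines(w = 1.4, grid = g), "domain")
})

test_that("density-weighted mixed lines reconstruct the pooled preference curve", {
  # The simulation is the oracle: pooled adoption probabilities from
  # uniform-start variant-preference runs should equal the per-frequency
  # density-weighted average of the slope-1 and slope-p_less lines.
  sc <- scenario_config(rule = "variant_preference", p_less = 0.2,
                        start_mode = "uniform_increments", n_reps = 200,
                        base_seed = 81)
  b <- run_batch(sc)
  m <- measure_runs(b)
  pref <- batch_info(b)$preferred_variant[m$run_id]
  grp <- pointwise_curve(m$x, m$counted, m$success)
  na <- tapply((pref == "A")[m$counted], m$x[m$counted], sum)
  w <- as.vector(na) / grp$n
  expected <- w * grp$p + (1 - w) * 0.2 * grp$p
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / grp$n)
  keep <- grp$n >= 100
  # ~100 simultaneous per-frequency comparisons: allow the expected handful
  # of 3-SE exceedances but bound them, and cap the worst deviation
  z <- (abs(grp$phat - expected) / pmax(se, 1e-12))[keep]
  expect_lte(mean(z > 3), 0.02)
  expect_lt(max(z), 4.5)
  # the mixture is convex (concave-up): it sags below the identity chord
  mid <- keep & grp$p > 0.05 & grp$p < 0.95
  expect_true(mean(expected[mid] < grp$p[mid]) > 0.99)
})
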