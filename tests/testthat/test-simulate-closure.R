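# Closure-trajectory generator

test_that("noiseless trajectories are piecewise linear with the preset slopes", {
  p <- closure_params(r_early = 0.6, r_late = 1.9, noise_sigma = 0,
                      L_start_range = c(230, 230), p_tear = 0)
  tr <- simulate_closure_trajectory(p, seed = 1)
  slopes <- diff(tr$lengths) / diff(tr$times)
  prev_len <- tr$lengths[-length(tr$lengths)]
  early_seg <- prev_len > 190
  # drop the final clamped segment (closure)
  full <- tr$lengths[-length(tr$lengths)] - 1.9 * 10 >= 0
  expect_equal(unname(slopes[early_seg]), rep(-0.6, sum(early_seg)))
  expect_equal(unname(slopes[!early_seg & full]),
               rep(-1.9, sum(!early_seg & full)))
  expect_identical(tr$outcome, "closed")
  expect_equal(tr$lengths[length(tr$lengths)], 0)
})

test_that("zero-rate embryos are recorded as arrested", {
  p <- closure_params(r_early = 0, r_late = 0, noise_sigma = 0,
                      p_tear = 0, p_arrest = 1, max_time = 120)
  tr <- simulate_closure_trajectory(p, seed = 3)
  expect_true(all(tr$lengths == tr$lengths[1]))
  expect_identical(tr$outcome, "arrested")
})

test_that("cohorts are reproducible and honor event probabilities", {
  nrx <- closure_preset("NrxIV4304", p_arrest = 0)
  coh <- simulate_cohort(nrx, n = 10, seed = 11)
  expect_identical(vapply(coh, function(tr) tr$outcome, character(1)),
                   rep("torn", 10))
  coh2 <- simulate_cohort(nrx, n = 10, seed = 11)
  expect_identical(coh, coh2)

  clean <- simulate_cohort(closure_params(p_tear = 0, p_arrest = 0),
                           n = 5, seed = 4)
  expect_identical(vapply(clean, function(tr) tr$outcome, character(1)),
                   rep("closed", 5))
})

test_that("tear sides follow the anterior bias and tears carry event times", {
  p <- closure_preset("NrxIV4304", p_arrest = 0, p_anterior_tear = 1)
  coh <- simulate_cohort(p, n = 8, seed = 2)
  expect_true(all(vapply(coh, function(tr) tr$tear_side, character(1)) ==
                    "anterior"))
  expect_true(all(is.finite(vapply(coh, function(tr) tr$event_time,
                                   numeric(1)))))
})

test_that("realized early slope matches the preset over a large cohort", {
  # Monte-Carlo check against the generator parameter: per-frame noisy
  # slopes over the early phase average to -r_early within 2 SE
  p <- closure_preset("wild_type", L_start_range = c(230, 230))
  coh <- simulate_cohort(p, n = 200, seed = 9)
  slopes <- unlist(lapply(coh, function(tr) {
    s <- diff(tr$lengths) / diff(tr$times)
    s[tr$true_lengths[-length(tr$true_lengths)] > 200]
  }))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) + p$r_early), 2 * se)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_closure_trajectory(closure_preset("wild_type"), seed = 5))
  invisible(simulate_cohort(closure_preset("cora4"), n = 3, seed = 6))
  invisible(simulate_cuticle_counts(0.5, 100, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(closure_params(r_early = -1), "r_early")
  expect_error(closure_params(frame_interval = 0), "frame_interval")
  expect_error(closure_params(p_tear = 1.5), "p_tear")
  expect_error(simulate_cohort(closure_preset("wild_type"), n = 0, seed = 1),
               ">= 1")
  expect_error(closure_preset("nonexistent"), "unknown preset")
})

test_that("binomial cuticle counts hit the endpoints and the rate", {
  expect_identical(simulate_cuticle_counts(0, 50, seed = 1), 0L)
  expect_identical(simulate_cuticle_counts(1, 50, seed = 1), 50L)
  k <- simulate_cuticle_counts(0.5, 1e4, seed = 2)
  expect_lt(abs(k / 1e4 - 0.5), 0.015)
})
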