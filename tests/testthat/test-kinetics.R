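# Alignment, two-phase rate estimation, outcome classification

test_that("hole length is the canthus-to-canthus distance", {
  expect_equal(measure_hole_length(c(0, 0), c(190, 0)), 190)
  expect_equal(measure_hole_length(c(0, 0), c(0, 0)), 0)
  expect_equal(measure_hole_length(c(1, 1), c(4, 5)), 5)
  expect_error(measure_hole_length(c(0, NA), c(1, 1)), "finite")
})

test_that("alignment picks the first window frame, with stated fallbacks", {
  mk <- function(lengths) structure(
    list(embryo_id = "e", genotype = "g",
         times = seq(0, by = 10, length.out = length(lengths)),
         lengths = lengths, t0_index = NA_integer_, late_start = NA,
         outcome = "unset", event_time = NA_real_,
         tear_side = NA_character_),
    class = "dc_trajectory")

  a <- align_trajectory(mk(c(241, 228, 214, 200)))
  expect_identical(a$t0_index, 2L)
  expect_equal(a$times[2], 0)

  b <- align_trajectory(mk(c(219, 210, 200)))
  expect_true(b$late_start)

  cc <- align_trajectory(mk(c(236, 217, 200)))  # skips the window
  expect_identical(cc$t0_index, 2L)
})

test_that("noiseless generator output recovers both rates exactly", {
  p <- closure_params(r_early = 0.6, r_late = 1.9, noise_sigma = 0,
                      L_start_range = c(230, 230), p_tear = 0)
  tr <- align_trajectory(simulate_closure_trajectory(p, seed = 1))
  f <- fit_phase_rates(tr)
  expect_equal(f$r_early, 0.6, tolerance = 1e-12)
  expect_equal(f$r_late, 1.9, tolerance = 1e-12)
  expect_equal(unname(coef(f)), c(f$r_early, f$r_late))
  # the early/late windows straddle the changepoint
  expect_gt(tr$lengths[f$early_window[1]], 220)
  expect_lt(tr$lengths[f$early_window[2]], 190)
})

test_that("flat trajectories give a zero early rate and no late rate", {
  tr <- structure(list(embryo_id = "e", genotype = "g",
                       times = seq(0, 60, by = 10),
                       lengths = rep(210, 7), t0_index = 1L,
                       late_start = FALSE, outcome = "unset",
                       event_time = NA_real_, tear_side = NA_character_),
                  class = "dc_trajectory")
  f <- fit_phase_rates(tr)
  expect_equal(f$r_early, 0)
  expect_true(is.na(f$r_late))
})

test_that("rates are shift-invariant and rescale with time units", {
  p <- closure_preset("wild_type", L_start_range = c(230, 230))
  tr <- align_trajectory(simulate_closure_trajectory(p, seed = 21))
  f0 <- fit_phase_rates(tr)
  shifted <- tr; shifted$times <- tr$times + 500
  f1 <- fit_phase_rates(shifted)
  expect_equal(coef(f1), coef(f0))
  scaled <- tr; scaled$times <- tr$times * 2
  f2 <- fit_phase_rates(scaled)
  expect_equal(unname(coef(f2)), unname(coef(f0)) / 2)
})

test_that("endpoint estimator agrees with the regression oracle on noisy data", {
  p <- closure_preset("wild_type", L_start_range = c(230, 230))
  coh <- simulate_cohort(p, n = 20, seed = 31)
  ends <- vapply(coh, function(tr) fit_phase_rates(tr)$r_early, numeric(1))
  regs <- vapply(coh, function(tr)
    fit_phase_rates(tr, method = "regression")$r_early, numeric(1))
  # both estimate the same slope over the same frames; they differ only
  # through the sigma = 2 um endpoint noise
  expect_lt(abs(mean(ends) - mean(regs)), 0.05)
})

test_that("outcomes classify by annotation, closure and arrest", {
  p <- closure_params(noise_sigma = 0, L_start_range = c(230, 230), p_tear = 0)
  closed <- simulate_closure_trajectory(p, seed = 1)
  expect_identical(classify_outcome(closed), "closed")

  torn <- simulate_closure_trajectory(
    closure_preset("NrxIV4304", p_arrest = 0, p_tear = 1), seed = 1)
  expect_identical(classify_outcome(torn), "torn")

  arrested <- structure(list(
    embryo_id = "e", genotype = "g", times = seq(0, 120, 10),
    lengths = c(seq(230, 140, length.out = 6), rep(120, 7)),
    t0_index = 1L, late_start = FALSE, outcome = "unset",
    event_time = NA_real_, tear_side = NA_character_),
    class = "dc_trajectory")
  expect_identical(classify_outcome(arrested), "arrested")
})

test_that("cohort summaries report outcome proportions and qualified rates", {
  trajs <- c(simulate_cohort(closure_preset("NrxIV4304", p_arrest = 0),
                             n = 7, seed = 5),
             simulate_cohort(closure_preset("NrxIV4304", p_arrest = 0,
                                            p_tear = 0), n = 1, seed = 6))
  s <- summarize_cohort(trajs)
  expect_equal(s$f_torn, 7 / 8)
  expect_equal(s$f_closed, 1 / 8)
  # late rate only from embryos that closed
  expect_equal(s$n_closed, 1L)

  wt <- summarize_cohort(simulate_cohort(
    closure_preset("wild_type"), n = 12, seed = 8))
  expect_equal(wt$f_torn, 0)
  expect_equal(wt$f_closed, 1)
  expect_true(is.finite(wt$mean_r_late))
})
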