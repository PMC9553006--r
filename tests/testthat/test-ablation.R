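# Recoil velocity, Kelvin-Voigt fitting, group comparisons

test_that("recoil velocity is first-frame displacement over dt", {
  rs <- structure(list(series_id = "s", genotype = "g",
                       location = "cable", phase = "early",
                       times = c(0, 3, 6), distances = c(4.0, 4.6, 5.0),
                       pre_cut = c(TRUE, FALSE, FALSE)),
                  class = "recoil_series")
  expect_equal(recoil_velocity(rs)$v, 0.2)
  flat <- rs; flat$distances <- c(4, 4, 4)
  expect_equal(recoil_velocity(flat)$v, 0)
  # noiseless Kelvin-Voigt closed form: v = D (1 - e^(-dt/tau)) / dt
  kv <- simulate_recoil(ablation_params(D = 3, tau = 20), seed = 1)
  expect_equal(recoil_velocity(kv)$v, 3 * (1 - exp(-3 / 20)) / 3,
               tolerance = 1e-12)
})

test_that("recoil velocity converges to D/tau as dt shrinks", {
  v_at <- function(dt) {
    p <- ablation_params(D = 3, tau = 20, sample_interval = dt)
    recoil_velocity(simulate_recoil(p, seed = 1))$v
  }
  target <- 3 / 20
  errs <- abs(vapply(c(3, 1, 0.1), v_at, numeric(1)) - target)
  expect_true(all(diff(errs) < 0))          # monotone improvement
  expect_lt(errs[3], 0.0004)                # near the limit at dt = 0.1 s
})

test_that("noiseless recoil series satisfy the closed form exactly", {
  p <- ablation_params(D = 3, tau = 20)
  rs <- simulate_recoil(p, seed = 1)
  expect_equal(rs$distances[2] - rs$distances[1],
               3 * (1 - exp(-0.15)), tolerance = 1e-12)
  expect_equal(rs$distances[rs$times == 60] - rs$distances[1],
               3 * (1 - exp(-3)), tolerance = 1e-12)
  # long-duration asymptote
  long <- simulate_recoil(ablation_params(D = 3, tau = 5, duration = 300),
                          seed = 1)
  expect_equal(max(long$distances) - long$distances[1], 3, tolerance = 1e-6)
})

test_that("noisy recoil means track the closed form over replicates", {
  p <- ablation_params(D = 3, tau = 20, noise_sigma = 0.1)
  reps <- vapply(1:1000, function(s)
    simulate_recoil(p, seed = s)$distances[-1], numeric(20))
  truth <- p$L0 + 3 * (1 - exp(-seq(3, 60, 3) / 20))
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(rowMeans(reps) - truth) < 2.5 * se + 1e-9))
})

test_that("the Kelvin-Voigt fit recovers noiseless parameters", {
  rs <- simulate_recoil(ablation_params(D = 3, tau = 20), seed = 1)
  f <- fit_kelvin_voigt(rs)
  expect_true(f$converged)
  expect_equal(f$D_hat, 3, tolerance = 1e-6)
  expect_equal(f$tau_hat, 20, tolerance = 1e-6)
  expect_lt(f$sse, 1e-12)
  expect_equal(unname(coef(f)), c(f$D_hat, f$tau_hat))
  expect_lt(max(abs(residuals(f))), 1e-6)
})

test_that("tau is equivariant under time rescaling", {
  rs <- simulate_recoil(ablation_params(D = 2, tau = 15, noise_sigma = 0.05),
                        seed = 7)
  f0 <- fit_kelvin_voigt(rs)
  rs2 <- rs; rs2$times <- rs$times * 4
  f1 <- fit_kelvin_voigt(rs2)
  expect_equal(f1$tau_hat, 4 * f0$tau_hat, tolerance = 1e-5)
  expect_equal(f1$D_hat, f0$D_hat, tolerance = 1e-6)
})

test_that("parameters are recovered within 10% across the (D, tau) grid", {
  for (D in c(1, 3)) for (tau in c(10, 30)) {
    p <- ablation_params(D = D, tau = tau, noise_sigma = 0.05)
    est <- vapply(1:30, function(s) coef(fit_kelvin_voigt(
      simulate_recoil(p, seed = 100 + s))), numeric(2))
    expect_lt(abs(median(est["D", ]) - D) / D, 0.1)
    expect_lt(abs(median(est["tau", ]) - tau) / tau, 0.1)
  }
})

test_that("the fit beats a dense grid-search oracle on noisy series", {
  p <- ablation_params(D = 3, tau = 20, noise_sigma = 0.1)
  for (s in 1:10) {
    rs <- simulate_recoil(p, seed = 200 + s)
    f <- fit_kelvin_voigt(rs)
    t_post <- rs$times[-1]
    dL <- rs$distances[-1] - rs$distances[1]
    expect_lte(f$sse, kv_grid_sse(t_post, dL) + 1e-9)
  }
})

test_that("group comparisons are calibrated and powered", {
  # identical constant groups: zero difference, p = 1
  cmp <- compare_mechanics(rep(c(2, 2), each = 5),
                           rep(c("a", "b"), each = 5))
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p, 1)

  # null calibration: Welch p uniform under equal presets
  p <- ablation_params(D = 3, tau = 20, noise_sigma = 0.05)
  tau_of <- function(seeds) vapply(seeds, function(s)
    fit_kelvin_voigt(simulate_recoil(p, seed = s))$tau_hat, numeric(1))
  pool <- tau_of(1:80)
  set.seed(99)
  pvals <- vapply(1:200, function(i) {
    idx <- sample(80, 40)
    stats::t.test(pool[idx[1:20]], pool[idx[21:40]])$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # power: two-fold tau difference at small noise is detected
  p2 <- ablation_params(D = 3, tau = 40, noise_sigma = 0.05)
  g1 <- tau_of(301:320)
  g2 <- vapply(321:340, function(s)
    fit_kelvin_voigt(simulate_recoil(p2, seed = s))$tau_hat, numeric(1))
  cmp2 <- compare_mechanics(c(g1, g2), rep(c("wt", "mut"), each = 20))
  expect_lt(cmp2$p, 0.01)

  expect_error(compare_mechanics(1:4, c("a", "a", "b", "b")), ">= 3")
})
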