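test_that("normalization divides by the initial band", {
  tc <- normalize_timecourse(c(0, 5, 10), c(100, 50, 25))
  expect_equal(tc$fractions, c(1, 0.5, 0.25))
  expect_equal(normalize_timecourse(c(0, 5, 10), c(80, 80, 80))$fractions,
               c(1, 1, 1))
  expect_error(normalize_timecourse(c(0, 5, 10), c(0, 50, 25)), "unnormalizable")
  expect_error(normalize_timecourse(c(0, 5, 5), c(10, 5, 2)), "increasing")
  expect_error(normalize_timecourse(c(0, 5), c(10, 5)), "3 time points")
})

test_that("noiseless exponential decay is fitted exactly", {
  t <- seq(0, 25, by = 5)
  rf <- fit_first_order(t, exp(-0.05 * t))
  expect_equal(rf$k, 0.05, tolerance = 1e-8)
  expect_true(rf$converged)
  expect_equal(rf$r_squared, 1, tolerance = 1e-10)
  # agrees with the closed-form log-linear slope
  f <- exp(-0.123 * t)
  slope <- -sum(t[-1] * log(f[-1])) / sum(t[-1]^2)
  expect_equal(fit_first_order(t, f)$k, slope, tolerance = 1e-10)
})

test_that("non-decaying fractions give a flagged k = 0 boundary fit", {
  t <- seq(0, 25, by = 5)
  rf <- fit_first_order(t, rep(1, length(t)))
  expect_equal(rf$k, 0)
  expect_true(rf$boundary)
  rising <- fit_first_order(t, 1 + 0.01 * t)
  expect_equal(rising$k, 0)
  expect_true(rising$boundary)
})

test_that("simulated noisy rates are recovered within sampling error", {
  # 200 seeded replicates at k = 0.08, additive noise sd 0.03
  t <- seq(0, 25, by = 5)
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    f <- pmax(0, exp(-0.08 * t) + rnorm(length(t), 0, 0.03))
    f[1] <- 1
    rf <- fit_first_order(t, f)
    abs(rf$k - 0.08) <= 3 * rf$k_se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the effectiveness model is recovered exactly from noiseless points", {
  ratios <- c(0, 10, 20, 40, 80, 160)
  kvals <- 0.1 / (1 + ratios / 40)
  ef <- fit_effectiveness(ratios, kvals)
  expect_equal(ef$k0, 0.1, tolerance = 1e-8)
  expect_equal(ef$phi, 40, tolerance = 1e-8)
  # fixing k0 leaves a one-parameter fit with the same solution
  ef_fix <- fit_effectiveness(ratios, kvals, fix_k0 = 0.1)
  expect_equal(ef_fix$phi, 40, tolerance = 1e-8)
  expect_true(is.na(ef_fix$k0_se))
})

test_that("the fitted curve halves at ratio = phi and decreases in ratio", {
  ratios <- c(0, 10, 20, 40, 80, 160)
  ef <- fit_effectiveness(ratios, 0.1 / (1 + ratios / 40))
  at_phi <- ef$k0 / (1 + ef$phi / ef$phi)
  expect_equal(at_phi, ef$k0 / 2, tolerance = 1e-12)
  grid <- ef$k0 / (1 + seq(0, 200, by = 5) / ef$phi)
  expect_true(all(diff(grid) < 0))
})

test_that("degenerate effectiveness inputs are flagged or rejected", {
  expect_error(fit_effectiveness(c(10, 20, 40), c(0.08, 0.06, 0.04)),
               "ratio-0")
  ef_flat <- fit_effectiveness(c(0, 10, 20), rep(0.1, 3))
  expect_true(ef_flat$no_inhibition)
  expect_identical(ef_flat$phi, Inf)
  expect_error(fit_effectiveness(c(0, 10), c(0.1, 0.05)), "distinct ratios")
})

test_that("phi -> Kd conversion is the molar-ratio rescaling", {
  expect_equal(kd_from_phi(1, 1), 1)
  expect_equal(kd_from_phi(43.422, 6.5947), 286.36, tolerance = 1e-4)
  # linear in both arguments
  expect_equal(kd_from_phi(2 * 43.422, 6.5947), 2 * kd_from_phi(43.422, 6.5947))
  expect_equal(kd_from_phi(43.422, 2 * 6.5947), 2 * kd_from_phi(43.422, 6.5947))
  expect_error(kd_from_phi(-1, 5), "positive")
})

test_that("molar concentration arithmetic is correct", {
  expect_equal(molar_concentration(22.358, 1000, 22358), 1, tolerance = 1e-12)
  expect_equal(molar_concentration(15, 100, 22358), 6.709, tolerance = 1e-3)
  expect_error(molar_concentration(0, 100, 22358), "positive")
})

test_that("bootstrap intervals are deterministic and collapse without noise", {
  ratios <- c(0, 10, 20, 40, 80, 160)
  kvals <- 0.1 / (1 + ratios / 40)
  bt1 <- bootstrap_effectiveness(ratios, kvals, n_boot = 200, seed = 5)
  bt2 <- bootstrap_effectiveness(ratios, kvals, n_boot = 200, seed = 5)
  expect_identical(bt1$ci, bt2$ci)
  expect_lt(diff(bt1$ci["phi", ]), 1e-6) # noiseless: width ~ 0
  expect_equal(unname(bt1$ci["phi", "lower"]), 40, tolerance = 1e-6)
})

test_that("phi estimation bias shrinks as noise vanishes", {
  err_at_noise <- vapply(c(0.06, 0.02, 0.005), function(sd) {
    errs <- vapply(1:40, function(s) {
      cfg <- simulation_config(noise_sd = sd, seed = s)
      per <- fit_timecourses(simulate_cleavage_series(cfg))
      abs(fit_effectiveness(per$ratio, per$k)$phi - cfg$phi)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(err_at_noise) < 0))
})
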