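# Scripted experiment protocols: sweep grids, robustness sampling,
# sensory modulation, rescue, and two-sided synchrony sweeps.

test_that("drive sweep recovers the no-wave / single / multiple regimes", {
  res <- sweep_drive(strengths = c(1.2, 1.7, 3.5),
                     durations = c(0.5, 2, 12), t_extra = 12)
  cell <- function(s, d) res[res$strength == s & res$duration == d, ]
  expect_identical(cell(1.2, 0.5)$n_waves, 0L)
  expect_true(is.na(cell(1.2, 0.5)$onset_delay))
  expect_identical(cell(1.7, 2)$n_waves, 1L)
  expect_gt(cell(1.7, 12)$n_waves, 1L)
  expect_identical(cell(3.5, 12)$n_waves, 1L)
  expect_true(cell(3.5, 12)$prolonged)
  # onset delay non-increasing in strength at fixed duration
  d2 <- res[res$duration == 2, ]
  d2 <- d2[order(d2$strength), ]
  expect_true(all(diff(d2$onset_delay[!is.na(d2$onset_delay)]) <= 0))
})

test_that("coupling grid shows excitation effects and inhibition tolerance", {
  # excitation-dominant cells lengthen contractions
  res <- sweep_intersegmental(b_values = c(17, 20, 24), d_values = -20)
  res <- res[order(res$b), ]
  expect_true(all(res$valid | res$reason != ""))
  ok <- res$mean_normalized_duration
  expect_true(all(diff(ok) > 0))
  # strong imbalance eliminates waves
  bad <- sweep_intersegmental(b_values = 34, d_values = -6)
  expect_false(bad$valid[1])
  expect_identical(bad$mean_normalized_duration[1], 0)
  expect_true(is.character(bad$reason[1]) && nzchar(bad$reason[1]))
  # the feasible span of d at the published cell exceeds the span of b
  b_scan <- sweep_intersegmental(b_values = seq(12, 32, by = 4),
                                 d_values = -20)
  d_scan <- sweep_intersegmental(b_values = 20,
                                 d_values = seq(-40, -8, by = 4))
  span <- function(x) sum(x$mean_normalized_duration > 0)
  expect_gte(span(d_scan), span(b_scan))
})

test_that("robustness sampling preserves sign, seed, and the noiseless limit", {
  # zero noise at a wave-producing mean: every trial succeeds
  r0 <- robustness_noise(20, -20, sigma_b = 0, sigma_d = 0, trials = 3,
                         seed = 5)
  expect_identical(r0$fraction, 1)
  # rejection sampling never flips the mean's sign, without mass at zero
  set.seed(99)
  b <- crawlwave:::sample_signed_weights(20, 15, 500)
  d <- crawlwave:::sample_signed_weights(-20, 15, 500)
  expect_true(all(b > 0))
  expect_true(all(d < 0))
  # seed reproducibility
  r1 <- robustness_noise(20, -20, sigma_b = 3, sigma_d = 3, trials = 4,
                         seed = 11)
  r2 <- robustness_noise(20, -20, sigma_b = 3, sigma_d = 3, trials = 4,
                         seed = 11)
  expect_identical(r1$trials, r2$trials)
  # directed sampling draws each direction independently
  r3 <- robustness_noise(20, -20, sigma_b = 3, sigma_d = 3, trials = 2,
                         seed = 11, edge_mode = "directed")
  expect_identical(nrow(r3$trials), 2L)
})

test_that("stronger mean coupling is more robust to noise", {
  weak <- robustness_noise(17, -17, sigma_b = 4, sigma_d = 4, trials = 8,
                           seed = 2)
  strong <- robustness_noise(24, -24, sigma_b = 4, sigma_d = 4, trials = 8,
                             seed = 2)
  expect_gte(strong$fraction, weak$fraction)
})

test_that("sensory feedback reshapes durations and phase lags as described", {
  # raising beta at gamma = 0 shortens every phase lag, preserving order
  sw <- sensory_sweep(beta_values = c(0, 10, 20), gamma_values = 0)
  # with sensory excitation present the wave is strictly ordered; at
  # beta = 0 the sustained drive prolongs A8 beyond A7 (invalid cell)
  expect_true(all(sw$valid[sw$beta > 0]))
  lags <- sapply(sw$phase_lags, function(x) x$lag)  # 7 x 3
  expect_true(all(lags[, 2] < lags[, 1]))
  expect_true(all(lags[, 3] < lags[, 2]))
  # raising gamma at beta = 20 lengthens anterior but not posterior lags
  sw2 <- sensory_sweep(beta_values = 20, gamma_values = c(0, 17))
  lags2 <- sapply(sw2$phase_lags, function(x) x$lag)
  anterior <- 5:7   # pairs closest to A1 (propagation order A8 -> A1)
  posterior <- 1:2
  expect_true(all(lags2[anterior, 2] > lags2[anterior, 1]))
  expect_true(all(abs(lags2[posterior, 2] - lags2[posterior, 1]) < 0.01))
  # beta = 20, gamma = 0 gives the long ~0.6 normalized duration
  expect_equal(sw$mean_normalized_duration[sw$beta == 20], 0.6,
               tolerance = 0.05)
})

test_that("sensory feedback rescues a weakly coupled chain", {
  res <- rescue_experiment(cpg_spec(chain = chain_coupling(16, -20)),
                           sensory_spec(25, 40, 0))
  without <- res[res$condition == "without_sensory", ]
  with_s <- res[res$condition == "with_sensory", ]
  expect_false(without$valid)
  expect_identical(without$reason, "no wave")
  expect_true(with_s$valid)
  expect_gt(with_s$mean_normalized_duration, 0)
})

test_that("two-sided sweeps carry per-cell classification and sentinels", {
  res <- two_sided_sweep("EE", c(2, 14), "b", 20, thresholds = c(0.3, 0.2))
  expect_identical(nrow(res), 4L)
  w2 <- res[res$weight == 2 & res$threshold == 0.3, ]
  expect_identical(w2$classification, "synchronous")
  expect_true(w2$waves_propagate)
  w14 <- res[res$weight == 14 & res$threshold == 0.3, ]
  expect_identical(w14$classification, "no_wave")
  expect_false(w14$waves_propagate)
})
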