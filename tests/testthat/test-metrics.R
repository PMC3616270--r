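# Wave quantification: crossing detection, durations, phase lags,
# validity classification, wave counting, onset delay, synchrony.

test_that("contraction intervals locate interpolated crossings", {
  # piecewise-linear pulse 0 -> 0.6 -> 0 over t = 0, 2, 4: crossings of
  # 0.3 at t = 1 and t = 3 analytically
  E <- matrix(0, nrow = 3, ncol = 8)
  E[, 5] <- c(0, 0.6, 0)
  traj <- synthetic_trajectory(c(0, 2, 4), E)
  tab <- contraction_intervals(traj, 0.3)
  row <- tab[tab$segment == 5, ]
  expect_equal(row$onset, 1.0)
  expect_equal(row$offset, 3.0)
  expect_false(row$truncated_onset || row$truncated_offset)
  expect_identical(nrow(tab), 1L)

  # constant suprathreshold activity: one boundary-flagged interval
  E2 <- matrix(0, nrow = 5, ncol = 8); E2[, 2] <- 0.4
  tab2 <- contraction_intervals(synthetic_trajectory(seq(0, 10, 2.5), E2),
                                0.3)
  row2 <- tab2[tab2$segment == 2, ]
  expect_equal(c(row2$onset, row2$offset), c(0, 10))
  expect_true(row2$truncated_onset && row2$truncated_offset)

  # everywhere subthreshold: empty table
  expect_identical(nrow(contraction_intervals(
    synthetic_trajectory(c(0, 1), matrix(0.1, 2, 8)), 0.3)), 0L)
  expect_error(contraction_intervals(baseline_trajectory(), 1.5), "threshold")
})

test_that("normalized durations and phase lags follow their definitions", {
  # one segment contracting (2, 6) within a wave spanning (0, 10)
  tab <- synthetic_contractions(onsets = c(8:2, 0), offsets = c(10, 9:4, 6))
  # forward wave: initiating segment 8 onset 0, terminal segment 1 offset 10
  nd <- normalized_durations(tab, "forward")
  expect_equal(attr(nd, "wave_duration"), 10)
  expect_equal(nd$normalized_duration[nd$segment == 8], 0.6)
  # evenly spaced onsets 0..7 with wave duration 10: all lags 0.1
  tab2 <- synthetic_contractions(onsets = 7:0, offsets = rep(10, 8))
  lags <- intersegmental_phase_lags(tab2, "forward")
  expect_equal(lags$lag, rep(0.1, 7))
  expect_identical(lags$from_segment, 8:2)
  # simultaneous onsets give zero lags
  tab3 <- synthetic_contractions(onsets = rep(1, 8), offsets = rep(2, 8))
  expect_equal(intersegmental_phase_lags(tab3, "forward")$lag, rep(0, 7))
  # full-span contractions give normalized duration 1 everywhere
  tab4 <- synthetic_contractions(onsets = rep(0, 8), offsets = rep(10, 8))
  expect_equal(normalized_durations(tab4, "forward")$normalized_duration,
               rep(1, 8))
  # multiple or missing intervals are rejected with a pointer to count_waves
  tab5 <- tab
  tab5 <- tab5[-3, ]
  tab5 <- crawlwave:::rewrap_contractions(tab5, tab)
  expect_error(normalized_durations(tab5, "forward"), "count_waves")
})

test_that("wave validity classification applies the offset-order rules", {
  # fully ordered forward wave: onsets 7..0 (A8 first), offsets increasing
  # toward A1
  good <- synthetic_contractions(onsets = 7:0, offsets = 11:4)
  expect_true(classify_wave(good, "forward", "strict")$valid)
  expect_true(classify_wave(good, "forward", "endpoint_relaxed")$valid)
  # A1 deactivating before A2: invalid strictly, valid relaxed
  a1_early <- synthetic_contractions(onsets = 7:0,
                                     offsets = c(9.5, 10:4))
  expect_false(classify_wave(a1_early, "forward", "strict")$valid)
  expect_identical(classify_wave(a1_early, "forward", "strict")$reason,
                   "offset order")
  expect_true(classify_wave(a1_early, "forward", "endpoint_relaxed")$valid)
  # onset inversion at A5/A6 is invalid under both rules
  bad_onsets <- synthetic_contractions(onsets = c(7:4, 2, 3, 1.5, 0.5),
                                       offsets = 11:4)
  # segments ordered 1..8 -> onsets per segment: A6 starts before A5
  for (rule in c("strict", "endpoint_relaxed")) {
    cls <- classify_wave(bad_onsets, "forward", rule)
    expect_false(cls$valid)
    expect_identical(cls$reason, "onset order")
  }
  # missing segment
  miss <- good[-2, ]
  miss <- crawlwave:::rewrap_contractions(miss, good)
  expect_identical(classify_wave(miss, "forward")$reason, "missing segment")
})

test_that("wave counting distinguishes none, single, and repeated waves", {
  sp <- cpg_spec()
  # weak short drive: no wave
  weak <- simulate_cpg(sp, forward_drive(strength = 1.2, duration = 0.5), 10)
  expect_identical(count_waves(weak, 0.3, "forward")$n_waves, 0L)
  # baseline: exactly one
  expect_identical(count_waves(baseline_trajectory(), 0.3,
                               "forward")$n_waves, 1L)
  # sustained intermediate drive: repeated waves
  multi <- simulate_cpg(sp, forward_drive(duration = 35), 45)
  cw <- count_waves(multi, 0.3, "forward")
  expect_gt(cw$n_waves, 1L)
  per_wave <- tidy(cw)
  expect_identical(nrow(per_wave), cw$n_waves)
  expect_true(all(per_wave$wave_duration > 0))
  # strong drive: one wave with a prolonged initiating contraction
  strong <- simulate_cpg(sp, forward_drive(strength = 3.5, duration = 10), 25)
  cws <- count_waves(strong, 0.3, "forward")
  expect_identical(cws$n_waves, 1L)
  expect_true(cws$prolonged[1])
})

test_that("wave onset delay decreases with drive strength", {
  sp <- cpg_spec()
  delays <- sapply(c(1.7, 2.5, 3.5), function(s) {
    pr <- forward_drive(strength = s, duration = 2)
    wave_onset_delay(simulate_cpg(sp, pr, 12), pr, 0.3)
  })
  expect_true(all(diff(delays) < 0))
  expect_true(all(delays > 0))
  # subthreshold drive gives NA
  pr0 <- forward_drive(strength = 1.2, duration = 0.5)
  expect_true(is.na(wave_onset_delay(simulate_cpg(sp, pr0, 10), pr0, 0.3)))
  # shifting the pulse onset leaves the delay unchanged
  pr1 <- forward_drive(onset = 0, duration = 2)
  pr2 <- forward_drive(onset = 1.5, duration = 2)
  d1 <- wave_onset_delay(simulate_cpg(sp, pr1, 12), pr1, 0.3)
  d2 <- wave_onset_delay(simulate_cpg(sp, pr2, 13.5), pr2, 0.3)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("crossing times are insensitive to the sampling resolution", {
  sp <- cpg_spec()
  coarse <- contraction_intervals(simulate_cpg(
    sp, forward_drive(), 12,
    solver_settings(output_resolution = 0.005)), 0.3)
  fine <- contraction_intervals(simulate_cpg(
    sp, forward_drive(), 12,
    solver_settings(output_resolution = 0.0005)), 0.3)
  expect_equal(coarse$onset, fine$onset, tolerance = 1e-3)
  expect_equal(coarse$offset, fine$offset, tolerance = 1e-3)
})

test_that("baseline wave durations peak at A8 and trough at A1", {
  m <- wave_metrics(baseline_trajectory(), 0.3, "forward")
  nd <- m$durations$normalized_duration
  expect_identical(which.max(nd), 8L)
  expect_identical(which.min(nd), 1L)
})

test_that("lowering the threshold lengthens contractions, speeds waves", {
  traj <- baseline_trajectory()
  d3 <- normalized_durations(contraction_intervals(traj, 0.3), "forward")
  d2 <- normalized_durations(contraction_intervals(traj, 0.2), "forward")
  l3 <- intersegmental_phase_lags(contraction_intervals(traj, 0.3), "forward")
  l2 <- intersegmental_phase_lags(contraction_intervals(traj, 0.2), "forward")
  expect_true(all(d2$normalized_duration >=
                    d3$normalized_duration - 1e-12))
  expect_true(all(l2$lag <= l3$lag + 1e-12))
})

test_that("left/right synchrony classifies the canonical regimes", {
  # identical sides: zero difference, synchronous
  spEE <- cpg_spec(contralateral = contralateral_spec("EE", 0))
  prEq <- drive_protocol(segment = c(8, 8), strength = c(1.7, 1.7),
                         duration = 2, side = c("left", "right"))
  trajEq <- simulate_cpg(spEE, prEq, 12)
  s <- left_right_sync(trajEq, 0.3, transient_cut = 0)
  expect_identical(s$mean_onset_difference, 0)
  expect_identical(s$classification, "synchronous")
  # silent side: no_wave
  prOne <- drive_protocol(segment = 8, strength = 1.7, duration = 2,
                          side = "left")
  sOne <- left_right_sync(simulate_cpg(spEE, prOne, 12), 0.3,
                          transient_cut = 0)
  expect_identical(sOne$classification, "no_wave")
  # II coupling alternates under sustained asymmetric drive
  spII <- cpg_spec(contralateral = contralateral_spec("II", -2))
  sII <- left_right_sync(simulate_cpg(spII, two_sided_drive(), 40), 0.3)
  expect_identical(sII$classification, "alternating")
  expect_true(sII$discarded)
  # EE coupling of strength 2 synchronizes
  spEE2 <- cpg_spec(contralateral = contralateral_spec("EE", 2))
  sEE <- left_right_sync(simulate_cpg(spEE2, two_sided_drive(), 40), 0.3)
  expect_identical(sEE$classification, "synchronous")
  expect_lte(sEE$mean_onset_difference, 0.1)
})

test_that("metric writers emit one row per wave with sidecar summary", {
  m <- wave_metrics(baseline_trajectory(), 0.3, "forward")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_wave_metrics(m, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 1L)
  expect_true(all(paste0("norm_duration_", 1:8) %in% names(tab)))
  expect_true(file.exists(paste0(path, ".json")))
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js[[1]]$wave_duration, m$wave_duration, tolerance = 1e-9)
})
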