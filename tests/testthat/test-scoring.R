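isi24 <- 1 / 2.4

test_that("interval-multiple detection picks the nearest stimulus multiple", {
  mk <- function(iti, n = 10) cumsum(rep(iti, n))
  expect_equal(detect_tap_interval(mk(0.84), isi24), 2L)
  expect_equal(detect_tap_interval(mk(0.42), isi24), 1L)
  expect_equal(detect_tap_interval(mk(1.26), isi24), 3L)
  # exact midpoint of multiples 1 and 2 ties to the smaller
  expect_equal(detect_tap_interval(mk(0.625), isi24), 1L)
  expect_true(is.na(detect_tap_interval(c(1, 2), isi24)))
})

test_that("wrong-rate rule excludes 1x and 3x trials only", {
  expect_false(exclude_wrong_rate(2L))
  expect_true(exclude_wrong_rate(1L))
  expect_true(exclude_wrong_rate(3L))
  expect_true(exclude_wrong_rate(NA_integer_))
  expect_error(exclude_wrong_rate(4L), "multiplier")
})

test_that("phase detection identifies the tapped parity", {
  stim <- generate_stimulus_train(2.4, 39.5)
  odd_taps <- stim$onsets[seq(3, 95, by = 2)]
  even_taps <- stim$onsets[seq(4, 94, by = 2)]
  expect_equal(detect_phase(odd_taps, stim), "odd")
  expect_equal(detect_phase(even_taps, stim), "even")
  expect_error(detect_phase(odd_taps[1:2], stim), "3 taps")
  expect_error(detect_phase(odd_taps, stim, kernel_sd = 0), "kernel_sd")
})

test_that("initial trim discards the first five taps", {
  ev12 <- tap_events(seq_len(12))
  out <- trim_initial_taps(ev12)
  expect_length(out$times, 7)
  expect_equal(out$discarded$reason, rep("initial_trim", 5))
  expect_length(trim_initial_taps(tap_events(1:5))$times, 0)
  expect_length(trim_initial_taps(tap_events(numeric(0)))$times, 0)
})

test_that("pause pruning drops the tap ending each outlier interval", {
  # intervals: nine of 0.83 s and one 3.5 s gap; Q3 + 3 IQR = 0.83
  t <- cumsum(c(0, rep(0.83, 5), 3.5, rep(0.83, 4)))
  out <- remove_pause_taps(tap_events(t))
  expect_equal(out$discarded$time, t[7])
  expect_equal(out$discarded$reason, "pause_outlier")
  expect_length(out$times, 10)

  # equal intervals: IQR = 0 but no interval exceeds the threshold
  reg <- remove_pause_taps(tap_events(cumsum(rep(0.83, 10))))
  expect_length(reg$times, 10)

  # two separated pauses are both caught in one pass
  t2 <- cumsum(c(0, rep(0.83, 3), 3.5, rep(0.83, 4), 3.5, rep(0.83, 3)))
  out2 <- remove_pause_taps(tap_events(t2))
  expect_equal(out2$discarded$time, c(t2[5], t2[10]))

  expect_warning(remove_pause_taps(tap_events(1:3)), "fewer than 4")
})

test_that("taps map to beat-circle angles with the stated conventions", {
  stim <- generate_stimulus_train(2.4, 39.5)
  P <- 2 * isi24
  anchor <- stim$onsets[3]  # odd parity anchor
  expect_equal(taps_to_angles(anchor, stim, "odd"), 0)
  expect_equal(taps_to_angles(anchor + P / 4, stim, "odd"), pi / 2,
               tolerance = 1e-9)
  # equidistant tap maps to +pi under the wrap convention
  expect_equal(taps_to_angles(anchor + P / 2, stim, "odd"), pi,
               tolerance = 1e-9)
  expect_equal(taps_to_angles(anchor - P / 4, stim, "odd"), -pi / 2,
               tolerance = 1e-9)
  # even parity shifts the anchor grid by one ISI
  expect_equal(taps_to_angles(stim$onsets[4], stim, "even"), 0)
  expect_equal(abs(taps_to_angles(stim$onsets[4], stim, "odd")), pi,
               tolerance = 1e-9)
})

test_that("score_trial runs the cleaning pipeline in order", {
  # noise-free correct tapper: perfect score
  sc <- score_trial(make_clean_trial(kappa = Inf))
  expect_false(sc$excluded)
  expect_equal(sc$multiplier, 2L)
  expect_equal(sc$parity, "odd")
  expect_equal(sc$R, 1, tolerance = 1e-9)
  expect_lt(sc$rayleigh_p, 1e-6)

  # every-beat tapper is excluded as wrong rate
  sc1 <- score_trial(make_clean_trial(kappa = 20, multiplier = 1, seed = 2))
  expect_true(sc1$excluded)
  expect_equal(sc1$reason, "wrong_rate")
  expect_equal(sc1$multiplier, 1L)

  # every-third-beat tapper likewise
  sc3 <- score_trial(make_clean_trial(kappa = 20, multiplier = 3, seed = 3))
  expect_true(sc3$excluded)
  expect_equal(sc3$multiplier, 3L)

  # even-locked tapper: parity detected, consistency near the Bessel ratio
  sc_even <- score_trial(make_clean_trial(kappa = 8, start_beat = 4, seed = 4))
  expect_false(sc_even$excluded)
  expect_equal(sc_even$parity, "even")
  expect_equal(sc_even$R, bessel_ratio(8), tolerance = 0.1)

  # too few taps flagged, not raised
  sc_few <- score_trial(as_trial(c(1, 2, 3, 4) * 0.8333333))
  expect_true(sc_few$excluded)
  expect_equal(sc_few$reason, "too_few_taps")
})

test_that("scores are invariant to a common time shift", {
  set.seed(61)
  tr <- make_clean_trial(kappa = 3, mean_phase = -0.3, seed = NULL)
  base <- score_trial(tr)
  shift <- 0.123456
  tr2 <- tr
  tr2$events <- tap_events(tr$events$times + shift)
  tr2$reference_stimuli$onsets <- tr$reference_stimuli$onsets + shift
  shifted <- score_trial(tr2)
  expect_equal(shifted$R, base$R, tolerance = 1e-9)
  expect_equal(shifted$direction_rad, base$direction_rad, tolerance = 1e-9)
  expect_equal(shifted$parity, base$parity)
  expect_equal(shifted$multiplier, base$multiplier)
})

test_that("shifting taps by one full beat period leaves R and direction alone", {
  set.seed(62)
  tr <- make_clean_trial(kappa = 3, mean_phase = -0.3, seed = NULL)
  base <- score_trial(tr)
  tr2 <- tr
  tr2$events <- tap_events(tr$events$times + 2 * isi24)
  shifted <- score_trial(tr2)
  expect_equal(shifted$R, base$R, tolerance = 1e-6)
  expect_equal(shifted$direction_rad, base$direction_rad, tolerance = 1e-6)
})

test_that("dropout guard inside score_trial discards post-dropout taps", {
  tr <- make_clean_trial(kappa = Inf)
  n_all <- length(tr$events$times)
  # place a dropout end right before a tap
  victim <- tr$events$times[12]
  sc <- score_trial(tr, dropout_end = victim - 0.1)
  expect_false(sc$excluded)
  # initial trim (5) + guarded tap (1) + the tap ending the gap the guard
  # opened, which the pause rule then flags (1)
  expect_equal(sc$n_taps, n_all - 7)
})
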