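test_that("velocity of simple signals matches calculus", {
  fps <- 100
  const <- diameter_trace(rep(50, 200), fps = fps, pixel_size = 1)
  expect_true(all(compute_velocity(const) == 0))

  ramp <- diameter_trace(10 + 0.25 * (0:199), fps = fps, pixel_size = 1)
  v <- compute_velocity(ramp)
  expect_equal(v[2:199], rep(0.25 * fps, 198))       # b um/frame -> b*fps um/s

  T0 <- 2                                             # d = 50 + 10 cos(2 pi t / T0)
  tt <- (0:999) / fps
  sine <- diameter_trace(50 + 10 * cos(2 * pi * tt / T0), fps = fps,
                         pixel_size = 1)
  vmin <- min(compute_velocity(sine))
  expect_lt(abs(vmin - (-20 * pi / T0)) / (20 * pi / T0), 0.01)

  expect_error(compute_velocity(const, smooth_window = 200), "parameter")
})

test_that("beat detection reproduces constructed interval boundaries", {
  # 50 seeded piecewise-linear traces; construction is the oracle
  set.seed(314)
  for (i in 1:8) {
    n_beats <- sample(3:8, 1)
    fx <- trapezoid_trace(n_beats,
                          contr = sample(6:12, 1), hold = sample(8:16, 1),
                          relax = sample(6:12, 1), plateau = sample(25:50, 1))
    bt <- detect_beats(fx$trace, smooth_window = 1)   # noiseless construction
    expect_equal(nrow(bt$beats), n_beats - 1)         # last beat has no next onset
    det_on <- round(bt$beats$onset_t * fx$fps) + 1
    det_re <- round(bt$beats$rel_end_t * fx$fps) + 1
    expect_true(all(abs(det_on - fx$onsets[seq_len(n_beats - 1)]) <= 1))
    expect_true(all(abs(det_re - fx$rel_ends[seq_len(n_beats - 1)]) <= 1))
  }
})

test_that("flat and single-dip traces behave at the extremes", {
  expect_equal(nrow(detect_beats(
    diameter_trace(rep(55, 300), fps = 100, pixel_size = 1))$beats), 0)

  fx <- trapezoid_trace(2, plateau = 60)
  bt <- detect_beats(fx$trace, smooth_window = 1)
  expect_equal(nrow(bt$beats), 1)
  si_true <- (fx$rel_ends[1] - fx$onsets[1]) / fx$fps
  # each boundary is localized within one frame, so SI is within two
  expect_lte(abs(bt$beats$si[1] - si_true), 2 / fx$fps)
})

test_that("beat morphology takes the DI max and SI min", {
  fx <- trapezoid_trace(3, dd = 60, sd = 40)
  bt <- detect_beats(fx$trace)
  m <- beat_morphology(bt$beats[1, ], fx$trace)
  expect_equal(unname(m["dd"]), 60)
  expect_equal(unname(m["sd"]), 40)
  expect_true(all(bt$beats$dd >= bt$beats$sd))
})

test_that("derived indices match their formulas and invariances", {
  expect_equal(fractional_shortening(100, 50), 50)
  expect_equal(fractional_shortening(80, 60), 25)
  expect_equal(fractional_shortening(70, 70), 0)
  expect_error(fractional_shortening(0, 10), "domain")

  expect_equal(ejection_fraction(100, 50), 75)
  expect_equal(ejection_fraction(70, 70), 0)
  expect_equal(ejection_fraction(80, 60), ejection_fraction(8, 6))  # scale free

  expect_equal(arrhythmia_index(rep(0.8, 6)), 0)
  expect_equal(arrhythmia_index(c(1, 1, 1, 1, 2)), sqrt(0.2) / 1)
  expect_equal(arrhythmia_index(3 * c(1, 1, 1, 1, 2)),
               arrhythmia_index(c(1, 1, 1, 1, 2)))
  expect_error(arrhythmia_index(0.5), "insufficient")

  expect_equal(stroke_volume(40, 20, 100), pi * 100 * (400 - 100) / 1000)
  expect_equal(stroke_volume(40, 40, 100), 0)
  expect_equal(stroke_volume(40, 20, 200), 2 * stroke_volume(40, 20, 100))
  expect_error(stroke_volume(20, 40, 100), "domain")
})

test_that("cardiac output integrates stroke volumes over beat time", {
  b <- data.frame(onset_t = c(0, 0.5), rel_end_t = c(0.2, 0.7),
                  si = 0.2, di = 0.3, hp = 0.5, dd = 40, sd = 20)
  bt <- flyheart:::beat_table(b, fps = 100)
  sv <- stroke_volume(40, 20, 100)
  expect_equal(cardiac_output(bt, 100), sv / 0.5)     # SV x HR, identical beats
  b0 <- b; b0$sd <- 40; b0$dd <- 40
  expect_equal(cardiac_output(flyheart:::beat_table(b0, 100), 100), 0)
  expect_error(cardiac_output(flyheart:::beat_table(data.frame(), 100), 100),
               "insufficient")
})

test_that("contractile latencies separate velocity extrema of a cosine beat", {
  fps <- 200; T0 <- 0.8
  tt <- (0:799) / fps
  tr <- diameter_trace(50 + 10 * cos(2 * pi * tt / T0), fps = fps,
                       pixel_size = 1)
  bt <- detect_beats(tr, smooth_window = 5)
  lat <- contractile_latency(tr, bt, smooth_window = 5)
  expect_true(all(lat$t_peak_contraction >= 0))
  expect_true(all(lat$t_contraction_to_relaxation >= 0))
  # extrema of the derivative of a cosine are half a period apart
  expect_true(all(abs(lat$t_contraction_to_relaxation - T0 / 2) <= 2 / fps))
})

test_that("arrhythmia filters use strict thresholds", {
  b <- data.frame(onset_t = 0:5, rel_end_t = 0:5 + 0.2,
                  si = c(0.3, 0.6, 0.51, 0.5, 0.2, 0.1),
                  di = c(0.9, 1.0, 1.01, 0.4, 0.3, 0.2),
                  hp = 1, dd = 60, sd = 40)
  bt <- flyheart:::beat_table(b, fps = 100)
  ev <- flag_arrhythmia_events(bt)
  expect_equal(ev$n_tachy, 2)                 # strictly > 0.5 s
  expect_equal(ev$n_brady, 1)                 # strictly > 1.0 s
  expect_equal(sort(ev$tachy_beats), c(2, 3))
  expect_equal(ev$brady_beats, 3)

  # monotone non-increasing counts in the thresholds
  thr <- seq(0.1, 1.2, by = 0.1)
  counts <- vapply(thr, function(x)
    flag_arrhythmia_events(bt, tachy_thr = x)$n_tachy, numeric(1))
  expect_true(all(diff(counts) <= 0))

  ev0 <- flag_arrhythmia_events(flyheart:::beat_table(data.frame(), 100))
  expect_equal(ev0$n_tachy + ev0$n_brady, 0)
})

test_that("aggregate statistics recover the simulator and satisfy identities", {
  s <- tiny_spec(hp_cv = 0, duration = 4, noise_sigma = 0)
  h <- simulate_heart(s, render = FALSE)
  tr <- diameter_trace(h$waveform, fps = s$fps, pixel_size = s$pixel_size)
  bt <- detect_beats(tr)
  st <- aggregate_stats(bt, roi_length_um = 100, trace = tr)
  expect_equal(st$dd, s$dd, tolerance = 1e-6)
  expect_equal(st$sd, s$sd, tolerance = 1e-6)
  expect_equal(st$hr, 1 / st$hp)
  expect_lt(abs(st$hp - s$hp_mean), 1.5 / s$fps)
  expect_equal(st$ai, 0, tolerance = 0.02)
  expect_true(all(bt$beats$hp == bt$beats$si + bt$beats$di))
  expect_lte(sum(bt$beats$hp), s$duration)

  one <- bt; one$beats <- one$beats[1, ]
  st1 <- aggregate_stats(one, roi_length_um = 100)
  expect_true(is.na(st1$ai))                  # AI needs >= 2 beats
  expect_error(aggregate_stats(flyheart:::beat_table(data.frame(), 100), 100),
               "insufficient")
})
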