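test_that("disk stimulus fields evaluate correctly", {
  stim <- light_disk(radius = 40, intensity = 1, background = 0.5)
  expect_equal(light_at(stim, 0, 0, 10), 1)
  expect_equal(light_at(stim, 100, 0, 10), 0.5)
  # before onset the field is background everywhere
  stim2 <- light_disk(onset_ms = 100)
  expect_equal(light_at(stim2, 0, 0, 50), 0.5)
  # annulus
  stim3 <- light_disk(radius = 40, ring = c(40, 80), ring_intensity = 0)
  expect_equal(light_at(stim3, 60, 0, 1), 0)
  expect_equal(light_at(stim3, 90, 0, 1), 0.5)
})

test_that("square-wave disk alternates between contrast level and background", {
  stim <- light_square_wave(contrast = -1, phase_ms = 200)
  expect_equal(light_at(stim, 0, 0, 50), 0)       # ON phase, -100 % contrast
  expect_equal(light_at(stim, 0, 0, 250), 0.5)    # OFF phase
  stim2 <- light_square_wave(contrast = 0.5)
  expect_equal(light_at(stim2, 0, 0, 50), 0.75)
})

test_that("cloud stimulus has the specified statistics", {
  cloud <- light_cloud(duration_s = 2, patch = c(150, 150), seed = 4)
  fr <- cloud$frames
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(mean(fr), 0.5, tolerance = 0.02)
  expect_equal(sd(fr), 0.175, tolerance = 0.02)
  # spatial correlation length consistent with the 12.5 um Gaussian filter:
  # filtering white noise with a Gaussian of SD sigma gives an
  # autocorrelation Gaussian with SD sigma * sqrt(2) = 2.83 px
  f1 <- fr[, , 1]
  rho <- vapply(1:4, function(lag)
    cor(as.vector(f1[1:(nrow(f1) - lag), ]), as.vector(f1[(1 + lag):nrow(f1), ])),
    0)
  sig_px <- vapply(1:4, function(lag) sqrt(-lag^2 / (2 * log(rho[lag]))), 0)
  expect_equal(median(sig_px), sqrt(2) * 12.5 / 6.25, tolerance = 0.3)
  # frames are uncorrelated in time
  expect_lt(abs(cor(as.vector(fr[, , 1]), as.vector(fr[, , 2]))), 0.1)
})

test_that("disk-electrode potential matches the analytic solution", {
  el <- disk_electrode("epiretinal", diameter = 80)
  a <- 40; V0 <- 10
  at <- function(x, y, z) electrode_potential(el, V0, x, y, z)
  expect_equal(at(0, 0, -2), V0)                       # disk center
  expect_equal(at(a, 0, -2), V0)                       # disk rim
  expect_equal(at(0, 0, -2 + a), V0 / 2)               # axial offset d = a
  # monotone decay along the axis and to zero far away
  axial <- at(0, 0, -2 + seq(0, 400, by = 10))
  expect_true(all(diff(axial) < 0))
  expect_lt(at(0, 0, 5000), 0.01 * V0)
  # linear in V0 (relative thresholds are conversion-invariant)
  expect_equal(electrode_potential(el, 20, 10, 5, 30),
               2 * electrode_potential(el, 10, 10, 5, 30))
})

test_that("antipodal sphere average obeys the analytic limits", {
  el <- disk_electrode("epiretinal")
  centers <- matrix(c(0, 0, 30), 1)
  # uniform field: zero coupling
  g0 <- retisim:::soma_coupling_gains(el, centers, 26, 2, n_pairs = 200,
                                      seed = 1,
                                      field = function(x, y, z) 5 + 0 * x)
  expect_equal(g0, 0)
  # linear field with gradient g along z: <|dv|> -> g * D / 2
  grad <- 0.3
  g1 <- retisim:::soma_coupling_gains(el, centers, 26, 2, n_pairs = 20000,
                                      seed = 1,
                                      field = function(x, y, z) grad * z)
  expect_equal(g1, 0.5 * 2 * grad * 26 / 2, tolerance = 0.02)
  # seeded determinism
  a <- soma_coupling_current(el, c(0, 0, 30), 26, 2, V0 = 50, seed = 9)
  b <- soma_coupling_current(el, c(0, 0, 30), 26, 2, V0 = 50, seed = 9)
  expect_identical(a, b)
  # sign follows the disk polarity
  neg <- soma_coupling_current(el, c(0, 0, 30), 26, 2, V0 = -50, seed = 9)
  expect_equal(neg, -a)
})

test_that("biphasic trains are charge balanced and cathodic first", {
  tr <- biphasic_train(amplitude_ua = 30)
  expect_equal(pulse_waveform(tr, 0.1), -1)
  expect_equal(pulse_waveform(tr, 0.6), 1)
  expect_equal(pulse_waveform(tr, 2), 0)
  # charge balance: integral over one period vanishes
  tt <- seq(0, 50 - 0.005, by = 0.005)
  expect_equal(sum(pulse_waveform(tr, tt)) * 0.005, 0, tolerance = 1e-6)
  # 20 pulse onsets in 1 s
  w <- pulse_waveform(tr, seq(0, 999.995, by = 0.005))
  onsets <- sum(diff(c(0, w < 0)) == 1)
  expect_equal(onsets, 20)
  expect_error(biphasic_train(30, frequency_hz = 20, phase_ms = 30),
               "fit")
})

test_that("waveform segmentation reproduces the pointwise waveform", {
  tr <- biphasic_train(amplitude_ua = 12, onset_ms = 7)
  seg <- retisim:::train_segments(tr, 200)
  mids <- (seg$breaks[-1] + seg$breaks[-length(seg$breaks)]) / 2
  expect_equal(seg$value, pulse_waveform(tr, mids))
})
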