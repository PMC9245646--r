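test_that("Hilbert phase of a pure cosine SO is the closed-form ramp", {
  fs <- 256
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  epoch <- -cos(2 * pi * 0.5 * (t - 1))   # 0.5 Hz, trough at t = 1 s
  ph <- so_phase(epoch, taper = 0)
  expect_equal(ph[[257]], 0)
  # phase(t) = 2 pi 0.5 (t - 1), i.e. pi rad/s: check away from the edges
  sel <- 129:385
  expect_lt(max(abs(ph[sel] - 2 * pi * 0.5 * (t[sel] - 1))), 0.05)
  # +/-500 ms map to +/- pi/2 for a 0.5-Hz wave
  expect_equal(ph[[257 + 128]], pi / 2, tolerance = 0.05)
  expect_equal(ph[[257 - 128]], -pi / 2, tolerance = 0.05)
})

test_that("phase is zero at the trough and antisymmetric under time reversal", {
  set.seed(50)
  epoch <- bandpass_detection(rnorm(512, sd = 10), 256)
  ph <- so_phase(epoch)
  expect_equal(ph[[257]], 0)
  phr <- so_phase(rev(epoch))
  # reversing time negates the phase ramp (up to the one-sample center shift)
  sel <- 100:412
  expect_lt(max(abs(ph[sel] + rev(phr)[sel - 1])), 0.2)
  expect_error(so_phase(rep(1, 512)), "zero-variance")
})

test_that("monotonic range clips at plateaus and the +/- pi bounds", {
  ramp <- seq(-2 * pi, 2 * pi, length.out = 512)
  attr(ramp, "center") <- 257L
  vr <- monotonic_valid_range(ramp)
  expect_equal(ramp[vr[1]] >= -pi && ramp[vr[2]] <= pi, TRUE)
  expect_lt(abs(ramp[vr[1]] + pi), 0.05)
  expect_lt(abs(ramp[vr[2]] - pi), 0.05)
  # plateau at +100 samples after the trough ends the interval there
  ph <- c(seq(-2, 0, length.out = 257), seq(0.01, 1, length.out = 100),
          rep(1, 155))
  attr(ph, "center") <- 257L
  vr <- monotonic_valid_range(ph)
  expect_equal(vr[2], 357)
  # an all-flat phase is too short -> skipped with a warning
  flat <- rep(0, 512); attr(flat, "center") <- 257L
  expect_warning(out <- monotonic_valid_range(flat), "skipped")
  expect_null(out)
})

test_that("the phase grid has 129 points and resampling is exact on ramps", {
  expect_length(so_phase_grid(), 129)
  expect_equal(so_phase_grid()[1], -pi)
  expect_equal(so_phase_grid()[129], pi)
  expect_equal(diff(so_phase_grid())[1], pi / 64)
  phases <- seq(-pi, pi, length.out = 200)
  # constant quantifier stays constant
  ps <- resample_to_phase(rep(1, 200), phases)
  expect_true(all(abs(ps$values - 1) < 1e-12, na.rm = TRUE))
  # cos profile recovered within linear-interpolation error
  ps <- resample_to_phase(cos(phases), phases)
  expect_lt(max(abs(ps$values - cos(ps$grid)), na.rm = TRUE), 1e-3)
  # grid points outside the covered range are missing
  ps <- resample_to_phase(cos(phases[1:100]), phases[1:100])
  expect_true(anyNA(ps$values))
  expect_warning(out <- resample_to_phase(1, 0), "skipped")
  expect_null(out)
})

test_that("averaging phase series uses available cases pointwise", {
  g <- so_phase_grid()
  a <- structure(list(grid = g, values = ifelse(g < 0, 1, NA),
                      n = as.integer(g < 0)), class = "phase_series")
  b <- structure(list(grid = g, values = ifelse(g >= 0, 3, NA),
                      n = as.integer(g >= 0)), class = "phase_series")
  m <- average_phase_series(list(a, b))
  expect_equal(m$values[g < 0], rep(1, sum(g < 0)))
  expect_equal(m$values[g >= 0], rep(3, sum(g >= 0)))
  # duplicates average to themselves
  m2 <- average_phase_series(list(a, a))
  expect_equal(m2$values, a$values)
  expect_error(average_phase_series(list()), "empty")
  # noisy cos profiles: mean within 3 standard errors everywhere
  set.seed(51)
  series <- lapply(1:100, function(i) {
    ph <- seq(-pi, pi, length.out = 193)
    resample_to_phase(cos(ph) + rnorm(193, sd = 0.1), ph)
  })
  m3 <- average_phase_series(series)
  expect_lt(max(abs(m3$values - cos(m3$grid)), na.rm = TRUE), 0.05)
})

test_that("peak extraction finds bumps, handles ties and scale invariance", {
  g <- so_phase_grid()
  mk <- function(v) structure(list(grid = g, values = v,
                                   n = rep(1L, length(g))),
                              class = "phase_series")
  # single bump at +pi/2: postpeak on the nose, prepeak at the left tail max
  s <- mk(cos(g - pi / 2)^2 + 1)
  pk <- extract_peaks(s)
  expect_lt(abs(pk$postpeak_phase - pi / 2), pi / 64 + 1e-9)
  # bimodal bumps at +/- pi/2
  s2 <- mk(exp(-(g - pi / 2)^2) + exp(-(g + pi / 2)^2))
  pk2 <- extract_peaks(s2)
  expect_lt(abs(pk2$postpeak_phase - pi / 2), pi / 64 + 1e-9)
  expect_lt(abs(pk2$prepeak_phase + pi / 2), pi / 64 + 1e-9)
  # constant series: ties go to the earliest grid point of each half-range
  s3 <- mk(rep(2, length(g)))
  pk3 <- extract_peaks(s3)
  expect_equal(pk3$prepeak_value, 2)
  expect_equal(pk3$prepeak_phase, g[2])
  expect_equal(pk3$postpeak_phase, g[66])
  # positive scaling does not move the peaks
  pk4 <- extract_peaks(mk(10 * (cos(g - pi / 2)^2 + 1)))
  expect_equal(pk4$postpeak_phase, pk$postpeak_phase)
  expect_equal(pk4$phase_values, 10 * pk$phase_values)
})
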