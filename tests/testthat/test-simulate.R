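test_that("the SO template honours amplitude and zero-crossing contracts", {
  w <- make_so_template(-100, 500, 256)
  expect_equal(min(w), -100)
  # negative half-wave spans 500 ms +/- one sample between zero crossings
  tri <- attr(w, "trough_index")
  neg <- which(w < 0)
  expect_lt(abs((max(neg) - min(neg) + 2) / 256 - 0.5), 2 / 256)
  expect_true(tri >= min(neg) && tri <= max(neg))
  # default template is (nearly) zero-mean and has p2p >= |amplitude|
  expect_lt(abs(mean(w)), 2)
  expect_gte(max(w) - min(w), 100)
  expect_error(make_so_template(-100, 0, 256), "duration")
})

test_that("criterion-violating templates are rejected by the detector", {
  # 200-ms half-wave: violates the 300-ms bound
  w <- make_so_template(-100, 200, 256)
  expect_equal(nrow(detect_sos(embed_waves(list(w), 10, 20), fs = 256)), 0)
  # -50 uV trough: violates the amplitude bound
  w <- make_so_template(-50, 500, 256)
  expect_equal(nrow(detect_sos(embed_waves(list(w), 10, 20), fs = 256)), 0)
  # a compliant one passes
  w <- make_so_template(-100, 500, 256)
  expect_equal(nrow(detect_sos(embed_waves(list(w), 10, 20), fs = 256)), 1)
})

test_that("simulation config validates its invariants", {
  expect_error(so_sim_config(so_halfwave_ms = 100), "halfwave")
  expect_error(so_sim_config(spindle_coupling_fraction = 1.5))
  expect_error(so_sim_config(base_coupling = diag(1.05, 22)), "unstable")
  # a boost that destabilises the coupling is caught at config time
  A <- diag(0.2, 22); A[2, 1] <- 0.2; A[1, 2] <- 0.2
  expect_error(so_sim_config(base_coupling = A, coupling_boost = 20),
               "boost")
})

test_that("simulate_subject is deterministic and respects its contracts", {
  cfg <- so_sim_config(duration_s = 300, so_rate = 1, seed = 5)
  sim1 <- simulate_subject(cfg)
  sim2 <- simulate_subject(cfg)
  expect_identical(sim1$recording$data, sim2$recording$data)
  expect_identical(sim1$truth$so_events, sim2$truth$so_events)
  # so_rate 0: pure VAR background, no events
  sim0 <- simulate_subject(so_sim_config(duration_s = 120, so_rate = 0, seed = 6))
  expect_null(sim0$truth$so_events)
  # troughs lie inside N2/SWS epochs and are separated by > 4 s
  tt <- sort(sim1$truth$so_events$trough_time)
  expect_true(all(diff(tt) > 4))
  ep <- floor(tt / 30) + 1
  expect_true(all(sim1$truth$stages[ep] %in% c("N2", "SWS")))
  # global SOs cover >= half the montage, local < one quarter
  fps <- strsplit(sim1$truth$so_events$footprint, ",")
  sizes <- lengths(fps)
  expect_true(all(sizes[sim1$truth$so_events$cluster == "Global"] >= 11))
  expect_true(all(sizes[sim1$truth$so_events$cluster == "Local"] < 5.5))
  # excessive SO rate errors
  expect_error(simulate_subject(so_sim_config(duration_s = 300, so_rate = 16,
                                              seed = 7)), "rate")
})

test_that("background far from troughs matches the Lyapunov covariance", {
  cfg <- so_sim_config(duration_s = 300, so_rate = 0, noise_sd = 1, seed = 8)
  sim <- simulate_subject(cfg)
  P <- var_stationary_cov(cfg$base_coupling, diag(cfg$noise_sd^2, 22))
  S <- tcrossprod(sim$recording$data) / ncol(sim$recording$data)
  expect_lt(max(abs(S - P)) / max(abs(P)), 0.1)
})

test_that("spindle bursts overlap the configured fraction of SOs", {
  cfg <- so_sim_config(duration_s = 600, so_rate = 1,
                       spindle_coupling_fraction = 0.5, seed = 9)
  sim <- simulate_subject(cfg)
  ev <- sim$truth$so_events
  sp <- sim$truth$spindle_events
  expect_equal(nrow(sp), round(0.5 * nrow(ev)), tolerance = 2)
  codes <- flag_coupling(ev, sp)
  expect_equal(sum(codes == 2L), nrow(sp))
})

test_that("behaviour generation plants the advertised linear dependence", {
  flow <- rnorm(40, 2, 0.5)
  # slope 0, no noise: all ratios exactly 1
  expect_equal(generate_behavior(flow, 0, 0), rep(1, 40))
  # deterministic given seed
  b1 <- generate_behavior(flow, 0.2, 0.05, seed = 3)
  expect_identical(b1, generate_behavior(flow, 0.2, 0.05, seed = 3))
  # planted slope is recovered by regression in almost every replicate
  set.seed(10)
  hits <- mean(replicate(100, {
    fl <- rnorm(40, 2, 0.5)
    b <- generate_behavior(fl, 0.2, 0.01, seed = sample.int(1e6, 1))
    f <- summary(lm(b ~ fl))
    f$coefficients[2, 1] > 0 && f$coefficients[2, 4] < 0.01
  }))
  expect_gte(hits, 0.95)
  expect_error(generate_behavior(c(1, 2), 0.1, 0.1), "3 subjects")
  expect_error(generate_behavior(rep(1, 5), 0.1, 0.1), "zero-variance")
})

test_that("recordings round-trip through the plain-text format", {
  cfg <- so_sim_config(duration_s = 60, so_rate = 0, seed = 11)
  sim <- simulate_subject(cfg)
  dir <- withr::local_tempdir()
  write_recording(sim$recording, file.path(dir, "s1"))
  rec2 <- read_recording(file.path(dir, "s1"))
  expect_equal(rec2$data, sim$recording$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(rec2$stages, sim$recording$stages)
  expect_identical(rec2$labels, sim$recording$labels)
  # missing analysis channel errors by name
  i_poz <- match("POz", sim$recording$labels)
  bad <- sim$recording$data[-i_poz, ]
  expect_error(recording(bad, 256, sim$recording$labels[-i_poz],
                         sim$recording$stages), "POz")
  # hypnogram shorter than the duration errors
  expect_error(recording(sim$recording$data, 256, sim$recording$labels,
                         sim$recording$stages[1]), "hypnogram")
})

test_that("stage masks follow 30-s epoch boundaries exactly", {
  rec <- recording(matrix(0, 22, 256 * 120), 256, default_channel_labels(),
                   c("N2", "REM", "N2", "REM"))
  m <- stage_mask(rec)
  expect_equal(sum(m), 2 * 7680)
  expect_true(all(m[1:7680]))
  expect_false(any(m[7681:15360]))
  expect_equal(stage_mask(rec, character(0)), rep(FALSE, 256 * 120))
  expect_error(stage_mask(rec, "NREM"), "unknown stage")
})
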