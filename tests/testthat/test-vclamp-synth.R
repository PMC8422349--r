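# Voltage-clamp protocol constructors and the sweep simulator.

test_that("I-V protocol enumerates test levels correctly", {
  p <- make_iv_protocol(-100, -90, 30, 10, 500)
  expect_length(p$sweeps, 13)  # (30 - (-90))/10 + 1
  expect_equal(p$meta$test_levels, seq(-90, 30, by = 10))
  single <- make_iv_protocol(-100, -50, -50, 10, 500)
  expect_length(single$sweeps, 1)
  expect_equal(single$sweeps[[1]]$segments[1, "level"], c(level = -50))
  long <- make_iv_protocol(pulse_ms = 5000)
  expect_equal(long$sweeps[[1]]$segments[1, "duration"], c(duration = 5000))
  expect_identical(long$name, "iv_long")
  expect_error(make_iv_protocol(-100, 0, -50, 10, 500))
})

test_that("SSI protocol has pre/post test pulses around the conditioning step", {
  p <- make_ssi_protocol(v_test = -30)
  expect_length(p$sweeps, 15)  # (-40 - (-110))/5 + 1
  seg <- p$sweeps[[1]]$segments
  expect_equal(seg[p$meta$pre_segment, "level"], c(level = -30))
  expect_equal(seg[p$meta$post_segment, "level"], c(level = -30))
  expect_equal(seg[3, "duration"], c(duration = 5000))
  expect_error(make_ssi_protocol(conditioning_ms = 500), "conditioning_ms")
})

test_that("deactivation protocol uses the published step durations", {
  wt <- make_deactivation_protocol(v_act = -30, act_ms = 15)
  expect_equal(wt$sweeps[[1]]$segments[1, "duration"], c(duration = 15))
  var <- make_deactivation_protocol(v_act = -30, act_ms = 50)
  expect_equal(var$sweeps[[1]]$segments[1, "duration"], c(duration = 50))
  # tail at the activation level: current is continuous across the "step"
  p <- test_params()
  same <- make_deactivation_protocol(v_act = -30, act_ms = 15, v_tails = -30)
  sw <- simulate_sweeps(p, same)
  st <- segment_times(same, 1, sw$meta$pre_ms)
  i_before <- approx(sw$time[[1]], sw$current[[1]], st$t_on[2] - 0.2)$y
  i_after <- approx(sw$time[[1]], sw$current[[1]], st$t_on[2] + 0.2)$y
  expect_equal(i_after, i_before, tolerance = 0.02)
})

test_that("AP waveform and train protocol are well formed", {
  w <- ap_waveform()
  expect_equal(w$v[1], w$baseline)
  expect_equal(w$v[length(w$v)], w$baseline)
  expect_lt(abs(max(w$v) - w$peak), 1)
  train <- make_ap_train_protocol(w, n = 99, rate_hz = 20)
  expect_equal(train$meta$period_ms, 50)
  expect_length(train$meta$ap_onsets_ms, 99)
  total <- 98 * 50 + w$duration_ms + 50
  expect_length(train$sweeps[[1]]$v, round(total / w$sample_interval) + 1)
  one <- make_ap_train_protocol(w, n = 1)
  expect_length(one$meta$ap_onsets_ms, 1)
  slow <- ap_waveform(decay_ms = 20)  # 121-ms waveform
  expect_error(make_ap_train_protocol(slow, rate_hz = 20), "fit")
})

test_that("simulated sweeps start at the holding equilibrium", {
  p <- test_params()
  sw <- simulate_sweeps(p, make_iv_protocol(pulse_ms = 100))
  hold <- -100
  i_analytic <- p$g_max * m_inf(hold, p)^p$p_act * h_inf(hold, p) * (hold - p$e_rev)
  for (s in c(1, 7, 13)) {
    expect_lt(abs(sw$current[[s]][1] - i_analytic),
              5e-3 * max(abs(i_analytic), 1e-9))
    expect_equal(sw$voltage[[s]][1], hold)
    expect_true(all(diff(sw$time[[s]]) > 0))
  }
})

test_that("holding at the reversal potential gives zero current", {
  p <- test_params(e_rev = 120)
  proto <- voltage_protocol("null", list(list(
    type = "segments", segments = cbind(level = 120, duration = 50))),
    holding = 120)
  sw <- simulate_sweeps(p, proto)
  expect_true(all(abs(sw$current[[1]]) < 1e-9))
})

test_that("halving dt changes samples by less than 0.1% of peak", {
  p <- test_params()
  proto <- make_iv_protocol(v_start = -30, v_end = -30, pulse_ms = 200)
  a <- simulate_sweeps(p, proto, dt = 0.05)
  b <- simulate_sweeps(p, proto, dt = 0.025)
  peak <- max(abs(a$current[[1]]))
  expect_lt(max(abs(a$current[[1]] - b$current[[1]])), 1e-3 * peak)
})

test_that("noise is reproducible, optional, and has the stated variance", {
  p <- test_params()
  sw <- simulate_sweeps(p, make_iv_protocol(pulse_ms = 800), dt = 0.1)
  expect_identical(add_noise(sw, 0), sw)
  n1 <- add_noise(sw, 5, seed = 42)
  n2 <- add_noise(sw, 5, seed = 42)
  expect_identical(n1$current, n2$current)
  expect_equal(n1$meta$noise_sd, 5)
  resid <- unlist(n1$current) - unlist(sw$current)
  expect_gte(length(resid), 1e5)
  expect_equal(var(resid), 25, tolerance = 0.05)
})

test_that("sweep sets round-trip through CSV + JSON sidecar", {
  p <- test_params()
  sw <- simulate_sweeps(p, make_iv_protocol(v_start = -50, v_end = -30,
                                            pulse_ms = 50), dt = 0.1)
  prefix <- file.path(tempdir(), "roundtrip")
  write_sweep_set(sw, prefix)
  back <- read_sweep_set(prefix)
  expect_equal(back$current, sw$current, tolerance = 1e-12)
  expect_equal(back$time, sw$time, tolerance = 1e-12)
  expect_equal(back$protocol$meta$test_levels, sw$protocol$meta$test_levels)
  expect_equal(back$meta$variant, "test")
  # tab-delimited input is accepted
  df <- read.csv(paste0(prefix, ".csv"))
  write.table(df, paste0(prefix, ".csv"), sep = "\t", row.names = FALSE)
  back2 <- read_sweep_set(prefix)
  expect_equal(back2$current, sw$current, tolerance = 1e-12)
  # malformed CSV errors with the column contract
  writeLines("a,b\n1,2", paste0(prefix, ".csv"))
  expect_error(read_sweep_set(prefix), "columns")
})

test_that("WT AP-clamp train facilitates then attenuates", {
  wt <- cav33_params("WT")
  ap <- simulate_sweeps(wt, make_ap_train_protocol(), dt = 0.05)
  onsets <- ap$protocol$meta$ap_onsets_ms + ap$meta$pre_ms
  peaks <- vapply(onsets, function(on) {
    sel <- ap$time[[1]] >= on & ap$time[[1]] <= on + 25
    min(ap$current[[1]][sel])
  }, numeric(1))
  imax <- which.min(peaks)   # most negative = largest inward
  expect_gt(imax, 1)         # facilitation over the first APs
  expect_lt(imax, 6)
  expect_true(all(diff(peaks[imax:length(peaks)]) >= 0))  # then attenuation
})
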