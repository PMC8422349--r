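# Conductance-based neuron: integration, spike detection, rheobase,
# train metrics, rebound behaviour, firing-mode taxonomy, spike-shape metrics.

no_t_config <- function(g_t = 0, ...) {
  cfg <- trn_base_config()
  cfg$g_t <- g_t
  extra <- list(...)
  cfg[names(extra)] <- extra
  cfg
}

flat_trace <- function(v, dur = 3000, dt = 0.5) {
  tt <- seq(0, dur, by = dt)
  structure(list(time = tt, v = rep_len(v, length(tt)),
                 i_inj = rep(0, length(tt)), dt = dt),
            class = "voltage_trace")
}

# Gaussian "spike" bumps on a baseline, for detector fixtures.
bump_trace <- function(centers, baseline = -70, peak = 10, width = 0.5,
                       dur = 3000, dt = 0.05) {
  tt <- seq(0, dur, by = dt)
  v <- rep(baseline, length(tt))
  for (c0 in centers) v <- pmax(v, baseline +
                                  (peak - baseline) * exp(-(tt - c0)^2 / (2 * width^2)))
  structure(list(time = tt, v = v, i_inj = rep(0, length(tt)), dt = dt),
            class = "voltage_trace")
}

test_that("the capacitor limit gives a linear voltage ramp", {
  cfg <- no_t_config(g_na = 0, g_k = 0, g_leak = 0)
  m <- build_model(cav33_params("WT"), cfg)
  tr <- integrate_model(m, stimulus_protocol(50, i_nA = 0.1), v0 = -70)
  # dv/dt = I / (c_m * area): 0.1 nA over 1 uF/cm2 * 1.43e-4 cm2
  slope_ref <- 0.1 * 1e-3 / (cfg$c_m * cfg$area)  # mV/ms
  slope_obs <- (tr$v[1601] - tr$v[801]) / (tr$time[1601] - tr$time[801])
  expect_equal(slope_obs, slope_ref, tolerance = 1e-6)
})

test_that("the model equilibrates to a stable rest and clamp release relaxes", {
  m <- build_model(cav33_params("WT"))
  tr <- integrate_model(m, stimulus_protocol(2500, i_nA = 0))
  n <- length(tr$v)
  dvdt <- abs(tr$v[n] - tr$v[n - 40]) / (tr$time[n] - tr$time[n - 40])
  expect_lt(dvdt, 0.01)                       # < 0.01 mV/ms after 2 s
  expect_lt(abs(tr$v[n] - tr$v[n - 4000]), 0.5)
  # clamp at -110 then release with zero input: relaxes up toward rest
  tr2 <- integrate_model(m, stimulus_protocol(c(100, 400), i_nA = 0,
                                              clamp_v = c(-110, NA)))
  expect_gt(tr2$v[length(tr2$v)], -80)
  expect_equal(tr2$v[2000], -110)  # clamped phase holds the level
})

test_that("all reversal potentials equal -> voltage converges to E", {
  cfg <- no_t_config(g_t = 1, e_na = -65, e_k = -65, e_leak = -65)
  p <- cav33_params("WT")
  p$e_rev <- -65
  m <- build_model(p, cfg)
  tr <- integrate_model(m, stimulus_protocol(1500, i_nA = 0), v0 = -100)
  expect_equal(tr$v[length(tr$v)], -65, tolerance = 1e-4)
})

test_that("spike detection finds constructed events and respects thresholds", {
  expect_length(detect_spikes(flat_trace(-70)), 0)
  tr <- bump_trace(c(500, 520))
  sp <- detect_spikes(tr)
  expect_length(sp, 2)
  expect_equal(sp, c(500, 520), tolerance = 1e-6)
  expect_length(detect_spikes(tr, threshold = 20), 0)  # above trace max
  # refractory merges crossings closer than 2 ms
  tr2 <- bump_trace(c(500, 501))
  expect_length(detect_spikes(tr2, refractory = 2), 1)
})

test_that("train metrics compute ISI statistics from spike times", {
  tr <- flat_trace(-70, dur = 3000)
  one <- train_metrics(tr, spike_times = 100)
  expect_equal(one$train_duration, 0)
  expect_true(is.na(one$f0))
  m <- train_metrics(tr, spike_times = seq(0, 48, by = 4))
  expect_equal(m$f0, 250)  # 4-ms first ISI
  expect_equal(m$train_duration, 48)
  expect_equal(m$f_ss, 250)  # constant train
  # f_ss uses only ISIs whose second spike lies in the final 500 ms of
  # spiking: here the 580-ms gap ending at 600 and the two 100-ms ISIs
  sp <- c(0, 10, 20, 600, 700, 800)
  m2 <- train_metrics(tr, spike_times = sp)
  expect_equal(m2$f_ss, mean(1000 / c(580, 100, 100)))
  expect_equal(m2$f0, 100)
})

test_that("rheobase search is an ascending grid with a sentinel", {
  leaky <- build_model(cav33_params("WT"), no_t_config(g_t = 0.97, g_leak = 5))
  expect_warning(r <- find_rheobase(leaky, i_min = 0.01, i_max = 0.05),
                 "not excitable")
  expect_true(is.na(r))
  m <- build_model(cav33_params("WT"))
  r <- find_rheobase(m, i_min = 0.25, i_max = 0.35)
  expect_equal(r, 0.29, tolerance = 1e-9)
})

test_that("halving dt preserves the spike train (count, onset, bounded drift)", {
  m <- build_model(cav33_params("WT"))
  ih <- holding_current(m, -110)
  stim <- stimulus_protocol(c(50, 200, 50), i_nA = ih + c(0, 0.35, 0),
                            clamp_v = c(-110, NA, NA))
  a <- detect_spikes(integrate_model(m, stim, dt = 0.0125))
  b <- detect_spikes(integrate_model(m, stim, dt = 0.00625))
  expect_length(b, length(a))
  # burst onset is converged to < 0.1 ms; across a 300-Hz train the phase
  # error accumulates, so later spikes are only bounded to < 1 ms
  expect_lt(max(abs(a[1:3] - b[1:3])), 0.1)
  expect_lt(max(abs(a - b)), 1)
})

test_that("the T current is the rebound mechanism", {
  no_t <- build_model(cav33_params("WT"), no_t_config(g_t = 0))
  rb0 <- rebound_run(no_t, total_ms = 3000)
  expect_length(rb0$metrics$spike_times, 0)
  expect_false(rb0$continuous)
  wt <- build_model(cav33_params("WT"))
  rb <- rebound_run(wt, total_ms = 5000)
  expect_gt(rb$metrics$n_spikes, 5)        # a burst fires...
  expect_lt(max(rb$metrics$spike_times), 3000)  # ...but ends (transient)
  expect_false(rb$continuous)
  # gain-of-function variant sustains continuous activity
  i860n <- build_model(cav33_params("I860N"))
  expect_true(rebound_run(i860n, total_ms = 5000)$continuous)
})

test_that("swapping gating parameters leaves the base cell untouched", {
  a <- build_model(cav33_params("WT"))
  b <- build_model(cav33_params("I860N"))
  for (f in c("c_m", "area", "g_na", "g_k", "g_leak", "e_na", "e_k",
              "e_leak", "v_shift", "g_t")) {
    expect_identical(a[[f]], b[[f]])
  }
  expect_false(identical(a$t_params, b$t_params))
})

test_that("integration is deterministic", {
  m <- build_model(cav33_params("I1306T"))
  s <- stimulus_protocol(c(100, 200, 100), i_nA = c(0, 0.3, 0),
                         clamp_v = c(-110, NA, NA))
  t1 <- integrate_model(m, s)
  t2 <- integrate_model(m, s)
  expect_identical(t1$v, t2$v)
})

test_that("firing modes follow the LTF / SO taxonomy", {
  expect_identical(classify_firing_mode(flat_trace(-75)), "silent")
  # subthreshold 10-mV oscillation around -50 mV for > 1 s: SO
  tt <- seq(0, 2500, by = 0.5)
  so <- structure(list(time = tt, v = -50 + 5 * sin(2 * pi * tt / 400),
                       i_inj = rep(0, length(tt)), dt = 0.5),
                  class = "voltage_trace")
  expect_identical(classify_firing_mode(so), "SO")
  # 1 s of spiking riding the up-state, then 2 s of pure oscillation: LTF+SO
  tt2 <- seq(0, 3000, by = 0.5)
  v2 <- -50 + 5 * sin(2 * pi * tt2 / 400)
  for (c0 in seq(50, 950, by = 100)) {
    v2 <- pmax(v2, -70 + 80 * exp(-(tt2 - c0)^2 / 0.5))
  }
  mix <- structure(list(time = tt2, v = v2, i_inj = rep(0, length(tt2)),
                        dt = 0.5), class = "voltage_trace")
  expect_identical(classify_firing_mode(mix), "LTF+SO")
  # spiking with no depolarized quiet epoch: LTF
  v3 <- rep(-70, length(tt2))
  for (c0 in seq(50, 2950, by = 100)) {
    v3 <- pmax(v3, -70 + 80 * exp(-(tt2 - c0)^2 / 0.5))
  }
  ltf <- structure(list(time = tt2, v = v3, i_inj = rep(0, length(tt2)),
                        dt = 0.5), class = "voltage_trace")
  expect_identical(classify_firing_mode(ltf), "LTF")
})

test_that("plateau area matches rectangle and triangle geometry", {
  tt <- seq(0, 400, by = 0.1)
  # square excursion: 10 mV above threshold for 100 ms -> 1000 mV*ms
  vsq <- ifelse(tt >= 100 & tt <= 200, -40, -70)
  sq <- structure(list(time = tt, v = vsq, i_inj = 0 * tt, dt = 0.1),
                  class = "voltage_trace")
  a <- plateau_area(sq, -50)
  expect_length(a$events, 1)
  expect_equal(a$total, 1000, tolerance = 0.01)
  # triangle: base 100 ms, height 20 mV -> 1000 mV*ms
  vtr <- -70 + pmax(0, 20 * (1 - abs(tt - 150) / 50))
  tr <- structure(list(time = tt, v = vtr, i_inj = 0 * tt, dt = 0.1),
                  class = "voltage_trace")
  expect_equal(plateau_area(tr, -70 + 1e-9)$total, 1000, tolerance = 0.01)
  # never above threshold: empty
  none <- plateau_area(sq, 0)
  expect_length(none$events, 0)
  expect_equal(none$total, 0)
})

test_that("90-10% decay slope is the chord of the falling phase", {
  tt <- seq(0, 60, by = 0.01)
  # linear fall of 100% amplitude over 10 ms: 80% falls over 8 ms
  amp <- 40
  v <- ifelse(tt < 20, -70, ifelse(tt < 21, -70 + amp * (tt - 20),
                                   pmax(-70, -70 + amp * (1 - (tt - 21) / 10))))
  tr <- structure(list(time = tt, v = v, i_inj = 0 * tt, dt = 0.01),
                  class = "voltage_trace")
  d <- decay_slope_90_10(tr, c(0, 60))
  expect_false(d$flagged)
  expect_equal(d$slope, -0.8 * amp / 8, tolerance = 0.01)
  # exponential decay: the chord slope, not the tangent
  tau <- 5
  v2 <- ifelse(tt < 10, -70, -70 + amp * exp(-(tt - 10) / tau))
  tr2 <- structure(list(time = tt, v = v2, i_inj = 0 * tt, dt = 0.01),
                   class = "voltage_trace")
  d2 <- decay_slope_90_10(tr2, c(5, 60))
  chord <- -0.8 * amp / (tau * (log(1 / 0.1) - log(1 / 0.9)))
  expect_equal(d2$slope, chord, tolerance = 0.02)
  # flat event is flagged
  d3 <- decay_slope_90_10(flat_trace(-70, dur = 100), c(0, 100))
  expect_true(d3$flagged)
})
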