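#' Voltage-clamp protocol container
#'
#' A protocol is a family of sweeps executed from a common holding
#' potential.  Each sweep is either a list of constant-voltage segments
#' (`(level mV, duration ms)` rows) or a pre-sampled command waveform (used
#' for action-potential clamp).  Constructors for the standard protocols are
#' [make_iv_protocol()], [make_ssi_protocol()],
#' [make_deactivation_protocol()] and [make_ap_train_protocol()].
#'
#' @param name protocol label (used by the analysis dispatcher).
#' @param sweeps list of sweeps; each is `list(type = "segments", segments =
#'   <matrix level,duration>)` or `list(type = "sampled", v = <mV samples>,
#'   sample_interval = <ms>)`.
#' @param holding holding potential (mV) applied before each sweep.
#' @param sample_interval recording sample interval, ms (default 0.1 = 10 kHz).
#' @param inter_sweep_interval rest at holding between sweeps, ms (sweeps are
#'   simulated from equilibrium, so this is metadata).
#' @param meta free-form list of protocol metadata (test levels etc.).
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(name, sweeps, holding = -100,
                             sample_interval = 0.1,
                             inter_sweep_interval = 5000, meta = list()) {
  stopifnot(is.character(name), length(sweeps) >= 1L,
            sample_interval > 0, is.finite(holding))
  for (sw in sweeps) {
    if (identical(sw$type, "segments")) {
      seg <- sw$segments
      if (!is.matrix(seg) || nrow(seg) < 1L || any(seg[, 2] <= 0)) {
        stop("each sweep needs >= 1 segment with positive durations", call. = FALSE)
      }
    } else if (identical(sw$type, "sampled")) {
      if (length(sw$v) < 2L) stop("sampled sweep too short", call. = FALSE)
    } else stop("unknown sweep type", call. = FALSE)
  }
  structure(list(name = name, sweeps = sweeps, holding = holding,
                 sample_interval = sample_interval,
                 inter_sweep_interval = inter_sweep_interval, meta = meta),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s: %d sweeps, holding %+.0f mV, %g kHz\n",
              x$name, length(x$sweeps), x$holding, 1 / x$sample_interval))
  invisible(x)
}

seg_sweep <- function(levels, durations) {
  list(type = "segments",
       segments = cbind(level = levels, duration = durations))
}

#' Current-voltage (I-V) step protocol
#'
#' One depolarizing test step per sweep, from `v_start` to `v_end`
#' inclusive.  The defaults (holding -100 mV, -90..+30 mV in 10-mV
#' increments, 500-ms pulses) give the 13-sweep family used for peak I-V and
#' fractional-activation analysis; `pulse_ms = 5000` gives the long-pulse
#' variant used to fit inactivation time constants.
#'
#' @param v_hold holding potential, mV.
#' @param v_start,v_end,step test-level range and increment, mV (`step` > 0,
#'   `v_end >= v_start`).
#' @param pulse_ms test-pulse duration, ms.
#' @param tail_ms post-pulse return to holding, ms.
#' @return A [voltage_protocol()].
#' @export
make_iv_protocol <- function(v_hold = -100, v_start = -90, v_end = 30,
                             step = 10, pulse_ms = 500, tail_ms = 50) {
  stopifnot(step > 0, v_end >= v_start, pulse_ms > 0)
  levels <- seq(v_start, v_end, by = step)
  if (length(levels) == 0L) stop("protocol has zero sweeps", call. = FALSE)
  sweeps <- lapply(levels, function(v) {
    seg_sweep(c(v, v_hold), c(pulse_ms, tail_ms))
  })
  voltage_protocol(name = if (pulse_ms >= 2000) "iv_long" else "iv",
                   sweeps = sweeps, holding = v_hold,
                   meta = list(test_levels = levels, pulse_ms = pulse_ms,
                               pulse_segment = 1L))
}

#' Steady-state inactivation (SSI) protocol
#'
#' Each sweep measures a reference test pulse from rest, recovers at
#' holding, applies a long conditioning step, and measures the test pulse
#' again; the post/pre peak ratio is the fractional availability at the
#' conditioning voltage.  Defaults: 5-s conditioning at -110..-40 mV in 5-mV
#' increments (15 sweeps).
#'
#' @param conditioning_ms conditioning duration, ms (>= 1000: the
#'   availability read-out assumes near-steady-state conditioning).
#' @param v_cond_start,v_cond_end,step conditioning range and increment, mV.
#' @param v_test test-pulse level, mV; use the variant's voltage of maximal
#'   activation.
#' @param test_ms test-pulse duration, ms.
#' @param v_hold holding potential, mV.
#' @param recover_ms rest at holding between the reference pulse and the
#'   conditioning step, ms.
#' @return A [voltage_protocol()].
#' @export
make_ssi_protocol <- function(conditioning_ms = 5000, v_cond_start = -110,
                              v_cond_end = -40, step = 5, v_test = -30,
                              test_ms = 100, v_hold = -100,
                              recover_ms = 3000) {
  stopifnot(conditioning_ms >= 1000, step > 0, v_cond_end >= v_cond_start)
  levels <- seq(v_cond_start, v_cond_end, by = step)
  sweeps <- lapply(levels, function(vc) {
    seg_sweep(c(v_test, v_hold, vc, v_test, v_hold),
              c(test_ms, recover_ms, conditioning_ms, test_ms, 20))
  })
  voltage_protocol(name = "ssi", sweeps = sweeps, holding = v_hold,
                   meta = list(cond_levels = levels, v_test = v_test,
                               test_ms = test_ms,
                               pre_segment = 1L, post_segment = 4L))
}

#' Tail-current (deactivation) protocol
#'
#' A brief activating step to the voltage of maximal activation -- long
#' enough to open the channels maximally without detectable inactivation
#' (15 ms for the wild-type channel, 50 ms for the slow-activating variants)
#' -- followed by repolarization to each tail level, where the decaying tail
#' current reports deactivation kinetics.
#'
#' @param v_hold holding potential, mV.
#' @param v_act activation-step level, mV.
#' @param act_ms activation-step duration, ms (1..100).
#' @param v_tails tail repolarization level(s), mV (one sweep each).
#' @param tail_ms tail duration, ms.
#' @return A [voltage_protocol()].
#' @export
make_deactivation_protocol <- function(v_hold = -100, v_act = -30,
                                       act_ms = 15, v_tails = -100,
                                       tail_ms = 50) {
  stopifnot(act_ms >= 1, act_ms <= 100, length(v_tails) >= 1)
  sweeps <- lapply(v_tails, function(vt) {
    seg_sweep(c(v_act, vt), c(act_ms, tail_ms))
  })
  voltage_protocol(name = "deactivation", sweeps = sweeps, holding = v_hold,
                   meta = list(v_act = v_act, act_ms = act_ms,
                               v_tails = v_tails, tail_segment = 2L))
}

#' Action-potential-like command waveform
#'
#' Piecewise-exponential depolarization modelled on a thalamic-neuron action
#' potential: an exponential rise from baseline reaching the peak at
#' `rise_ms`, then an exponential decay with time constant `decay_ms`,
#' truncated (and pinned to baseline) after six decay time constants.
#'
#' @param baseline,peak baseline and peak command levels, mV (`peak >
#'   baseline`).
#' @param rise_ms rise duration, ms.
#' @param decay_ms decay time constant, ms.
#' @param sample_interval sample interval, ms.
#' @return An object of class `ap_waveform` with the sampled command (starts
#'   and ends at `baseline`).
#' @export
ap_waveform <- function(baseline = -70, peak = 20, rise_ms = 1, decay_ms = 4,
                        sample_interval = 0.1) {
  stopifnot(peak > baseline, rise_ms > 0, decay_ms > 0, sample_interval > 0)
  dur <- rise_ms + 6 * decay_ms
  t <- seq(0, dur, by = sample_interval)
  tau_r <- rise_ms / log(100)  # reaches within 1% of peak at rise_ms
  v <- ifelse(t < rise_ms,
              peak + (baseline - peak) * exp(-t / tau_r),
              baseline + (peak - baseline) * exp(-(t - rise_ms) / decay_ms))
  v[length(v)] <- baseline
  structure(list(baseline = baseline, peak = peak, rise_ms = rise_ms,
                 decay_ms = decay_ms, sample_interval = sample_interval,
                 duration_ms = dur, v = v),
            class = "ap_waveform")
}

#' Action-potential clamp train protocol
#'
#' Repeats an AP-like command waveform `n` times at `rate_hz` in one
#' continuous sweep at baseline, with one inter-AP period of trailing
#' baseline.  Defaults reproduce the 99-depolarization, 20-Hz train.
#'
#' @param waveform an [ap_waveform()].
#' @param n number of APs (>= 1).
#' @param rate_hz repetition rate; the waveform must fit within the period.
#' @return A [voltage_protocol()] with a single sampled sweep; AP onset
#'   times are in `meta$ap_onsets_ms`.
#' @export
make_ap_train_protocol <- function(waveform = ap_waveform(), n = 99,
                                   rate_hz = 20) {
  stopifnot(inherits(waveform, "ap_waveform"), n >= 1, rate_hz > 0)
  period <- 1000 / rate_hz
  if (waveform$duration_ms > period) {
    stop("AP waveform (", waveform$duration_ms,
         " ms) does not fit in the ", period, " ms period", call. = FALSE)
  }
  si <- waveform$sample_interval
  total <- (n - 1) * period + waveform$duration_ms + period
  nt <- round(total / si) + 1L
  v <- rep(waveform$baseline, nt)
  onsets <- (seq_len(n) - 1) * period
  for (on in onsets) {
    i0 <- round(on / si)
    idx <- i0 + seq_along(waveform$v)
    v[idx] <- waveform$v
  }
  voltage_protocol(
    name = "ap_train",
    sweeps = list(list(type = "sampled", v = v, sample_interval = si)),
    holding = waveform$baseline, sample_interval = si,
    meta = list(n_ap = n, rate_hz = rate_hz, period_ms = period,
                ap_onsets_ms = onsets, ap_duration_ms = waveform$duration_ms))
}

# Duration of one sweep (ms), excluding the pre-holding added at simulation.
sweep_duration <- function(sweep, sample_interval) {
  if (identical(sweep$type, "segments")) sum(sweep$segments[, 2])
  else (length(sweep$v) - 1L) * sweep$sample_interval
}

#' Segment onset/offset times of a recorded sweep
#'
#' Onset and offset times (ms) of each constant-voltage segment of sweep
#' `i`, in recorded time: 0 is the start of the pre-holding equilibration
#' window of length `pre_ms` that [simulate_sweeps()] prepends (stored in
#' the sweep set's `meta$pre_ms`).  Used to build analysis windows (pulse,
#' tail, conditioning).
#'
#' @param protocol a [voltage_protocol()] with segment-type sweeps.
#' @param i sweep index.
#' @param pre_ms recorded holding window before the first segment, ms.
#' @return Data frame with columns `level`, `t_on`, `t_off`.
#' @export
segment_times <- function(protocol, i, pre_ms) {
  sw <- protocol$sweeps[[i]]
  if (!identical(sw$type, "segments")) {
    stop("sweep ", i, " is a sampled command; segment times are undefined",
         call. = FALSE)
  }
  dur <- sw$segments[, 2]
  t_off <- pre_ms + cumsum(dur)
  data.frame(level = sw$segments[, 1], t_on = t_off - dur, t_off = t_off)
}
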