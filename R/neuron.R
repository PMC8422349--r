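#' Default (calibrated) base configuration of the TRN-style neuron
#'
#' Membrane and spike-machinery parameters of the single-compartment
#' conductance-based model: transient Na+ and delayed-rectifier K+ kinetics
#' of the Traub lineage with an adjustable threshold shift, a leak, and a
#' T-type conductance supplied by [gating_params()] in density mode.  The
#' shipped values were calibrated once (see `scripts/calibrate_base_model.R`
#' in the source repository) so that the wild-type channel gives a rheobase
#' of 0.29 nA from -110 mV and a rebound-burst initial frequency near
#' 255 Hz, then frozen; variant simulations swap only the T-channel gating
#' parameters.
#'
#' @param file optional path to a JSON config; defaults to the packaged one.
#' @return Named list of membrane parameters.
#' @export
trn_base_config <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "trn_base_model.json", package = "gatesim")
  }
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  cfg
}

#' Assemble a single-compartment TRN-style neuron model
#'
#' @param t_params [gating_params()] of the embedded T-type channel; its
#'   `g_max` is ignored in favour of the configured conductance density
#'   `g_t` (mS/cm^2) so that variants differ only in gating, not in channel
#'   expression -- except for variants whose `g_max` encodes an expression
#'   difference, which is applied as a relative factor when
#'   `scale_gt_by_gmax = TRUE`.
#' @param config base-model configuration, see [trn_base_config()].
#' @param scale_gt_by_gmax multiply the configured T-conductance density by
#'   `t_params$g_max / config$g_max_ref` (default FALSE: pure gating swap).
#' @return An object of class `trn_model`.
#' @export
build_model <- function(t_params, config = trn_base_config(),
                        scale_gt_by_gmax = FALSE) {
  stopifnot(inherits(t_params, "gating_params"))
  need <- c("c_m", "area", "g_na", "g_k", "g_leak", "e_na", "e_k", "e_leak",
            "v_shift", "g_t")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (config$c_m <= 0 || config$area <= 0 ||
      any(unlist(config[c("g_na", "g_k", "g_leak", "g_t")]) < 0)) {
    stop("conductances must be >= 0 and c_m, area > 0", call. = FALSE)
  }
  g_t <- config$g_t
  if (scale_gt_by_gmax) {
    ref <- if (!is.null(config$g_max_ref)) config$g_max_ref else t_params$g_max
    g_t <- g_t * t_params$g_max / ref
  }
  structure(c(config[need], list(g_t = g_t, t_params = t_params)),
            class = "trn_model")
}

#' @export
print.trn_model <- function(x, ...) {
  cat(sprintf("<trn_model> T-channel %s: gNa %g, gK %g, gL %g, gT %g mS/cm^2, area %.3g cm^2\n",
              x$t_params$name, x$g_na, x$g_k, x$g_leak, x$g_t, x$area))
  invisible(x)
}

#' Current-clamp stimulus protocol
#'
#' Ordered segments of injected current and/or voltage clamp.  A segment
#' with a finite `clamp_v` forces the membrane to that voltage (used for the
#' pre-step conditioning of the firing protocols); otherwise `i_nA` is
#' injected.
#'
#' @param duration_ms segment durations, ms (> 0).
#' @param i_nA injected current per segment, nA.
#' @param clamp_v per-segment clamp voltage, mV, or `NA` for free membrane.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(duration_ms, i_nA = 0, clamp_v = NA) {
  n <- length(duration_ms)
  stopifnot(n >= 1, all(duration_ms > 0))
  i_nA <- rep_len(i_nA, n)
  clamp_v <- rep_len(clamp_v, n)
  structure(data.frame(duration_ms = duration_ms, i_nA = i_nA,
                       clamp_v = clamp_v),
            class = c("stimulus_protocol", "data.frame"))
}

#' Integrate the neuron model under a stimulus
#'
#' Fixed-step integration: exponential (exact at fixed voltage) updates for
#' all gates and a linearized implicit update for the membrane voltage,
#' unconditionally stable at the default 0.025-ms step.  Gates start at
#' steady state for the initial voltage (the first segment's clamp level if
#' clamped, otherwise `v0`).  Deterministic.
#'
#' @param model a [build_model()] result.
#' @param stimulus a [stimulus_protocol()].
#' @param dt time step, ms (default 0.0125; see the vignette's numerics
#'   notes).
#' @param v0 initial voltage when the first segment is unclamped, mV.
#' @param record_every record every n-th step (default 1).
#' @return An object of class `voltage_trace` with `time` (ms), `v` (mV),
#'   `i_inj` (nA) and `dt`.
#' @export
integrate_model <- function(model, stimulus, dt = 0.0125, v0 = NULL,
                            record_every = 1L) {
  stopifnot(inherits(model, "trn_model"),
            inherits(stimulus, "stimulus_protocol"), dt > 0)
  n_per <- pmax(1L, round(stimulus$duration_ms / dt))
  i_inj <- rep(stimulus$i_nA, times = n_per)
  clamped <- rep(!is.na(stimulus$clamp_v), times = n_per)
  vclamp <- rep(ifelse(is.na(stimulus$clamp_v), 0, stimulus$clamp_v),
                times = n_per)
  if (is.null(v0)) {
    v0 <- if (clamped[1]) vclamp[1] else model$e_leak
  }
  # The neuron model consumes only the activation and inactivation tau
  # tables (with constant extrapolation): the published model-parameter list
  # for the simulated neuron does not include tail-deactivation kinetics, so
  # the tau_deact_table is used by the voltage-clamp simulator only.
  tp <- model$t_params
  mt <- tp$tau_act_table
  ht <- tp$tau_inact_table
  out <- cpp_neuron_run(dt, length(i_inj), i_inj, clamped, vclamp,
                        model$c_m, model$area, model$g_na, model$g_k,
                        model$g_leak, model$e_na, model$e_k, model$e_leak,
                        model$v_shift, model$g_t, tp$e_rev,
                        tp$v_half_act, tp$k_act, tp$v_half_inact, tp$k_inact,
                        tp$p_act, mt[, 1], mt[, 2], ht[, 1], ht[, 2],
                        v0, as.integer(record_every))
  if (isTRUE(out$blew_up)) {
    stop("numerical blow-up (|v| > 200 mV): reduce dt (used ", dt, " ms)",
         call. = FALSE)
  }
  structure(list(time = out$time, v = out$v, i_inj = out$i_inj,
                 dt = dt * record_every),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %.0f ms at dt %.3g ms; v in [%.1f, %.1f] mV\n",
              max(x$time), x$dt, min(x$v), max(x$v)))
  invisible(x)
}

#' Detect action potentials in a voltage trace
#'
#' Upward threshold crossings separated by at least the refractory period;
#' each spike is timed at the local voltage maximum following its crossing.
#'
#' @param trace a `voltage_trace` (or list with `time` and `v`).
#' @param threshold detection threshold, mV (default -20).
#' @param refractory minimum separation between crossings, ms (default 2).
#' @return Numeric vector of spike times, ms (possibly empty).
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 2) {
  v <- trace$v; tt <- trace$time
  n <- length(v)
  if (n < 3L) return(numeric(0))
  cross <- which(v[-1] >= threshold & v[-n] < threshold)
  times <- numeric(0)
  last <- -Inf
  for (c0 in cross) {
    if (tt[c0] - last < refractory) next
    last <- tt[c0]
    j <- c0 + 1L
    while (j < n && v[j + 1L] >= v[j]) j <- j + 1L
    times <- c(times, tt[j])
  }
  times
}

#' Holding current that sets the resting potential
#'
#' The standing injection (nA) that balances all ionic currents at voltage
#' `v`, i.e. makes `v` a resting point of the model.  Used by the firing
#' protocols that "set" the resting membrane potential to a level (e.g.
#' -110 mV) away from the model's natural rest, the way a current-clamp
#' experimenter applies a holding current.
#'
#' @param model a `trn_model`.
#' @param v target resting voltage, mV.
#' @return Holding current, nA.
#' @export
holding_current <- function(model, v) {
  stopifnot(inherits(model, "trn_model"))
  tp <- model$t_params
  u <- v - model$v_shift
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 + x / (2 * y)),
                                 x / (1 - exp(-x / y)))
  am <- 0.32 * vtrap(u - 13, 4); bm <- 0.28 * vtrap(40 - u, 5)
  ah <- 0.128 * exp((17 - u) / 18); bh <- 4 / (1 + exp((40 - u) / 5))
  an <- 0.032 * vtrap(u - 15, 5); bn <- 0.5 * exp((10 - u) / 40)
  i_dens <- model$g_leak * (v - model$e_leak) +
    model$g_na * (am / (am + bm))^3 * (ah / (ah + bh)) * (v - model$e_na) +
    model$g_k * (an / (an + bn))^4 * (v - model$e_k) +
    model$g_t * m_inf(v, tp)^tp$p_act * h_inf(v, tp) * (v - tp$e_rev)
  i_dens * model$area * 1000  # uA/cm^2 * cm^2 -> uA -> nA
}

#' Rheobase by ascending grid search
#'
#' The smallest current injection of a fixed-duration pulse that elicits at
#' least one spike, searched on an ascending grid.  The resting membrane
#' potential is set to `v_init` for the whole run: the membrane is clamped
#' there before the pulse (gates equilibrated), and a standing
#' [holding_current()] keeps `v_init` the resting point after release, so
#' the test pulse rides on top of the hold.
#'
#' @param model a `trn_model`.
#' @param pulse_ms pulse duration, ms (default 200).
#' @param v_init pre-pulse clamp level, mV (default -110).
#' @param i_min,i_max,step search grid, nA (default 0.01-nA resolution).
#' @param clamp_ms pre-pulse clamp duration, ms.
#' @param tail_ms recording after the pulse, ms.
#' @param dt integration step, ms.
#' @return Rheobase in nA, or `NA` (with a warning) when no grid current
#'   elicits a spike ("not excitable in range").
#' @export
find_rheobase <- function(model, pulse_ms = 200, v_init = -110,
                          i_min = 0.01, i_max = 0.45, step = 0.01,
                          clamp_ms = 100, tail_ms = 50, dt = 0.0125) {
  stopifnot(i_min < i_max, step > 0)
  i_hold <- holding_current(model, v_init)
  for (i in seq(i_min, i_max, by = step)) {
    tr <- integrate_model(model,
                          stimulus_protocol(c(clamp_ms, pulse_ms, tail_ms),
                                            i_nA = i_hold + c(0, i, 0),
                                            clamp_v = c(v_init, NA, NA)),
                          dt = dt)
    sp <- detect_spikes(tr)
    if (any(sp > clamp_ms & sp <= clamp_ms + pulse_ms)) return(i)
  }
  warning("not excitable in range [", i_min, ", ", i_max, "] nA")
  NA_real_
}

#' Spike-train metrics
#'
#' Train duration (first-to-last spike peak), initial frequency f0 (inverse
#' of the first interspike interval), steady-state frequency f_ss (mean
#' inverse ISI over ISIs whose second spike falls in the final 500 ms of
#' spiking), and the firing-mode label of the trace.
#'
#' @param trace a `voltage_trace`.
#' @param spike_times optional precomputed spike times; detected with
#'   default settings otherwise.
#' @param window optional `c(t0, t1)` restricting spikes to a time window
#'   (e.g. the stimulus pulse).
#' @return An object of class `spike_train_metrics` with `spike_times`,
#'   `n_spikes`, `train_duration`, `f0`, `f_ss` and `firing_mode` (frequency
#'   fields are `NA` with fewer than 2 spikes).
#' @export
train_metrics <- function(trace, spike_times = NULL, window = NULL) {
  if (is.null(spike_times)) spike_times <- detect_spikes(trace)
  if (!is.null(window)) {
    spike_times <- spike_times[spike_times >= window[1] & spike_times <= window[2]]
  }
  n <- length(spike_times)
  if (n < 2L) {
    return(structure(list(spike_times = spike_times, n_spikes = n,
                          train_duration = 0, f0 = NA_real_, f_ss = NA_real_,
                          firing_mode = if (n == 0) "silent" else "LTF"),
                     class = "spike_train_metrics"))
  }
  isi <- diff(spike_times)
  last <- spike_times[n]
  late <- isi[spike_times[-1] > last - 500]
  structure(list(spike_times = spike_times, n_spikes = n,
                 train_duration = last - spike_times[1],
                 f0 = 1000 / isi[1],
                 f_ss = mean(1000 / late),
                 firing_mode = classify_firing_mode(trace)),
            class = "spike_train_metrics")
}

#' @export
print.spike_train_metrics <- function(x, ...) {
  cat(sprintf("<spike_train_metrics> %d spikes, duration %.1f ms, f0 %.1f Hz, f_ss %.1f Hz, mode %s\n",
              x$n_spikes, x$train_duration, x$f0, x$f_ss, x$firing_mode))
  invisible(x)
}

#' Rebound / free-run protocol
#'
#' Clamps the membrane at the up-state level, applies a brief
#' hyperpolarizing clamp step, then lets the model run unclamped for the
#' remainder of the protocol.  A wild-type-like T-current produces a
#' transient rebound burst; left-shifted gain-of-function variants can
#' sustain continuous activity for the whole run.
#'
#' @param model a `trn_model`.
#' @param v_up up-state clamp level, mV (default -60).
#' @param v_hyp hyperpolarizing step level, mV (default -110).
#' @param hyp_ms hyperpolarizing step duration, ms (default 100).
#' @param up_ms up-state clamp duration, ms.
#' @param total_ms total protocol duration, ms (default 10 s).
#' @param dt integration step, ms.
#' @return List with the `trace`, `metrics` (on the unclamped phase),
#'   `release_ms` (time of release) and `continuous` (TRUE when electrical
#'   activity persists into the final second of the run: late spikes, or a
#'   maintained depolarized up-state / subthreshold oscillation with mean
#'   voltage above -60 mV, as opposed to a return to rest).
#' @export
rebound_run <- function(model, v_up = -60, v_hyp = -110, hyp_ms = 100,
                        up_ms = 500, total_ms = 10000, dt = 0.0125) {
  stopifnot(total_ms >= up_ms + hyp_ms)
  free_ms <- total_ms - up_ms - hyp_ms
  tr <- integrate_model(model,
                        stimulus_protocol(c(up_ms, hyp_ms, free_ms),
                                          i_nA = 0,
                                          clamp_v = c(v_up, v_hyp, NA)),
                        dt = dt)
  release <- up_ms + hyp_ms
  free <- keep_window(tr, c(release, total_ms))
  met <- train_metrics(free)
  sp <- met$spike_times
  final <- keep_window(tr, c(total_ms - 1000, total_ms))
  continuous <- (length(sp) > 0 && max(sp) > total_ms - 1000) ||
    mean(final$v) > -60
  list(trace = tr, metrics = met, release_ms = release,
       continuous = continuous)
}

# Restrict a voltage_trace to a time window.
keep_window <- function(trace, window) {
  sel <- trace$time >= window[1] & trace$time <= window[2]
  structure(list(time = trace$time[sel], v = trace$v[sel],
                 i_inj = trace$i_inj[sel], dt = trace$dt),
            class = "voltage_trace")
}

#' Classify the firing mode of a trace
#'
#' `LTF` (low-threshold tonic/burst firing) when spikes are present and no
#' slow-oscillation epoch exists; `SO` when at least `min_dur` ms of
#' contiguous spike-free trace sits depolarized (mean v > -60 mV) with a
#' subthreshold peak-to-peak oscillation of 2--20 mV; `LTF+SO` when both
#' occur; `silent` otherwise.
#'
#' @param trace a `voltage_trace` (>= 2 s for a meaningful call).
#' @param threshold,refractory spike-detection settings.
#' @param min_dur minimum SO epoch duration, ms (default 1000).
#' @param margin_ms trace excluded around each spike when scanning for
#'   spike-free epochs, ms.
#' @return One of `"LTF"`, `"SO"`, `"LTF+SO"`, `"silent"`.
#' @export
classify_firing_mode <- function(trace, threshold = -20, refractory = 2,
                                 min_dur = 1000, margin_ms = 25) {
  sp <- detect_spikes(trace, threshold, refractory)
  has_spikes <- length(sp) > 0
  edges <- c(min(trace$time), sort(sp), max(trace$time))
  has_so <- FALSE
  for (k in seq_len(length(edges) - 1L)) {
    t0 <- edges[k] + if (k > 1) margin_ms else 0
    t1 <- edges[k + 1L] - if (k < length(edges) - 1L) margin_ms else 0
    if (t1 - t0 < min_dur) next
    seg <- keep_window(trace, c(t0, t1))
    p2p <- diff(range(seg$v))
    if (mean(seg$v) > -60 && p2p >= 2 && p2p <= 20) { has_so <- TRUE; break }
  }
  if (has_spikes && has_so) "LTF+SO"
  else if (has_spikes) "LTF"
  else if (has_so) "SO"
  else "silent"
}

#' Area above threshold of suprathreshold excursions
#'
#' \eqn{\int (v - \theta)\,dt} (trapezoid) over each contiguous epoch with
#' `v` above the threshold, e.g. the plateau phase of a calcium-driven
#' action potential.
#'
#' @param trace a `voltage_trace`.
#' @param threshold plateau threshold, mV.
#' @return List with per-event areas (`events`, mV ms; empty when the trace
#'   never crosses the threshold) and their `total`.
#' @export
plateau_area <- function(trace, threshold) {
  above <- trace$v > threshold
  if (!any(above)) return(list(events = numeric(0), total = 0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  events <- numeric(0)
  for (k in which(r$values)) {
    i0 <- max(1L, starts[k] - 1L)
    i1 <- min(length(trace$v), ends[k] + 1L)
    vv <- pmax(trace$v[i0:i1] - threshold, 0)
    events <- c(events, trapz(trace$time[i0:i1], vv))
  }
  list(events = events, total = sum(events))
}

#' 90--10% decay slope of an event
#'
#' Linear chord slope of the falling phase between the 90% and 10%
#' amplitude crossings of an event (peak relative to the event's end
#' baseline); negative for a decaying event.
#'
#' @param trace a `voltage_trace`.
#' @param event `c(t0, t1)` window containing one excursion; the baseline is
#'   the minimum voltage after the peak within the window.
#' @return List with `slope` (mV/ms), the crossing times `t90`/`t10`, and a
#'   `flagged` logical (TRUE when the crossings cannot be located).
#' @export
decay_slope_90_10 <- function(trace, event) {
  seg <- keep_window(trace, event)
  if (length(seg$v) < 5L) stop("event window too short", call. = FALSE)
  ipk <- which.max(seg$v)
  peak <- seg$v[ipk]
  base <- min(seg$v[ipk:length(seg$v)])
  amp <- peak - base
  if (amp <= 0) return(list(slope = NA_real_, t90 = NA, t10 = NA, flagged = TRUE))
  cross_time <- function(level) {
    vv <- seg$v[ipk:length(seg$v)]
    tt <- seg$time[ipk:length(seg$v)]
    i <- which(vv[-1] <= level & vv[-length(vv)] > level)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    w <- (vv[i] - level) / (vv[i] - vv[i + 1])
    tt[i] + w * (tt[i + 1] - tt[i])
  }
  t90 <- cross_time(base + 0.9 * amp)
  t10 <- cross_time(base + 0.1 * amp)
  if (is.na(t90) || is.na(t10) || t10 <= t90) {
    return(list(slope = NA_real_, t90 = t90, t10 = t10, flagged = TRUE))
  }
  list(slope = -0.8 * amp / (t10 - t90), t90 = t90, t10 = t10,
       flagged = FALSE)
}
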