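# Least-squares backend: multi-start Nelder-Mead/BFGS on the residual sum of
# squares with deterministic +/-20% jitter of the initial guess (3 starts).
ls_multistart <- function(par0, rss_fn) {
  safe_rss <- function(p) {
    v <- rss_fn(p)
    if (!is.finite(v)) 1e300 else v
  }
  jit <- rbind(rep(1, length(par0)), 0.8, 1.2)
  best <- NULL
  for (j in seq_len(nrow(jit))) {
    for (method in c("Nelder-Mead", "BFGS")) {
      fit <- tryCatch(
        stats::optim(par0 * jit[j, ], safe_rss, method = method,
                     control = list(maxit = 2000, reltol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
  }
  if (is.null(best)) stop("least-squares fit failed from every start", call. = FALSE)
  best
}

#' Peak current and time to peak in a trace window
#'
#' The peak is the most-negative (inward-convention) sample inside the
#' window; time to peak is measured from the window start (the pulse onset).
#' For noisy recordings, picking the raw most-negative sample is biased by
#' extreme-value selection, so a centered moving-average filter of
#' `smooth_samples` points (odd; 1 = no smoothing) can be applied before
#' peak picking.
#'
#' @param time,current sample times (ms) and currents (pA).
#' @param window `c(t0, t1)` in ms; must overlap the trace.
#' @param smooth_samples odd number of samples of a centered moving average
#'   applied before peak detection (default 1: raw samples).
#' @return List with `i_peak` (pA), `time_to_peak` (ms) and `t_peak`
#'   (absolute time, ms).
#' @export
peak_and_ttp <- function(time, current, window, smooth_samples = 1) {
  stopifnot(length(time) == length(current), length(window) == 2L)
  sel <- time >= window[1] & time <= window[2]
  if (!any(sel)) stop("empty analysis window", call. = FALSE)
  tt <- time[sel]; ii <- current[sel]
  if (smooth_samples > 1 && length(ii) > smooth_samples) {
    k <- smooth_samples - smooth_samples %% 2 + 1  # force odd
    ii <- stats::filter(ii, rep(1 / k, k), sides = 2)
    keep <- !is.na(ii)
    tt <- tt[keep]; ii <- as.numeric(ii[keep])
  }
  k <- which.min(ii)
  list(i_peak = ii[k], time_to_peak = tt[k] - window[1], t_peak = tt[k])
}

# Moving-average width (samples) used automatically for noisy sweep sets:
# ~1.5 ms of samples, or none for noise-free data.
auto_smooth <- function(sweeps) {
  if (is.null(sweeps$meta$noise_sd) || sweeps$meta$noise_sd <= 0) return(1L)
  k <- round(1.5 / sweeps$protocol$sample_interval)
  as.integer(max(3L, k - k %% 2 + 1L))
}

# Per-sweep peak currents of an I-V family (pulse segment window).
iv_peaks <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  proto <- sweeps$protocol
  seg <- proto$meta$pulse_segment
  if (is.null(seg)) stop("protocol has no pulse segment metadata", call. = FALSE)
  sm <- auto_smooth(sweeps)
  vapply(seq_along(sweeps$current), function(s) {
    st <- segment_times(proto, s, sweeps$meta$pre_ms)
    peak_and_ttp(sweeps$time[[s]], sweeps$current[[s]],
                 c(st$t_on[seg], st$t_off[seg]), smooth_samples = sm)$i_peak
  }, numeric(1))
}

#' Fit the peak current-voltage relationship
#'
#' Least-squares fit of the standard ohmic-Boltzmann I-V model
#' \deqn{I(V) = g_{max} (V - E_{rev}) / (1 + e^{-(V - V_{1/2})/k})}
#' to peak currents.  Either pass a `sweep_set` from an I-V protocol (peaks
#' are extracted per sweep) or explicit `v_levels`/`i_peak` vectors.
#'
#' @param x a `sweep_set`, or a numeric vector of test levels (mV).
#' @param i_peak peak currents (pA) when `x` is a vector.
#' @return An object of class `iv_fit` with the fitted `g_max` (nS),
#'   `e_rev`, `v_half`, `k` (mV), the per-level peaks, `i_peak` (most
#'   negative peak), `v_max` (level of maximal inward current), `rss` and a
#'   `converged` flag (non-convergence is flagged, never silent).
#' @export
fit_iv <- function(x, i_peak = NULL) {
  if (inherits(x, "sweep_set")) {
    v_levels <- x$protocol$meta$test_levels
    i_peak <- iv_peaks(x)
  } else {
    v_levels <- x
  }
  stopifnot(length(v_levels) == length(i_peak))
  if (length(v_levels) < 6L) stop("need >= 6 test levels", call. = FALSE)
  if (all(abs(i_peak) < 1e-12) || min(i_peak) >= 0) {
    stop("no inward limb in the I-V data", call. = FALSE)
  }
  # initial guesses: E_rev from the depolarized limb, V1/2 from half-maximal
  # conductance, k = 5 mV
  e0 <- max(v_levels) + 60
  g0 <- min(i_peak) / (v_levels[which.min(i_peak)] - e0)
  gg <- i_peak / (v_levels - e0)
  v0 <- v_levels[which.min(abs(gg - max(gg) / 2))]
  model <- function(p, v) {
    p[1] * (v - p[2]) / (1 + exp(-(v - p[3]) / exp(p[4])))
  }
  rss_fn <- function(p) {
    r <- i_peak - model(p, v_levels)
    sum(r * r)
  }
  fit <- ls_multistart(c(g0, e0, v0, log(5)), rss_fn)
  converged <- !is.null(fit) && is.finite(fit$value)
  p <- if (converged) fit$par else c(g0, e0, v0, log(5))
  structure(list(v_levels = v_levels, i_peak_per_level = i_peak,
                 i_peak = min(i_peak),
                 v_max = v_levels[which.min(i_peak)],
                 g_max = p[1], e_rev = p[2], v_half = p[3], k = exp(p[4]),
                 rss = if (converged) fit$value else NA_real_,
                 converged = converged,
                 diagnostics = if (converged) fit$convergence else "optim failed"),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("<iv_fit> Ipeak %.1f pA at Vmax %+.0f mV; g_max %.2f nS, E_rev %+.1f mV, V1/2 %.2f mV, k %.2f mV%s\n",
              x$i_peak, x$v_max, x$g_max, x$e_rev, x$v_half, x$k,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

# Shared Boltzmann least-squares fit on (v, y) data.
fit_boltzmann <- function(v, y, direction = c("ascending", "descending"),
                          p = 1) {
  direction <- match.arg(direction)
  if (length(v) < 4L) stop("Boltzmann fit needs >= 4 points", call. = FALSE)
  sgn <- if (direction == "ascending") 1 else -1
  model <- function(par) {
    1 / (1 + exp(-sgn * (v - par[1]) / exp(par[2])))^p
  }
  v0 <- v[which.min(abs(y - 0.5^p))]
  rss_fn <- function(par) { r <- y - model(par); sum(r * r) }
  fit <- ls_multistart(c(v0, log(5)), rss_fn)
  structure(list(v_half = fit$par[1], k = exp(fit$par[2]),
                 direction = direction, p = p, rss = fit$value,
                 n_points = length(v), v = v, y = y),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s: V1/2 %.2f mV, k %.2f mV (p = %g, n = %d, rss %.3g)\n",
              x$direction, x$v_half, x$k, x$p, x$n_points, x$rss))
  invisible(x)
}

#' Fractional activation curve from an I-V family
#'
#' Converts peak currents to conductances with the fitted reversal
#' potential, \eqn{G(V) = I_{peak}(V) / (V - E_{rev})}, normalizes to the
#' maximum, and fits an ascending Boltzmann raised to the activation-gate
#' exponent (levels within 1 mV of the reversal potential are excluded).
#'
#' When the sweep family itself is supplied (rather than only an I-V fit),
#' each peak conductance is first corrected for the inactivation that has
#' accrued by the time of the peak: the post-peak decay of the sweep is fit
#' mono-exponentially and the envelope is back-extrapolated to pulse onset,
#' \eqn{G_{corr} = G \cdot e^{t_{peak}/\hat\tau}}.  Without this correction
#' the apparent midpoint is biased depolarized by a fraction of a millivolt
#' to a few millivolts, because slowly activating sweeps lose more channels
#' to inactivation before the peak.  Sweeps carrying less than 5% of the
#' maximal current keep their raw conductance (their decay is not reliably
#' fittable and their correction factor is close to 1).
#'
#' @param x a `sweep_set` from an I-V protocol (preferred: enables the
#'   inactivation correction) or an [fit_iv()] result (raw peaks).
#' @param p activation-gate exponent used in the fit (default 2, matching
#'   the m^2 h channel formulation).
#' @param ivfit optional precomputed [fit_iv()] when `x` is a `sweep_set`.
#' @return A `boltzmann_fit` (direction `"ascending"`).
#' @export
fractional_activation <- function(x, p = 2, ivfit = NULL) {
  if (inherits(x, "iv_fit")) {
    fit <- x
    sweeps <- NULL
  } else if (inherits(x, "sweep_set")) {
    sweeps <- x
    fit <- if (is.null(ivfit)) fit_iv(x) else ivfit
  } else stop("x must be a sweep_set or an iv_fit", call. = FALSE)
  keep <- abs(fit$v_levels - fit$e_rev) > 1
  v <- fit$v_levels[keep]
  g <- fit$i_peak_per_level[keep] / (v - fit$e_rev)
  if (!is.null(sweeps)) {
    seg <- sweeps$protocol$meta$pulse_segment
    sm <- auto_smooth(sweeps)
    i_max <- max(abs(fit$i_peak_per_level))
    for (j in seq_along(v)) {
      s <- which(keep)[j]
      if (abs(fit$i_peak_per_level[s]) < 0.05 * i_max) next
      st <- segment_times(sweeps$protocol, s, sweeps$meta$pre_ms)
      win <- c(st$t_on[seg], st$t_off[seg])
      pk <- peak_and_ttp(sweeps$time[[s]], sweeps$current[[s]], win,
                         smooth_samples = sm)
      dec <- fit_exp_decay(sweeps$time[[s]], sweeps$current[[s]],
                           c(pk$t_peak, win[2]))
      # only trust corrections from well-separated decays: a noisy tau
      # estimate below ~2x the time to peak would blow the factor up
      if (!dec$flagged && is.finite(dec$tau) &&
          dec$tau > 2 * pk$time_to_peak) {
        g[j] <- g[j] * exp(pk$time_to_peak / dec$tau)
      }
    }
  }
  fit_boltzmann(v, g / max(g), "ascending", p = p)
}

#' Fractional inactivation after 500 ms
#'
#' \eqn{1 - I(t_{on} + 500)/I_{peak}} for a depolarizing pulse, using the
#' inward (negative) current convention; 0 for a non-inactivating current,
#' approaching 1 for complete inactivation.
#'
#' @param time,current trace samples (ms, pA).
#' @param pulse_window `c(t_on, t_off)` of the pulse, ms; needs `t_off >=
#'   t_on + 500`.
#' @return Fraction in \[0, 1\] for monotone decay.
#' @export
fractional_inactivation_500 <- function(time, current, pulse_window) {
  stopifnot(diff(pulse_window) >= 500)
  pk <- peak_and_ttp(time, current, pulse_window)
  if (pk$i_peak == 0) stop("zero peak current", call. = FALSE)
  i500 <- stats::approx(time, current, xout = pulse_window[1] + 500)$y
  1 - i500 / pk$i_peak
}

#' Mono-exponential decay fit
#'
#' Least-squares fit of \eqn{I(t) = A e^{-(t - t_0)/\tau} + C} over a trace
#' window starting at or after the current peak.  A window with no decaying
#' component is returned flagged rather than as an error.
#'
#' @param time,current trace samples (ms, pA).
#' @param window `c(t0, t1)` fit window, ms.
#' @return An object of class `exp_fit`: `tau` (ms), `amplitude` (pA),
#'   `offset` (pA), `window`, `rss`, `flagged` and `reason`.
#' @export
fit_exp_decay <- function(time, current, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 5L) stop("fit window contains too few samples", call. = FALSE)
  tt <- time[sel] - window[1]
  yy <- current[sel]
  c0 <- mean(yy[tt >= 0.9 * max(tt)])
  a0 <- yy[1] - c0
  flagged <- FALSE; reason <- NA_character_
  if (abs(a0) < 1e-3 * (abs(c0) + diff(range(yy)) + 1e-12) ||
      diff(range(yy)) < 1e-9) {
    # constant segment: no decay to fit
    return(structure(list(tau = NA_real_, amplitude = 0, offset = mean(yy),
                          window = window, rss = sum((yy - mean(yy))^2),
                          flagged = TRUE, reason = "no decaying component"),
                     class = "exp_fit"))
  }
  t_e <- tt[which.min(abs(yy - (c0 + a0 / exp(1))))]
  tau0 <- max(t_e, 4 * (tt[2] - tt[1]))
  rss_fn <- function(p) {
    r <- yy - (p[1] * exp(-tt / exp(p[2])) + p[3])
    sum(r * r)
  }
  fit <- ls_multistart(c(a0, log(tau0), c0), rss_fn)
  tau <- exp(fit$par[2]); a <- fit$par[1]
  if (a * a0 < 0 || abs(a) < 0.02 * diff(range(yy))) {
    flagged <- TRUE; reason <- "non-decaying or negligible amplitude"
  }
  structure(list(tau = tau, amplitude = a, offset = fit$par[3],
                 window = window, rss = fit$value,
                 flagged = flagged, reason = reason),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> tau %.3g ms, A %.3g pA, C %.3g pA over [%g, %g] ms%s\n",
              x$tau, x$amplitude, x$offset, x$window[1], x$window[2],
              if (x$flagged) paste0(" [FLAGGED: ", x$reason, "]") else ""))
  invisible(x)
}

#' Deactivation time constant from a tail sweep
#'
#' Mono-exponential fit of the decaying tail current after repolarization.
#' The fit starts `skip_samples` samples after the voltage step to skip the
#' command discontinuity (real recordings carry a capacitive transient
#' there).
#'
#' @param sweeps a `sweep_set` from [make_deactivation_protocol()].
#' @param sweep sweep index (one per tail level).
#' @param skip_samples samples skipped after repolarization (default 2).
#' @return An `exp_fit` (see [fit_exp_decay()]).
#' @export
deactivation_tau <- function(sweeps, sweep = 1L, skip_samples = 2L) {
  stopifnot(inherits(sweeps, "sweep_set"))
  seg <- sweeps$protocol$meta$tail_segment
  if (is.null(seg)) stop("protocol has no tail segment metadata", call. = FALSE)
  st <- segment_times(sweeps$protocol, sweep, sweeps$meta$pre_ms)
  si <- sweeps$protocol$sample_interval
  fit_exp_decay(sweeps$time[[sweep]], sweeps$current[[sweep]],
                c(st$t_on[seg] + skip_samples * si, st$t_off[seg]))
}

#' Steady-state inactivation curve
#'
#' Fractional availability at each conditioning voltage as the post/pre
#' peak-current ratio of the two test pulses of each SSI sweep, fitted with
#' a descending Boltzmann.  Sweeps whose reference pulse carries no current
#' are excluded with a warning.
#'
#' @param sweeps a `sweep_set` from [make_ssi_protocol()].
#' @return A `boltzmann_fit` (direction `"descending"`) whose `v`/`y` data
#'   are the conditioning levels and availability ratios.
#' @export
ssi_curve <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  meta <- sweeps$protocol$meta
  if (is.null(meta$pre_segment)) stop("not an SSI protocol", call. = FALSE)
  lev <- meta$cond_levels
  sm <- auto_smooth(sweeps)
  ratio <- rep(NA_real_, length(lev))
  for (s in seq_along(lev)) {
    st <- segment_times(sweeps$protocol, s, sweeps$meta$pre_ms)
    pre <- peak_and_ttp(sweeps$time[[s]], sweeps$current[[s]],
                        c(st$t_on[meta$pre_segment], st$t_off[meta$pre_segment]),
                        smooth_samples = sm)
    post <- peak_and_ttp(sweeps$time[[s]], sweeps$current[[s]],
                         c(st$t_on[meta$post_segment], st$t_off[meta$post_segment]),
                         smooth_samples = sm)
    if (abs(pre$i_peak) < 1e-9) {
      warning("sweep ", s, " excluded: zero reference-pulse current")
      next
    }
    ratio[s] <- post$i_peak / pre$i_peak
  }
  keep <- is.finite(ratio)
  fit_boltzmann(lev[keep], ratio[keep], "descending", p = 1)
}

#' Midpoint shift between two Boltzmann fits
#'
#' `fit_var$v_half - fit_ref$v_half`; negative values are hyperpolarizing
#' shifts.  Both fits must have the same direction.
#'
#' @param fit_ref,fit_var `boltzmann_fit` objects.
#' @return Shift in mV.
#' @export
v_half_shift <- function(fit_ref, fit_var) {
  stopifnot(inherits(fit_ref, "boltzmann_fit"),
            inherits(fit_var, "boltzmann_fit"))
  if (!identical(fit_ref$direction, fit_var$direction)) {
    stop("fits have different directions", call. = FALSE)
  }
  fit_var$v_half - fit_ref$v_half
}

#' Compare window currents across variants
#'
#' Summarizes [window_curve()] for each parameter set and reports areas
#' relative to the wild-type entry (which must be present as `"WT"`).
#'
#' @param params_list named list of [gating_params()] (must include `WT`).
#' @param v_grid voltage grid passed to [window_curve()].
#' @return Data frame with columns `variant`, `peak_voltage`, `peak_value`,
#'   `area` and `area_ratio`.
#' @export
window_compare <- function(params_list, v_grid = seq(-100, 0, by = 0.1)) {
  nms <- vapply(params_list, function(p) p$name, character(1))
  if (!"WT" %in% nms) stop("parameter list must contain WT", call. = FALSE)
  wc <- lapply(params_list, window_curve, v_grid = v_grid)
  area_wt <- wc[[which(nms == "WT")[1]]]$area
  data.frame(variant = nms,
             peak_voltage = vapply(wc, `[[`, numeric(1), "peak_voltage"),
             peak_value = vapply(wc, `[[`, numeric(1), "peak_value"),
             area = vapply(wc, `[[`, numeric(1), "area"),
             area_ratio = vapply(wc, `[[`, numeric(1), "area") / area_wt,
             row.names = NULL)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Action-potential clamp charge metrics
#'
#' Per AP of a 20-Hz AP-clamp train: the persistent (pace-making) current as
#' the mean current over the 5 ms before AP onset, the charge carried during
#' the AP waveform, and the charge over the 10 ms after the return to
#' baseline (trapezoid integration; charges in pC, negative = influx).
#'
#' @param sweeps a `sweep_set` from [make_ap_train_protocol()].
#' @return Data frame with one row per AP: `sweep`, `persistent_pA`,
#'   `charge_during_pC`, `charge_after_pC`.
#' @export
ap_clamp_metrics <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  meta <- sweeps$protocol$meta
  if (is.null(meta$ap_onsets_ms)) stop("not an AP-train protocol", call. = FALSE)
  tt <- sweeps$time[[1]]
  ii <- sweeps$current[[1]]
  onsets <- meta$ap_onsets_ms + sweeps$meta$pre_ms
  dur <- meta$ap_duration_ms
  if (max(onsets) + dur + 10 > max(tt)) {
    stop("trace shorter than the AP train: protocol misaligned", call. = FALSE)
  }
  res <- lapply(seq_along(onsets), function(k) {
    on <- onsets[k]
    pre <- tt >= on - 5 & tt < on
    dd <- tt >= on & tt <= on + dur
    aft <- tt >= on + dur & tt <= on + dur + 10
    data.frame(sweep = k,
               persistent_pA = mean(ii[pre]),
               charge_during_pC = trapz(tt[dd], ii[dd]) / 1000,
               charge_after_pC = trapz(tt[aft], ii[aft]) / 1000)
  })
  do.call(rbind, res)
}
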