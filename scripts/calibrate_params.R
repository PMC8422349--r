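#!/usr/bin/env Rscript
# One-time construction + calibration of inst/extdata/cav33_variants.json.
#
# The raw patch-clamp recordings behind the published Cav3.3 variant study
# are not public, so the shipped parameter file is a synthetic
# transcription: a literature-typical wild-type Cav3.3 baseline plus, per
# variant, the published midpoint shifts and kinetic slowings.  The free
# constants below (baseline tables, per-variant tau scale factors) were
# chosen ONCE so that simulated recordings reproduce the published
# measured quantities, then frozen:
#   - activation V1/2 shifts: I860N -15.5, I860M -8.1, I1306T -14.5,
#     M1425I -13.7 mV
#   - inactivation V1/2 shifts: I860N -6.6, I860M -5.9, M1425I -6.8,
#     I1306T ~0 mV
#   - fractional inactivation at 500 ms, Vmax: WT 95-98%, I860N ~52%,
#     I860M ~87%
#   - time to peak at Vmax: I860N > 3x WT, I860M ~2x WT
#   - tail-current deactivation tau: I860N up to ~10x WT, I860M ~ WT,
#     I1306T and M1425I intermediate
#   - window current: WT peak near -50 mV; variant peaks in [-70, -60] mV;
#     enlarged for I860N / I1306T, not for I860M / M1425I
#   - peak current: M1425I doubled (g_max x2)
#
# Run from the repository root:  Rscript scripts/calibrate_params.R
# Re-running regenerates the file bit-identically and prints the checks.

suppressMessages(library(gatesim))

tau_tab <- function(v, tau) list(v = v, tau = tau)

v_act <- c(-70, -60, -50, -40, -30, -20, -10, 0, 10, 30)
# bell-shaped in V (fast deactivation at hyperpolarized potentials, maximum
# near the activation midpoint, fast activation when depolarized)
wt_tau_act <- c(30, 22, 13, 7, 4, 3, 2.6, 2.3, 2.1, 1.9)
v_inact <- c(-100, -90, -80, -70, -60, -50, -40, -30, -20, -10, 0, 30)
wt_tau_inact <- c(350, 400, 420, 400, 300, 220, 180, 160, 150, 145, 140, 130)
v_deact <- c(-120, -100, -80)
wt_tau_deact <- c(2.8, 3.2, 5.0)

wt <- list(
  v_half_act = -48, k_act = 5.5,
  v_half_inact = -72, k_inact = 5.0,
  p_act = 2, g_max = 20, e_rev = 120,
  tau_act_table = tau_tab(v_act, wt_tau_act),
  tau_inact_table = tau_tab(v_inact, wt_tau_inact),
  tau_deact_table = tau_tab(v_deact, wt_tau_deact),
  provenance = paste(
    "SYNTHETIC baseline: literature-typical whole-cell Cav3.3 (HEK) values;",
    "raw recordings not public. Boltzmann midpoints/slopes and tau tables",
    "chosen so the simulated wild-type reproduces the published measured",
    "behaviour (window peak near -50 mV, 95-98% inactivation at 500 ms,",
    "tail tau ~1.6 ms at -100 mV)."))

# Per-variant deltas (published activation/inactivation midpoint shifts)
# and tau scale factors (calibrated to the published kinetic ratios).
# k_inact: the published record gives no slope factors for the variants; the
# variant inactivation slopes are calibrated so that the window currents
# reproduce the published geometry (variant peaks in [-70, -60] mV;
# enlarged only for I860N / I1306T).
# d_act / d_inact are inverse-calibrated: the published shifts are MEASURED
# (pipeline) values, and slow gating biases the measured midpoint slightly
# away from the underlying gate midpoint, so the gate deltas stored here are
# the published shift plus that measured bias (one fixed-point iteration).
# s_act is a per-voltage scale vector over v_act: the published kinetic
# analysis found activation significantly slowed only at -50 mV (and -40 mV
# for I860N), so the slowing is concentrated there and tapers off at more
# depolarized test potentials.
sact_vec <- function(lo, mid, at30, hi) c(lo, lo, mid, mid, at30,
                                          hi, hi, hi, hi, hi)
variant_spec <- list(
  I860N  = list(d_act = -15.67, d_inact = -7.67, k_act = 5.5, k_inact = 6.0,
                s_act = sact_vec(1.3, 2.6, 2.5, 1.3),
                s_inact = 3.75, s_deact = 10.0, g_fac = 1,
                note = "measured activation shift -15.5 mV; measured inactivation shift -6.6 mV; slowest kinetics (52% inactivation at 500 ms, >3x time to peak, ~10x slower deactivation)"),
  I860M  = list(d_act = -8.58, d_inact = -5.9, k_act = 5.8, k_inact = 4.3,
                s_act = sact_vec(1.2, 2.0, 2.0, 1.9),
                s_inact = 1.43, s_deact = 1.1, g_fac = 1,
                note = "measured activation shift -8.1 mV; measured inactivation shift -5.9 mV; mildest variant (~87% inactivation at 500 ms, ~2x time to peak, deactivation like wild-type)"),
  I1306T = list(d_act = -14.74, d_inact = 0, k_act = 5.5, k_inact = 4.2,
                s_act = sact_vec(1.3, 2.6, 2.0, 1.2),
                s_inact = 2.6, s_deact = 4.0, g_fac = 1,
                note = "measured activation shift -14.5 mV; no significant inactivation shift; slowed kinetics and deactivation; enlarged window current"),
  M1425I = list(d_act = -14.07, d_inact = -6.8, k_act = 5.5, k_inact = 3.4,
                s_act = sact_vec(1.3, 2.6, 2.0, 1.2),
                s_inact = 2.2, s_deact = 3.0, g_fac = 2,
                note = "measured activation shift -13.7 mV; measured inactivation shift -6.8 mV; peak current doubled (g_max x2); slowed deactivation"))

variants <- list(WT = wt)
for (nm in names(variant_spec)) {
  sp <- variant_spec[[nm]]
  v <- wt
  v$v_half_act <- wt$v_half_act + sp$d_act
  v$v_half_inact <- wt$v_half_inact + sp$d_inact
  v$k_act <- sp$k_act
  v$k_inact <- sp$k_inact
  v$tau_act_table$tau <- wt_tau_act * sp$s_act
  v$tau_inact_table$tau <- wt_tau_inact * sp$s_inact
  v$tau_deact_table$tau <- wt_tau_deact * sp$s_deact
  v$g_max <- wt$g_max * sp$g_fac
  v$provenance <- paste("SYNTHETIC:", sp$note,
                        "- midpoint deltas from the published main text,",
                        "tau scalings calibrated to the published ratios.")
  variants[[nm]] <- v
}

out <- list(
  description = paste(
    "Cav3.3 gating parameters: wild-type and the gain-of-function variants",
    "I860N, I860M, I1306T, M1425I. SYNTHETIC transcription calibrated to",
    "published measured values (see provenance per record and the package",
    "vignette); not raw experimental fits."),
  variants = variants)

path <- file.path("inst", "extdata", "cav33_variants.json")
dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", path, "\n\n")

## ---- verification against the published anchors -------------------------
p <- cav33_params(file = path)

cat("== window currents ==\n")
print(window_compare(p))

measure <- function(params) {
  iv <- simulate_sweeps(params, make_iv_protocol(), dt = 0.025)
  fit <- fit_iv(iv)
  fa <- fractional_activation(iv, ivfit = fit)
  s <- which.min(fit$i_peak_per_level)
  st <- segment_times(iv$protocol, s, iv$meta$pre_ms)
  win <- c(st$t_on[1], st$t_off[1])
  pk <- peak_and_ttp(iv$time[[s]], iv$current[[s]], win)
  fi <- fractional_inactivation_500(iv$time[[s]], iv$current[[s]], win)
  dp <- make_deactivation_protocol(v_act = fit$v_max,
                                   act_ms = if (params$name == "WT") 15 else 50)
  dt_fit <- deactivation_tau(simulate_sweeps(params, dp))
  ssi <- ssi_curve(simulate_sweeps(params, make_ssi_protocol(v_test = fit$v_max)))
  list(v_half_act = fa$v_half, v_max = fit$v_max, i_peak = fit$i_peak,
       ttp = pk$time_to_peak, frac500 = fi, tau_deact = dt_fit$tau,
       v_half_inact = ssi$v_half)
}

m <- lapply(p, measure)
cat("\n== measured pipeline values ==\n")
for (nm in names(m)) {
  x <- m[[nm]]
  cat(sprintf("%-7s Vmax %+4.0f  Ipeak %8.1f  ttp %6.2f ms  frac500 %5.1f%%  tau_deact %6.2f ms  V1/2act %7.2f  V1/2inact %7.2f\n",
              nm, x$v_max, x$i_peak, x$ttp, 100 * x$frac500, x$tau_deact,
              x$v_half_act, x$v_half_inact))
}
w <- m$WT
cat("\n== anchor checks ==\n")
chk <- function(label, val, ok) cat(sprintf("%-46s %10.3f  %s\n", label, val,
                                            if (ok) "OK" else "MISS"))
sh <- function(nm) m[[nm]]$v_half_act - w$v_half_act
shi <- function(nm) m[[nm]]$v_half_inact - w$v_half_inact
chk("activation shift I860N (-15.5)", sh("I860N"), abs(sh("I860N") + 15.5) < 0.5)
chk("activation shift I860M (-8.1)", sh("I860M"), abs(sh("I860M") + 8.1) < 0.5)
chk("activation shift I1306T (-14.5)", sh("I1306T"), abs(sh("I1306T") + 14.5) < 0.5)
chk("activation shift M1425I (-13.7)", sh("M1425I"), abs(sh("M1425I") + 13.7) < 0.5)
chk("inactivation shift M1425I (-6.8)", shi("M1425I"), abs(shi("M1425I") + 6.8) < 0.5)
chk("inactivation shift I860N (-6.6)", shi("I860N"), abs(shi("I860N") + 6.6) < 0.5)
chk("inactivation shift I860M (-5.9)", shi("I860M"), abs(shi("I860M") + 5.9) < 0.5)
chk("WT frac500 (95-98%)", 100 * w$frac500,
    w$frac500 > 0.95 && w$frac500 < 0.98)
chk("I860N frac500 (~52%)", 100 * m$I860N$frac500,
    abs(m$I860N$frac500 - 0.52) < 0.03)
chk("I860M frac500 (~87%)", 100 * m$I860M$frac500,
    abs(m$I860M$frac500 - 0.87) < 0.03)
chk("ttp ratio I860N (>3)", m$I860N$ttp / w$ttp, m$I860N$ttp / w$ttp > 3)
chk("ttp ratio I860M (~2)", m$I860M$ttp / w$ttp,
    abs(m$I860M$ttp / w$ttp - 2) < 0.5)
chk("tau_deact ratio I860N (~10)", m$I860N$tau_deact / w$tau_deact,
    m$I860N$tau_deact / w$tau_deact > 5)
chk("tau_deact ratio I860M (~1)", m$I860M$tau_deact / w$tau_deact,
    abs(m$I860M$tau_deact / w$tau_deact - 1) < 0.3)
chk("Ipeak ratio M1425I (~2)", m$M1425I$i_peak / w$i_peak,
    abs(m$M1425I$i_peak / w$i_peak - 2) < 0.3)
wc <- window_compare(p)
chk("WT window peak (near -50)", wc$peak_voltage[wc$variant == "WT"],
    abs(wc$peak_voltage[wc$variant == "WT"] + 50) <= 3)
for (nm in names(variant_spec)) {
  pv <- wc$peak_voltage[wc$variant == nm]
  chk(paste(nm, "window peak in [-70,-60]"), pv, pv >= -70 && pv <= -60)
}
chk("I860N window ratio (>1.5)", wc$area_ratio[wc$variant == "I860N"],
    wc$area_ratio[wc$variant == "I860N"] > 1.5)
chk("I1306T window ratio (>1.5)", wc$area_ratio[wc$variant == "I1306T"],
    wc$area_ratio[wc$variant == "I1306T"] > 1.5)
chk("I860M window ratio (~1)", wc$area_ratio[wc$variant == "I860M"],
    abs(wc$area_ratio[wc$variant == "I860M"] - 1) < 0.35)
chk("M1425I window ratio (~1)", wc$area_ratio[wc$variant == "M1425I"],
    abs(wc$area_ratio[wc$variant == "M1425I"] - 1) < 0.35)

cat("\n== AP-clamp persistent current (early sweeps) ==\n")
pers <- function(params) {
  ap <- simulate_sweeps(params, make_ap_train_protocol(), dt = 0.05)
  mean(ap_clamp_metrics(ap)$persistent_pA[2:6])
}
pw <- pers(p$WT); pn <- pers(p$I860N)
# The published "order of magnitude" early-sweep persistent ratio is not
# attainable together with the published facilitation of the early AP peaks:
# both are governed by the same m-gate relaxation at the -70 mV inter-AP
# baseline (slow relaxation -> facilitation but a large wild-type persistent
# current; fast relaxation -> the reverse). Facilitation is the anchored
# invariant; the ratio is reported here and documented as a known miss.
chk("I860N/WT persistent ratio (reported; >1.5)", pn / pw, pn / pw > 1.5)
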