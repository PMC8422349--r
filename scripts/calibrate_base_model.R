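#!/usr/bin/env Rscript
# One-time calibration of the single-compartment TRN-style base model,
# frozen into inst/extdata/trn_base_model.json.
#
# The published simulation used a ModelDB thalamic-neuron model whose
# morphology and conductance densities are not printed, so the base cell is
# reconstructed here: one compartment, Traub-lineage Na+/K+ spike kinetics
# with threshold shift v_shift, leak, and the T-type conductance in density
# mode.  Structural constants (c_m = 1 uF/cm^2, area 1.43e-4 cm^2 -- a
# ~70-um-diameter soma --, g_na = 100 mS/cm^2, g_k = 15 mS/cm^2, e_na = +50,
# e_k = -80, e_leak = -66 mV, v_shift = -45 mV) were fixed first on the
# qualitative requirements (spike threshold above the low-threshold-spike
# plateau; a transient rebound burst followed by silence for the wild-type
# channel); then (g_leak, g_t) were tuned on the grid below to the two
# wild-type anchors and frozen:
#   - rheobase 0.29 nA (200-ms pulse from a resting potential set to -110 mV,
#     0.01-nA grid)
#   - rebound-burst initial frequency f0 ~ 255 Hz
# All variant simulations swap only the channel gating parameters.
#
# Run from the repository root after scripts/calibrate_params.R:
#   Rscript scripts/calibrate_base_model.R

suppressMessages(library(gatesim))

base <- list(c_m = 1, area = 1.43e-4, g_na = 100, g_k = 15,
             e_na = 50, e_k = -80, e_leak = -66, v_shift = -45,
             g_max_ref = 20)
wt <- cav33_params("WT", file = file.path("inst", "extdata",
                                          "cav33_variants.json"))

score <- function(g_leak, g_t) {
  cfg <- c(base, list(g_leak = g_leak, g_t = g_t))
  m <- build_model(wt, cfg)
  rheo <- find_rheobase(m)
  rb <- rebound_run(m, total_ms = 3000)
  c(rheo = rheo, f0 = rb$metrics$f0)
}

cat("grid search around the WT anchors (rheobase 0.29 nA, f0 255.1 Hz):\n")
best <- NULL
for (g_leak in c(0.047, 0.048, 0.049)) {
  for (g_t in c(0.95, 0.97, 1.00)) {
    s <- score(g_leak, g_t)
    cat(sprintf("  g_leak %.3f g_t %.2f: rheobase %.2f nA, f0 %.1f Hz\n",
                g_leak, g_t, s["rheo"], s["f0"]))
    err <- abs(s["rheo"] - 0.29) / 0.29 + abs(s["f0"] - 255.1) / 255.1
    if (!is.finite(err)) err <- Inf  # no rebound burst in this cell
    if (is.null(best) || err < best$err) {
      best <- list(g_leak = g_leak, g_t = g_t, err = err, s = s)
    }
  }
}
cat(sprintf("frozen: g_leak = %.3f mS/cm^2, g_t = %.2f mS/cm^2 (rheobase %.2f nA, f0 %.1f Hz)\n",
            best$g_leak, best$g_t, best$s["rheo"], best$s["f0"]))

cfg <- c(base, list(g_leak = best$g_leak, g_t = best$g_t))
cfg$provenance <- paste(
  "SYNTHETIC single-compartment reconstruction of the published TRN-neuron",
  "simulation (original ModelDB configuration not printed). g_leak and g_t",
  "calibrated once to the wild-type anchors (rheobase 0.29 nA, rebound f0",
  "~255 Hz) by scripts/calibrate_base_model.R, then frozen; variant runs",
  "swap only the channel gating parameters.")
path <- file.path("inst", "extdata", "trn_base_model.json")
jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", path, "\n")
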