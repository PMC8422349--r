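# Shared fixtures: a simple analytic parameter set for unit tests, and a
# generator of random physiological parameter sets for property tests.

test_params <- function(v_half_act = -45, k_act = 5, v_half_inact = -72,
                        k_inact = 4, p_act = 2, g_max = 10, e_rev = 120,
                        tau_act = NULL, tau_inact = NULL, tau_deact = NULL) {
  if (is.null(tau_act)) {
    tau_act <- cbind(c(-70, -60, -50, -40, -30, -20, 0, 30),
                     c(15, 22, 13, 7, 4, 3, 2.3, 1.9))
  }
  if (is.null(tau_inact)) {
    tau_inact <- cbind(c(-100, -80, -60, -40, -20, 0, 30),
                       c(350, 420, 300, 180, 150, 140, 130))
  }
  gating_params("test", v_half_act, k_act, v_half_inact, k_inact,
                tau_act, tau_inact, tau_deact_table = tau_deact,
                p_act = p_act, g_max = g_max, e_rev = e_rev)
}

# Random Cav3.3-like parameter sets. The generator stays inside the
# physiological regime the pipeline assumes: activation much faster than
# inactivation at every voltage (time-scale separation) and inactivation
# time constants short enough that 5-s conditioning reaches steady state.
random_params <- function(n = 1, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    lapply(seq_len(n), function(i) {
      va <- runif(1, -55, -40)
      ka <- runif(1, 4, 7)
      vi <- runif(1, -80, -65)
      ki <- runif(1, 3.5, 6)
      sa <- runif(1, 0.7, 1.3)
      si <- runif(1, 0.8, 1.4)
      g <- runif(1, 10, 40)
      test_params(va, ka, vi, ki, g_max = g,
                  tau_act = cbind(c(-70, -60, -50, -40, -30, -20, 0, 30),
                                  sa * c(15, 22, 13, 7, 4, 3, 2.3, 1.9)),
                  tau_inact = cbind(c(-100, -80, -60, -40, -20, 0, 30),
                                    si * c(350, 420, 300, 180, 150, 140, 130)))
    })
  })
}

# Full measurement pipeline used by the recovery properties: I-V family ->
# fractional activation; SSI family -> inactivation midpoint; 5-s pulse at
# Vmax -> inactivation time constant.
recover_params <- function(params, dt = 0.05, noise_sd = 0, seed = 1,
                           with_tau = TRUE) {
  iv <- simulate_sweeps(params, make_iv_protocol(), dt = dt)
  if (noise_sd > 0) iv <- add_noise(iv, noise_sd, seed)
  fit <- fit_iv(iv)
  fa <- fractional_activation(iv, p = params$p_act, ivfit = fit)
  ssi <- simulate_sweeps(params, make_ssi_protocol(v_test = fit$v_max), dt = dt)
  if (noise_sd > 0) ssi <- add_noise(ssi, noise_sd, seed + 1000)
  sc <- ssi_curve(ssi)
  out <- list(v_half_act = fa$v_half, v_half_inact = sc$v_half,
              v_max = fit$v_max)
  if (with_tau) {
    long <- make_iv_protocol(v_start = fit$v_max, v_end = fit$v_max,
                             pulse_ms = 5000)
    sw <- simulate_sweeps(params, long, dt = dt)
    st <- segment_times(long, 1, sw$meta$pre_ms)
    pk <- peak_and_ttp(sw$time[[1]], sw$current[[1]], c(st$t_on[1], st$t_off[1]))
    dec <- fit_exp_decay(sw$time[[1]], sw$current[[1]],
                         c(pk$t_peak + 50, st$t_off[1]))
    out$tau_inact_vmax <- dec$tau
    out$tau_inact_true <- tau_gate(fit$v_max, params$tau_inact_table)
  }
  out
}

# Boltzmann fit object from exact ascending data (for shift arithmetic tests).
fit_boltzmann_for_test <- function(vh, k = 5) {
  v <- seq(-90, 10, by = 5)
  gatesim:::fit_boltzmann(v, 1 / (1 + exp(-(v - vh) / k)), "ascending", p = 1)
}
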