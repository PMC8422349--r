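# Run manifest: one JSON per output directory with the command, a config
# snapshot, input checksums, seeds and the package version.
write_manifest <- function(out_dir, command, config = list(), files = character(),
                           seeds = list()) {
  files <- files[file.exists(files)]
  manifest <- list(
    command = command,
    config = config,
    checksums = as.list(tools::md5sum(files)),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("gatesim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Voltage of maximal activation for a variant under the default I-V family
# (noise-free simulation + peak extraction).
variant_vmax <- function(params, dt = 0.025) {
  sweeps <- simulate_sweeps(params, make_iv_protocol(pulse_ms = 200), dt = dt)
  pk <- iv_peaks(sweeps)
  sweeps$protocol$meta$test_levels[which.min(pk)]
}

#' Generate synthetic voltage-clamp recordings for a variant
#'
#' Builds the named protocol with variant-appropriate settings (test pulses
#' at the variant's voltage of maximal activation; 15-ms activation step for
#' the wild-type deactivation protocol, 50 ms for the slow variants),
#' simulates the sweep family, optionally adds recording noise, and writes
#' the CSV + JSON sidecar plus a run manifest.
#'
#' @param variant variant name in the parameter file (see [cav33_params()]).
#' @param protocol one of `"iv"`, `"iv_long"`, `"ssi"`, `"deactivation"`,
#'   `"ap_train"`.
#' @param out_dir output directory (created if needed).
#' @param noise_sd Gaussian noise sd, pA.
#' @param seed noise seed.
#' @param params_file optional alternative parameter JSON.
#' @param dt integration step, ms.
#' @return The sweep-file prefix, invisibly.
#' @export
gen_vclamp <- function(variant, protocol = c("iv", "iv_long", "ssi",
                                             "deactivation", "ap_train"),
                       out_dir, noise_sd = 0, seed = 1L, params_file = NULL,
                       dt = 0.025) {
  protocol <- match.arg(protocol)
  all_params <- cav33_params(file = params_file)
  if (!variant %in% names(all_params)) {
    stop("unknown variant '", variant, "'; available: ",
         paste(names(all_params), collapse = ", "), call. = FALSE)
  }
  params <- all_params[[variant]]
  proto <- switch(
    protocol,
    iv = make_iv_protocol(),
    iv_long = make_iv_protocol(pulse_ms = 5000),
    ssi = make_ssi_protocol(v_test = variant_vmax(params)),
    deactivation = make_deactivation_protocol(
      v_act = variant_vmax(params),
      act_ms = if (identical(variant, "WT")) 15 else 50),
    ap_train = make_ap_train_protocol())
  sweeps <- simulate_sweeps(params, proto, dt = dt)
  if (noise_sd > 0) sweeps <- add_noise(sweeps, noise_sd, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- file.path(out_dir, paste0(variant, "_", protocol))
  write_sweep_set(sweeps, prefix)
  write_manifest(out_dir, command = "gen_vclamp",
                 config = list(variant = variant, protocol = protocol,
                               noise_sd = noise_sd, dt = dt),
                 files = paste0(prefix, c(".csv", ".json")),
                 seeds = list(noise = if (noise_sd > 0) seed else NULL))
  invisible(prefix)
}

#' Run the analysis pipeline on stored sweep sets
#'
#' Reads each sweep-file prefix, dispatches on the protocol name in its
#' sidecar (I-V: peak/IV/Boltzmann/fractional-inactivation analysis; long
#' I-V: decay time constants; SSI: availability curve; deactivation: tail
#' fits; AP train: charge metrics) and writes one TSV of metric rows plus a
#' JSON with the full fit objects.
#'
#' @param prefixes character vector of sweep-file prefixes (as returned by
#'   [gen_vclamp()]).
#' @param out_dir output directory.
#' @return The metrics data frame, invisibly.
#' @export
fit_sweeps <- function(prefixes, out_dir) {
  rows <- list()
  fits <- list()
  add <- function(variant, metric, value, units, protocol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variant = variant, metric = metric, value = value, units = units,
      protocol = protocol)
  }
  for (prefix in prefixes) {
    sweeps <- tryCatch(read_sweep_set(prefix),
                       error = function(e) stop("failed to read '", prefix,
                                                "': ", conditionMessage(e),
                                                call. = FALSE))
    variant <- sweeps$meta$variant
    pname <- sweeps$protocol$name
    if (pname %in% c("iv", "iv_long")) {
      fit <- fit_iv(sweeps)
      fa <- fractional_activation(sweeps, ivfit = fit)
      add(variant, "i_peak", fit$i_peak, "pA", pname)
      add(variant, "v_max", fit$v_max, "mV", pname)
      add(variant, "g_max", fit$g_max, "nS", pname)
      add(variant, "e_rev", fit$e_rev, "mV", pname)
      add(variant, "v_half_act", fa$v_half, "mV", pname)
      add(variant, "k_act", fa$k, "mV", pname)
      s_max <- which.min(fit$i_peak_per_level)
      st <- segment_times(sweeps$protocol, s_max, sweeps$meta$pre_ms)
      seg <- sweeps$protocol$meta$pulse_segment
      win <- c(st$t_on[seg], st$t_off[seg])
      pk <- peak_and_ttp(sweeps$time[[s_max]], sweeps$current[[s_max]], win)
      add(variant, "time_to_peak", pk$time_to_peak, "ms", pname)
      if (diff(win) >= 500) {
        add(variant, "frac_inact_500",
            fractional_inactivation_500(sweeps$time[[s_max]],
                                        sweeps$current[[s_max]], win),
            "fraction", pname)
      }
      if (pname == "iv_long") {
        decay <- fit_exp_decay(sweeps$time[[s_max]], sweeps$current[[s_max]],
                               c(pk$t_peak, win[2]))
        add(variant, "tau_inact_vmax", decay$tau, "ms", pname)
        fits[[paste0(variant, "_decay")]] <- unclass(decay)
      }
      fits[[paste0(variant, "_", pname)]] <-
        list(iv = unclass(fit), activation = unclass(fa))
    } else if (pname == "ssi") {
      fit <- ssi_curve(sweeps)
      add(variant, "v_half_inact", fit$v_half, "mV", pname)
      add(variant, "k_inact", fit$k, "mV", pname)
      fits[[paste0(variant, "_ssi")]] <- unclass(fit)
    } else if (pname == "deactivation") {
      for (s in seq_along(sweeps$current)) {
        fit <- deactivation_tau(sweeps, s)
        add(variant, sprintf("tau_deact_tail%d", s), fit$tau, "ms", pname)
        fits[[sprintf("%s_deact_%d", variant, s)]] <- unclass(fit)
      }
    } else if (pname == "ap_train") {
      met <- ap_clamp_metrics(sweeps)
      add(variant, "persistent_early", mean(met$persistent_pA[2:6]), "pA", pname)
      add(variant, "charge_during_total", sum(met$charge_during_pC), "pC", pname)
      add(variant, "charge_after_total", sum(met$charge_after_pC), "pC", pname)
      fits[[paste0(variant, "_ap")]] <- met
    } else {
      stop("no analysis for protocol '", pname, "' in '", prefix, "'",
           call. = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(out, file.path(out_dir, "metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_manifest(out_dir, command = "fit_sweeps",
                 config = list(prefixes = prefixes),
                 files = unlist(lapply(prefixes, paste0, c(".csv", ".json"))))
  invisible(out)
}

# Printed simulation anchors for the five variants (rheobase nA; train
# duration ms at 0.35 nA; rebound f0 / f_ss Hz; continuous activity).
fig6_reference <- function() {
  data.frame(
    variant = c("WT", "I860M", "M1425I", "I1306T", "I860N"),
    rheobase_nA = c(0.29, 0.22, 0.20, 0.19, 0.18),
    train_duration_ms = c(132.7, 156.3, 243.5, 376.3, 302.9),
    rebound_f0_Hz = c(255.1, 355.5, 338.2, 320.9, 320.3),
    rebound_fss_Hz = c(NA, 91.5, NA, 44.9, 129.2),
    continuous = c(FALSE, TRUE, FALSE, TRUE, TRUE))
}

#' Variant firing-phenotype table (rheobase, train, rebound)
#'
#' Runs, for every variant in the parameter file under the frozen base
#' model: the rheobase grid search from -110 mV, the 200-ms maximal
#' (0.35-nA) injection train, and the 10-s rebound/free-run protocol.
#' Reports the published reference values next to each measurement with
#' pass/fail at the documented tolerances (0.02 nA on rheobase, 15% on
#' durations and frequencies -- base-model reconstruction uncertainty makes
#' tighter bounds untestable).
#'
#' @param out_dir optional output directory for the TSV + manifest.
#' @param variants variant names (default: the five shipped ones).
#' @param i_train training-pulse amplitude, nA (default 0.35).
#' @param total_ms rebound run length, ms (default 10 s).
#' @param dt integration step, ms.
#' @return Data frame with one row per variant.
#' @export
reproduce_fig6 <- function(out_dir = NULL, variants = NULL, i_train = 0.35,
                           total_ms = 10000, dt = 0.0125) {
  params <- cav33_params()
  ref <- fig6_reference()
  if (is.null(variants)) variants <- ref$variant
  cfg <- trn_base_config()
  rows <- lapply(variants, function(vn) {
    model <- build_model(params[[vn]], cfg)
    rheo <- find_rheobase(model, dt = dt)
    i_hold <- holding_current(model, -110)
    tr <- integrate_model(model,
                          stimulus_protocol(c(100, 200, 700),
                                            i_nA = i_hold + c(0, i_train, 0),
                                            clamp_v = c(-110, NA, NA)),
                          dt = dt)
    tm <- train_metrics(tr, window = c(100, Inf))
    rb <- rebound_run(model, total_ms = total_ms, dt = dt)
    data.frame(variant = vn, rheobase_nA = rheo,
               train_duration_ms = tm$train_duration,
               rebound_f0_Hz = rb$metrics$f0,
               rebound_fss_Hz = rb$metrics$f_ss,
               continuous = rb$continuous)
  })
  out <- do.call(rbind, rows)
  out <- merge(out, ref, by = "variant", suffixes = c("", "_ref"),
               sort = FALSE)
  out$rheobase_pass <- abs(out$rheobase_nA - out$rheobase_nA_ref) <= 0.02
  out$duration_pass <- abs(out$train_duration_ms - out$train_duration_ms_ref) <=
    0.15 * out$train_duration_ms_ref
  out$f0_pass <- abs(out$rebound_f0_Hz - out$rebound_f0_Hz_ref) <=
    0.15 * out$rebound_f0_Hz_ref
  out$continuous_pass <- out$continuous == out$continuous_ref
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(out_dir, "fig6_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_manifest(out_dir, command = "reproduce_fig6",
                   config = c(cfg, list(i_train = i_train, dt = dt)))
  }
  out
}
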