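#' Simulate whole-cell currents under a voltage-clamp protocol
#'
#' Deterministic forward model of the channel under a command-voltage
#' protocol: the gates are equilibrated at the holding potential, relaxed
#' along the command with exact exponential updates on a fine time grid, and
#' the ohmic current is recorded at the protocol's sample interval.  Each
#' recorded sweep starts with `pre_ms` of holding so the first samples show
#' the equilibrium holding current.
#'
#' @param params a [gating_params()] object (whole-cell mode: `g_max` in nS,
#'   currents in pA).
#' @param protocol a [voltage_protocol()].
#' @param dt integration step, ms (> 0 and <= the protocol sample interval;
#'   segment edges are rounded to the dt grid).
#' @param pre_ms recorded holding window before the first segment, ms.
#' @return An object of class `sweep_set`: lists `time`, `current`,
#'   `voltage` (one numeric vector per sweep), the protocol, and `meta`
#'   (variant, dt, pre_ms, noise sd/seed once noise is added).
#' @export
simulate_sweeps <- function(params, protocol, dt = 0.025, pre_ms = 20) {
  stopifnot(inherits(params, "gating_params"),
            inherits(protocol, "voltage_protocol"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  si <- protocol$sample_interval
  if (dt > si + 1e-12) stop("dt must not exceed the sample interval", call. = FALSE)
  thin <- max(1L, round(si / dt))
  dt_eff <- si / thin

  hold <- protocol$holding
  m0 <- m_inf(hold, params)
  h0 <- h_inf(hold, params)
  mt <- m_tau_table(params)
  ht <- params$tau_inact_table

  time <- current <- voltage <- vector("list", length(protocol$sweeps))
  for (s in seq_along(protocol$sweeps)) {
    sw <- protocol$sweeps[[s]]
    if (identical(sw$type, "segments")) {
      n_per <- round(c(pre_ms, sw$segments[, 2]) / dt_eff)
      v_cmd <- rep(c(hold, sw$segments[, 1]), times = n_per)
    } else {
      n_pre <- round(pre_ms / dt_eff)
      t_sw <- (seq_along(sw$v) - 1L) * sw$sample_interval
      t_fine <- seq(0, t_sw[length(t_sw)], by = dt_eff)
      v_fine <- stats::approx(t_sw, sw$v, xout = t_fine)$y
      v_cmd <- c(rep(hold, n_pre), v_fine[-1L])
    }
    v_cmd <- c(hold, v_cmd)  # state at t = 0 is the holding equilibrium
    tr <- cpp_gate_trace(v_cmd, dt_eff, m0, h0,
                         params$v_half_act, params$k_act,
                         params$v_half_inact, params$k_inact, params$p_act,
                         mt[, 1], mt[, 2], ht[, 1], ht[, 2],
                         params$g_max, params$e_rev)
    idx <- seq(1L, length(v_cmd), by = thin)
    time[[s]] <- (idx - 1L) * dt_eff
    current[[s]] <- tr$i[idx]
    voltage[[s]] <- v_cmd[idx]
  }
  structure(list(protocol = protocol, time = time, current = current,
                 voltage = voltage,
                 meta = list(variant = params$name, dt = dt_eff,
                             pre_ms = pre_ms, noise_sd = 0, seed = NA)),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s under '%s': %d sweeps, %d samples each, noise sd %g pA\n",
              x$meta$variant, x$protocol$name, length(x$current),
              length(x$current[[1]]), x$meta$noise_sd))
  invisible(x)
}

#' Add Gaussian recording noise to a sweep set
#'
#' Independent white Gaussian noise per sample, reproducible for a given
#' seed.  The global RNG state is left untouched.
#'
#' @param sweeps a `sweep_set`.
#' @param sd noise standard deviation, pA (>= 0).
#' @param seed integer seed recorded in the sweep-set metadata.
#' @return The noisy `sweep_set`.
#' @export
add_noise <- function(sweeps, sd, seed = 1L) {
  stopifnot(inherits(sweeps, "sweep_set"), sd >= 0)
  if (sd == 0) return(sweeps)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sweeps$current <- lapply(sweeps$current, function(i) i + stats::rnorm(length(i), 0, sd))
  sweeps$meta$noise_sd <- sd
  sweeps$meta$seed <- seed
  sweeps
}

#' Write / read a sweep set as CSV plus JSON sidecar
#'
#' The CSV has columns `sweep, time_ms, v_mV, i_pA` (one block per sweep);
#' the sidecar (`<prefix>.json`) carries the protocol definition and the
#' metadata needed to re-analyse the traces.  The reader accepts comma- or
#' tab-delimited files.
#'
#' @param sweeps a `sweep_set`.
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return `write_sweep_set`: the prefix, invisibly. `read_sweep_set`: the
#'   `sweep_set`.
#' @export
write_sweep_set <- function(sweeps, prefix) {
  stopifnot(inherits(sweeps, "sweep_set"))
  df <- do.call(rbind, lapply(seq_along(sweeps$current), function(s) {
    data.frame(sweep = s, time_ms = sweeps$time[[s]],
               v_mV = sweeps$voltage[[s]], i_pA = sweeps$current[[s]])
  }))
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  proto <- sweeps$protocol
  side <- list(
    protocol = list(
      name = proto$name, holding = proto$holding,
      sample_interval = proto$sample_interval,
      inter_sweep_interval = proto$inter_sweep_interval,
      meta = proto$meta,
      sweeps = lapply(proto$sweeps, function(sw) {
        if (identical(sw$type, "segments"))
          list(type = "segments", level = sw$segments[, 1],
               duration = sw$segments[, 2])
        else list(type = "sampled", v = sw$v,
                  sample_interval = sw$sample_interval)
      })),
    meta = sweeps$meta)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  first <- readLines(csv, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(csv, header = TRUE, sep = sep)
  need <- c("sweep", "time_ms", "v_mV", "i_pA")
  if (!all(need %in% names(df))) {
    stop("malformed sweep CSV '", csv, "': need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  p <- side$protocol
  sweeps_def <- lapply(seq_len(nrow_of(p$sweeps)), function(i) {
    sw <- index_rec(p$sweeps, i)
    if (identical(sw$type, "segments"))
      seg_sweep(unlist(sw$level), unlist(sw$duration))
    else list(type = "sampled", v = unlist(sw$v),
              sample_interval = sw$sample_interval)
  })
  proto <- voltage_protocol(p$name, sweeps_def, holding = p$holding,
                            sample_interval = p$sample_interval,
                            inter_sweep_interval = p$inter_sweep_interval,
                            meta = as.list(p$meta))
  ids <- sort(unique(df$sweep))
  split_by <- function(col) lapply(ids, function(s) df[[col]][df$sweep == s])
  structure(list(protocol = proto, time = split_by("time_ms"),
                 current = split_by("i_pA"), voltage = split_by("v_mV"),
                 meta = as.list(side$meta)),
            class = "sweep_set")
}

# jsonlite may simplify a homogeneous list of records into a data frame;
# these two helpers index either representation uniformly.
nrow_of <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
index_rec <- function(x, i) if (is.data.frame(x)) lapply(x, `[[`, i) else x[[i]]
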