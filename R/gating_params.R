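#' Gating parameters for a Cav3.3-type channel variant
#'
#' Bundles the Boltzmann steady-state parameters, tabulated voltage-dependent
#' time constants, maximal conductance and reversal potential that define one
#' channel variant in the Hodgkin-Huxley-style gate model \eqn{I = \bar g\,
#' m^{p}\,h\,(V - E_{rev})}.
#'
#' Time constants are supplied as tables of (voltage mV, tau ms) pairs and
#' interpolated linearly with constant extrapolation beyond the table edges
#' (see [tau_gate()]).  When a deactivation table is given it describes the
#' m-gate at hyperpolarized voltages (tail-current kinetics); it is merged
#' with the activation table into a single m-gate tau curve, so its voltages
#' must all lie below the activation table's.
#'
#' @param name variant label, e.g. `"WT"`, `"I860N"`.
#' @param v_half_act,k_act midpoint (mV) and slope factor (mV, > 0) of the
#'   steady-state activation Boltzmann.
#' @param v_half_inact,k_inact midpoint and slope factor (mV, > 0) of the
#'   steady-state inactivation Boltzmann.
#' @param tau_act_table,tau_inact_table two-column matrices (or data frames)
#'   of (voltage mV, tau ms) with strictly increasing voltages, at least two
#'   rows each.
#' @param tau_deact_table optional table for the m-gate at hyperpolarized
#'   voltages (deactivation); all voltages must be below the activation
#'   table's smallest voltage.
#' @param p_act integer activation-gate exponent (>= 1, default 2: the
#'   standard m^2 h T-current formulation).
#' @param g_max maximal conductance: nS in whole-cell mode, mS/cm^2 when the
#'   parameters are used inside a neuron model (density mode).
#' @param e_rev reversal potential (mV), default +120.
#'
#' @return An object of class `gating_params`.
#' @seealso [cav33_params()] for the shipped variant library,
#'   [shift_params()] for derived variants.
#' @export
gating_params <- function(name, v_half_act, k_act, v_half_inact, k_inact,
                          tau_act_table, tau_inact_table,
                          tau_deact_table = NULL,
                          p_act = 2, g_max = 20, e_rev = 120) {
  stopifnot(is.character(name), length(name) == 1L)
  for (x in c(v_half_act, k_act, v_half_inact, k_inact, g_max, e_rev, p_act)) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("gating parameters must be finite scalars", call. = FALSE)
    }
  }
  if (k_act <= 0 || k_inact <= 0) stop("slope factors must be > 0", call. = FALSE)
  if (p_act < 1 || p_act != round(p_act)) stop("p_act must be an integer >= 1", call. = FALSE)
  if (g_max < 0) stop("g_max must be >= 0", call. = FALSE)

  tau_act_table <- check_tau_table(tau_act_table, "tau_act_table")
  tau_inact_table <- check_tau_table(tau_inact_table, "tau_inact_table")
  if (!is.null(tau_deact_table)) {
    tau_deact_table <- check_tau_table(tau_deact_table, "tau_deact_table")
    if (max(tau_deact_table[, 1]) >= min(tau_act_table[, 1])) {
      stop("tau_deact_table voltages must all lie below the tau_act_table range",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, v_half_act = v_half_act, k_act = k_act,
         v_half_inact = v_half_inact, k_inact = k_inact,
         p_act = as.integer(p_act),
         tau_act_table = tau_act_table, tau_inact_table = tau_inact_table,
         tau_deact_table = tau_deact_table, g_max = g_max, e_rev = e_rev),
    class = "gating_params")
}

check_tau_table <- function(tab, what) {
  tab <- as.matrix(tab)
  if (!is.numeric(tab) || ncol(tab) != 2L || nrow(tab) < 2L) {
    stop(what, " must be a numeric table of >= 2 (voltage, tau) rows",
         call. = FALSE)
  }
  if (anyNA(tab) || any(!is.finite(tab))) stop(what, " contains non-finite values", call. = FALSE)
  if (any(diff(tab[, 1]) <= 0)) stop(what, " voltages must be strictly increasing", call. = FALSE)
  if (any(tab[, 2] <= 0)) stop(what, " time constants must be > 0", call. = FALSE)
  dimnames(tab) <- list(NULL, c("v", "tau"))
  tab
}

#' @export
print.gating_params <- function(x, ...) {
  cat(sprintf("<gating_params> %s\n", x$name))
  cat(sprintf("  activation:   V1/2 = %7.2f mV, k = %.2f mV, m^%d\n",
              x$v_half_act, x$k_act, x$p_act))
  cat(sprintf("  inactivation: V1/2 = %7.2f mV, k = %.2f mV\n",
              x$v_half_inact, x$k_inact))
  cat(sprintf("  g_max = %.3g, E_rev = %+.0f mV\n", x$g_max, x$e_rev))
  cat(sprintf("  tau tables: act %d pts, inact %d pts%s\n",
              nrow(x$tau_act_table), nrow(x$tau_inact_table),
              if (is.null(x$tau_deact_table)) "" else
                sprintf(", deact %d pts", nrow(x$tau_deact_table))))
  invisible(x)
}

# Effective m-gate tau table: deactivation table (hyperpolarized) merged
# below the activation table when present.
m_tau_table <- function(params) {
  if (is.null(params$tau_deact_table)) return(params$tau_act_table)
  rbind(params$tau_deact_table, params$tau_act_table)
}

#' Shift and scale gating parameters
#'
#' Returns a copy of `params` with the activation and inactivation midpoints
#' shifted (negative = hyperpolarizing) and the inactivation time-constant
#' table scaled.  Used to express variants as deltas from a reference
#' parameter set; zero deltas with unit scaling is the identity.
#'
#' @param params a [gating_params()] object.
#' @param d_act,d_inact midpoint shifts in mV.
#' @param scale_tau_inact multiplicative factor (> 0) on the inactivation
#'   tau table.
#' @param name optional new variant label.
#' @return A `gating_params` object.
#' @export
shift_params <- function(params, d_act = 0, d_inact = 0, scale_tau_inact = 1,
                         name = NULL) {
  stopifnot(inherits(params, "gating_params"),
            is.finite(d_act), is.finite(d_inact), scale_tau_inact > 0)
  out <- params
  out$v_half_act <- params$v_half_act + d_act
  out$v_half_inact <- params$v_half_inact + d_inact
  out$tau_inact_table[, 2] <- params$tau_inact_table[, 2] * scale_tau_inact
  if (!is.null(name)) out$name <- name
  out
}

#' Load the shipped Cav3.3 variant parameter library
#'
#' Reads the packaged gating-parameter file covering the wild-type channel
#' and the gain-of-function variants I860N, I860M, I1306T and M1425I.  The
#' wild-type baseline uses literature-typical whole-cell Cav3.3 values; each
#' variant applies the reported midpoint shifts and kinetic slowings (see the
#' file's provenance notes and the package vignette: the underlying patch
#' clamp data are not public, so the file is a calibrated synthetic
#' transcription).
#'
#' @param variant optional variant name; when given, returns that single
#'   [gating_params()] object instead of the full list.
#' @param file path to a parameter JSON file; defaults to the packaged one.
#' @return A named list of `gating_params` (or a single object).
#' @export
cav33_params <- function(variant = NULL, file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "cav33_variants.json", package = "gatesim")
  }
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  recs <- raw$variants
  out <- list()
  for (nm in names(recs)) {
    r <- recs[[nm]]
    out[[nm]] <- gating_params(
      name = nm,
      v_half_act = r$v_half_act, k_act = r$k_act,
      v_half_inact = r$v_half_inact, k_inact = r$k_inact,
      tau_act_table = do.call(cbind, r$tau_act_table),
      tau_inact_table = do.call(cbind, r$tau_inact_table),
      tau_deact_table = if (!is.null(r$tau_deact_table))
        do.call(cbind, r$tau_deact_table),
      p_act = r$p_act, g_max = r$g_max, e_rev = r$e_rev)
  }
  if (is.null(variant)) return(out)
  if (!variant %in% names(out)) {
    stop("unknown variant '", variant, "'; available: ",
         paste(names(out), collapse = ", "), call. = FALSE)
  }
  out[[variant]]
}
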