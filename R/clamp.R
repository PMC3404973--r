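# Driving the Markov chain through clamp protocol families and turning
# occupancies into measurable currents.

#' Current-conversion settings for clamp simulations
#'
#' Defaults reflect the recording solutions of the experiments the
#' simulations emulate: external K 4 mM, internal K 130 mM at 23 C, giving
#' `E_K` about -88.8 mV, and the conventional conductance scaling
#' `sqrt(Ko / 5.4)`. The conductance density default is the endocardial
#' ventricular value of the Ten Tusscher-Panfilov model; none of these
#' were published for the original simulations, so all are configurable.
#'
#' @param g_Kr Maximal conductance density, nS/pF.
#' @param Ko External potassium, mM (sets the default `Ko_factor`).
#' @param E_K Potassium reversal potential, mV.
#' @param Ko_factor Dimensionless conductance scaling.
#' @param capacitance Cell capacitance, pF, or `NULL`. When given, simulated
#'   currents are reported in pA (density times capacitance) instead of
#'   pA/pF; the experimental cells ranged between 10 and 20 pF.
#' @return An object of class `current_config`.
#' @export
current_config <- function(g_Kr = 0.153, Ko = 4,
                           E_K = nernst_potential(Ko, 130, temperature = 23),
                           Ko_factor = sqrt(Ko / 5.4),
                           capacitance = NULL) {
  stopifnot(g_Kr >= 0, Ko > 0, is.finite(E_K), Ko_factor > 0)
  if (!is.null(capacitance)) stopifnot(capacitance > 0)
  structure(list(g_Kr = g_Kr, Ko = Ko, E_K = E_K, Ko_factor = Ko_factor,
                 capacitance = capacitance),
            class = "current_config")
}

#' Simulate the current of one clamp sweep
#'
#' Integrates the occupancies along the protocol and converts the open
#' probability to current with [markov_current()]. The initial state
#' defaults to the steady state at the protocol's first (holding) voltage.
#'
#' @param protocol A [voltage_protocol()].
#' @param params A [rate_constant_set()].
#' @param config A [current_config()].
#' @param init Optional initial [occupancy_state()].
#' @param dt_out Output sampling interval, ms.
#' @param method Integration backend, see [integrate_occupancy()].
#' @return A [current_trace()] annotated with the protocol segments. The
#'   final occupancy is attached as attribute `"final_state"` so families
#'   can chain sweeps.
#' @export
simulate_sweep <- function(protocol, params, config = current_config(),
                           init = NULL, dt_out = NULL, method = "exact") {
  occ <- integrate_occupancy(protocol, params, init = init,
                             dt_out = dt_out, method = method)
  I <- config$g_Kr * config$Ko_factor * occ$O * (occ$voltage - config$E_K)
  unit <- "pA/pF"
  if (!is.null(config$capacitance)) {
    I <- I * config$capacitance
    unit <- "pA"
  }
  starts <- cumsum(c(0, protocol$segments$duration))
  segs <- data.frame(start = starts[-length(starts)], end = starts[-1L],
                     voltage = protocol$segments$voltage)
  # the output grid may stop dt short of the protocol end; keep the
  # final annotation inside the trace span
  segs$end[nrow(segs)] <- min(segs$end[nrow(segs)], max(occ$time))
  tr <- current_trace(occ$time, I, unit = unit, segments = segs,
                      label = protocol$label, condition = params$condition)
  attr(tr, "final_state") <- occupancy_state(
    unlist(occ[nrow(occ), herg_states]))
  attr(tr, "occupancy") <- occ
  tr
}

#' Simulate a whole protocol family
#'
#' Sweeps are run sequentially from the steady state at the holding
#' potential; between sweeps the channel relaxes at the holding potential
#' for the family's inter-sweep interval (it is simulated, not assumed
#' complete), so slow accumulation across sweeps is captured.
#'
#' @param family A [protocol_family()].
#' @param params A [rate_constant_set()].
#' @param config A [current_config()].
#' @param dt_out Output sampling interval, ms.
#' @param method Integration backend.
#' @return An object of class `clamp_family`: a list with the `traces`
#'   (one [current_trace()] per sweep, named by sweep voltage), the
#'   `family`, the `condition` and the `config`.
#' @export
simulate_family <- function(family, params, config = current_config(),
                            dt_out = NULL, method = "exact") {
  stopifnot(inherits(family, "protocol_family"),
            inherits(params, "rate_constant_set"))
  hold_V <- family$template$segments$voltage[1L]
  state <- herg_steady_state(hold_V, params)
  traces <- vector("list", length(family$sweep_voltages))
  for (i in seq_along(family$sweep_voltages)) {
    pr <- sweep_protocol(family, i)
    tr <- tryCatch(
      simulate_sweep(pr, params, config, init = state,
                     dt_out = dt_out, method = method),
      error = function(e) stop("simulate_family: sweep ", i, " (",
                               family$sweep_voltages[i], " mV): ",
                               conditionMessage(e), call. = FALSE))
    traces[[i]] <- tr
    state <- attr(tr, "final_state")
    if (family$interpulse > 0)
      state <- occupancy_state(
        propagate_exact(hold_V, params, state, family$interpulse)[, 1L])
  }
  names(traces) <- sprintf("%+g", family$sweep_voltages)
  structure(list(traces = traces, family = family,
                 condition = params$condition, config = config),
            class = "clamp_family")
}

#' @export
print.clamp_family <- function(x, ...) {
  cat(sprintf("<clamp_family> %s: %d sweep(s) of '%s'\n", x$condition,
              length(x$traces), x$family$template$label))
  invisible(x)
}

#' Measurement tables from a simulated family
#'
#' `end_pulse_currents()` tabulates the mean current over the final window
#' of the varying (step) segment per sweep; `tail_peaks()` tabulates the
#' signed peak of a tail/test segment per sweep.
#'
#' @param fam A `clamp_family` from [simulate_family()].
#' @param segment Segment index to measure; defaults to the varying segment
#'   for `end_pulse_currents()` and the one after it for `tail_peaks()`.
#' @param window,skip Passed to the measurement operators.
#' @return A data frame with columns `voltage` and `current` (and `time`
#'   for peaks).
#' @export
end_pulse_currents <- function(fam, segment = NULL, window = 50) {
  stopifnot(inherits(fam, "clamp_family"))
  if (is.null(segment)) segment <- fam$family$vary_segment
  data.frame(
    voltage = fam$family$sweep_voltages,
    current = vapply(fam$traces, measure_end_pulse, numeric(1L),
                     segment = segment, window = window)
  )
}

#' @rdname end_pulse_currents
#' @export
tail_peaks <- function(fam, segment = NULL, skip = 1) {
  stopifnot(inherits(fam, "clamp_family"))
  if (is.null(segment)) segment <- fam$family$vary_segment + 1L
  pk <- lapply(fam$traces, measure_tail_peak, segment = segment, skip = skip)
  data.frame(voltage = fam$family$sweep_voltages,
             current = vapply(pk, `[[`, numeric(1L), "current"),
             time = vapply(pk, `[[`, numeric(1L), "time"))
}
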