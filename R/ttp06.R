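# Human endocardial ventricular action-potential model (Ten Tusscher &
# Panfilov 2006 formulation) with the rapid delayed rectifier carried by
# the five-state Markov hERG chain. Paced simulation and action-potential
# duration metrics.

#' State-variable names of the ventricular cell model
#'
#' Membrane potential, intracellular ion concentrations, the
#' Hodgkin-Huxley gates of the endocardial model, the ryanodine-receptor
#' recovery variable, and the five Markov occupancies that replace the
#' original I_Kr activation/inactivation gates.
#'
#' @format Character vector of length 22.
#' @export
ttp06_state_names <- c("V", "Nai", "Ki", "Cai", "CaSR", "CaSS",
                       "m", "h", "j", "d", "f", "f2", "fCass",
                       "r", "s", "xs", "Rbar",
                       "C1", "C2", "C3", "O", "I")

# rate_constant_set -> flat 24-vector for the compiled right-hand side
flatten_rates <- function(params) {
  stopifnot(inherits(params, "rate_constant_set"))
  as.numeric(unlist(lapply(params$rates[herg_transitions],
                           function(l) c(l$a, l$b, l$v0))))
}

#' Default initial state of the paced cell
#'
#' Resting values of the endocardial model with the Markov block
#' initialised at its steady state for the resting potential. Intended as
#' the starting point of a pre-pacing run, not as an exact fixed point.
#'
#' @param params A [rate_constant_set()] for the Markov I_Kr block.
#' @param V Initial membrane potential, mV.
#' @return Named numeric state vector of length 22.
#' @export
ttp06_initial_state <- function(params, V = -86.2) {
  y <- c(V = V, Nai = 11.6, Ki = 138.3, Cai = 0.0002, CaSR = 1.3,
         CaSS = 0.0002, m = 0, h = 0.75, j = 0.75, d = 0, f = 1, f2 = 1,
         fCass = 1, r = 0, s = 1, xs = 0, Rbar = 1,
         herg_steady_state(V, params))
  names(y) <- ttp06_state_names
  y
}

#' Time derivative of the ventricular cell state
#'
#' Evaluates all membrane currents of the endocardial model with
#' `I_Kr = g_Kr * sqrt(Ko / 5.4) * p_O * (V - E_K)`, where the open
#' probability `p_O` comes from the Markov block driven by `params`, and
#' returns the full state derivative (charge-conservation form of
#' `dV/dt`).
#'
#' @param state Named state vector of length 22 (see
#'   [ttp06_state_names]).
#' @param params A [rate_constant_set()].
#' @param g_Kr I_Kr conductance density, nS/pF; the endocardial default of
#'   the original formulation.
#' @param istim Applied stimulus current, pA/pF (negative = depolarising).
#' @return A list with `derivatives` (named, 1/ms) and `currents` (named,
#'   pA/pF).
#' @export
cell_rhs <- function(state, params, g_Kr = 0.153, istim = 0) {
  stopifnot(length(state) == 22L)
  if (any(!is.finite(state))) {
    bad <- ttp06_state_names[which(!is.finite(state))[1L]]
    stop("cell_rhs: non-finite state variable '", bad, "'")
  }
  res <- .ttp06_rhs_cpp(as.numeric(state), flatten_rates(params),
                        g_Kr, istim)
  dy <- as.numeric(res$dy)
  names(dy) <- ttp06_state_names
  list(derivatives = dy, currents = res$currents)
}

#' Pacing specification for action-potential simulations
#'
#' @param cycle_length Pacing cycle length, ms.
#' @param amplitude Stimulus amplitude, pA/pF (negative = depolarising);
#'   -52 pA/pF for 1 ms is a conventional suprathreshold choice for this
#'   model.
#' @param duration Stimulus duration, ms.
#' @param beats Number of paced beats.
#' @param record Which beat indices to record in full.
#' @return A list of class `pacing_spec`.
#' @export
pacing_spec <- function(cycle_length = 1000, amplitude = -52,
                        duration = 1, beats = 50,
                        record = beats) {
  stopifnot(cycle_length > 0, duration > 0, duration < cycle_length,
            beats >= 1, all(record >= 1), all(record <= beats))
  structure(list(cycle_length = cycle_length, amplitude = amplitude,
                 duration = duration, beats = as.integer(beats),
                 record = as.integer(sort(unique(record)))),
            class = "pacing_spec")
}

#' Simulate a paced train of action potentials
#'
#' Integrates the cell model beat by beat with the adaptive stiff solver
#' (the Markov block under the control rates carries an extremely fast
#' eigenmode, so a stiff method is required). Each beat is split at the
#' stimulus edge so the solver never steps across the discontinuity. The
#' membrane potential of every beat is kept (coarsely sampled) for
#' beat-to-beat duration metrics; the beats named in `pacing$record` are
#' recorded in full.
#'
#' @param params A [rate_constant_set()] for the Markov I_Kr block.
#' @param pacing A [pacing_spec()].
#' @param g_Kr I_Kr conductance density, nS/pF.
#' @param init Initial state; default [ttp06_initial_state()].
#' @param dt_record Output interval for recorded beats, ms.
#' @param dt_coarse Output interval for the per-beat V traces, ms.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `paced_ap`: per-beat APD90/APD50/diastolic
#'   tables, the recorded beats as data frames (`time` relative to the
#'   beat's stimulus, all state variables), the final state, pacing and
#'   condition metadata, and a `no_ap` flag marking beats whose peak
#'   potential never exceeded 0 mV.
#' @export
simulate_paced <- function(params, pacing = pacing_spec(), g_Kr = 0.153,
                           init = NULL, dt_record = 0.1, dt_coarse = 0.5,
                           rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(pacing, "pacing_spec"))
  if (is.null(init)) init <- ttp06_initial_state(params)
  stopifnot(length(init) == 22L)
  mr <- flatten_rates(params)
  rhs <- function(t, y, p) {
    list(as.numeric(.ttp06_rhs_cpp(y, mr, g_Kr, p)$dy))
  }
  solve_span <- function(y, times, istim) {
    out <- deSolve::lsoda(y, times, rhs, istim, rtol = rtol, atol = atol,
                          hmax = 1)
    if (attr(out, "istate")[1L] < 0)
      stop("simulate_paced: solver failure (t = ",
           utils::tail(times, 1L), " ms of beat)")
    out
  }

  y <- as.numeric(init)
  cl <- pacing$cycle_length
  apd90 <- apd50 <- dia <- peak <- rep(NA_real_, pacing$beats)
  no_ap <- logical(pacing$beats)
  recorded <- list()
  for (b in seq_len(pacing$beats)) {
    full <- b %in% pacing$record
    dt1 <- if (full) min(dt_record, pacing$duration / 4) else
      pacing$duration / 2
    t1 <- unique(c(seq(0, pacing$duration, by = dt1), pacing$duration))
    o1 <- solve_span(y, t1, pacing$amplitude)
    y <- o1[nrow(o1), -1L]
    dt2 <- if (full) dt_record else dt_coarse
    t2 <- unique(c(seq(pacing$duration, cl, by = dt2), cl))
    o2 <- solve_span(y, t2, 0)
    y <- o2[nrow(o2), -1L]

    tb <- c(o1[, 1L], o2[-1L, 1L])
    Vb <- c(o1[, 2L], o2[-1L, 2L])
    dia[b] <- Vb[1L]
    peak[b] <- max(Vb)
    no_ap[b] <- peak[b] <= 0
    if (!no_ap[b]) {
      apd90[b] <- tryCatch(apd(tb, Vb, 0.9), error = function(e) NA_real_)
      apd50[b] <- tryCatch(apd(tb, Vb, 0.5), error = function(e) NA_real_)
    }
    if (full) {
      df <- as.data.frame(rbind(o1, o2[-1L, ]))
      names(df) <- c("time", ttp06_state_names)
      recorded[[as.character(b)]] <- df
    }
  }
  structure(list(
    beats = data.frame(beat = seq_len(pacing$beats), apd90 = apd90,
                       apd50 = apd50, diastolic = dia, peak = peak,
                       no_ap = no_ap),
    recorded = recorded, final_state = stats::setNames(y, ttp06_state_names),
    pacing = pacing, g_Kr = g_Kr, condition = params$condition),
    class = "paced_ap")
}

#' @export
print.paced_ap <- function(x, ...) {
  last <- x$beats[nrow(x$beats), ]
  cat(sprintf("<paced_ap> %s: %d beat(s) at CL %g ms\n", x$condition,
              nrow(x$beats), x$pacing$cycle_length))
  if (last$no_ap) {
    cat("  final beat elicited NO action potential\n")
  } else {
    cat(sprintf("  final beat: APD90 = %.1f ms, APD50 = %.1f ms, rest = %.1f mV, peak = %.1f mV\n",
                last$apd90, last$apd50, last$diastolic, last$peak))
  }
  invisible(x)
}

#' @export
plot.paced_ap <- function(x, beat = NULL, ...) {
  if (!length(x$recorded)) stop("no recorded beats to plot")
  if (is.null(beat)) beat <- names(x$recorded)[length(x$recorded)]
  df <- x$recorded[[as.character(beat)]]
  plot(df$time, df$V, type = "l", xlab = "time (ms)", ylab = "V (mV)",
       main = paste0(x$condition, ", beat ", beat), ...)
  invisible(x)
}

#' Action-potential duration at a repolarisation fraction
#'
#' Duration from the maximal upstroke velocity to the repolarisation
#' crossing of `V_rest + (1 - fraction) * amplitude`, where `V_rest` is
#' the potential at the start of the trace and the amplitude is
#' `peak - rest`; the crossing is located by linear interpolation between
#' samples.
#'
#' @param time,V The action-potential trace (ms, mV); `time` may start
#'   anywhere. Alternatively `time` may be a data frame with columns
#'   `time` and `V`.
#' @param fraction Repolarisation fraction in (0, 1); 0.9 for APD90.
#' @return Duration in ms.
#' @export
apd <- function(time, V = NULL, fraction = 0.9) {
  if (is.data.frame(time)) { V <- time$V; time <- time$time }
  stopifnot(length(time) == length(V), length(time) > 3L,
            fraction > 0, fraction < 1)
  rest <- V[1L]
  peak <- max(V)
  amp <- peak - rest
  if (amp <= 0) stop("apd: no depolarisation in trace")
  dvdt <- diff(V) / diff(time)
  i_up <- which.max(dvdt)
  t_up <- time[i_up]
  thr <- rest + (1 - fraction) * amp
  i_peak <- which.max(V)
  cross <- NA_real_
  for (i in seq(i_peak, length(V) - 1L)) {
    if (V[i] > thr && V[i + 1L] <= thr) {
      cross <- time[i] + (time[i + 1L] - time[i]) *
        (V[i] - thr) / (V[i] - V[i + 1L])
      break
    }
  }
  if (is.na(cross))
    stop("apd: repolarisation never crosses the ",
         fraction * 100, "% level")
  cross - t_up
}

#' Summary metrics of one action potential
#'
#' @param trace Data frame with columns `time` (ms) and `V` (mV), e.g. a
#'   recorded beat of [simulate_paced()].
#' @return A list with `apd90`, `apd50` (ms), `resting` and `peak`
#'   potentials (mV) and `dvdt_max` (mV/ms).
#' @export
ap_metrics <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("time", "V") %in% names(trace)))
  list(apd90 = apd(trace$time, trace$V, 0.9),
       apd50 = apd(trace$time, trace$V, 0.5),
       resting = trace$V[1L],
       peak = max(trace$V),
       dvdt_max = max(diff(trace$V) / diff(trace$time)))
}
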