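# Master-equation machinery for the five-state gating chain:
# generator matrix, steady states, and occupancy integration under
# piecewise-constant voltage commands.

#' Validate a vector of state occupancies
#'
#' An occupancy state holds the five probabilities of C1, C2, C3, O and I.
#' Each must lie in [0, 1] (up to `tol`) and they must sum to 1 within
#' `tol`.
#'
#' @param p Numeric vector of length 5 (names optional).
#' @param tol Tolerance on the probability constraints.
#' @return The validated, named occupancy vector.
#' @export
occupancy_state <- function(p, tol = 1e-8) {
  stopifnot(is.numeric(p), length(p) == 5L)
  if (any(!is.finite(p))) stop("occupancy_state: non-finite probability")
  if (any(p < -tol) || any(p > 1 + tol))
    stop("occupancy_state: probabilities outside [0, 1]")
  if (abs(sum(p) - 1) > tol)
    stop("occupancy_state: probabilities sum to ", sum(p), ", not 1")
  p <- pmin(pmax(as.numeric(p), 0), 1)
  names(p) <- herg_states
  p
}

#' Generator matrix of the gating chain at a fixed voltage
#'
#' Assembles the eight transition rates into the 5x5 master-equation
#' generator `Q` with the convention `dp/dt = Q p`: `Q[j, i]` is the rate
#' from state i to state j for adjacent states of the linear chain
#' `C1 <-> C2 <-> C3 <-> O <-> I`, the diagonal holds minus the total rate
#' out of each state, and all other entries are exactly zero. Every column
#' sums to zero, which is what conserves total probability.
#'
#' @param V Membrane potential, mV; finite scalar.
#' @param params A [rate_constant_set()].
#' @return A 5x5 matrix with `herg_states` dimnames.
#' @export
herg_generator <- function(V, params) {
  stopifnot(is.numeric(V), length(V) == 1L, is.finite(V),
            inherits(params, "rate_constant_set"))
  k <- eval_rates(params, V)
  Q <- matrix(0, 5L, 5L, dimnames = list(herg_states, herg_states))
  up <- k[c("k12", "k23", "k34", "k45")]
  dn <- k[c("k21", "k32", "k43", "k54")]
  for (i in 1:4) {
    Q[i + 1L, i] <- up[i]
    Q[i, i + 1L] <- dn[i]
  }
  diag(Q) <- -colSums(Q)
  Q
}

#' Steady-state occupancy at a fixed voltage
#'
#' For this birth-death chain the stationary distribution has the closed
#' form `p[i+1] / p[i] = k(i, i+1) / k(i+1, i)` (detailed balance), which is
#' evaluated directly and normalised. Used to initialise every clamp
#' simulation at the holding potential.
#'
#' @inheritParams herg_generator
#' @return An [occupancy_state()].
#' @export
herg_steady_state <- function(V, params) {
  stopifnot(is.numeric(V), length(V) == 1L, is.finite(V),
            inherits(params, "rate_constant_set"))
  k <- eval_rates(params, V)
  ratios <- c(1,
              k[["k12"]] / k[["k21"]],
              k[["k23"]] / k[["k32"]],
              k[["k34"]] / k[["k43"]],
              k[["k45"]] / k[["k54"]])
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("herg_steady_state: degenerate chain at V = ", V,
         " mV (a transition rate underflowed or overflowed)")
  p <- cumprod(ratios)
  occupancy_state(p / sum(p))
}

# Spectral propagator at fixed voltage. The generator of a birth-death
# chain is symmetrizable by the square root of its stationary distribution,
# so the eigendecomposition can be done on a symmetric matrix; this stays
# accurate even with the extremely stiff published k32 (~1.6e7/ms), where
# general dense matrix exponentials lose digits on long segments.
# Returns the 5 x length(t_rel) occupancy matrix.
propagate_exact <- function(V, params, p0, t_rel) {
  pi_ss <- herg_steady_state(V, params)
  d <- sqrt(pi_ss)
  Q <- herg_generator(V, params)
  S <- Q * outer(1 / d, d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  w <- crossprod(e$vectors, p0 / d)
  P <- d * (e$vectors %*% (exp(outer(e$values, t_rel)) * as.vector(w)))
  # clip the tiny negative round-off and renormalise
  P[P < 0] <- 0
  sweep(P, 2L, colSums(P), "/")
}

propagate_ode <- function(V, params, p0, t_rel, rtol = 1e-8, atol = 1e-10) {
  Q <- herg_generator(V, params)
  ts <- unique(sort(c(0, t_rel)))
  # always-stiff BDF with the exact (constant) Jacobian: the control-set
  # generator carries an eigenmode of ~1.6e7/ms at every voltage, which
  # defeats the non-stiff startup phase of method-switching solvers
  out <- deSolve::vode(y = as.numeric(p0), times = ts,
                       func = function(t, y, parms) list(as.numeric(parms %*% y)),
                       jacfunc = function(t, y, parms) parms,
                       jactype = "fullusr",
                       parms = Q, rtol = rtol, atol = atol,
                       maxsteps = 100000)
  if (attr(out, "istate")[1L] < 0)
    stop("propagate_ode: solver failure at V = ", V, " mV")
  P <- t(out[match(t_rel, ts), -1L, drop = FALSE])
  dimnames(P) <- NULL
  P
}

#' Integrate state occupancies along a voltage-clamp command
#'
#' Solves the master equation `dp/dt = Q(V(t)) p` for a piecewise-constant
#' voltage protocol. Within each constant-voltage segment the default
#' backend propagates the occupancy analytically through the spectral
#' decomposition of the generator (exact up to round-off, and robust to the
#' very stiff published control rates); the `"ode"` backend uses the
#' adaptive stiff solver of \pkg{deSolve} instead.
#'
#' @param protocol A [voltage_protocol()].
#' @param params A [rate_constant_set()].
#' @param init Initial [occupancy_state()]; default is the steady state at
#'   the protocol's first (holding) voltage.
#' @param dt_out Output sampling interval, ms; defaults to the protocol's
#'   sampling interval.
#' @param method `"exact"` (spectral propagator) or `"ode"` (stiff solver).
#' @param rtol,atol Solver tolerances for `method = "ode"`.
#' @return A data frame of class `occupancy_series` with columns `time`,
#'   `voltage`, `segment` and the five occupancies `C1`, `C2`, `C3`, `O`,
#'   `I`, sampled uniformly at `dt_out`.
#' @export
integrate_occupancy <- function(protocol, params, init = NULL, dt_out = NULL,
                                method = c("exact", "ode"),
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(protocol, "voltage_protocol"),
            inherits(params, "rate_constant_set"))
  method <- match.arg(method)
  segs <- protocol$segments
  if (nrow(segs) == 0L) stop("integrate_occupancy: empty protocol")
  if (is.null(dt_out)) dt_out <- protocol$dt
  stopifnot(is.numeric(dt_out), dt_out > 0)
  if (is.null(init)) init <- herg_steady_state(segs$voltage[1L], params)
  init <- occupancy_state(init)

  total <- sum(segs$duration)
  times <- seq(0, total, by = dt_out)
  starts <- cumsum(c(0, segs$duration))
  # sample t belongs to segment i when t in [start_i, start_{i+1}); the
  # final sample belongs to the last segment
  seg_of <- pmin(findInterval(times, starts,
                              rightmost.closed = TRUE), nrow(segs))
  P <- matrix(NA_real_, 5L, length(times))
  voltage <- segs$voltage[seg_of]
  p <- init
  for (i in seq_len(nrow(segs))) {
    idx <- which(seg_of == i)
    t_rel <- times[idx] - starts[i]
    t_eval <- unique(c(t_rel, segs$duration[i]))
    res <- tryCatch(
      switch(method,
             exact = propagate_exact(segs$voltage[i], params, p, t_eval),
             ode = propagate_ode(segs$voltage[i], params, p, t_eval,
                                 rtol = rtol, atol = atol)),
      error = function(e) stop("integrate_occupancy: solver failure in ",
                               "segment ", i, " (t = ", starts[i], " ms): ",
                               conditionMessage(e), call. = FALSE))
    if (length(idx)) P[, idx] <- res[, seq_along(t_rel), drop = FALSE]
    p <- res[, length(t_eval)]
  }
  out <- data.frame(time = times, voltage = voltage, segment = seg_of,
                    t(P))
  names(out)[4:8] <- herg_states
  attr(out, "protocol") <- protocol
  attr(out, "condition") <- params$condition
  class(out) <- c("occupancy_series", "data.frame")
  out
}

#' Open-channel current from an occupancy state
#'
#' The current equation follows the rapid-delayed-rectifier convention of
#' the Ten Tusscher-Panfilov ventricular model:
#' `I = g_Kr * Ko_factor * p_O * (V - E_K)`, in pA/pF when `g_Kr` is a
#' conductance density in nS/pF.
#'
#' @param occ An [occupancy_state()] (length-5 vector) or a numeric vector
#'   of open probabilities.
#' @param V Membrane potential(s), mV.
#' @param g_Kr Maximal conductance density, nS/pF; non-negative.
#' @param E_K Potassium reversal potential, mV.
#' @param Ko_factor Dimensionless conductance scaling for external
#'   potassium, conventionally `sqrt(Ko / 5.4)`.
#' @return Current density, pA/pF.
#' @export
markov_current <- function(occ, V, g_Kr, E_K, Ko_factor = 1) {
  stopifnot(is.numeric(g_Kr), length(g_Kr) == 1L)
  if (g_Kr < 0) stop("markov_current: g_Kr must be non-negative")
  p_open <- if (length(occ) == 5L && !is.null(names(occ)) &&
                "O" %in% names(occ)) {
    occupancy_state(occ)[["O"]]
  } else if (length(occ) == 5L && is.null(dim(occ)) && is.null(names(occ))) {
    occupancy_state(occ)[["O"]]
  } else {
    as.numeric(occ)
  }
  g_Kr * Ko_factor * p_open * (V - E_K)
}

#' Nernst equilibrium potential
#'
#' @param c_out,c_in Extracellular and intracellular concentrations (same
#'   units).
#' @param temperature Temperature in degrees Celsius.
#' @param z Ion valence.
#' @return Potential in mV.
#' @examples
#' nernst_potential(4, 130, temperature = 23)  # E_K of the recording solutions
#' @export
nernst_potential <- function(c_out, c_in, temperature = 23, z = 1) {
  stopifnot(c_out > 0, c_in > 0)
  1000 * 8.314462618 * (273.15 + temperature) /
    (z * 96485.33212) * log(c_out / c_in)
}
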