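# Voltage-dependent transition rates of the five-state hERG gating chain.
# All rates are in 1/ms, voltages in mV, time in ms throughout the package.

#' State and transition labels of the hERG gating chain
#'
#' The chain is linear, `C1 <-> C2 <-> C3 <-> O <-> I`: three closed states,
#' one open state and one inactivated state. Transitions are labelled by the
#' state indices they connect (`k12` = C1 to C2, `k45` = O to I, and so on).
#'
#' @format Character vectors of length 5 (`herg_states`) and 8
#'   (`herg_transitions`).
#' @export
herg_states <- c("C1", "C2", "C3", "O", "I")

#' @rdname herg_states
#' @export
herg_transitions <- c("k12", "k21", "k23", "k32", "k34", "k43", "k45", "k54")

#' Exponential voltage dependence of a single transition rate
#'
#' A rate law is `rate(V) = a * exp(b * (V + v0))` with `a` in 1/ms, `b` in
#' 1/mV and the offset `v0` in mV. Voltage-independent transitions have
#' `b = 0` and `v0 = 0`.
#'
#' @param a Prefactor, 1/ms; must be strictly positive.
#' @param b Voltage coefficient, 1/mV.
#' @param v0 Voltage offset, mV.
#' @return An object of class `rate_law`.
#' @examples
#' law <- rate_law(0.01507341, 0.001459408)
#' eval_rate_law(law, V = 0)
#' @export
rate_law <- function(a, b = 0, v0 = 0) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(v0), length(v0) == 1L, is.finite(v0))
  if (a <= 0) stop("rate_law: prefactor 'a' must be > 0, got ", a)
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 v0 = as.numeric(v0)), class = "rate_law")
}

#' @param law A `rate_law`.
#' @param V Membrane potential(s), mV.
#' @rdname rate_law
#' @export
eval_rate_law <- function(law, V) {
  stopifnot(inherits(law, "rate_law"), is.numeric(V), all(is.finite(V)))
  law$a * exp(law$b * (V + law$v0))
}

#' @export
print.rate_law <- function(x, ...) {
  if (x$b == 0) {
    cat(sprintf("<rate_law> %.10g /ms (voltage independent)\n", x$a))
  } else {
    off <- if (x$v0 != 0) sprintf("(V%+.10g)", x$v0) else "V"
    cat(sprintf("<rate_law> %.10g * exp(%.10g * %s) /ms\n", x$a, x$b, off))
  }
  invisible(x)
}

#' Bundle of the eight transition-rate laws for one recording condition
#'
#' @param rates Named list with exactly one [rate_law()] per transition in
#'   [herg_transitions].
#' @param condition Condition label, e.g. `"PSS"` or `"C16CAR"`.
#' @return An object of class `rate_constant_set`.
#' @seealso [pss_rates()], [c16car_rates()], [load_rate_params()]
#' @export
rate_constant_set <- function(rates, condition = "custom") {
  stopifnot(is.list(rates), is.character(condition), length(condition) == 1L)
  missing <- setdiff(herg_transitions, names(rates))
  extra <- setdiff(names(rates), herg_transitions)
  if (length(missing))
    stop("rate_constant_set: missing transition(s): ",
         paste(missing, collapse = ", "))
  if (length(extra))
    stop("rate_constant_set: unknown transition(s): ",
         paste(extra, collapse = ", "),
         "; valid ids are ", paste(herg_transitions, collapse = ", "))
  for (nm in herg_transitions)
    if (!inherits(rates[[nm]], "rate_law"))
      stop("rate_constant_set: '", nm, "' is not a rate_law")
  structure(list(condition = condition, rates = rates[herg_transitions]),
            class = "rate_constant_set")
}

#' @export
print.rate_constant_set <- function(x, ...) {
  cat("<rate_constant_set> condition:", x$condition, "\n")
  for (nm in herg_transitions) {
    cat(sprintf("  %s: ", nm))
    print(x$rates[[nm]])
  }
  invisible(x)
}

#' Published rate constants for the control (PSS) condition
#'
#' The transition rates of the hERG Markov chain in physiological saline
#' solution. Note the anomalously large printed value of the C3 -> C2 rate
#' (`k32 = 15686841` /ms, voltage independent): it makes the C3 state drain
#' essentially instantaneously and suppresses open-state occupancy by some
#' eight orders of magnitude relative to C2. It is reproduced here exactly as
#' published; use `k32_a` to substitute a corrected value if desired (the
#' matched C16-CAR value, 0.01686841, suggests a transcription slip), which
#' then labels the set `"PSS*"`.
#'
#' @param k32_a Optional replacement prefactor for the `k32` transition
#'   (1/ms). `NULL` keeps the published value.
#' @return A [rate_constant_set()] labelled `"PSS"`.
#' @export
pss_rates <- function(k32_a = NULL) {
  k32 <- if (is.null(k32_a)) 15686841 else k32_a
  rate_constant_set(
    list(
      k12 = rate_law(0.01507341, 0.001459408),
      k21 = rate_law(0.05364064, -0.19822938),
      k23 = rate_law(0.08927204),
      k32 = rate_law(k32),
      k34 = rate_law(0.01066403, 0.00131023),
      k43 = rate_law(0.0005743, -0.0006156),
      k45 = rate_law(0.05042237, 0.00854485, 18),
      k54 = rate_law(0.01731608, -0.04090733, 18)
    ),
    condition = if (is.null(k32_a)) "PSS" else "PSS*"
  )
}

#' Published rate constants in the presence of 3 uM palmitoyl-carnitine
#'
#' The transition rates of the hERG Markov chain with 3 uM C16
#' acylcarnitine applied extracellularly.
#'
#' @return A [rate_constant_set()] labelled `"C16CAR"`.
#' @export
c16car_rates <- function() {
  rate_constant_set(
    list(
      k12 = rate_law(0.02007341, 0.07865593),
      k21 = rate_law(0.2364064, -0.00011822938),
      k23 = rate_law(0.02927204),
      k32 = rate_law(0.01686841),
      k34 = rate_law(0.15066403, 0.0231023),
      k43 = rate_law(0.00037433, -0.04078603),
      k45 = rate_law(0.16042237, 0.01554485, 4.5),
      k54 = rate_law(0.03731608, -0.05090733, 4.5)
    ),
    condition = "C16CAR"
  )
}

#' Evaluate one transition rate at a membrane potential
#'
#' @param transition One of [herg_transitions].
#' @param V Membrane potential(s), mV; finite.
#' @param params A [rate_constant_set()].
#' @return Rate(s) in 1/ms, strictly positive.
#' @examples
#' transition_rate("k12", 0, pss_rates())   # equals the printed prefactor
#' @export
transition_rate <- function(transition, V, params) {
  stopifnot(inherits(params, "rate_constant_set"),
            is.character(transition), length(transition) == 1L)
  if (!transition %in% herg_transitions)
    stop("unknown transition '", transition, "'; valid ids are ",
         paste(herg_transitions, collapse = ", "))
  eval_rate_law(params$rates[[transition]], V)
}

# All eight rates at a single voltage, as a named vector.
eval_rates <- function(params, V) {
  vapply(params$rates, eval_rate_law, numeric(1L), V = V)
}

#' Read and write rate-constant sets as JSON
#'
#' The JSON layout is `{"condition": ..., "rates": {"k12": {"a": ..,
#' "b": .., "v0": ..}, ...}}`. Numbers are written at full precision so the
#' published constants survive a round-trip exactly.
#'
#' @param path File path.
#' @return `load_rate_params` returns a [rate_constant_set()];
#'   `write_rate_params` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_rate_params(pss_rates(), f)
#' load_rate_params(f)
#' @export
load_rate_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$rates)) stop("parameter file has no 'rates' field: ", path)
  missing <- setdiff(herg_transitions, names(obj$rates))
  if (length(missing))
    stop("parameter file ", path, " is missing transition(s): ",
         paste(missing, collapse = ", "))
  laws <- lapply(herg_transitions, function(nm) {
    r <- obj$rates[[nm]]
    if (is.null(r$a)) stop("transition '", nm, "' has no prefactor 'a'")
    if (r$a <= 0) stop("transition '", nm, "' has non-positive prefactor")
    rate_law(r$a, if (is.null(r$b)) 0 else r$b,
             if (is.null(r$v0)) 0 else r$v0)
  })
  names(laws) <- herg_transitions
  cond <- if (is.null(obj$condition)) "custom" else obj$condition
  rate_constant_set(laws, condition = cond)
}

#' @param params A [rate_constant_set()].
#' @rdname load_rate_params
#' @export
write_rate_params <- function(params, path) {
  stopifnot(inherits(params, "rate_constant_set"))
  obj <- list(
    condition = params$condition,
    rates = lapply(params$rates, function(l) list(a = l$a, b = l$b, v0 = l$v0))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
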