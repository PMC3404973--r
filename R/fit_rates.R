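# Estimating Markov rate constants from current traces by Nelder-Mead
# simplex minimisation of the summed squared residuals between simulated
# and observed sweeps. Prefactors are optimised in log space so they stay
# positive; voltage coefficients and offsets are optimised directly.

# Parse free-parameter names like "k23", "k12.a", "k45.b", "k54.v0" into
# (transition, field) pairs. A bare transition id means its prefactor.
parse_free <- function(free) {
  if (!length(free)) return(data.frame(transition = character(),
                                       field = character()))
  parts <- strsplit(free, ".", fixed = TRUE)
  out <- data.frame(
    transition = vapply(parts, `[[`, character(1L), 1L),
    field = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "a",
                   character(1L))
  )
  bad <- !out$transition %in% herg_transitions
  if (any(bad))
    stop("fit_markov_rates: unknown transition(s): ",
         paste(unique(out$transition[bad]), collapse = ", "))
  bad <- !out$field %in% c("a", "b", "v0")
  if (any(bad))
    stop("fit_markov_rates: unknown field(s): ",
         paste(unique(out$field[bad]), collapse = ", "),
         " (valid: a, b, v0)")
  out
}

get_free <- function(params, spec) {
  vapply(seq_len(nrow(spec)),
         function(i) params$rates[[spec$transition[i]]][[spec$field[i]]],
         numeric(1L))
}

set_free <- function(params, spec, theta) {
  for (i in seq_len(nrow(spec))) {
    v <- theta[i]
    if (spec$field[i] == "a") v <- exp(v)
    params$rates[[spec$transition[i]]][[spec$field[i]]] <- v
  }
  params
}

to_theta <- function(values, spec) {
  ifelse(spec$field == "a", log(values), values)
}

#' Estimate Markov rate constants from observed clamp traces
#'
#' Simulates the protocol family at candidate rate constants and minimises
#' the sum over all sweeps of squared current residuals with the
#' Nelder-Mead simplex. Only the parameters named in `free` move; the rest
#' stay at `init`. The optimisation is deterministic given `init` and
#' `options`.
#'
#' @param observed List of [current_trace()] objects, one per sweep of
#'   `family`, on the time grid the simulator will use.
#' @param family The [protocol_family()] that produced the observations.
#' @param free Character vector naming the free parameters as
#'   `"<transition>"` (prefactor) or `"<transition>.<field>"` with field
#'   `a`, `b` or `v0`, e.g. `c("k23", "k12.a")`. Empty means evaluate only.
#' @param init A [rate_constant_set()] of starting values.
#' @param config A [current_config()]; must match the one used for the
#'   observations.
#' @param dt_out Simulation output interval, ms; defaults to the family
#'   template's sampling interval.
#' @param options A [fit_options()].
#' @return An object of class `markov_rate_fit`: the fitted
#'   [rate_constant_set()] (`params`), the final and initial objective
#'   values, the history of accepted (improving) objective values, the
#'   evaluation count and a convergence flag. When the iteration cap is
#'   hit the best-so-far parameters are returned with
#'   `converged = FALSE`.
#' @export
fit_markov_rates <- function(observed, family, free = character(),
                             init, config = current_config(),
                             dt_out = NULL, options = fit_options()) {
  stopifnot(inherits(family, "protocol_family"),
            inherits(init, "rate_constant_set"),
            is.list(observed),
            length(observed) == length(family$sweep_voltages))
  spec <- parse_free(free)
  obs_mat <- lapply(observed, function(tr) {
    stopifnot(inherits(tr, "current_trace"))
    tr$current
  })

  n_eval <- 0L
  history <- numeric()
  objective <- function(theta) {
    p <- set_free(init, spec, theta)
    val <- tryCatch({
      sim <- simulate_family(family, p, config, dt_out = dt_out)
      tot <- 0
      for (i in seq_along(sim$traces)) {
        si <- sim$traces[[i]]$current
        if (length(si) != length(obs_mat[[i]]))
          stop("simulated and observed grids differ in sweep ", i)
        tot <- tot + sum((si - obs_mat[[i]])^2)
      }
      tot
    }, error = function(e) Inf)
    n_eval <<- n_eval + 1L
    if (!length(history) || val < history[length(history)])
      history <<- c(history, val)
    val
  }

  theta0 <- to_theta(get_free(init, spec), spec)
  f0 <- objective(if (nrow(spec)) theta0 else numeric())
  if (!is.finite(f0))
    stop("fit_markov_rates: objective is non-finite at the initial ",
         "parameters")
  if (nrow(spec) == 0L) {
    return(structure(list(params = init, value = f0, init_value = f0,
                          history = history, evaluations = n_eval,
                          converged = TRUE, free = free),
                     class = "markov_rate_fit"))
  }

  # Nelder-Mead also for a single free parameter (optim warns that 1-D
  # simplex search is crude; it is the method being implemented here)
  o <- suppressWarnings(
    stats::optim(theta0, objective, method = "Nelder-Mead",
                 control = list(maxit = options$max_iter,
                                reltol = options$reltol)))
  structure(list(params = set_free(init, spec, o$par), value = o$value,
                 init_value = f0, history = history,
                 evaluations = n_eval, converged = o$convergence == 0L,
                 free = free),
            class = "markov_rate_fit")
}

#' @export
print.markov_rate_fit <- function(x, ...) {
  cat(sprintf("<markov_rate_fit> %d free parameter(s): %s\n",
              length(x$free), paste(x$free, collapse = ", ")))
  cat(sprintf("  objective %.6g -> %.6g in %d evaluations%s\n",
              x$init_value, x$value, x$evaluations,
              if (x$converged) "" else " (iteration cap reached)"))
  invisible(x)
}

#' @export
coef.markov_rate_fit <- function(object, ...) {
  spec <- parse_free(object$free)
  vals <- get_free(object$params, spec)
  names(vals) <- if (nrow(spec)) paste(spec$transition, spec$field,
                                       sep = ".") else character()
  vals
}
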