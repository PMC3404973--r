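# Synthetic inputs with the statistical structure the analyses assume:
# noisy biexponential tails, Boltzmann datasets, and per-cell cohorts whose
# summaries mirror the mean +/- SEM tables of patch-clamp studies. All
# stochastic output is reproducible from an explicit seed.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

#' Generate a (noisy) biexponential tail current
#'
#' Samples `A0 + A1 exp(-t/tau1) + A2 exp(-t/tau2)` on a uniform grid and
#' adds i.i.d. Gaussian noise. The noiseless curve is exact; with
#' `noise_sd > 0` a seed is required so every trace is reproducible.
#'
#' @param A0,A1,A2 Amplitudes (current units).
#' @param tau1,tau2 Time constants, ms; positive.
#' @param duration Trace duration, ms (at least about 3 * tau1 is advisable
#'   for resolvable fits).
#' @param sampling_khz Sampling rate, kHz; default 5 kHz.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   current units; non-negative.
#' @param seed Integer seed; mandatory when `noise_sd > 0`.
#' @param unit Current unit tag.
#' @return A [current_trace()] with a single annotated segment. The
#'   generating parameters are attached as attribute `"truth"`.
#' @export
generate_tail_trace <- function(A1, A2, tau1, tau2, A0 = 0,
                                duration = 8000, sampling_khz = 5,
                                noise_sd = 0, seed = NULL,
                                unit = "pA") {
  stopifnot(tau1 > 0, tau2 > 0, duration > 0, sampling_khz > 0)
  if (noise_sd < 0) stop("generate_tail_trace: negative noise SD")
  if (noise_sd > 0 && is.null(seed))
    stop("generate_tail_trace: a seed is required for noisy output")
  tt <- seq(0, duration, by = 1 / sampling_khz)
  y <- A0 + A1 * exp(-tt / tau1) + A2 * exp(-tt / tau2)
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(tt), sd = noise_sd))
  tr <- current_trace(tt, y, unit = unit,
                      segments = data.frame(start = 0, end = duration,
                                            voltage = -55),
                      label = "synthetic tail")
  attr(tr, "truth") <- c(A0 = A0, A1 = A1, A2 = A2,
                         tau1 = tau1, tau2 = tau2)
  tr
}

#' Generate a (noisy) normalised Boltzmann dataset
#'
#' @param V Voltage grid, mV; non-empty.
#' @param V_half Half-maximal voltage, mV.
#' @param s Slope factor, mV; positive.
#' @param direction `"activation"` or `"availability"`.
#' @param noise_sd Gaussian noise SD on the normalised-current axis.
#' @param seed Integer seed; mandatory when `noise_sd > 0`.
#' @return A data frame with columns `voltage` and `current`.
#' @export
generate_boltzmann_dataset <- function(V, V_half, s,
                                       direction = c("activation",
                                                     "availability"),
                                       noise_sd = 0, seed = NULL) {
  direction <- match.arg(direction)
  if (!length(V)) stop("generate_boltzmann_dataset: empty voltage grid")
  stopifnot(s > 0, noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed))
    stop("generate_boltzmann_dataset: a seed is required for noisy output")
  sgn <- if (direction == "activation") 1 else -1
  y <- 1 / (1 + exp(sgn * (V_half - V) / s))
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(V), sd = noise_sd))
  data.frame(voltage = V, current = y)
}

#' Specification of a synthetic cell cohort
#'
#' Per-cell generating parameters are drawn from normal distributions
#' truncated to positive values for time constants and slope factors
#' (resampling until positive), mimicking cell-to-cell variability behind
#' the mean +/- SEM cohort tables of patch-clamp studies.
#'
#' @param n Number of cells; at least 1 (at least 2 when an SEM is wanted).
#' @param means,sds Named numeric vectors of population means and SDs. For
#'   tail cohorts use names `tau1`, `tau2`, `A1`, `A2`, `A0`; for Boltzmann
#'   cohorts `V_half` and `s`.
#' @param noise_sd Trace noise SD as a fraction of the initial tail
#'   amplitude (tails) or absolute on the normalised axis (Boltzmann);
#'   default 2 percent of the initial amplitude.
#' @param capacitance Range of cell capacitances, pF.
#' @param seed Integer seed (mandatory: cohorts are always stochastic).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, means, sds, noise_sd = 0.02,
                        capacitance = c(10, 20), seed) {
  stopifnot(n >= 1L, is.numeric(means), is.numeric(sds),
            !is.null(names(means)), all(names(sds) %in% names(means)),
            all(sds >= 0), noise_sd >= 0, length(capacitance) == 2L)
  if (missing(seed) || is.null(seed))
    stop("cohort_spec: a seed is mandatory")
  structure(list(n = as.integer(n), means = means,
                 sds = sds[names(means)], noise_sd = noise_sd,
                 capacitance = capacitance, seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_positive <- function(n, mean, sd, positive) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  if (positive) {
    for (i in seq_len(100)) {
      bad <- x <= 0
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    if (any(x <= 0)) stop("cohort draw: cannot sample positive values")
  }
  x
}

#' Generate a synthetic cohort and its fitted summary table
#'
#' Draws per-cell parameters from the spec's population distributions,
#' generates each cell's dataset, fits it with the matching fitter
#' ([fit_biexp()] or [fit_boltzmann()]) and summarises the fitted
#' parameters as mean +/- SEM over cells.
#'
#' @param spec A [cohort_spec()].
#' @param kind `"tails"` or `"boltzmann"`.
#' @param ... Further arguments to the generator (e.g. `duration`,
#'   `sampling_khz` for tails; `V`, `direction` for Boltzmann datasets).
#' @return A list of class `synthetic_cohort` with `cells` (per-cell
#'   datasets), `truth` (per-cell generating parameters), `fits` (per-cell
#'   fit objects), and `summary` (data frame `parameter`, `mean`, `sem`,
#'   `n` of the fitted values).
#' @export
generate_cohort <- function(spec, kind = c("tails", "boltzmann"), ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  kind <- match.arg(kind)
  if (spec$n < 2L)
    stop("generate_cohort: need n >= 2 cells for an SEM")
  dots <- list(...)
  positive_pars <- c("tau1", "tau2", "s")

  with_seed(spec$seed, {
    truth <- as.data.frame(lapply(names(spec$means), function(nm)
      draw_positive(spec$n, spec$means[[nm]], spec$sds[[nm]],
                    nm %in% positive_pars)))
    names(truth) <- names(spec$means)
    truth$capacitance <- stats::runif(spec$n, spec$capacitance[1L],
                                      spec$capacitance[2L])
    cell_seeds <- sample.int(.Machine$integer.max, spec$n)

    cells <- vector("list", spec$n)
    fits <- vector("list", spec$n)
    for (i in seq_len(spec$n)) {
      if (kind == "tails") {
        amp0 <- sum(truth$A0[i], truth$A1[i], truth$A2[i], na.rm = TRUE)
        args <- c(list(A1 = truth$A1[i], A2 = truth$A2[i],
                       tau1 = truth$tau1[i], tau2 = truth$tau2[i],
                       A0 = if ("A0" %in% names(truth)) truth$A0[i] else 0,
                       noise_sd = spec$noise_sd * abs(amp0),
                       seed = cell_seeds[i]), dots)
        cells[[i]] <- do.call(generate_tail_trace, args)
        fits[[i]] <- fit_biexp(cells[[i]])
      } else {
        args <- c(list(V_half = truth$V_half[i], s = truth$s[i],
                       noise_sd = spec$noise_sd, seed = cell_seeds[i]),
                  if (is.null(dots$V)) list(V = seq(-80, 50, 10)) else NULL,
                  dots)
        cells[[i]] <- do.call(generate_boltzmann_dataset, args)
        fits[[i]] <- fit_boltzmann(cells[[i]]$voltage, cells[[i]]$current,
                                   direction = if (is.null(dots$direction))
                                     "activation" else dots$direction)
      }
    }
  })

  par_names <- if (kind == "tails") c("tau1", "tau2") else c("V_half", "s")
  est <- sapply(par_names, function(p)
    vapply(fits, function(f) coef(f)[[p]], numeric(1L)))
  summary <- data.frame(
    parameter = par_names,
    mean = colMeans(est),
    sem = apply(est, 2L, stats::sd) / sqrt(spec$n),
    n = spec$n, row.names = NULL)

  structure(list(cells = cells, truth = truth, fits = fits,
                 summary = summary, spec = spec, kind = kind),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %s, n = %d cells (seed %d)\n", x$kind,
              x$spec$n, x$spec$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
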