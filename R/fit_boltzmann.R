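# Boltzmann description of the voltage dependence of activation and
# availability:
#   activation:   I/Imax = Imax_scale / (1 + exp((Vhalf - V) / s))
#   availability: I/Imax = Imax_scale / (1 + exp((V - Vhalf) / s))
# with slope factor s > 0 in both directions; availability decreases with
# depolarisation.

#' Normalise tail-peak currents for an activation curve
#'
#' Divides the per-sweep tail peaks by the peak of largest magnitude, so
#' the normalised curve saturates at 1 (up to noise).
#'
#' @param peaks Signed tail-peak currents, one per sweep, or the data frame
#'   returned by [tail_peaks()].
#' @param voltages Optional sweep voltages; taken from `peaks` when it is a
#'   data frame.
#' @return A data frame with columns `voltage` and `current` (normalised).
#' @export
normalize_tail_curve <- function(peaks, voltages = NULL) {
  if (is.data.frame(peaks)) {
    voltages <- peaks$voltage
    peaks <- peaks$current
  }
  stopifnot(is.numeric(peaks), length(peaks) >= 1L)
  if (all(peaks == 0)) stop("normalize_tail_curve: all peaks are zero")
  ref <- peaks[which.max(abs(peaks))]
  if (is.null(voltages)) voltages <- seq_along(peaks)
  data.frame(voltage = voltages, current = peaks / ref)
}

#' Fit a Boltzmann sigmoid to normalised current-voltage points
#'
#' @param V Voltages, mV; at least 5 points spanning at least 40 mV.
#' @param y Normalised currents.
#' @param direction `"activation"` (increasing with depolarisation) or
#'   `"availability"` (decreasing).
#' @param options A [fit_options()].
#' @return An object of class `boltzmann_fit` with coefficients `V_half`
#'   (mV), `s` (slope factor, mV, positive) and `I_max` (scale), the
#'   residual norm and a convergence flag. Data lying on a single plateau
#'   (no resolvable transition) yield `converged = FALSE`.
#' @examples
#' d <- generate_boltzmann_dataset(seq(-80, 50, 10), V_half = -17.4, s = 6)
#' coef(fit_boltzmann(d$voltage, d$current))
#' @export
fit_boltzmann <- function(V, y, direction = c("activation", "availability"),
                          options = fit_options()) {
  direction <- match.arg(direction)
  if (is.data.frame(V)) { y <- V$current; V <- V$voltage }
  stopifnot(is.numeric(V), is.numeric(y), length(V) == length(y))
  if (length(V) < 5L)
    stop("fit_boltzmann: need at least 5 points, got ", length(V))
  if (diff(range(V)) < 40)
    stop("fit_boltzmann: points must span at least 40 mV")
  sgn <- if (direction == "activation") 1 else -1

  # initial values: V_half at the interpolated half-crossing, slope from
  # the quartile crossings
  ord <- order(V)
  Vo <- V[ord]; yo <- y[ord]
  ymax <- max(abs(y))
  cross <- function(level) {
    z <- yo / ymax - level
    i <- which(z[-1L] * z[-length(z)] <= 0)[1L]
    if (is.na(i)) return(NA_real_)
    Vo[i] + (Vo[i + 1L] - Vo[i]) * z[i] / (z[i] - z[i + 1L])
  }
  v50 <- cross(0.5)
  v25 <- cross(0.25); v75 <- cross(0.75)
  s0 <- if (!is.na(v25) && !is.na(v75) && v25 != v75)
    abs(v75 - v25) / (2 * log(3)) else 6
  if (is.na(v50)) v50 <- stats::median(V)
  plateau <- diff(range(y)) < 0.1 * max(abs(y), 1e-12)

  dat <- data.frame(V = V, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Imax / (1 + exp(sgn * (Vhalf - V) / s)), data = dat,
      start = list(Imax = ymax, Vhalf = v50, s = max(s0, 0.5)),
      lower = c(Imax = 0, Vhalf = min(V) - 200, s = 1e-3),
      upper = c(Imax = Inf, Vhalf = max(V) + 200, s = 1e3),
      control = minpack.lm::nls.lm.control(
        maxiter = min(options$max_iter, 1024), ftol = options$reltol)),
    error = function(e) NULL)

  if (is.null(fit)) {
    coefs <- c(V_half = v50, s = s0, I_max = ymax)
    rss <- sum((y - coefs[["I_max"]] /
                  (1 + exp(sgn * (coefs[["V_half"]] - V) / s0)))^2)
    converged <- FALSE
  } else {
    cf <- stats::coef(fit)
    coefs <- c(V_half = unname(cf[["Vhalf"]]), s = unname(cf[["s"]]),
               I_max = unname(cf[["Imax"]]))
    rss <- sum(stats::resid(fit)^2)
    converged <- !plateau
  }
  structure(list(coefficients = coefs, direction = direction, rss = rss,
                 converged = converged, n = length(V),
                 data = data.frame(voltage = V, current = y)),
            class = "boltzmann_fit")
}

#' @export
coef.boltzmann_fit <- function(object, ...) object$coefficients

#' @export
print.boltzmann_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<boltzmann_fit> %s: V_half = %.4g mV, s = %.4g mV, I_max = %.4g\n",
              x$direction, cf[["V_half"]], cf[["s"]], cf[["I_max"]]))
  cat(sprintf("  rss = %.4g over %d points\n", x$rss, x$n))
  if (!x$converged) cat("  NOT CONVERGED (no resolvable transition)\n")
  invisible(x)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @param object A `boltzmann_fit`.
#' @param newdata Optional voltages (mV) at which to evaluate the sigmoid.
#' @param ... Unused.
#' @rdname fit_boltzmann
#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  V <- if (is.null(newdata)) object$data$voltage else as.numeric(newdata)
  cf <- object$coefficients
  sgn <- if (object$direction == "activation") 1 else -1
  cf[["I_max"]] / (1 + exp(sgn * (cf[["V_half"]] - V) / cf[["s"]]))
}

#' @export
fitted.boltzmann_fit <- function(object, ...) predict(object)

#' @export
residuals.boltzmann_fit <- function(object, ...)
  object$data$current - predict(object)

#' @export
plot.boltzmann_fit <- function(x, ...) {
  plot(x$data$voltage, x$data$current, xlab = "voltage (mV)",
       ylab = "I / Imax", ...)
  vv <- seq(min(x$data$voltage), max(x$data$voltage), length.out = 200)
  graphics::lines(vv, predict(x, vv), col = "red", lwd = 2)
  graphics::abline(v = x$coefficients[["V_half"]], lty = 3)
  invisible(x)
}
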