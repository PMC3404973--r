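# Two-exponential description of deactivating tail currents:
#   I(t) = A0 + A1 * exp(-t / tau1) + A2 * exp(-t / tau2),
# with t measured from the start of the fit window and tau1 >= tau2
# (tau1 is the slow component). Fitting uses variable projection: for
# fixed time constants the amplitudes are a linear least-squares solve, so
# only the two (log) time constants are optimised, by Nelder-Mead from a
# log-spaced grid of starting pairs.

#' Options for the least-squares fitters
#'
#' @param max_iter Iteration cap for the nonlinear optimiser.
#' @param reltol Relative convergence tolerance on the sum of squared
#'   residuals.
#' @param tau_grid Multipliers of the window length used as the log-spaced
#'   grid of time-constant starting values.
#' @param start Optional named starting values overriding the grid search.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_iter = 2000, reltol = 1e-13,
                        tau_grid = c(0.02, 0.15, 1), start = NULL) {
  stopifnot(max_iter > 0, reltol > 0, all(tau_grid > 0))
  structure(list(max_iter = max_iter, reltol = reltol,
                 tau_grid = tau_grid, start = start),
            class = "fit_options")
}

#' Fit a two-exponential decay to a current trace
#'
#' @param x A [current_trace()], or a numeric time vector (ms) when `y` is
#'   given.
#' @param ... Passed on to methods.
#' @return An object of class `biexp_fit` with components `coefficients`
#'   (`A0`, `A1`, `A2`, `tau1`, `tau2`; `tau1 >= tau2`), `rss`, `converged`,
#'   `degenerate` (the fit is effectively mono-exponential), and the fitted
#'   data. Non-convergence is reported through the flag, never as an error.
#' @examples
#' tr <- generate_tail_trace(A1 = 100, A2 = 100, tau1 = 1663, tau2 = 314.4,
#'                           duration = 8000)
#' coef(fit_biexp(tr))
#' @export
fit_biexp <- function(x, ...) UseMethod("fit_biexp")

#' @param segment Segment index of the tail within the trace; defaults to
#'   the last annotated segment (or the whole trace when unannotated).
#' @param window Optional absolute time interval `c(t0, t1)` (ms)
#'   restricting the fit. By default the window starts 2 samples after the
#'   segment boundary, excluding the step discontinuity.
#' @param options A [fit_options()].
#' @rdname fit_biexp
#' @export
fit_biexp.current_trace <- function(x, segment = NULL, window = NULL,
                                    options = fit_options(), ...) {
  if (is.null(window)) {
    idx <- if (is.null(x$segments)) seq_along(x$time) else {
      if (is.null(segment)) segment <- nrow(x$segments)
      segment_index(x, segment)
    }
    if (length(idx) > 2L && !is.null(x$segments)) idx <- idx[-(1:2)]
  } else {
    stopifnot(length(window) == 2L, window[1L] < window[2L])
    idx <- which(x$time >= window[1L] - 1e-9 & x$time <= window[2L] + 1e-9)
    if (!length(idx)) stop("fit_biexp: window outside trace")
  }
  fit_biexp.default(x$time[idx], x$current[idx], options = options)
}

#' @param y Current samples when `x` is a time vector.
#' @rdname fit_biexp
#' @export
fit_biexp.default <- function(x, y, options = fit_options(), ...) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 50L)
    stop("fit_biexp: need at least 50 samples in the window, got ",
         length(x))
  t0 <- x[1L]
  tt <- x - t0
  span <- tt[length(tt)]

  design <- function(taus) cbind(1, exp(-tt / taus[1L]), exp(-tt / taus[2L]))
  rss_of <- function(log_taus) {
    taus <- exp(log_taus)
    if (any(!is.finite(taus)) || any(taus <= 0) || any(taus > 1e3 * span))
      return(sum((y - mean(y))^2) * 10)
    f <- stats::.lm.fit(design(taus), y)
    sum(f$residuals^2)
  }

  if (!is.null(options$start)) {
    starts <- list(log(c(options$start[["tau1"]], options$start[["tau2"]])))
  } else {
    grid <- span * options$tau_grid
    starts <- list()
    best <- Inf
    for (t1 in grid) for (t2 in grid) {
      v <- rss_of(log(c(t1, t2)))
      if (v < best) { best <- v; starts[[1L]] <- log(c(t1, t2)) }
    }
    # perturbed second start guards against a poor grid optimum
    starts[[2L]] <- starts[[1L]] + c(1, -1)
  }

  best_fit <- NULL
  for (s in starts) {
    o <- stats::optim(s, rss_of, method = "Nelder-Mead",
                      control = list(maxit = options$max_iter,
                                     reltol = options$reltol))
    if (is.null(best_fit) || o$value < best_fit$value) best_fit <- o
  }
  taus <- sort(exp(best_fit$par), decreasing = TRUE)  # tau1 = slow
  A <- qr.coef(qr(design(taus)), y)
  A[is.na(A)] <- 0
  amp_scale <- max(abs(A), diff(range(y)), .Machine$double.eps)
  degenerate <- taus[1L] / taus[2L] < 1.1 ||
    min(abs(A[2:3])) < 1e-3 * amp_scale
  coefs <- c(A0 = unname(A[1L]), A1 = unname(A[2L]), A2 = unname(A[3L]),
             tau1 = taus[1L], tau2 = taus[2L])

  structure(list(coefficients = coefs, rss = best_fit$value,
                 converged = best_fit$convergence == 0L,
                 degenerate = degenerate, n = length(tt),
                 t_origin = t0, data = list(time = x, current = y)),
            class = "biexp_fit")
}

#' @export
coef.biexp_fit <- function(object, ...) object$coefficients

#' @export
print.biexp_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<biexp_fit> tau1 = %.6g ms (slow), tau2 = %.6g ms (fast)\n",
              cf[["tau1"]], cf[["tau2"]]))
  cat(sprintf("  A0 = %.6g, A1 = %.6g, A2 = %.6g; rss = %.6g; n = %d\n",
              cf[["A0"]], cf[["A1"]], cf[["A2"]], x$rss, x$n))
  if (!x$converged) cat("  NOT CONVERGED\n")
  if (x$degenerate)
    cat("  degenerate: effectively mono-exponential (tau1 ~ tau2 or a\n",
        " vanishing amplitude)\n")
  invisible(x)
}

#' @export
summary.biexp_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @param newdata Optional times (ms, absolute) at which to evaluate the
#'   fitted curve.
#' @rdname fit_biexp
#' @export
predict.biexp_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$time else as.numeric(newdata)
  tt <- tt - object$t_origin
  cf <- object$coefficients
  cf[["A0"]] + cf[["A1"]] * exp(-tt / cf[["tau1"]]) +
    cf[["A2"]] * exp(-tt / cf[["tau2"]])
}

#' @export
fitted.biexp_fit <- function(object, ...) predict(object)

#' @export
residuals.biexp_fit <- function(object, ...)
  object$data$current - predict(object)

#' @export
plot.biexp_fit <- function(x, ...) {
  plot(x$data$time, x$data$current, type = "l", col = "grey50",
       xlab = "time (ms)", ylab = "current", ...)
  graphics::lines(x$data$time, fitted(x), col = "red", lwd = 2)
  invisible(x)
}
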