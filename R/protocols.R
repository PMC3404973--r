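# Voltage-clamp command descriptions: single piecewise-constant protocols
# and sweep families with one varying segment.

#' Piecewise-constant voltage-clamp command
#'
#' @param durations Segment durations, ms; all > 0.
#' @param voltages Segment command voltages, mV; same length as `durations`.
#' @param dt Sampling interval, ms; default 0.2 ms (5 kHz, the acquisition
#'   rate of the recordings the simulations emulate).
#' @param label Optional protocol label.
#' @return An object of class `voltage_protocol` with a `segments` data
#'   frame, the sampling interval `dt` and the `label`.
#' @export
voltage_protocol <- function(durations, voltages, dt = 0.2, label = "") {
  stopifnot(is.numeric(durations), is.numeric(voltages),
            length(durations) == length(voltages), length(durations) >= 1L,
            all(is.finite(durations)), all(is.finite(voltages)),
            is.numeric(dt), length(dt) == 1L, dt > 0)
  if (any(durations <= 0)) stop("voltage_protocol: durations must be > 0")
  structure(list(
    segments = data.frame(duration = as.numeric(durations),
                          voltage = as.numeric(voltages)),
    dt = as.numeric(dt),
    label = as.character(label)
  ), class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s: %d segment(s), %.6g ms total, dt = %g ms\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$segments), sum(x$segments$duration), x$dt))
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  %d: %8.6g ms @ %+.6g mV\n", i,
                x$segments$duration[i], x$segments$voltage[i]))
  invisible(x)
}

total_duration <- function(protocol) sum(protocol$segments$duration)

#' Family of sweeps sharing a template protocol with one varying segment
#'
#' @param template A [voltage_protocol()].
#' @param vary_segment Index of the segment whose voltage varies per sweep.
#' @param sweep_voltages Voltages, mV, one per sweep; non-empty.
#' @param interpulse Inter-sweep interval at the holding potential (the
#'   template's first segment voltage), ms. The family simulator relaxes
#'   the channel at the holding potential for this long between sweeps, so
#'   cumulative protocols are faithful.
#' @return An object of class `protocol_family`.
#' @export
protocol_family <- function(template, vary_segment, sweep_voltages,
                            interpulse = 18000) {
  stopifnot(inherits(template, "voltage_protocol"),
            is.numeric(vary_segment), length(vary_segment) == 1L,
            is.numeric(sweep_voltages), length(sweep_voltages) >= 1L,
            all(is.finite(sweep_voltages)),
            is.numeric(interpulse), interpulse >= 0)
  if (vary_segment < 1 || vary_segment > nrow(template$segments))
    stop("protocol_family: vary_segment out of range")
  structure(list(template = template,
                 vary_segment = as.integer(vary_segment),
                 sweep_voltages = as.numeric(sweep_voltages),
                 interpulse = as.numeric(interpulse)),
            class = "protocol_family")
}

#' @export
print.protocol_family <- function(x, ...) {
  cat(sprintf("<protocol_family> %d sweep(s), varying segment %d (%s mV), interpulse %g ms\n",
              length(x$sweep_voltages), x$vary_segment,
              paste(range(x$sweep_voltages), collapse = " to "),
              x$interpulse))
  print(x$template)
  invisible(x)
}

# Concrete protocol of the i-th sweep.
sweep_protocol <- function(family, i) {
  pr <- family$template
  pr$segments$voltage[family$vary_segment] <- family$sweep_voltages[i]
  pr$label <- sprintf("%s [sweep %+g mV]", pr$label, family$sweep_voltages[i])
  pr
}

#' Standard hERG clamp protocol families
#'
#' `build_iv_family()` encodes the steady-state current-voltage protocol:
#' from a holding potential of -70 mV, 5 s steps to voltages between -80
#' and +50 mV in 10 mV increments, with the deactivating tail recorded at
#' -55 mV. `build_single_step_family()` encodes the repeated single test
#' pulse: 5 s to -10 mV applied every 18 s. `build_availability_family()`
#' encodes the two-pulse availability protocol: a 1 s conditioning pulse to
#' +40 mV, a 25 ms interpulse to voltages between -120 and +10 mV, then a
#' test pulse back to +40 mV.
#'
#' Each sweep starts with a short baseline segment at the holding
#' potential; tail and test segment durations are package choices (the
#' protocols specify only where the measurements are taken).
#'
#' @param tail_ms Duration of the -55 mV tail segment, ms.
#' @param hold_ms Duration of the baseline segment at -70 mV, ms.
#' @param dt Sampling interval, ms.
#' @return A [protocol_family()].
#' @export
build_iv_family <- function(tail_ms = 5000, hold_ms = 100, dt = 0.2) {
  tpl <- voltage_protocol(c(hold_ms, 5000, tail_ms), c(-70, 0, -55),
                          dt = dt, label = "IV")
  protocol_family(tpl, vary_segment = 2L,
                  sweep_voltages = seq(-80, 50, by = 10),
                  interpulse = 18000)
}

#' @rdname build_iv_family
#' @export
build_single_step_family <- function(tail_ms = 8000, hold_ms = 100, dt = 0.2) {
  tpl <- voltage_protocol(c(hold_ms, 5000, tail_ms), c(-70, -10, -55),
                          dt = dt, label = "single-step")
  protocol_family(tpl, vary_segment = 2L, sweep_voltages = -10,
                  interpulse = 18000)
}

#' @param test_ms Duration of the +40 mV test pulse, ms.
#' @rdname build_iv_family
#' @export
build_availability_family <- function(test_ms = 500, hold_ms = 100, dt = 0.2) {
  tpl <- voltage_protocol(c(hold_ms, 1000, 25, test_ms), c(-70, 40, -120, 40),
                          dt = dt, label = "availability")
  protocol_family(tpl, vary_segment = 3L,
                  sweep_voltages = seq(-120, 10, by = 10),
                  interpulse = 18000)
}

#' Read and write protocols and protocol families as JSON
#'
#' Round-trips are lossless: structure, voltages, durations, sampling
#' interval and labels are preserved exactly.
#'
#' @param x A [voltage_protocol()] or [protocol_family()].
#' @param path File path.
#' @export
write_protocol <- function(x, path) {
  if (inherits(x, "protocol_family")) {
    obj <- list(type = "protocol_family",
                template = unclass(x$template),
                vary_segment = x$vary_segment,
                sweep_voltages = x$sweep_voltages,
                interpulse = x$interpulse)
  } else if (inherits(x, "voltage_protocol")) {
    obj <- c(list(type = "voltage_protocol"), unclass(x))
  } else stop("write_protocol: not a protocol or family")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(tpl) voltage_protocol(tpl$segments$duration,
                                       tpl$segments$voltage,
                                       dt = tpl$dt, label = tpl$label)
  if (identical(obj$type, "voltage_protocol")) return(mk(obj))
  if (identical(obj$type, "protocol_family"))
    return(protocol_family(mk(obj$template), obj$vary_segment,
                           obj$sweep_voltages, obj$interpulse))
  stop("read_protocol: unrecognised protocol file: ", path)
}
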