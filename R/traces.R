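# Current traces: the uniformly sampled time series produced by the clamp
# simulator (or loaded from delimited text), plus the measurement operators
# used for the published analyses.

#' Uniformly sampled current time series
#'
#' @param time Time grid, ms; strictly increasing and uniform.
#' @param current Current samples; finite, same length as `time`.
#' @param unit `"pA"` or `"pA/pF"` (current density).
#' @param segments Optional data frame annotating protocol segments with
#'   columns `start`, `end` (ms) and `voltage` (mV); must lie within the
#'   trace span.
#' @param label,condition Optional labels.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(time, current, unit = c("pA/pF", "pA"),
                          segments = NULL, label = "", condition = "") {
  unit <- match.arg(unit)
  stopifnot(is.numeric(time), is.numeric(current),
            length(time) == length(current), length(time) >= 2L)
  if (any(!is.finite(current))) stop("current_trace: non-finite samples")
  dts <- diff(time)
  if (any(dts <= 0)) stop("current_trace: time must be strictly increasing")
  if (diff(range(dts)) > 1e-6 * mean(dts))
    stop("current_trace: time grid is not uniform")
  if (!is.null(segments)) {
    stopifnot(is.data.frame(segments),
              all(c("start", "end", "voltage") %in% names(segments)))
    if (min(segments$start) < time[1L] - 1e-9 ||
        max(segments$end) > time[length(time)] + 1e-9)
      stop("current_trace: segment annotations outside trace span")
  }
  structure(list(time = as.numeric(time), current = as.numeric(current),
                 unit = unit, segments = segments,
                 label = as.character(label),
                 condition = as.character(condition)),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %s%s: %d samples, %.6g..%.6g ms, unit %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
              length(x$time), x$time[1L], x$time[length(x$time)], x$unit))
  if (!is.null(x$segments)) {
    cat("  segments:\n")
    print(x$segments, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  plot(x$time, x$current, type = "l", xlab = "time (ms)",
       ylab = paste0("current (", x$unit, ")"), main = x$label, ...)
  if (!is.null(x$segments))
    abline(v = x$segments$start[-1L], col = "grey70", lty = 3)
  invisible(x)
}

# Sample indices of a trace belonging to annotated segment i.
segment_index <- function(trace, segment) {
  if (is.null(trace$segments)) stop("trace has no segment annotations")
  if (segment < 1 || segment > nrow(trace$segments))
    stop("segment index ", segment, " out of range (1..",
         nrow(trace$segments), ")")
  s <- trace$segments[segment, ]
  which(trace$time >= s$start - 1e-9 & trace$time <= s$end + 1e-9)
}

#' Mean current over the final window of a protocol segment
#'
#' The "end-pulse" current of the published current-voltage analysis: the
#' mean of the last `window` ms of the given segment.
#'
#' @param trace A [current_trace()] with segment annotations.
#' @param segment Segment index.
#' @param window Averaging window, ms; must not exceed the segment.
#' @return Mean current (same unit as the trace).
#' @export
measure_end_pulse <- function(trace, segment, window = 50) {
  stopifnot(inherits(trace, "current_trace"), window > 0)
  idx <- segment_index(trace, segment)
  s <- trace$segments[segment, ]
  if (window > s$end - s$start + 1e-9)
    stop("measure_end_pulse: window (", window,
         " ms) longer than segment (", s$end - s$start, " ms)")
  sel <- idx[trace$time[idx] >= s$end - window - 1e-9]
  mean(trace$current[sel])
}

#' Peak of a deactivating tail segment
#'
#' Returns the extremum (largest magnitude) of the current within the
#' segment and its time. The first `skip` samples after the voltage step
#' are excluded so the instantaneous-jump artefact at the segment boundary
#' cannot masquerade as the peak; "hooked" tails whose extremum lies in the
#' segment interior are therefore measured at the hook. The signed current
#' at the extremum is returned (sign convention: whatever the trace
#' carries; outward currents are positive in this package's simulations).
#'
#' @inheritParams measure_end_pulse
#' @param skip Number of initial samples to exclude.
#' @return A list with elements `current` (signed value at the peak) and
#'   `time` (ms).
#' @export
measure_tail_peak <- function(trace, segment, skip = 1) {
  stopifnot(inherits(trace, "current_trace"), skip >= 0)
  idx <- segment_index(trace, segment)
  if (skip > 0 && length(idx) > skip) idx <- idx[-seq_len(skip)]
  if (length(idx) == 0L) stop("measure_tail_peak: empty segment")
  k <- idx[which.max(abs(trace$current[idx]))]
  list(current = trace$current[k], time = trace$time[k])
}

#' Read and write current traces as delimited text
#'
#' Traces are stored as comma-separated `time_ms,current,unit` with `#`
#' header lines carrying the label, condition and segment annotations.
#' Round-trips preserve the grid, samples, unit and annotations.
#'
#' @param path File path.
#' @param trace A [current_trace()].
#' @export
write_trace <- function(path, trace) {
  stopifnot(inherits(trace, "current_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# label: ", trace$label),
               paste0("# condition: ", trace$condition),
               paste0("# segments: ",
                      if (is.null(trace$segments)) "" else
                        jsonlite::toJSON(trace$segments, digits = NA)),
               "time_ms,current,unit"), con)
  writeLines(sprintf("%.17g,%.17g,%s", trace$time, trace$current,
                     trace$unit), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ": ?"), lines[hdr], value = TRUE)
    if (!length(ln)) "" else sub(paste0("^# ", key, ": ?"), "", ln[1L])
  }
  body_start <- if (length(hdr)) max(hdr) + 1L else 1L
  if (!grepl("^time_ms,current,unit", lines[body_start]))
    stop("malformed trace header at line ", body_start, " of ", path,
         ": expected 'time_ms,current,unit'")
  dat <- utils::read.csv(text = lines[body_start:length(lines)])
  if (nrow(dat) < 2L) stop("trace file too short: ", path)
  dts <- diff(dat$time_ms)
  if (any(dts <= 0) || diff(range(dts)) > 1e-6 * mean(dts)) {
    bad <- which(abs(dts - stats::median(dts)) >
                 1e-6 * stats::median(abs(dts)))[1L]
    stop("non-uniform time grid in ", path, " near line ",
         body_start + bad + 1L)
  }
  segjson <- get_field("segments")
  segs <- if (nzchar(segjson))
    as.data.frame(jsonlite::fromJSON(segjson)) else NULL
  current_trace(dat$time_ms, dat$current, unit = unique(dat$unit)[1L],
                segments = segs, label = get_field("label"),
                condition = get_field("condition"))
}
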