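# Current-trace container, file round-trips and measurement operators.

make_segmented_trace <- function(time, current, bounds, volts,
                                 unit = "pA") {
  segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L],
                     voltage = volts)
  current_trace(time, current, unit = unit, segments = segs,
                label = "fixture", condition = "synthetic")
}

test_that("trace validation enforces a uniform, increasing grid", {
  expect_error(current_trace(c(0, 1, 1.5), c(0, 0, 0)), "not uniform")
  expect_error(current_trace(c(0, 1, 0.5), c(0, 0, 0)), "increasing")
  expect_error(current_trace(0:3, c(0, NA, 0, 0)), "non-finite")
})

test_that("trace files round-trip losslessly including unit and segments", {
  tt <- seq(0, 100, by = 0.5)
  tr <- make_segmented_trace(tt, sin(tt / 10) * 3.7, c(0, 40, 100),
                             c(-70, -10), unit = "pA/pF")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(f, tr)
  back <- read_trace(f)
  expect_identical(back$time, tr$time)
  expect_identical(back$current, tr$current)
  expect_identical(back$unit, "pA/pF")
  expect_equal(back$segments, tr$segments)
  expect_identical(back$label, tr$label)
  expect_identical(back$condition, tr$condition)
})

test_that("malformed trace files raise parse errors with locations", {
  tt <- seq(0, 10, by = 1)
  tr <- current_trace(tt, tt * 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(f, tr)
  lines <- readLines(f)
  # shuffle the time column
  body <- lines[-(1:4)]
  writeLines(c(lines[1:4], rev(body)), f)
  expect_error(read_trace(f), "non-uniform time grid")
  writeLines(c(lines[1:3], "t,i,u", body), f)
  expect_error(read_trace(f), "expected 'time_ms,current,unit'")
})

test_that("end-pulse measurement averages the final window", {
  tt <- seq(0, 1000, by = 1)
  tr <- make_segmented_trace(tt, rep(7, length(tt)), c(0, 600, 1000),
                             c(-10, -55))
  expect_equal(measure_end_pulse(tr, 1L, window = 50), 7)
  # linear ramp: mean over the final window in closed form
  ramp <- make_segmented_trace(tt, 0.1 * tt, c(0, 600, 1000), c(-10, -55))
  got <- measure_end_pulse(ramp, 1L, window = 100)
  expect_equal(got, 0.1 * mean(seq(500, 600, by = 1)))
  expect_error(measure_end_pulse(tr, 1L, window = 700), "longer than")
})

test_that("tail-peak measurement finds boundary and interior extrema", {
  tt <- seq(0, 2000, by = 1)
  decay <- 100 * exp(-tt / 300) + 50 * exp(-tt / 40)
  tr <- make_segmented_trace(tt, decay, c(0, 2000), -55)
  pk <- measure_tail_peak(tr, 1L, skip = 0)
  expect_equal(pk$current, decay[1L])
  expect_equal(pk$time, 0)
  # hooked tail: rise then decay, extremum in the interior
  hook <- 100 * exp(-tt / 500) - 80 * exp(-tt / 30)
  trh <- make_segmented_trace(tt, hook, c(0, 2000), -55)
  pkh <- measure_tail_peak(trh, 1L)
  expect_gt(pkh$time, 10)
  expect_equal(pkh$current, max(hook))
  expect_error(measure_tail_peak(trh, 5L), "out of range")
})

test_that("measurements are invariant to a constant time offset", {
  tt <- seq(0, 1000, by = 0.5)
  y <- 30 * exp(-tt / 200) + 3
  tr0 <- make_segmented_trace(tt, y, c(0, 400, 1000), c(-10, -55))
  tr1 <- make_segmented_trace(tt + 12345, y, c(0, 400, 1000) + 12345,
                              c(-10, -55))
  expect_equal(measure_end_pulse(tr0, 2L), measure_end_pulse(tr1, 2L))
  p0 <- measure_tail_peak(tr0, 2L)
  p1 <- measure_tail_peak(tr1, 2L)
  expect_equal(p0$current, p1$current)
  expect_equal(p1$time - p0$time, 12345)
  f0 <- fit_biexp(tr0, segment = 2L)
  f1 <- fit_biexp(tr1, segment = 2L)
  expect_equal(coef(f0), coef(f1), tolerance = 1e-6)
})
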