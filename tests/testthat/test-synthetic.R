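# Synthetic-data generators: exactness, determinism, round-trips, cohorts.

test_that("noiseless generators reproduce the analytic curves exactly", {
  tr <- generate_tail_trace(A1 = 100, A2 = 50, tau1 = 2331, tau2 = 469,
                            A0 = 3, duration = 1000, sampling_khz = 1)
  tt <- tr$time
  expect_identical(tr$current,
                   3 + 100 * exp(-tt / 2331) + 50 * exp(-tt / 469))
  d <- generate_boltzmann_dataset(c(-30, -26.5, 0), V_half = -26.5, s = 6)
  expect_equal(d$current[2L], 0.5)
})

test_that("the same seed reproduces the same draw; different seeds differ", {
  a <- generate_tail_trace(100, 100, 1000, 200, noise_sd = 2, seed = 5,
                           duration = 100, sampling_khz = 1)
  b <- generate_tail_trace(100, 100, 1000, 200, noise_sd = 2, seed = 5,
                           duration = 100, sampling_khz = 1)
  c <- generate_tail_trace(100, 100, 1000, 200, noise_sd = 2, seed = 6,
                           duration = 100, sampling_khz = 1)
  expect_identical(a$current, b$current)
  expect_false(identical(a$current, c$current))
  # the global RNG stream is left untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1)
  invisible(generate_tail_trace(1, 1, 10, 2, noise_sd = 1, seed = 3,
                                duration = 10, sampling_khz = 1))
  expect_identical(rnorm(1), before)
})

test_that("stochastic output without a seed is refused", {
  expect_error(generate_tail_trace(1, 1, 10, 2, noise_sd = 1,
                                   duration = 10), "seed")
  expect_error(generate_boltzmann_dataset(seq(-80, 50, 10), -20, 6,
                                          noise_sd = 0.1), "seed")
  expect_error(generate_tail_trace(1, 1, 10, 2, noise_sd = -1,
                                   duration = 10), "negative")
  expect_error(generate_boltzmann_dataset(numeric(), -20, 6), "empty")
})

test_that("generate-then-fit round-trips converge as noise vanishes", {
  tr <- generate_tail_trace(A1 = 100, A2 = 100, tau1 = 2331, tau2 = 469,
                            duration = 8000)
  cf <- coef(fit_biexp(tr, window = c(0.4, 8000)))
  expect_lt(abs(cf[["tau1"]] - 2331) / 2331, 1e-3)
  expect_lt(abs(cf[["tau2"]] - 469) / 469, 1e-3)
})

test_that("direction flip mirrors the Boltzmann dataset", {
  V <- seq(-60, 20, 10)
  act <- generate_boltzmann_dataset(V, -20, 6, "activation")
  av <- generate_boltzmann_dataset(V, -20, 6, "availability")
  expect_equal(act$current + av$current, rep(1, length(V)))
})

test_that("a zero-variance cohort is degenerate with zero SEM", {
  sp <- cohort_spec(n = 4, means = c(tau1 = 1000, tau2 = 200, A1 = 100,
                                     A2 = 100, A0 = 0),
                    sds = c(tau1 = 0, tau2 = 0, A1 = 0, A2 = 0, A0 = 0),
                    noise_sd = 0, seed = 11)
  ch <- generate_cohort(sp, "tails", duration = 4000, sampling_khz = 1)
  expect_equal(ch$summary$sem, c(0, 0), tolerance = 1e-9)
  expect_equal(length(unique(ch$truth$tau1)), 1L)
})

test_that("the reported SEM is SD/sqrt(n) of the per-cell estimates", {
  sp <- cohort_spec(n = 6, means = c(V_half = -17.4, s = 6),
                    sds = c(V_half = 2, s = 0.5), noise_sd = 0.01,
                    seed = 21)
  ch <- generate_cohort(sp, "boltzmann")
  est <- vapply(ch$fits, function(f) coef(f)[["V_half"]], numeric(1))
  expect_equal(ch$summary$mean[1L], mean(est))
  expect_equal(ch$summary$sem[1L], sd(est) / sqrt(6))
})

test_that("a cohort at published control means recovers the mean tau1", {
  # population SD chosen as SEM * sqrt(n) of the published cohort
  sp <- cohort_spec(n = 12,
                    means = c(tau1 = 1663, tau2 = 314.4, A1 = 100,
                              A2 = 100, A0 = 0),
                    sds = c(tau1 = 118.5 * sqrt(12), tau2 = 26.5 * sqrt(12),
                            A1 = 10, A2 = 10, A0 = 0),
                    noise_sd = 0.02, seed = 42)
  ch <- generate_cohort(sp, "tails", duration = 8000, sampling_khz = 1)
  row <- ch$summary[ch$summary$parameter == "tau1", ]
  # the cohort estimate is unbiased for the cells actually drawn: its mean
  # sits within 2 SEM of the mean generating value of this sample (the
  # sample mean itself scatters around the population mean by design)
  expect_lt(abs(row$mean - mean(ch$truth$tau1)), 2 * row$sem)
  expect_lt(abs(row$mean - mean(ch$truth$tau1)) / mean(ch$truth$tau1),
            0.02)
  # the dispersion across cells is on the order of the published SEM
  expect_gt(row$sem, 50)
  expect_lt(row$sem, 250)
})

test_that("cohorts demand a seed and at least two cells", {
  expect_error(cohort_spec(3, c(tau1 = 1), c(tau1 = 0)), "seed")
  sp <- cohort_spec(1, c(V_half = -20, s = 6), c(V_half = 0, s = 0),
                    seed = 1)
  expect_error(generate_cohort(sp, "boltzmann"), "n >= 2")
})
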