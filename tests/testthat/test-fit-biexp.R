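# Two-exponential deactivation fits: exact recovery, degeneracy handling,
# noise robustness, and agreement with an independent nonlinear
# least-squares route.

table_values <- list(
  control_3uM_step = c(tau1 = 1663, tau2 = 314.4),   # intracellular control
  pss_dose_series = c(tau1 = 2331, tau2 = 469),
  c18_10uM = c(tau1 = 772, tau2 = 191)
)

test_that("noiseless tails are recovered to well under 0.1 percent", {
  for (nm in names(table_values)) {
    tv <- table_values[[nm]]
    tr <- generate_tail_trace(A1 = 100, A2 = 100, tau1 = tv[["tau1"]],
                              tau2 = tv[["tau2"]], duration = 8000)
    f <- fit_biexp(tr, window = c(0.4, 8000))
    expect_true(f$converged, info = nm)
    expect_lt(abs(coef(f)[["tau1"]] - tv[["tau1"]]) / tv[["tau1"]], 1e-3)
    expect_lt(abs(coef(f)[["tau2"]] - tv[["tau2"]]) / tv[["tau2"]], 1e-3)
  }
})

test_that("the fitted curve at the window origin matches the first sample", {
  tr <- generate_tail_trace(A1 = 80, A2 = 40, tau1 = 1500, tau2 = 250,
                            A0 = 10, duration = 6000)
  f <- fit_biexp(tr, window = c(0, 6000))
  cf <- coef(f)
  expect_equal(cf[["A0"]] + cf[["A1"]] + cf[["A2"]], tr$current[1L],
               tolerance = 1e-6)
})

test_that("a mono-exponential input raises the degenerate flag", {
  tr <- generate_tail_trace(A1 = 100, A2 = 0, tau1 = 800, tau2 = 800,
                            duration = 5000, sampling_khz = 1)
  f <- fit_biexp(tr)
  expect_true(f$degenerate)
  expect_true(is.finite(coef(f)[["tau1"]]))
})

test_that("short windows are rejected", {
  tr <- generate_tail_trace(A1 = 100, A2 = 50, tau1 = 800, tau2 = 100,
                            duration = 5000, sampling_khz = 1)
  expect_error(fit_biexp(tr$time[1:20], tr$current[1:20]), "at least 50")
})

test_that("median recovery under 2 percent noise stays within 5 percent", {
  for (nm in c("control_3uM_step", "pss_dose_series")) {
    tv <- table_values[[nm]]
    err1 <- err2 <- numeric(50)
    for (i in 1:50) {
      tr <- generate_tail_trace(A1 = 100, A2 = 100, tau1 = tv[["tau1"]],
                                tau2 = tv[["tau2"]], duration = 8000,
                                sampling_khz = 1, noise_sd = 0.02 * 200,
                                seed = 7000 + i)
      cf <- coef(fit_biexp(tr))
      err1[i] <- abs(cf[["tau1"]] - tv[["tau1"]]) / tv[["tau1"]]
      err2[i] <- abs(cf[["tau2"]] - tv[["tau2"]]) / tv[["tau2"]]
    }
    expect_lt(median(err1), 0.05)
    expect_lt(median(err2), 0.05)
  }
})

test_that("variable-projection fit agrees with an independent nls route", {
  tr <- generate_tail_trace(A1 = 120, A2 = 60, tau1 = 1800, tau2 = 300,
                            A0 = 5, duration = 8000, sampling_khz = 1,
                            noise_sd = 2, seed = 99)
  cf <- coef(fit_biexp(tr))
  ind <- minpack.lm::nlsLM(
    y ~ A0 + A1 * exp(-t / tau1) + A2 * exp(-t / tau2),
    data = data.frame(t = tr$time, y = tr$current),
    start = list(A0 = 0, A1 = 100, A2 = 100, tau1 = 1000, tau2 = 100),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13))
  ci <- coef(ind)
  expect_equal(cf[["tau1"]], ci[["tau1"]], tolerance = 2e-3)
  expect_equal(cf[["tau2"]], ci[["tau2"]], tolerance = 2e-3)
  expect_equal(cf[["A1"]], ci[["A1"]], tolerance = 1e-2)
})

test_that("fits are invariant to a uniform time-unit rescaling", {
  tr <- generate_tail_trace(A1 = 100, A2 = 50, tau1 = 1200, tau2 = 200,
                            duration = 6000, sampling_khz = 1)
  f_ms <- fit_biexp(tr$time, tr$current)
  f_s <- fit_biexp(tr$time / 1000, tr$current)
  expect_equal(coef(f_s)[["tau1"]] * 1000, coef(f_ms)[["tau1"]],
               tolerance = 1e-6)
  expect_equal(coef(f_s)[["tau2"]] * 1000, coef(f_ms)[["tau2"]],
               tolerance = 1e-6)
  expect_equal(coef(f_s)[c("A0", "A1", "A2")],
               coef(f_ms)[c("A0", "A1", "A2")], tolerance = 1e-6)
})

test_that("predict and residuals are consistent with the data", {
  tr <- generate_tail_trace(A1 = 100, A2 = 50, tau1 = 900, tau2 = 150,
                            duration = 5000, sampling_khz = 1)
  f <- fit_biexp(tr)
  expect_equal(fitted(f) + residuals(f), f$data$current)
  expect_lt(max(abs(residuals(f))), 1e-6)
})
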