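# Shared fixtures built in code. Expensive simulations (the 50-beat paced
# runs and the single-step tail simulations) are memoised so several test
# files can assert on the same run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

condition_params <- function(cond) {
  switch(cond, PSS = pss_rates(), C16CAR = c16car_rates(),
         stop("unknown condition ", cond))
}

# 50 pre-paced beats at 1000 ms cycle length, beats 49 and 50 recorded
cached_paced <- function(cond) {
  cached(paste0("paced_", cond), {
    simulate_paced(condition_params(cond),
                   pacing_spec(cycle_length = 1000, beats = 50,
                               record = c(49, 50)))
  })
}

# single 5 s step to -10 mV with an 8 s deactivating tail at -55 mV
cached_single_step <- function(cond) {
  cached(paste0("tail_", cond), {
    fam <- build_single_step_family(dt = 1)
    simulate_family(fam, condition_params(cond), dt_out = 1)
  })
}

# two-exponential fit of the post-peak tail of the single-step trace
cached_tail_fit <- function(cond) {
  cached(paste0("tailfit_", cond), {
    tr <- cached_single_step(cond)$traces[[1L]]
    pk <- measure_tail_peak(tr, 3L)
    fit_biexp(tr, window = c(pk$time, max(tr$time)))
  })
}

# random piecewise-constant protocols for oracle-equivalence properties
random_protocols <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(2:5, 1L)
    voltage_protocol(durations = round(runif(k, 5, 400), 1),
                     voltages = round(runif(k, -120, 50)),
                     dt = 5, label = sprintf("random-%d", i))
  })
}
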