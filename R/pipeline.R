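# End-to-end pipeline: simulate both recording conditions, extract the
# published measurements (IV table, activation/availability Boltzmann
# parameters, tail time constants), simulate paced action potentials, and
# report condition differences in one machine-readable structure.

#' Configuration of an end-to-end pipeline run
#'
#' @param pss_path,c16car_path Optional paths to rate-parameter JSON files;
#'   `NULL` uses the built-in published sets ([pss_rates()],
#'   [c16car_rates()]).
#' @param config A [current_config()] for the clamp stages.
#' @param dt_out Clamp simulation output interval, ms (coarser than the
#'   acquisition default to keep full pipeline runs light).
#' @param tail_ms Tail duration for the deactivation stage, ms.
#' @param beats,cycle_length Pacing for the action-potential stage.
#' @param g_Kr Conductance density for the action-potential stage, nS/pF.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic; the seed is part of the provenance header).
#' @param verbose Log stage progress to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(pss_path = NULL, c16car_path = NULL,
                       config = current_config(), dt_out = 1,
                       tail_ms = 8000, beats = 50, cycle_length = 1000,
                       g_Kr = 0.153, seed = 1L, verbose = FALSE) {
  for (p in c(pss_path, c16car_path))
    if (!is.null(p) && !file.exists(p))
      stop("run_config: parameter file not found: ", p)
  structure(list(pss_path = pss_path, c16car_path = c16car_path,
                 config = config, dt_out = dt_out, tail_ms = tail_ms,
                 beats = beats, cycle_length = cycle_length, g_Kr = g_Kr,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

config_fingerprint <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(cfg, NULL, version = 2L), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages, per condition (control saline and palmitoyl-carnitine):
#' end-pulse current-voltage table from the IV family; activation curve
#' from normalised tail peaks with its Boltzmann fit; availability curve
#' from the two-pulse family with its Boltzmann fit; two-exponential fit
#' of the deactivating tail of the single-step protocol; paced
#' action-potential metrics. The report also carries the
#' condition differences and per-stage status/timing. A failed stage is
#' marked `failed` and stages depending on it are skipped; the function
#' itself does not throw for stage errors.
#'
#' @param cfg A [run_config()].
#' @return A nested list of class `pipeline_report`, serialisable with
#'   [write_report()].
#' @export
pipeline_run <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  log_msg <- function(...) if (cfg$verbose) message(sprintf(...))
  report <- list(seed = cfg$seed, config_hash = config_fingerprint(cfg),
                 stages = list(), conditions = list())

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    el <- proc.time()[["elapsed"]] - t0
    log_msg("stage %-22s %s (%.2f s)", name,
            if (res$ok) "ok" else paste("FAILED:", res$error), el)
    report$stages[[name]] <<- list(
      status = if (res$ok) "ok" else "failed",
      seconds = round(el, 3),
      error = if (res$ok) NULL else res$error)
    if (res$ok) res$value else NULL
  }

  params <- run_stage("load_params", function() list(
    PSS = if (is.null(cfg$pss_path)) pss_rates() else
      load_rate_params(cfg$pss_path),
    C16CAR = if (is.null(cfg$c16car_path)) c16car_rates() else
      load_rate_params(cfg$c16car_path)))
  if (is.null(params)) {
    for (nm in c("clamp", "deactivation", "action_potential"))
      report$stages[[nm]] <- list(status = "skipped",
                                  reason = "load_params failed")
    class(report) <- "pipeline_report"
    return(report)
  }

  clamp <- run_stage("clamp", function() {
    lapply(params, function(p) {
      iv <- simulate_family(build_iv_family(dt = cfg$dt_out), p,
                            cfg$config, dt_out = cfg$dt_out)
      act <- normalize_tail_curve(tail_peaks(iv))
      act_fit <- fit_boltzmann(act$voltage, act$current, "activation")
      av <- simulate_family(build_availability_family(dt = cfg$dt_out), p,
                            cfg$config, dt_out = cfg$dt_out)
      pk <- tail_peaks(av, segment = 4L)
      avn <- normalize_tail_curve(pk)
      av_fit <- fit_boltzmann(avn$voltage, avn$current, "availability")
      list(iv_table = end_pulse_currents(iv),
           activation = list(points = act,
                             V_half = coef(act_fit)[["V_half"]],
                             s = coef(act_fit)[["s"]],
                             converged = act_fit$converged),
           availability = list(points = avn,
                               V_half = coef(av_fit)[["V_half"]],
                               s = coef(av_fit)[["s"]],
                               converged = av_fit$converged))
    })
  })

  deact <- run_stage("deactivation", function() {
    lapply(params, function(p) {
      fam <- simulate_family(build_single_step_family(
        tail_ms = cfg$tail_ms, dt = cfg$dt_out), p, cfg$config,
        dt_out = cfg$dt_out)
      tr <- fam$traces[[1L]]
      pk <- measure_tail_peak(tr, 3L)
      ft <- fit_biexp(tr, window = c(pk$time, max(tr$time)))
      list(tau1 = coef(ft)[["tau1"]], tau2 = coef(ft)[["tau2"]],
           peak = pk$current, degenerate = ft$degenerate,
           converged = ft$converged)
    })
  })

  ap <- run_stage("action_potential", function() {
    lapply(params, function(p) {
      pa <- simulate_paced(p, pacing_spec(cycle_length = cfg$cycle_length,
                                          beats = cfg$beats),
                           g_Kr = cfg$g_Kr)
      last <- pa$beats[nrow(pa$beats), ]
      list(apd90 = last$apd90, apd50 = last$apd50,
           diastolic = last$diastolic, peak = last$peak,
           no_ap = last$no_ap)
    })
  })

  report$conditions <- lapply(names(params), function(nm) {
    c(list(condition = nm),
      if (!is.null(clamp)) clamp[[nm]],
      if (!is.null(deact)) list(deactivation = deact[[nm]]),
      if (!is.null(ap)) list(action_potential = ap[[nm]]))
  })
  names(report$conditions) <- names(params)

  if (!is.null(deact) && !is.null(ap)) {
    report$deltas <- list(
      tau1 = deact$C16CAR$tau1 - deact$PSS$tau1,
      tau2 = deact$C16CAR$tau2 - deact$PSS$tau2,
      apd90 = ap$C16CAR$apd90 - ap$PSS$apd90,
      apd50 = ap$C16CAR$apd50 - ap$PSS$apd50)
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed", x$seed, "hash", x$config_hash, "\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-18s %s\n", nm, x$stages[[nm]]$status))
  if (!is.null(x$deltas)) {
    cat(sprintf("  tau1 delta (C16-PSS): %.4g ms; tau2 delta: %.4g ms\n",
                x$deltas$tau1, x$deltas$tau2))
    cat(sprintf("  APD90 delta (C16-PSS): %.4g ms\n", x$deltas$apd90))
  }
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns",
                       null = "null")
  invisible(path)
}
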