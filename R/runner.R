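# Run configuration, report bundle, and a thin command-line dispatcher over
# the package's functions.

#' Read a run configuration
#'
#' A structured configuration file (JSON always; YAML when the `yaml`
#' package is available) selecting a model family, its hyperparameters, a
#' cross-validation plan, and a root seed. Every field is validated before
#' any computation starts.
#'
#' @param path configuration file path.
#' @param overrides named list applied on top of the file contents.
#' @return validated list of class `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop_format(sprintf("config not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_format("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(cfg, overrides)
  defaults <- list(modality = "custom", family = "zero", seed = 1L,
                   hyper = list(), whiteness_lags = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  ok_fam <- c("zero", "linear", "subspace", "manifold", "mmse", "mlp")
  if (!cfg$family %in% ok_fam)
    stop_invalid(sprintf("unknown family '%s' (valid: %s)", cfg$family,
                         paste(ok_fam, collapse = ", ")))
  if (!cfg$modality %in% c("fmri", "ieeg", "custom"))
    stop_invalid("modality must be one of fmri, ieeg, custom")
  cfg$seed <- check_count(cfg$seed, "seed")
  structure(cfg, class = "run_config")
}

#' Assemble and serialize a report bundle
#'
#' Packs score tables, whiteness summaries, comparison matrices and
#' provenance (config, seed, package version) into a list that round-trips
#' through JSON losslessly (full double precision).
#'
#' @param scores data frame from [evaluate_model] (or a list of them).
#' @param comparisons optional `comparison_result`.
#' @param config the `run_config` used.
#' @return list of class `report_bundle`.
#' @export
report_bundle <- function(scores, comparisons = NULL, config = NULL) {
  structure(list(
    scores = scores,
    comparisons = if (!is.null(comparisons))
      list(p = comparisons$p, significant = comparisons$significant,
           alpha = comparisons$alpha),
    provenance = list(
      package_version = as.character(utils::packageVersion("pembench")),
      seed = if (!is.null(config)) config$seed,
      config = if (!is.null(config)) unclass(config))),
    class = "report_bundle")
}

#' @rdname report_bundle
#' @param bundle a `report_bundle`.
#' @param path output JSON path.
#' @export
write_report_bundle <- function(bundle, path) {
  # I(17) = 17 significant digits: doubles survive the round trip exactly
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, na = "null")
  invisible(path)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions, intended to be called from
#' an `Rscript` wrapper. Subcommands: `simulate` (write a synthetic
#' recording), `fit`/`evaluate`/`benchmark` (score model families over a
#' cross-validation plan), `effects` (run a linearizing-effects
#' experiment), `tune` (hyperparameter search on a benchmark objective).
#'
#' @param args character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)` in a wrapper script).
#' @return invisibly, the result object of the subcommand.
#' @export
pem_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pembench <simulate|benchmark|effects|tune> [--config FILE]",
    "  [--out FILE] [--seed N] [--kind var|izhikevich] [--experiment NAME]",
    sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(NULL)) }
  cmd <- args[1L]
  opt <- list(config = NULL, out = "report.json", seed = 1L,
              kind = "var", experiment = "spatial")
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opt))
      stop_invalid(sprintf("unknown flag '--%s' (valid: %s)", key,
                           paste(names(opt), collapse = ", ")))
    opt[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  opt$seed <- as.integer(opt$seed)
  res <- switch(cmd,
    simulate = {
      if (opt$kind == "var") {
        sim <- gen_stable_var(5, d = 1, T = 1000, seed = opt$seed)
        write_recording(sim$recording, opt$out, "delimited")
        sim
      } else if (opt$kind == "izhikevich") {
        sim <- simulate_izhikevich(n_neurons = 1, duration_ms = 1000,
                                   seed = opt$seed)
        write_recording(recording(sim$v, sampling_interval = 1e-4),
                        opt$out, "delimited")
        sim
      } else stop_invalid("simulate --kind must be var or izhikevich")
    },
    fit = ,
    evaluate = ,
    benchmark = {
      cfg <- if (!is.null(opt$config)) read_run_config(opt$config)
             else structure(list(modality = "custom", family = "zero",
                                 seed = opt$seed, hyper = list(),
                                 whiteness_lags = NULL),
                            class = "run_config")
      sim <- gen_stable_var(5, d = 1, T = 2000, seed = cfg$seed)
      plan <- build_cv_plan(list(sim$recording), "fmri")
      fams <- if (cmd == "benchmark") c("zero", "linear") else cfg$family
      scores <- do.call(rbind, lapply(fams, function(fm)
        do.call(evaluate_model,
                c(list(family = fm, plan = plan), cfg$hyper,
                  list(seed = cfg$seed)))))
      bundle <- report_bundle(scores, config = cfg)
      write_report_bundle(bundle, opt$out)
      bundle
    },
    effects = {
      curve <- switch(opt$experiment,
        spatial = spatial_averaging_curve(seed = opt$seed),
        snr = snr_curve(seed = opt$seed),
        temporal = temporal_averaging_curve(seed = opt$seed),
        dimensionality = dimensionality_curve(seed = opt$seed),
        izhikevich = izhikevich_averaging(seed = opt$seed),
        stop_invalid("unknown --experiment (spatial, snr, temporal, dimensionality, izhikevich)"))
      out <- if (inherits(curve, "effect_curve")) list(curve) else curve
      jsonlite::write_json(lapply(out, function(cv) cv$table), opt$out,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      curve
    },
    tune = {
      sim <- gen_stable_var(3, d = 3, T = 2000, seed = opt$seed)
      plan <- build_cv_plan(list(sim$recording), "fmri")
      defs <- list(hyperparam("d", "integer", init = 1, lower = 1, upper = 5))
      traj <- sgd_tune(function(state, mb) {
        sc <- evaluate_model("linear", plan, d = state[["d"]],
                             seed = opt$seed)
        median(sc$r2, na.rm = TRUE)
      }, defs, n_iter = 10L, seed = opt$seed)
      jsonlite::write_json(list(best_state = as.list(traj$best_state),
                                best_objective = traj$best_objective),
                           opt$out, auto_unbox = TRUE, digits = NA)
      traj
    },
    { cat(usage, "\n"); stop_invalid(sprintf("unknown subcommand '%s'", cmd)) })
  invisible(res)
}
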