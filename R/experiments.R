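#' Summarize a table of trials
#'
#' Deterministic block summary of a trial table with columns `trial`,
#' `choice`, `rt`, `correct`. Undecided trials (`choice` = NA) are counted
#' separately and excluded from accuracy and all RT statistics; accuracy is
#' the fraction correct among decided trials with defined correctness.
#' Summaries pool exactly: the summary of a concatenation of tables equals
#' the weighted combination of the parts.
#'
#' @param trials data frame with columns `trial`, `choice`, `rt`, `correct`.
#' @return An object of class `trial_block`: the table in `$trials` plus
#'   `n_trials`, `n_decided`, `n_undecided`, `accuracy`, `rt_mean`, `rt_var`,
#'   `rt_sem`, and the correct/error splits `rt_mean_correct`,
#'   `rt_mean_error`, `rt_sem_correct`, `rt_sem_error`.
#' @export
summarize_trials <- function(trials) {
  need <- c("trial", "choice", "rt", "correct")
  if (!is.data.frame(trials) || !all(need %in% names(trials)))
    stop("trial table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(trials) == 0L) {
    return(structure(list(trials = trials, n_trials = 0L, n_decided = 0L,
                          n_undecided = 0L, accuracy = NA_real_,
                          rt_mean = NA_real_, rt_var = NA_real_,
                          rt_sem = NA_real_, rt_mean_correct = NA_real_,
                          rt_mean_error = NA_real_, rt_sem_correct = NA_real_,
                          rt_sem_error = NA_real_, empty = TRUE),
                     class = "trial_block"))
  }
  dec <- !is.na(trials$choice)
  rt <- trials$rt[dec]
  scored <- dec & !is.na(trials$correct)
  rt_c <- trials$rt[scored & trials$correct]
  rt_e <- trials$rt[scored & !trials$correct]
  mv <- function(x) if (length(x)) mean(x) else NA_real_
  vv <- function(x) if (length(x) > 1L) stats::var(x) else
    if (length(x) == 1L) 0 else NA_real_
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else
    if (length(x) == 1L) 0 else NA_real_
  structure(list(trials = trials,
                 n_trials = nrow(trials),
                 n_decided = sum(dec),
                 n_undecided = sum(!dec),
                 accuracy = if (any(scored)) mean(trials$correct[scored]) else NA_real_,
                 rt_mean = mv(rt), rt_var = vv(rt), rt_sem = sem(rt),
                 rt_mean_correct = mv(rt_c), rt_mean_error = mv(rt_e),
                 rt_sem_correct = sem(rt_c), rt_sem_error = sem(rt_e),
                 empty = FALSE),
            class = "trial_block")
}

#' @export
print.trial_block <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("Empty trial block\n")
    return(invisible(x))
  }
  cat(sprintf("Trial block: %d trials (%d decided, %d undecided)\n",
              x$n_trials, x$n_decided, x$n_undecided))
  cat(sprintf("  accuracy %.4f | RT mean %.4g, var %.4g, sem %.3g\n",
              x$accuracy, x$rt_mean, x$rt_var, x$rt_sem))
  cat(sprintf("  RT correct %.4g, error %.4g\n",
              x$rt_mean_correct, x$rt_mean_error))
  invisible(x)
}

#' Experiment configuration
#'
#' A validated description of a reproducible experiment: the experiment name
#' (`"hicks"`, `"fig2"`, `"fig3"` or `"custom"`), its parameter block, the
#' trial count and the master seed. Per-component seeds are derived
#' deterministically from the master seed by a fixed counter scheme, so any
#' sub-computation is reproducible in isolation. Configurations round-trip
#' through YAML with [write_config()] / [read_config()].
#'
#' Parameter blocks (flat key/value):
#' \describe{
#'   \item{hicks}{`n_list`, `target_accuracy`, `I1`, `sigma`, `tau`, `theta0`
#'     (starting threshold for calibration), `dt`, `t_max`.}
#'   \item{fig2}{`n`, `sigma`, `theta`, `dt`, `t_max`, `I1_grid`,
#'     `calibration_trials` (0 skips fixed-threshold calibration).}
#'   \item{fig3}{`n`, `tau`, `tau_I`, `s`, `c`, `g`, `I0`, `sigma`, `theta`,
#'     `duration`, `dt`, `epsilon`.}
#' }
#'
#' @param experiment experiment name.
#' @param params named list, the experiment's parameter block.
#' @param n_trials number of trials.
#' @param seed master seed (integer).
#' @param out_dir output directory for [run_experiment()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("hicks", "fig2", "fig3", "custom"),
                              params = list(), n_trials = 1000, seed = 1L,
                              out_dir = tempdir()) {
  experiment <- match.arg(experiment)
  if (n_trials < 1) stop("config error at `n_trials`: must be >= 1", call. = FALSE)
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("config error at `seed`: must be a single integer", call. = FALSE)
  defaults <- switch(experiment,
    hicks = list(n_list = c(2, 4, 8), target_accuracy = 0.8, I1 = 0.0116,
                 sigma = 1, tau = 20, theta0 = 3, dt = 1, t_max = 1e5),
    fig2 = list(n = 3, sigma = 0.03, theta = 1.05, dt = 0.05, t_max = 1e4,
                I1_grid = c(0, 0.005, 0.01), calibration_trials = 0),
    fig3 = list(n = 3, tau = 20, tau_I = 10, s = 1, c = 1, g = 1, I0 = 0.5,
                sigma = 0.01, theta = 0.5, duration = 8000, dt = 0.1,
                epsilon = 1),
    custom = list())
  unknown <- setdiff(names(params), names(defaults))
  if (experiment != "custom" && length(unknown))
    stop("config error at `params.", unknown[1], "`: unknown key", call. = FALSE)
  defaults[names(params)] <- params
  structure(list(experiment = experiment, params = defaults,
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path file path of a YAML configuration.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  experiment_config(experiment = raw$experiment,
                    params = if (is.null(raw$params)) list() else raw$params,
                    n_trials = raw$n_trials, seed = raw$seed,
                    out_dir = if (is.null(raw$out_dir)) tempdir() else raw$out_dir)
}

#' @rdname experiment_config
#' @param config an `experiment_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a configured experiment
#'
#' Dispatches on the experiment name, writes the trial / summary tables as
#' CSV, a JSON summary, and a provenance record (full configuration, seed and
#' package version) into `config$out_dir`. The same configuration always
#' produces byte-identical outputs.
#'
#' @param config an [experiment_config()].
#' @return Invisibly, a named character vector of the files written, with the
#'   computed result object in attribute `"result"`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  result <- switch(config$experiment,
    hicks = {
      base <- ddm_params(n = 2, tau = p$tau, I = c(p$I1, 0), sigma = p$sigma,
                         theta = p$theta0, dt = p$dt, t_max = p$t_max)
      hicks_experiment(p$n_list, p$target_accuracy, base,
                       n_trials = config$n_trials, seed = config$seed)
    },
    fig2 = {
      mp <- msprt_params(n = p$n, I = 0, sigma = p$sigma, theta = p$theta,
                         dt = p$dt, t_max = p$t_max)
      theta_fixed <- if (p$calibration_trials > 0)
        calibrate_fixed_threshold(mp, n_trials = p$calibration_trials,
                                  seed = config$seed)$theta_fixed
      else p$theta
      list(table = run_fig2_comparison(p$I1_grid, mp,
                                       n_trials = config$n_trials,
                                       seed = config$seed,
                                       theta_fixed = theta_fixed),
           theta_fixed = theta_fixed)
    },
    fig3 = {
      np <- network_params(n = p$n, tau = p$tau, tau_I = p$tau_I, s = p$s,
                           c = p$c, g = p$g, I = p$I0, sigma = p$sigma,
                           phi = transfer_piecewise_sqrt())
      track_network(np, epsilon = p$epsilon, theta = p$theta,
                    duration = p$duration, dt = p$dt,
                    n_trials = config$n_trials, seed = config$seed)
    },
    custom = stop("custom experiments are run through the package API directly",
                  call. = FALSE))
  files <- c()
  written <- function(name) file.path(config$out_dir, name)
  ok <- FALSE
  on.exit(if (!ok) unlink(files), add = TRUE)
  if (config$experiment == "hicks") {
    utils::write.csv(result$table, written("hicks_table.csv"), row.names = FALSE)
    jsonlite::write_json(list(fit = result$fit, fit_linear = result$fit_linear,
                              var_mean = result$var_mean),
                         written("hicks_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(table = written("hicks_table.csv"),
               summary = written("hicks_summary.json"))
  } else if (config$experiment == "fig2") {
    utils::write.csv(result$table, written("fig2_table.csv"), row.names = FALSE)
    jsonlite::write_json(list(theta_fixed = result$theta_fixed),
                         written("fig2_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(table = written("fig2_table.csv"),
               summary = written("fig2_summary.json"))
  } else if (config$experiment == "fig3") {
    utils::write.csv(result$trials, written("fig3_trials.csv"), row.names = FALSE)
    jsonlite::write_json(list(agreement = result$agreement,
                              n_both_decided = result$n_both_decided,
                              mean_rt_diff = result$mean_rt_diff,
                              max_deviation = result$max_deviation),
                         written("fig3_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(table = written("fig3_trials.csv"),
               summary = written("fig3_summary.json"))
  }
  prov <- written("provenance.json")
  jsonlite::write_json(list(config = unclass(config),
                            package_version =
                              as.character(utils::packageVersion("multiddm"))),
                       prov, auto_unbox = TRUE, digits = NA)
  files <- c(files, provenance = prov)
  ok <- TRUE
  attr(files, "result") <- result
  invisible(files)
}
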