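#' Parameters for the multiple sequential probability ratio test
#'
#' Evidence for alternative i arrives as increments
#' `dy_i = I_i dt + sigma sqrt(dt) N(0,1)` (Gaussian evidence with mean `I_i`
#' and variance `sigma^2` per unit time; time is dimensionless, tau = 1). The
#' Bayesian test integrates the log-posterior dynamics
#' `dL_i = dy_i - sum_k w_k dy_k` (softmax weights `w = softmax(y)`) and its
#' common mode `M_C` from `L_i(0) = M_C(0) = 0`, and reports alternative i
#' when the competition part of the log-posterior exceeds the moving bound
#' `theta - M_C(t)`.
#'
#' Two integration schemes for the common mode are provided via `update`:
#' \describe{
#'   \item{`"euler"` (default)}{Euler-Maruyama stepping of the common-mode
#'     ODE, the same scheme used for every other stochastic model in the
#'     package. The discrete integral of the log-normalizer then lacks its
#'     Ito drift (about `sigma^2 (1 - sum(w^2)) / 2` per unit time), so at
#'     zero coherence `M_C` stays near 0 and the moving bound stays near
#'     `theta`. This is the convention under which the published
#'     fixed-threshold calibration (1.05 with a moving threshold matching
#'     1.073 fixed, at sigma = 0.03, n = 3) is reproduced.}
#'   \item{`"exact"`}{closed-form update `M_C = mean(y) - logsumexp(y) +
#'     ln(n)`, the exact continuum integral. The rule is then the posterior
#'     criterion `exp(L_i) >= exp(theta)/n`, satisfiable only for
#'     `theta < ln(n)` (the normalized log-posterior is bounded above by 0;
#'     a warning is issued otherwise). This is substantially more
#'     conservative at the same theta: the accumulated Ito correction makes
#'     the moving bound grow, and zero-coherence reaction times are several
#'     times longer than under `"euler"`.}
#' }
#' In both schemes the reported log-posterior state `L` is the exactly
#' normalized `y - logsumexp(y)` (so `sum(exp(L)) = 1` to machine precision),
#' and the Bayesian and moving-threshold-DDM routes are algebraically
#' identical trial by trial.
#'
#' @param n number of alternatives.
#' @param I length-n vector of evidence means.
#' @param sigma evidence noise intensity per unit time.
#' @param theta decision threshold (log-posterior scale).
#' @param dt time step (tau = 1 units).
#' @param t_max trial cutoff; undecided trials are excluded from RT statistics.
#' @param update common-mode integration scheme, `"euler"` or `"exact"`.
#' @return An object of class `msprt_params`.
#' @export
msprt_params <- function(n = 3, I = 0, sigma = 0.03, theta = 1.05,
                         dt = 0.05, t_max = 1e4,
                         update = c("euler", "exact")) {
  if (length(n) != 1L || n != round(n) || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (!(t_max > dt && dt > 0)) stop("need t_max > dt > 0", call. = FALSE)
  update <- match.arg(update)
  if (update == "exact" && theta >= log(n))
    warning("theta >= ln(n): the posterior criterion exp(L) >= exp(theta)/n is unsatisfiable",
            call. = FALSE)
  n <- as.integer(n)
  structure(list(n = n, I = rep_len(as.numeric(I), n), sigma = sigma,
                 theta = theta, dt = dt, t_max = t_max, update = update),
            class = "msprt_params")
}

#' @export
print.msprt_params <- function(x, ...) {
  cat(sprintf("MSPRT: n = %d, sigma = %g, theta = %g, dt = %g, t_max = %g, update = %s\n  I = (%s)\n",
              x$n, x$sigma, x$theta, x$dt, x$t_max, x$update,
              paste(signif(x$I, 4), collapse = ", ")))
  invisible(x)
}

.update_code <- function(params) if (params$update == "euler") 1L else 0L

.msprt_one <- function(params, mode, seed, return_path, noise, theta) {
  if (!is.null(seed)) set.seed(seed)
  nsteps <- as.integer(round(params$t_max / params$dt))
  res <- msprt_trials_cpp(params$n, params$I, params$sigma, theta,
                          params$dt, nsteps, mode, 1L, .update_code(params),
                          return_path, noise)
  row <- res$trials[1, ]
  decided <- row[1] > 0
  target <- .correct_target(params$I)
  out <- list(choice = if (decided) as.integer(row[1]) else NA_integer_,
              rt = row[2], decided = decided,
              correct = if (!decided || is.na(target)) NA else row[1] == target,
              posterior_at_decision = if (decided) row[3] else NA_real_)
  if (return_path) {
    out$y <- res$y
    out$L <- res$L
    out$M_C <- res$M_C
    out$times <- seq(0, by = params$dt, length.out = nrow(res$y))
  }
  structure(out, class = "msprt_trial")
}

#' @export
print.msprt_trial <- function(x, ...) {
  if (x$decided)
    cat(sprintf("Choice %d at t = %g (posterior %.4f)\n", x$choice, x$rt,
                x$posterior_at_decision))
  else cat(sprintf("Undecided at t_max = %g\n", x$rt))
  invisible(x)
}

#' Simulate one Bayesian MSPRT trial
#'
#' Maintains the accumulated evidence `y`, the exactly normalized
#' log-posteriors `L = y - logsumexp(y)` (so `sum(exp(L)) = 1` at every step
#' by construction) and the common mode `M_C`; decides when the
#' competition-basis reconstruction of `L` reaches `theta - M_C(t)`.
#'
#' @param params an [msprt_params()].
#' @param seed optional integer seed.
#' @param return_path if `TRUE`, also return the `y`, `L` and `M_C`
#'   trajectories (truncated at the decision).
#' @param noise optional n x nsteps standard-normal matrix (shared noise,
#'   single trial).
#' @return A list of class `msprt_trial`: `choice`, `rt`, `correct`,
#'   `decided`, `posterior_at_decision`, and the trajectories when requested.
#' @export
simulate_bayesian_trial <- function(params, seed = NULL, return_path = FALSE,
                                    noise = NULL) {
  stopifnot(inherits(params, "msprt_params"))
  .msprt_one(params, 0L, seed, return_path, noise, params$theta)
}

#' Simulate one moving-threshold DDM trial
#'
#' The pure DDM route to the same test: the decision variables `X_k` are
#' accumulated directly from the projected evidence increments (tau = 1), and
#' the reconstruction `-(i-1) X_{i-1} + sum_{l>=i} X_l` is compared with the
#' moving bound `theta - M_C(t)`. Because the logsumexp term of the
#' log-posteriors is pure common mode, this is mathematically identical to
#' [simulate_bayesian_trial()]: under shared noise the two produce the same
#' choice and reaction time on every trial.
#'
#' @inheritParams simulate_bayesian_trial
#' @return A list of class `msprt_trial`.
#' @export
simulate_mt_ddm_trial <- function(params, seed = NULL, return_path = FALSE,
                                  noise = NULL) {
  stopifnot(inherits(params, "msprt_params"))
  .msprt_one(params, 1L, seed, return_path, noise, params$theta)
}

#' Simulate one fixed-threshold DDM trial
#'
#' Same decision variables as [simulate_mt_ddm_trial()] but with a constant
#' bound `theta` in place of the moving bound.
#'
#' @inheritParams simulate_bayesian_trial
#' @param theta fixed threshold (defaults to `params$theta`).
#' @return A list of class `msprt_trial`.
#' @export
simulate_fixed_ddm_trial <- function(params, seed = NULL, return_path = FALSE,
                                     noise = NULL, theta = params$theta) {
  stopifnot(inherits(params, "msprt_params"))
  .msprt_one(params, 2L, seed, return_path, noise, theta)
}

#' Run a block of MSPRT-family trials
#'
#' @param params an [msprt_params()].
#' @param n_trials number of trials.
#' @param model `"bayesian"`, `"mt"` (moving-threshold DDM) or `"fixed"`.
#' @param seed optional integer seed.
#' @param theta threshold override (used for the fixed model's calibrated
#'   value; defaults to `params$theta`).
#' @param correct_choice which alternative counts as correct (defaults to the
#'   argmax of `I`; at zero coherence, pass 1 to score the designated target).
#' @param trial_seeds optional integer vector of per-trial seeds (length
#'   `n_trials`); when given, trial i consumes a private noise stream seeded
#'   by `trial_seeds[i]`, so two models or two thresholds evaluated with the
#'   same vector see common random numbers trial by trial.
#' @return A `trial_block` (see [summarize_trials()]).
#' @export
run_msprt_block <- function(params, n_trials, model = c("bayesian", "mt", "fixed"),
                            seed = NULL, theta = params$theta,
                            correct_choice = NULL, trial_seeds = NULL) {
  stopifnot(inherits(params, "msprt_params"), n_trials >= 1)
  model <- match.arg(model)
  mode <- match(model, c("bayesian", "mt", "fixed")) - 1L
  nsteps <- as.integer(round(params$t_max / params$dt))
  upd <- .update_code(params)
  if (is.null(trial_seeds)) {
    if (!is.null(seed)) set.seed(seed)
    res <- msprt_trials_cpp(params$n, params$I, params$sigma, theta,
                            params$dt, nsteps, mode, as.integer(n_trials),
                            upd, FALSE, NULL)
    m <- res$trials
  } else {
    stopifnot(length(trial_seeds) == n_trials)
    m <- matrix(NA_real_, n_trials, 3L)
    for (i in seq_len(n_trials)) {
      set.seed(trial_seeds[i])
      m[i, ] <- msprt_trials_cpp(params$n, params$I, params$sigma, theta,
                                 params$dt, nsteps, mode, 1L, upd,
                                 FALSE, NULL)$trials[1, ]
    }
  }
  target <- if (is.null(correct_choice)) .correct_target(params$I) else correct_choice
  df <- data.frame(trial = seq_len(nrow(m)),
                   choice = ifelse(m[, 1] > 0, m[, 1], NA_integer_),
                   rt = m[, 2],
                   correct = if (is.na(target)) NA else
                     ifelse(m[, 1] > 0, m[, 1] == target, NA))
  summarize_trials(df)
}

#' Calibrate a fixed threshold to match the Bayesian model's mean RT
#'
#' At zero coherence (all evidence means equal), bisection-searches the
#' constant threshold of the fixed-threshold DDM until its mean decided
#' reaction time matches that of the Bayesian (moving-threshold) test run at
#' `params$theta`. Common random numbers are used across evaluations: trial i
#' always runs on a private stream seeded by `seed + i`, so the mean RT is a
#' smooth, monotone function of the threshold (checked over the bracket) and
#' the bisection is stable.
#'
#' @param params an [msprt_params()] with zero-coherence inputs.
#' @param n_trials trials per evaluation (the reference uses the same count).
#' @param seed integer seed for the common random numbers.
#' @param tol bisection tolerance on the threshold (default 1e-3).
#' @param bracket search interval for the fixed threshold.
#' @param model reference model (`"bayesian"` by default; calibrating `"mt"`
#'   or `"fixed"` against itself returns `params$theta` up to tolerance).
#' @param coarse_trials optional smaller trial count used for a first, cheap
#'   bisection pass; the full-`n_trials` pass then only refines a narrow
#'   bracket around the coarse root.
#' @return A list: `theta_fixed`, `rt_target` (reference mean RT), `rt_fixed`
#'   (achieved), `evaluations`.
#' @export
calibrate_fixed_threshold <- function(params, n_trials = 10000, seed = 1L,
                                      tol = 2.5e-3, bracket = NULL,
                                      model = "bayesian",
                                      coarse_trials = NULL) {
  stopifnot(inherits(params, "msprt_params"))
  if (diff(range(params$I)) != 0)
    stop("calibration requires zero-coherence inputs", call. = FALSE)
  trial_seeds <- (as.integer(seed) + seq_len(n_trials)) %% .Machine$integer.max
  ref <- run_msprt_block(params, n_trials, model = model,
                         correct_choice = 1L, trial_seeds = trial_seeds)
  rt_target <- ref$rt_mean
  if (is.null(bracket)) bracket <- c(params$theta * 0.6, params$theta * 1.6)
  if (!is.null(coarse_trials) && coarse_trials < n_trials) {
    coarse <- calibrate_fixed_threshold(params, n_trials = coarse_trials,
                                        seed = seed, tol = tol,
                                        bracket = bracket, model = model)
    half <- max(0.015, 5 * tol)
    bracket <- c(max(bracket[1], coarse$theta_fixed - half),
                 min(bracket[2], coarse$theta_fixed + half))
  }
  rt_at <- function(th) {
    blk <- run_msprt_block(params, n_trials, model = "fixed",
                           theta = th, correct_choice = 1L,
                           trial_seeds = trial_seeds)
    blk$rt_mean
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- rt_at(lo); f_hi <- rt_at(hi)
  evals <- 2L
  if (f_hi < f_lo)
    stop("calibration failure: mean RT not increasing over the bracket", call. = FALSE)
  if (rt_target < f_lo || rt_target > f_hi) {
    if (!is.null(coarse_trials)) {
      # narrowed bracket missed the root; fall back to the full one
      lo <- params$theta * 0.6; hi <- params$theta * 1.6
      f_lo <- rt_at(lo); f_hi <- rt_at(hi); evals <- evals + 2L
    }
    if (rt_target < f_lo || rt_target > f_hi)
      stop("calibration failure: target RT not bracketed", call. = FALSE)
  }
  while ((hi - lo) > tol) {
    mid <- (lo + hi) / 2
    f_mid <- rt_at(mid)
    evals <- evals + 1L
    if (f_mid < rt_target) lo <- mid else hi <- mid
    if (evals > 40L) break
  }
  theta_fixed <- (lo + hi) / 2
  list(theta_fixed = theta_fixed, rt_target = rt_target,
       rt_fixed = rt_at(theta_fixed), evaluations = evals + 1L)
}

#' Three-model accuracy/RT comparison over an input grid
#'
#' Sweeps the mean of input 1 (inputs 2..n stay at zero) and tabulates
#' accuracy (fraction choosing alternative 1) and correct/error reaction
#' times, with standard errors, for the Bayesian test, the moving-threshold
#' DDM and the fixed-threshold DDM. The fixed model's threshold should first
#' be matched at zero coherence with [calibrate_fixed_threshold()].
#'
#' @param I1_grid numeric vector of input-1 means.
#' @param params an [msprt_params()] (its `I` is overridden on the grid).
#' @param n_trials trials per model and grid point.
#' @param seed integer seed; each grid point gets a deterministic derived
#'   seed, shared by the three models, so the Bayesian and moving-threshold
#'   rows are generated from identical noise streams (and come out
#'   identical), and the fixed-threshold row sees common random numbers.
#' @param theta_fixed threshold for the fixed model (defaults to
#'   `params$theta`, i.e. uncalibrated).
#' @return A data frame with columns model, I1, n_decided, accuracy,
#'   accuracy_sem, rt_mean, rt_correct, rt_error, rt_sem.
#' @export
run_fig2_comparison <- function(I1_grid, params, n_trials = 2000, seed = 1L,
                                theta_fixed = params$theta) {
  stopifnot(inherits(params, "msprt_params"))
  models <- c("bayesian", "mt", "fixed")
  rows <- list()
  for (mi in seq_along(models)) {
    for (gi in seq_along(I1_grid)) {
      p <- params
      p$I <- c(I1_grid[gi], rep(0, params$n - 1L))
      th <- if (models[mi] == "fixed") theta_fixed else params$theta
      blk <- run_msprt_block(p, n_trials, model = models[mi],
                             seed = seed + 1009L * gi,
                             theta = th, correct_choice = 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        model = models[mi], I1 = I1_grid[gi], n_decided = blk$n_decided,
        accuracy = blk$accuracy,
        accuracy_sem = sqrt(blk$accuracy * (1 - blk$accuracy) /
                              max(blk$n_decided, 1L)),
        rt_mean = blk$rt_mean, rt_correct = blk$rt_mean_correct,
        rt_error = blk$rt_mean_error, rt_sem = blk$rt_sem)
    }
  }
  do.call(rbind, rows)
}
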