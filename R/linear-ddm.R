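#' Parameters for the (n-1)-dimensional linear DDM
#'
#' The reduced drift-diffusion model obtained by projecting the `s = 1` linear
#' competition network onto the competition basis. The k-th decision variable
#' obeys `tau * dX_k = (e_k . I) / (k + k^2) dt + (e_k . xi) / (k + k^2)`,
#' with n independent population noise streams `xi_i` of intensity `sigma`
#' projected onto the basis, so the decision variables are coupled only
#' through their noise correlations. A trial ends at the first step where any
#' reconstructed coordinate
#' `-(i-1) X_{i-1} + sum_{l>=i} X_l + m_C_offset` reaches `theta`
#' (population i wins); ties are broken by largest overshoot, then lowest
#' index.
#'
#' @param n number of alternatives.
#' @param tau integration time constant (ms).
#' @param I length-n input vector; its projections onto the competition
#'   vectors are the drifts.
#' @param sigma noise intensity of each population stream.
#' @param theta decision threshold on the reconstructed coordinates (the
#'   neuronal threshold `r_th` minus the common-mode steady state `M_C`,
#'   already absorbed).
#' @param m_C_offset constant common-mode value used in reconstruction
#'   (default 0).
#' @param dt integration step (ms).
#' @param t_max trial cutoff (ms); a trial still undecided at `t_max` has
#'   `choice = NA` and is excluded from accuracy and RT statistics.
#' @param x0 initial decision variables (default all zero).
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(n, tau = 20, I, sigma = 1, theta, m_C_offset = 0,
                       dt = 0.1, t_max = 2e4, x0 = 0) {
  if (length(n) != 1L || n != round(n) || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (theta <= 0) stop("`theta` must be positive", call. = FALSE)
  if (!(t_max > dt && dt > 0)) stop("need t_max > dt > 0", call. = FALSE)
  n <- as.integer(n)
  structure(list(n = n, tau = tau, I = rep_len(as.numeric(I), n),
                 sigma = sigma, theta = theta, m_C_offset = m_C_offset,
                 dt = dt, t_max = t_max, x0 = rep_len(as.numeric(x0), n - 1L)),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "Linear DDM: n = %d, tau = %g ms, sigma = %g, theta = %g, dt = %g ms, t_max = %g ms\n  I = (%s)\n",
    x$n, x$tau, x$sigma, x$theta, x$dt, x$t_max,
    paste(signif(x$I, 4), collapse = ", ")))
  invisible(x)
}

.correct_target <- function(I) {
  top <- which(I == max(I))
  if (length(top) > 1L) NA_integer_ else top
}

#' Simulate a single linear DDM trial
#'
#' @param params a [ddm_params()].
#' @param seed optional integer seed.
#' @param return_path if `TRUE`, also return the decision-variable trajectory
#'   (matrix with one column per `X_k`, truncated at the decision).
#' @param noise optional n x nsteps matrix of pre-drawn standard-normal
#'   deviates (shared-noise comparisons; single trial only).
#' @return A list of class `ddm_trial`: `choice` (1..n, or `NA` if undecided),
#'   `rt` (ms), `correct` (`TRUE`/`FALSE`, or `NA` when undecided or when the
#'   inputs tie), `decided`, and optionally `path`.
#' @export
simulate_ddm_trial <- function(params, seed = NULL, return_path = FALSE,
                               noise = NULL) {
  stopifnot(inherits(params, "ddm_params"))
  if (!is.null(seed)) set.seed(seed)
  nsteps <- as.integer(round(params$t_max / params$dt))
  res <- ddm_trials_cpp(params$n, params$tau, params$I, params$sigma,
                        params$theta, params$m_C_offset, params$dt, nsteps,
                        params$x0, 1L, return_path, noise)
  .ddm_trial(res$trials[1, ], params, path = res$path)
}

.ddm_trial <- function(row, params, path = NULL) {
  decided <- row[1] > 0
  target <- .correct_target(params$I)
  structure(list(choice = if (decided) as.integer(row[1]) else NA_integer_,
                 rt = row[2], decided = decided,
                 correct = if (!decided || is.na(target)) NA else row[1] == target,
                 path = path),
            class = "ddm_trial")
}

#' @export
print.ddm_trial <- function(x, ...) {
  if (x$decided)
    cat(sprintf("Choice %d at rt = %g ms (correct: %s)\n", x$choice, x$rt,
                format(x$correct)))
  else cat(sprintf("Undecided at t_max = %g ms\n", x$rt))
  invisible(x)
}

#' Run a block of linear DDM trials
#'
#' Aggregates seeded, reproducible trials and reports accuracy and reaction
#' time statistics, split by correct and error trials. Undecided trials are
#' excluded from accuracy and RT statistics and counted separately.
#'
#' @param params a [ddm_params()].
#' @param n_trials number of trials.
#' @param seed optional integer seed (same seed, bit-identical block).
#' @return An object of class `trial_block` (see [summarize_trials()]), with
#'   the per-trial table in `$trials`.
#' @export
run_ddm_block <- function(params, n_trials, seed = NULL) {
  stopifnot(inherits(params, "ddm_params"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  nsteps <- as.integer(round(params$t_max / params$dt))
  res <- ddm_trials_cpp(params$n, params$tau, params$I, params$sigma,
                        params$theta, params$m_C_offset, params$dt, nsteps,
                        params$x0, as.integer(n_trials), FALSE, NULL)
  m <- res$trials
  target <- .correct_target(params$I)
  df <- data.frame(trial = seq_len(nrow(m)),
                   choice = ifelse(m[, 1] > 0, m[, 1], NA_integer_),
                   rt = m[, 2],
                   correct = if (is.na(target)) NA else
                     ifelse(m[, 1] > 0, m[, 1] == target, NA))
  summarize_trials(df)
}

#' Calibrate the decision threshold to a target accuracy
#'
#' Accuracy is non-decreasing in the threshold, so a bisection search with
#' common random numbers (the same seed is reused for every evaluation)
#' converges to a threshold whose block accuracy is within `tol` of
#' `target_accuracy`.
#'
#' @param params a [ddm_params()] with a non-degenerate (non-tied) input.
#' @param target_accuracy desired fraction correct, in (1/n, 1).
#' @param n_trials trials per evaluation.
#' @param tol acceptable accuracy mismatch (default 0.01).
#' @param theta_bracket search interval for theta.
#' @param seed integer seed for the common random numbers.
#' @return A list with `theta`, `accuracy` (achieved at `theta`), and
#'   `evaluations`.
#' @export
calibrate_threshold <- function(params, target_accuracy, n_trials = 2000,
                                tol = 0.01, theta_bracket = NULL, seed = 1L) {
  stopifnot(inherits(params, "ddm_params"))
  if (is.na(.correct_target(params$I)))
    stop("degenerate target: inputs tie, every threshold gives chance accuracy",
         call. = FALSE)
  if (target_accuracy <= 1 / params$n || target_accuracy >= 1)
    stop("target accuracy must lie in (1/n, 1)", call. = FALSE)
  if (is.null(theta_bracket)) theta_bracket <- c(params$theta / 10, params$theta * 4)
  acc_at <- function(theta) {
    p <- params; p$theta <- theta
    blk <- run_ddm_block(p, n_trials, seed = seed)
    if (blk$n_decided == 0L)
      stop("calibration failure: no decided trials at theta = ", signif(theta, 4),
           "; shrink the bracket or raise t_max", call. = FALSE)
    blk$accuracy
  }
  lo <- theta_bracket[1]; hi <- theta_bracket[2]
  a_lo <- acc_at(lo); a_hi <- acc_at(hi)
  evals <- 2L
  if (a_lo > target_accuracy || a_hi < target_accuracy)
    stop("calibration failure: target accuracy not bracketed by theta range",
         call. = FALSE)
  if (a_hi < a_lo)
    stop("calibration failure: accuracy not increasing over bracket", call. = FALSE)
  theta <- (lo + hi) / 2; acc <- acc_at(theta)
  while (abs(acc - target_accuracy) > tol && (hi - lo) > 1e-6 * theta_bracket[2]) {
    if (acc < target_accuracy) lo <- theta else hi <- theta
    theta <- (lo + hi) / 2
    acc <- acc_at(theta)
    evals <- evals + 1L
    if (evals > 60L) break
  }
  list(theta = theta, accuracy = acc, evaluations = evals)
}

#' Hick's-law experiment: reaction time versus number of alternatives
#'
#' For each n in `n_list`, the threshold is calibrated so that block accuracy
#' equals `target_accuracy`, a fresh block is simulated, and the mean and
#' variance of the decided reaction times are recorded. The mean RT is then
#' fit with the logarithmic law `RT = a + b * ln(c + n)` by nonlinear least
#' squares (and, for comparison, with a straight line in n), and the RT
#' variance is regressed on the mean RT.
#'
#' The input convention is a drift toward alternative 1: for each n the input
#' vector is `c(I_1, 0, ..., 0)` with `I_1` taken from `base$I[1]`.
#'
#' @param n_list integer vector of alternative counts (>= 3 values).
#' @param target_accuracy fixed accuracy across n.
#' @param base a [ddm_params()] providing tau, sigma, dt, t_max and the drift.
#' @param n_trials trials per block.
#' @param seed integer seed.
#' @param calibration_trials trials per calibration evaluation (defaults to
#'   `n_trials`).
#' @return An object of class `hicks_result`: `table` (n, theta, accuracy,
#'   rt_mean, rt_var), `fit` (a, b, c, rss), `fit_linear` (rss of RT ~ n),
#'   `var_mean` (slope, intercept, r_squared of variance vs mean).
#' @export
hicks_experiment <- function(n_list, target_accuracy, base, n_trials = 4000,
                             seed = 1L, calibration_trials = n_trials) {
  if (length(n_list) < 3L)
    stop("fit underdetermined: need at least 3 values of n", call. = FALSE)
  stopifnot(inherits(base, "ddm_params"))
  rows <- lapply(seq_along(n_list), function(j) {
    n <- n_list[j]
    p <- ddm_params(n = n, tau = base$tau, I = c(base$I[1], rep(0, n - 1L)),
                    sigma = base$sigma, theta = base$theta,
                    m_C_offset = base$m_C_offset, dt = base$dt,
                    t_max = base$t_max)
    # more competitors dilute accuracy at a given threshold, so the search
    # interval has to grow with n
    cal <- calibrate_threshold(p, target_accuracy, n_trials = calibration_trials,
                               seed = seed + j,
                               theta_bracket = c(base$theta / 10,
                                                 1.5 * n * base$theta))
    p$theta <- cal$theta
    blk <- run_ddm_block(p, n_trials, seed = seed + 1000L + j)
    data.frame(n = n, theta = cal$theta, accuracy = blk$accuracy,
               rt_mean = blk$rt_mean, rt_var = blk$rt_var)
  })
  tab <- do.call(rbind, rows)
  fit <- fit_hicks_law(tab$n, tab$rt_mean)
  lin <- stats::lm(rt_mean ~ n, data = tab)
  vm <- stats::lm(rt_var ~ rt_mean, data = tab)
  structure(list(
    table = tab,
    fit = fit,
    fit_linear = list(rss = sum(stats::residuals(lin)^2)),
    var_mean = list(slope = unname(stats::coef(vm)[2]),
                    intercept = unname(stats::coef(vm)[1]),
                    r_squared = summary(vm)$r.squared)),
    class = "hicks_result")
}

#' Fit the logarithmic reaction-time law
#'
#' Nonlinear least-squares fit of `RT = a + b * ln(c + n)` to mean reaction
#' times as a function of the number of alternatives.
#'
#' @param n vector of alternative counts (>= 3 distinct values).
#' @param rt_mean mean reaction times, same length.
#' @return A list with `a`, `b`, `c` and the residual sum of squares `rss`.
#' @export
fit_hicks_law <- function(n, rt_mean) {
  if (length(n) < 3L || length(rt_mean) != length(n))
    stop("fit underdetermined: need at least 3 (n, rt) pairs", call. = FALSE)
  dat <- data.frame(n = n, rt_mean = rt_mean)
  fit <- minpack.lm::nlsLM(rt_mean ~ a + b * log(cc + n), data = dat,
                           start = list(a = min(rt_mean),
                                        b = diff(range(rt_mean)) /
                                          max(diff(log(range(n) + 1)), 1e-6),
                                        cc = 1),
                           lower = c(-Inf, -Inf, 1 - min(n) + 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  list(a = unname(co["a"]), b = unname(co["b"]), c = unname(co["cc"]),
       rss = sum(stats::residuals(fit)^2))
}

#' @export
print.hicks_result <- function(x, ...) {
  cat("Hick's-law experiment\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Log-law fit: RT = %.4g + %.4g * ln(%.4g + n), rss = %.4g (linear rss %.4g)\n",
              x$fit$a, x$fit$b, x$fit$c, x$fit$rss, x$fit_linear$rss))
  cat(sprintf("RT variance vs mean: slope %.4g, R^2 = %.3f\n",
              x$var_mean$slope, x$var_mean$r_squared))
  invisible(x)
}

#' @export
plot.hicks_result <- function(x, ...) {
  plot(x$table$n, x$table$rt_mean, xlab = "number of alternatives n",
       ylab = "mean RT (ms)", pch = 19, ...)
  ngrid <- seq(min(x$table$n), max(x$table$n), length.out = 100)
  graphics::lines(ngrid, x$fit$a + x$fit$b * log(x$fit$c + ngrid))
  invisible(x)
}
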