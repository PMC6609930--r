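#' Simulate the linear competition network
#'
#' Euler-Maruyama integration of the n excitatory populations with global
#' inhibitory feedback,
#' `tau * dr_i = (-(1 - s) r_i - c r_I + I_i) dt + xi_i`,
#' `tau_I * dr_I = (-r_I + (g/n) sum_j r_j + I_I) dt + xi_I`.
#' The per-step noise increment on each excitatory rate is
#' `sigma * sqrt(dt) / tau` (the noise enters inside `tau * dr`). Per step the
#' RNG is consumed as: n excitatory draws in population order, then one
#' inhibitory draw.
#'
#' At `s = 1`, the projections of the rates onto the competition vectors are
#' exact drift-diffusion processes, uncoupled from the common and inhibitory
#' modes: feeding the same standard-normal draws to [simulate_ddm_trial()]
#' via `noise` reproduces them step for step.
#'
#' @param params a [network_params()] object (transfer functions are ignored:
#'   the model is linear by construction).
#' @param duration simulated time (ms).
#' @param dt integration step (ms); a warning is issued when `dt > tau_I / 10`.
#' @param seed optional integer seed fixing all noise draws.
#' @param r0,r_I0 initial excitatory rates (scalar or length n) and inhibitory rate.
#' @param noise optional list `list(E = <n x nsteps matrix>, I = <nsteps vector>)`
#'   of pre-drawn standard-normal deviates for shared-noise comparisons.
#' @return An object of class `rate_trajectory`: `times` (ms), `rates`
#'   (matrix, one column per population), `r_inh`, `dt`, `params`.
#' @export
simulate_linear <- function(params, duration, dt = 0.1, seed = NULL,
                            r0 = 0, r_I0 = 0, noise = NULL) {
  stopifnot(inherits(params, "network_params"))
  .check_step(duration, dt, params$tau_I)
  if (!is.null(seed)) set.seed(seed)
  nsteps <- as.integer(round(duration / dt))
  r0 <- rep_len(as.numeric(r0), params$n)
  res <- sim_network_cpp(params$n, params$tau, params$tau_I, params$s,
                         params$c, params$g, params$I, params$I_I,
                         params$sigma, params$sigma_I, 0L, 0L,
                         r0, r_I0, dt, nsteps,
                         if (is.null(noise)) NULL else noise$E,
                         if (is.null(noise)) NULL else noise$I)
  .trajectory(res, nsteps, dt, params)
}

#' Simulate the nonlinear competition network
#'
#' As [simulate_linear()] but with the rates passed through the transfer
#' functions: `tau * dr_i = (-r_i + phi(s r_i - c r_I + I_i)) dt + xi_i` and
#' `tau_I * dr_I = (-r_I + phi_I((g/n) sum_j r_j + I_I)) dt + xi_I`. The noise
#' is additive on the rates (outside the transfer function), modeling
#' fluctuations in population firing rather than in the input; rates are not
#' clipped at zero, so noise can make them transiently negative.
#'
#' Transfer functions shipped with the package run in compiled code; arbitrary
#' user-supplied closures fall back to an R loop.
#'
#' @inheritParams simulate_linear
#' @return A `rate_trajectory`.
#' @export
simulate_nonlinear <- function(params, duration, dt = 0.1, seed = NULL,
                               r0 = 0, r_I0 = 0, noise = NULL) {
  stopifnot(inherits(params, "network_params"))
  .check_step(duration, dt, params$tau_I)
  if (!is.null(seed)) set.seed(seed)
  nsteps <- as.integer(round(duration / dt))
  r0 <- rep_len(as.numeric(r0), params$n)
  code_E <- params$phi$cpp_code
  code_I <- params$phi_I$cpp_code
  if (!is.na(code_E) && !is.na(code_I)) {
    res <- sim_network_cpp(params$n, params$tau, params$tau_I, params$s,
                           params$c, params$g, params$I, params$I_I,
                           params$sigma, params$sigma_I, code_E, code_I,
                           r0, r_I0, dt, nsteps,
                           if (is.null(noise)) NULL else noise$E,
                           if (is.null(noise)) NULL else noise$I)
    return(.trajectory(res, nsteps, dt, params))
  }
  .simulate_nonlinear_r(params, dt, nsteps, r0, r_I0, noise)
}

# R fallback for user-supplied transfer closures
.simulate_nonlinear_r <- function(params, dt, nsteps, r0, r_I0, noise) {
  n <- params$n
  rates <- matrix(NA_real_, nsteps + 1L, n)
  r_inh <- numeric(nsteps + 1L)
  r <- r0; ri <- r_I0
  rates[1L, ] <- r; r_inh[1L] <- ri
  se <- params$sigma * sqrt(dt) / params$tau
  si <- params$sigma_I * sqrt(dt) / params$tau_I
  phi <- params$phi$value; phi_I <- params$phi_I$value
  for (t in seq_len(nsteps)) {
    if (is.null(noise)) {
      eps <- stats::rnorm(n); epsI <- stats::rnorm(1L)
    } else {
      eps <- noise$E[, t]; epsI <- noise$I[t]
    }
    drive_I <- phi_I(params$g / n * sum(r) + params$I_I)
    r_new <- r + dt / params$tau *
      (-r + phi(params$s * r - params$c * ri + params$I)) + se * eps
    ri <- ri + dt / params$tau_I * (-ri + drive_I) + si * epsI
    r <- r_new
    rates[t + 1L, ] <- r; r_inh[t + 1L] <- ri
  }
  .trajectory(list(rates = rates, r_inh = r_inh), nsteps, dt, params)
}

.check_step <- function(duration, dt, tau_I) {
  if (!is.finite(duration) || duration <= 0 || !is.finite(dt) || dt <= 0)
    stop("`duration` and `dt` must be positive", call. = FALSE)
  if (dt > tau_I / 10)
    warning("dt > tau_I / 10; integration may be inaccurate", call. = FALSE)
}

.trajectory <- function(res, nsteps, dt, params) {
  colnames(res$rates) <- paste0("r_", seq_len(params$n))
  structure(list(times = seq(0, by = dt, length.out = nsteps + 1L),
                 rates = res$rates, r_inh = res$r_inh, dt = dt,
                 params = params),
            class = "rate_trajectory")
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat(sprintf("Rate trajectory: %d populations + inhibition, %d steps of %g ms (%g ms)\n",
              ncol(x$rates), length(x$times) - 1L, x$dt, max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.rate_trajectory <- function(x, ...) {
  out <- data.frame(time_ms = x$times)
  out <- cbind(out, as.data.frame(x$rates))
  out$r_I <- x$r_inh
  out
}

#' @export
plot.rate_trajectory <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$rates, x$r_inh), type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "rate", ...)
  graphics::legend("topleft", bty = "n", lty = 1, col = seq_len(ncol(x$rates) + 1L),
                   legend = c(colnames(x$rates), "r_I"))
  invisible(x)
}

#' Steady state of the common and inhibitory modes (linear network, s = 1)
#'
#' Ignoring noise, the common and inhibitory modes of the linear network with
#' `s = 1` settle at `M_C = mean(I) / (c g) - I_I / g` and
#' `M_I = mean(I) / c`. The competition modes have zero drift at `s = 1` and
#' keep their initial value.
#'
#' @param params a [network_params()] (the formula assumes `s = 1`; a warning
#'   is issued otherwise).
#' @return A list of class `mode_steady_state` with elements `M_C` and `M_I`.
#' @export
mode_steady_state <- function(params) {
  stopifnot(inherits(params, "network_params"))
  if (params$c * params$g == 0)
    stop("singular parameters: c * g must be nonzero", call. = FALSE)
  if (params$s != 1)
    warning("steady-state formula is derived at s = 1", call. = FALSE)
  Ibar <- mean(params$I)
  structure(list(M_C = Ibar / (params$c * params$g) - params$I_I / params$g,
                 M_I = Ibar / params$c),
            class = "mode_steady_state")
}

#' Closed-form eigenvalues of the linear network
#'
#' The linearized dynamics about the symmetric state split into the
#' (n-1)-fold degenerate competition eigenvalue `lambda_1 = -(1 - s) / tau`
#' and the pair governing the coupled common/inhibitory subsystem. At `s = 1`
#' the pair reduces to
#' `lambda_{2,3} = -(1 / (2 tau_I)) (1 +/- sqrt(1 - 4 (tau_I / tau) c g))`,
#' whose real parts are always negative; for general `s` the exact 2x2
#' closed form is returned.
#'
#' @param params a [network_params()].
#' @return An object of class `stability_result`: `lambda_competition`,
#'   `competition_multiplicity` (= n-1), `lambda_common` (length 2, complex),
#'   `eigenvalues` (all n+1 values, competition value repeated).
#' @export
linear_mode_eigenvalues <- function(params) {
  stopifnot(inherits(params, "network_params"))
  .mode_eigenvalues(params, dphi = 1, dphi_I = 1)
}

#' Closed-form eigenvalues of the nonlinear network at a fixed point
#'
#' At the symmetric fixed point the competition eigenvalue is
#' `lambda_1 = -(1 - s phi') / tau` with multiplicity n-1, and the
#' common/inhibitory pair is
#' `lambda_{2,3} = -(tau + tau_I (1 - s phi')) / (2 tau tau_I) +/-
#'  sqrt((tau - tau_I (1 - s phi'))^2 - 4 tau tau_I c g phi' phi_I') / (2 tau tau_I)`,
#' with the derivatives evaluated at the fixed-point arguments. The fixed
#' point loses stability along the competition subspace when `s phi' = 1`.
#'
#' @param params a [network_params()].
#' @param fp a [find_fixed_point()] result.
#' @return A `stability_result` (see [linear_mode_eigenvalues()]).
#' @export
nonlinear_eigenvalues <- function(params, fp) {
  stopifnot(inherits(params, "network_params"), inherits(fp, "fixed_point"))
  .mode_eigenvalues(params,
                    dphi = params$phi$d1(fp$arg_E),
                    dphi_I = params$phi_I$d1(fp$arg_I))
}

.mode_eigenvalues <- function(params, dphi, dphi_I) {
  tau <- params$tau; tau_I <- params$tau_I
  leak <- 1 - params$s * dphi
  lambda1 <- -leak / tau
  tr <- -(tau + tau_I * leak) / (tau * tau_I)
  disc <- (tau - tau_I * leak)^2 -
    4 * tau * tau_I * params$c * params$g * dphi * dphi_I
  sq <- sqrt(as.complex(disc)) / (2 * tau * tau_I)
  lambda23 <- tr / 2 + c(sq, -sq)
  if (all(Im(lambda23) == 0)) lambda23 <- Re(lambda23)
  structure(list(lambda_competition = lambda1,
                 competition_multiplicity = params$n - 1L,
                 lambda_common = lambda23,
                 eigenvalues = c(rep(lambda1, params$n - 1L), lambda23)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Competition eigenvalue %.6g (multiplicity %d)\n",
              x$lambda_competition, x$competition_multiplicity))
  cat("Common/inhibitory pair:", format(x$lambda_common, digits = 6), "\n")
  invisible(x)
}

#' Symmetric fixed point of the nonlinear network
#'
#' Solves `R = phi(s R - c R_I + I_0)` with `R_I = phi_I(g R + I_I)` for the
#' state in which all excitatory populations share the rate `R` (requires
#' equal inputs; `I_0` is taken as `I[1]`).
#'
#' @param params a [network_params()] with equal inputs.
#' @param bracket search interval for `R` (default `c(-10, 10)`), widened
#'   automatically if no sign change is found at first.
#' @param tol root tolerance (default 1e-12).
#' @return An object of class `fixed_point`: `R`, `R_I`, `arg_E` (argument of
#'   phi), `arg_I` (argument of phi_I).
#' @export
find_fixed_point <- function(params, bracket = c(-10, 10), tol = 1e-12) {
  stopifnot(inherits(params, "network_params"))
  if (diff(range(params$I)) > 0)
    stop("symmetric fixed point requires equal inputs", call. = FALSE)
  I0 <- params$I[1]
  h <- function(R) {
    R_I <- params$phi_I$value(params$g * R + params$I_I)
    params$phi$value(params$s * R - params$c * R_I + I0) - R
  }
  root <- .find_root(h, bracket, tol,
                     failure = "no symmetric fixed point found in bracket")
  R <- root
  arg_I <- params$g * R + params$I_I
  R_I <- params$phi_I$value(arg_I)
  arg_E <- params$s * R - params$c * R_I + I0
  structure(list(R = R, R_I = R_I, arg_E = arg_E, arg_I = arg_I),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("Symmetric fixed point: R = %.8g, R_I = %.8g\n", x$R, x$R_I))
  invisible(x)
}

#' Critical common input at which the winner-take-all instability appears
#'
#' Follows the symmetric fixed-point branch as the common input `I_0` varies
#' and root-finds `1 - s phi'(arg_E(I_0)) = 0`, the condition at which the
#' (n-1)-fold competition eigenvalue crosses zero.
#'
#' @param params a [network_params()]; its `I` is ignored in favor of the
#'   scanned `I_0`.
#' @param I0_bracket interval of common inputs over which `1 - s phi'` changes
#'   sign.
#' @param tol root tolerance (default 1e-10).
#' @return The critical input `I_0*` (numeric scalar).
#' @export
find_bifurcation <- function(params, I0_bracket, tol = 1e-10) {
  stopifnot(inherits(params, "network_params"))
  crit <- function(I0) {
    p <- params
    p$I <- rep(I0, params$n)
    fp <- find_fixed_point(p)
    1 - params$s * params$phi$d1(fp$arg_E)
  }
  lo <- crit(I0_bracket[1]); hi <- crit(I0_bracket[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    stop("no bifurcation: 1 - s*phi' does not change sign over the bracket",
         call. = FALSE)
  stats::uniroot(crit, I0_bracket, tol = tol)$root
}

.find_root <- function(f, bracket, tol, failure) {
  # scan for a sign change (endpoints alone can miss paired roots), then
  # polish with uniroot on the first bracketing interval
  scan <- function(br, npts) {
    xs <- seq(br[1], br[2], length.out = npts)
    fx <- vapply(xs, f, numeric(1))
    ok <- which(is.finite(fx[-npts]) & is.finite(fx[-1]) &
                  fx[-npts] * fx[-1] <= 0)
    if (length(ok)) c(xs[ok[1]], xs[ok[1] + 1]) else NULL
  }
  hit <- scan(bracket, 201L)
  if (is.null(hit))
    hit <- scan(bracket + c(-1, 1) * 10 * diff(range(bracket)), 801L)
  if (is.null(hit)) stop(failure, call. = FALSE)
  stats::uniroot(f, hit, tol = tol)$root
}

#' Project a rate trajectory onto the competition basis
#'
#' Convenience wrapper returning the decision-variable trajectories
#' `X_k(t)` and the common mode `m_C(t)` of a simulated network.
#'
#' @param traj a `rate_trajectory`.
#' @return A list with `times`, `X` (matrix, one column per decision
#'   variable) and `m_C`.
#' @export
trajectory_modes <- function(traj) {
  stopifnot(inherits(traj, "rate_trajectory"))
  n <- ncol(traj$rates)
  basis <- competition_basis(n)
  X <- traj$rates %*% t(basis$E)
  X <- sweep(X, 2, basis$norms, "/")
  colnames(X) <- paste0("X_", seq_len(n - 1L))
  list(times = traj$times, X = X, m_C = rowMeans(traj$rates))
}
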