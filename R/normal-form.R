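#' Cubic normal-form coefficients for two-alternative competition
#'
#' Near the winner-take-all instability of the two-population network the
#' decision variable obeys the cubic (pitchfork) normal form
#' `tau dX/dT = eta (Ibar_1 - Ibar_2) + mu DeltaI X + gamma X^3 + xi`, with
#' coefficients determined by the transfer-function derivatives at the
#' symmetric fixed point:
#' `eta = phi'/2`, `mu = s^2 phi'' / (c g phi_I')`, and
#' `gamma = s^3 (phi'')^2 (s - c g phi_I') / (2 c g phi' phi_I') + s^3 phi'''/6`.
#' The reflection symmetry of the two-way competition forbids quadratic
#' terms, which is why the n = 2 reduction differs qualitatively from the
#' quadratic normal forms at n >= 3. The bifurcation is supercritical for
#' `gamma < 0` (X saturates) and subcritical for `gamma > 0` (X escapes,
#' the network is multi-stable).
#'
#' @param params a [network_params()] with n = 2.
#' @param fp the [find_fixed_point()] at which to evaluate the derivatives.
#' @return An object of class `nf_coefficients2`: `eta`, `mu`, `gamma`,
#'   `criticality` (`"supercritical"`, `"subcritical"` or `"degenerate"`).
#' @export
nf_coefficients_2afc <- function(params, fp) {
  stopifnot(inherits(params, "network_params"), inherits(fp, "fixed_point"))
  d1 <- params$phi$d1(fp$arg_E)
  d2 <- params$phi$d2(fp$arg_E)
  d3 <- params$phi$d3(fp$arg_E)
  dI1 <- params$phi_I$d1(fp$arg_I)
  s <- params$s; cg <- params$c * params$g
  if (cg * d1 * dI1 == 0)
    stop("singular coefficient: c * g * phi' * phi_I' vanishes at the fixed point",
         call. = FALSE)
  gamma <- s^3 * d2^2 * (s - cg * dI1) / (2 * cg * d1 * dI1) + s^3 * d3 / 6
  structure(list(
    eta = d1 / 2,
    mu = s^2 * d2 / (cg * dI1),
    gamma = gamma,
    criticality = if (gamma < 0) "supercritical"
                  else if (gamma > 0) "subcritical" else "degenerate"),
    class = "nf_coefficients2")
}

#' @export
print.nf_coefficients2 <- function(x, ...) {
  cat(sprintf("2AFC cubic normal form: eta = %.6g, mu = %.6g, gamma = %.6g (%s)\n",
              x$eta, x$mu, x$gamma, x$criticality))
  invisible(x)
}

#' Quadratic normal-form model for n >= 3 alternatives
#'
#' Container for the reduced winner-take-all dynamics near the instability:
#' the k-th decision variable obeys
#' `tau dX_k = a (e_k . Ibar)/(k + k^2)
#'   + b/(2(k + k^2)) ( sum_{j<k}(j + j^2) X_j^2 - k(k^2 - 1) X_k^2
#'                      + 2(k + k^2) X_k sum_{j>k} X_j )
#'   + (e_k . xi)/(k + k^2)`,
#' with `a = phi'` and `b = s^2 phi''` for the rate network studied here.
#' The whole drift field is the (scaled) negative gradient of the potential
#' returned by [nf_potential()].
#'
#' @param n number of alternatives (>= 2; at n = 2 the quadratic terms vanish
#'   identically and the cubic form [nf_coefficients_2afc()] is the relevant
#'   reduction).
#' @param a input coefficient (phi' for the derived network).
#' @param b quadratic coefficient (s^2 phi'').
#' @param I_bar length-n input-perturbation vector (deviations from the
#'   common input at the bifurcation).
#' @return An object of class `potential_model`, with `projected_inputs`
#'   holding the raw dot products `e_j . I_bar`.
#' @export
potential_model <- function(n, a, b, I_bar = 0) {
  if (length(n) != 1L || n != round(n) || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  n <- as.integer(n)
  I_bar <- rep_len(as.numeric(I_bar), n)
  basis <- competition_basis(n)
  structure(list(n = n, a = a, b = b, I_bar = I_bar,
                 projected_inputs = as.numeric(basis$E %*% I_bar),
                 norms = basis$norms),
            class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("Quadratic normal form: n = %d, a = %.6g, b = %.6g\n  I_bar = (%s)\n",
              x$n, x$a, x$b, paste(signif(x$I_bar, 4), collapse = ", ")))
  invisible(x)
}

#' Deterministic drift field of the quadratic normal form
#'
#' Evaluates `tau * dX_k/dt` (without noise) for the model of
#' [potential_model()]. At n = 3 this reduces exactly to
#' `tau dX_1 = (a/2)(Ibar_1 - Ibar_2) + b X_1 X_2` and
#' `tau dX_2 = (a/6)(Ibar_1 + Ibar_2 - 2 Ibar_3) + (b/6)(X_1^2 - 3 X_2^2)`.
#'
#' @param X numeric vector of length n-1.
#' @param model a [potential_model()].
#' @return numeric vector of length n-1.
#' @export
nf_drift <- function(X, model) {
  stopifnot(inherits(model, "potential_model"))
  n <- model$n
  if (length(X) != n - 1L)
    stop("`X` must have length ", n - 1L, call. = FALSE)
  k <- seq_len(n - 1L)
  kk <- model$norms                          # k + k^2
  w <- kk * X^2
  prefix <- c(0, cumsum(w))[k]               # sum_{j<k} (j+j^2) X_j^2
  suffix <- rev(c(0, cumsum(rev(X))))[-1]    # sum_{j>k} X_j
  quad <- prefix - k * (k^2 - 1) * X^2 + 2 * kk * X * suffix
  model$a * model$projected_inputs / kk + model$b / (2 * kk) * quad
}

#' Potential landscape of the quadratic normal form
#'
#' The multivariate function
#' `f(X) = -a sum_j (e_j . Ibar) X_j
#'        - (b/2) ( sum_{j=1}^{n-2} (j + j^2) X_j^2 sum_{i>j} X_i
#'                  - sum_{j=1}^{n-1} j(j^2 - 1)/3 X_j^3 )`
#' whose scaled negative gradient reproduces [nf_drift()] exactly:
#' `tau dX_k/dt = -(1/(k + k^2)) df/dX_k`. Along noise-free trajectories
#' `df/dt = -sum_k (df/dX_k)^2 / (k + k^2) <= 0`, so the decision dynamics is
#' the motion of a particle descending this landscape, with noise diffusing
#' it; the quadratic landscape is globally unstable, which is what drives the
#' decision variables to the boundary.
#'
#' @param X numeric vector of length n-1.
#' @param model a [potential_model()].
#' @return scalar value of the potential.
#' @export
nf_potential <- function(X, model) {
  stopifnot(inherits(model, "potential_model"))
  n <- model$n
  if (length(X) != n - 1L)
    stop("`X` must have length ", n - 1L, call. = FALSE)
  k <- seq_len(n - 1L)
  kk <- model$norms
  suffix <- rev(c(0, cumsum(rev(X))))[-1]
  cross <- if (n > 2L) sum(kk[1:(n - 2L)] * X[1:(n - 2L)]^2 * suffix[1:(n - 2L)]) else 0
  cubic <- sum(k * (k^2 - 1) / 3 * X^3)
  -model$a * sum(model$projected_inputs * X) - model$b / 2 * (cross - cubic)
}

#' Simulate the nonlinear (normal-form) DDM
#'
#' Euler-Maruyama simulation in original time of the reduced winner-take-all
#' dynamics, with population-space noise projected onto the competition basis
#' (noise scale in X-space is `sigma / epsilon`, matching the amplitude
#' scaling of the reconstruction `r = R0 + epsilon * sum_k e_k X_k`). For a
#' [potential_model()] (n >= 3) the quadratic drift field [nf_drift()] is
#' used; for an [nf_coefficients_2afc()] object the cubic form is used and
#' the extra arguments `DeltaI` (common input offset) and `I_bar` (length-2)
#' apply.
#'
#' The decision rule mirrors the linear DDM: population i wins at the first
#' step where its reconstructed coordinate crosses the threshold. With
#' `threshold = "rate"` the comparison is `R0 + epsilon * recon_i >= theta`
#' (theta on the firing-rate scale); with `threshold = "X"` it is
#' `recon_i >= theta` directly in decision-variable space.
#'
#' Because the quadratic flow is globally unstable, trajectories that exceed
#' `cap` in any `|X_k|` without having crossed a boundary are stopped and
#' flagged `capped` rather than treated as errors.
#'
#' @param model a [potential_model()] or [nf_coefficients_2afc()].
#' @param theta decision threshold.
#' @param tau time constant (ms).
#' @param sigma population-noise scale.
#' @param dt step (ms); `t_max` trial cutoff (ms).
#' @param seed optional integer seed.
#' @param epsilon amplitude of the reconstruction scaling (default 1:
#'   simulate in unscaled variables).
#' @param R0 fixed-point rate added in the rate-space reconstruction.
#' @param threshold `"rate"` or `"X"` (see above).
#' @param x0 initial decision variables.
#' @param cap divergence guard on `|X_k|` (default `10 * theta / epsilon`).
#' @param return_path if `TRUE`, include the X trajectory.
#' @param noise optional n x nsteps standard-normal matrix (single trial).
#' @param DeltaI,I_bar n = 2 cubic-form inputs (ignored for
#'   `potential_model`, which carries its own `I_bar`).
#' @return A list of class `nf_trial`: `choice`, `rt`, `decided`, `capped`,
#'   and optionally `path`.
#' @export
simulate_normal_form <- function(model, theta, tau = 20, sigma = 0, dt = 0.1,
                                 t_max = 2000, seed = NULL, epsilon = 1,
                                 R0 = 0, threshold = c("rate", "X"), x0 = 0,
                                 cap = NULL, return_path = FALSE, noise = NULL,
                                 DeltaI = 0, I_bar = c(0, 0)) {
  threshold <- match.arg(threshold)
  if (is.null(cap)) cap <- 10 * theta / epsilon
  if (!is.null(seed)) set.seed(seed)
  nsteps <- as.integer(round(t_max / dt))
  if (inherits(model, "potential_model")) {
    x0 <- rep_len(as.numeric(x0), model$n - 1L)
    res <- nf_trials_cpp(model$n, tau, model$a, model$b, model$I_bar,
                         sigma / epsilon, epsilon, R0, theta,
                         threshold == "rate", dt, nsteps, cap, x0, 1L,
                         return_path, noise)
    row <- res$trials[1, ]
    out <- list(choice = if (row[3] == 1) as.integer(row[1]) else NA_integer_,
                rt = row[2], decided = row[3] == 1, capped = row[3] == -1)
    if (return_path) out$path <- res$path
    return(structure(out, class = "nf_trial"))
  }
  if (!inherits(model, "nf_coefficients2"))
    stop("`model` must be a potential_model or nf_coefficients2 object",
         call. = FALSE)
  .simulate_nf2(model, theta, tau, sigma, dt, nsteps, epsilon, R0, threshold,
                x0[1], cap, return_path, noise, DeltaI, I_bar)
}

# cubic n = 2 normal form, scalar R loop
.simulate_nf2 <- function(cf, theta, tau, sigma, dt, nsteps, epsilon, R0,
                          threshold, x0, cap, return_path, noise, DeltaI, I_bar) {
  drive <- cf$eta * (I_bar[1] - I_bar[2])
  sfac <- (sigma / epsilon) * sqrt(dt) / (2 * tau)   # (xi_1 - xi_2)/2 projection
  X <- x0
  path <- if (return_path) numeric(nsteps + 1L) else NULL
  if (return_path) path[1L] <- X
  choice <- NA_integer_; rt <- nsteps * dt; decided <- FALSE; capped <- FALSE
  for (t in seq_len(nsteps)) {
    eps <- if (is.null(noise)) stats::rnorm(2L) else noise[, t]
    X <- X + dt / tau * (drive + cf$mu * DeltaI * X + cf$gamma * X^3) +
      sfac * (eps[1] - eps[2])
    if (return_path) path[t + 1L] <- X
    recon <- c(X, -X)
    val <- if (threshold == "rate") R0 + epsilon * recon else recon
    hits <- which(val >= theta)
    if (length(hits)) {
      over <- val[hits] - theta
      choice <- hits[which.max(over)]
      rt <- t * dt; decided <- TRUE
      if (return_path) path <- path[seq_len(t + 1L)]
      break
    }
    if (abs(X) > cap) {
      capped <- TRUE; rt <- t * dt
      if (return_path) path <- path[seq_len(t + 1L)]
      break
    }
  }
  structure(list(choice = choice, rt = rt, decided = decided, capped = capped,
                 path = path),
            class = "nf_trial")
}

#' @export
print.nf_trial <- function(x, ...) {
  if (x$decided)
    cat(sprintf("Choice %d at rt = %g ms\n", x$choice, x$rt))
  else if (x$capped)
    cat(sprintf("Capped (divergence guard) at t = %g ms without decision\n", x$rt))
  else cat(sprintf("Undecided at t_max = %g ms\n", x$rt))
  invisible(x)
}

#' Run a block of quadratic normal-form trials
#'
#' @param model a [potential_model()].
#' @param n_trials number of trials.
#' @inheritParams simulate_normal_form
#' @return A `trial_block` plus a `n_capped` count; correctness is scored
#'   against the argmax of `I_bar` (NA on ties).
#' @export
run_nf_block <- function(model, n_trials, theta, tau = 20, sigma = 0.01,
                         dt = 0.1, t_max = 2000, seed = NULL, epsilon = 1,
                         R0 = 0, threshold = c("rate", "X"), x0 = 0,
                         cap = NULL) {
  stopifnot(inherits(model, "potential_model"), n_trials >= 1)
  threshold <- match.arg(threshold)
  if (is.null(cap)) cap <- 10 * theta / epsilon
  if (!is.null(seed)) set.seed(seed)
  nsteps <- as.integer(round(t_max / dt))
  x0 <- rep_len(as.numeric(x0), model$n - 1L)
  res <- nf_trials_cpp(model$n, tau, model$a, model$b, model$I_bar,
                       sigma / epsilon, epsilon, R0, theta,
                       threshold == "rate", dt, nsteps, cap, x0,
                       as.integer(n_trials), FALSE, NULL)
  m <- res$trials
  target <- .correct_target(model$I_bar)
  df <- data.frame(trial = seq_len(nrow(m)),
                   choice = ifelse(m[, 3] == 1, m[, 1], NA_integer_),
                   rt = m[, 2],
                   correct = if (is.na(target)) NA else
                     ifelse(m[, 3] == 1, m[, 1] == target, NA))
  blk <- summarize_trials(df)
  blk$n_capped <- sum(m[, 3] == -1)
  blk
}

#' Compare the full nonlinear network with its normal-form reduction
#'
#' Simulates the rate network at its winner-take-all bifurcation and the
#' quadratic normal form from matched initial conditions and shared
#' population-noise streams (the normal form's noise is the projection of the
#' same excitatory draws the network uses). Reports, per trial, the winners
#' and reaction times of both systems (first coordinate to reach `theta`:
#' network rates vs reconstruction `R + epsilon * recon(X)`), and the
#' sup-norm deviation between the network rates and the reconstruction over
#' the pre-decision interval.
#'
#' @param params a [network_params()] whose common input puts it at the
#'   bifurcation (`|lambda_1|` must be below `lambda_tol`); `params$I` may
#'   additionally carry a small per-population perturbation `I_bar` around
#'   that common value.
#' @param epsilon reconstruction amplitude (Fig.-3-style tracking uses 1).
#' @param theta decision threshold on the rates.
#' @param duration,dt simulation window (ms).
#' @param n_trials number of shared-noise trials.
#' @param seed integer seed.
#' @param lambda_tol tolerance on the competition eigenvalue at the fixed
#'   point (refuses with a diagnostic if exceeded).
#' @return A list of class `tracking_report`: `trials` (data frame with
#'   winner_network, winner_nf, rt_network, rt_nf, deviation), `agreement`
#'   (fraction of trials, among those where both decided, with the same
#'   winner), `mean_rt_diff`, `max_deviation`, `fixed_point`, `model`.
#' @export
track_network <- function(params, epsilon = 1, theta = 0.5, duration = 2000,
                          dt = 0.1, n_trials = 100, seed = 1L,
                          lambda_tol = 1e-6) {
  stopifnot(inherits(params, "network_params"))
  I0 <- mean(params$I)
  I_bar <- params$I - I0
  p0 <- params; p0$I <- rep(I0, params$n)
  fp <- find_fixed_point(p0)
  stab <- nonlinear_eigenvalues(p0, fp)
  if (abs(stab$lambda_competition) > lambda_tol)
    stop(sprintf("network is not at its bifurcation: |lambda_1| = %.3g > %.3g",
                 abs(stab$lambda_competition), lambda_tol), call. = FALSE)
  a <- p0$phi$d1(fp$arg_E)
  b <- params$s^2 * p0$phi$d2(fp$arg_E)
  model <- potential_model(params$n, a, b, I_bar / epsilon^2)
  basis <- competition_basis(params$n)
  nsteps <- as.integer(round(duration / dt))
  set.seed(seed)
  rows <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    NE <- matrix(stats::rnorm(params$n * nsteps), params$n, nsteps)
    NI <- stats::rnorm(nsteps)
    net <- simulate_nonlinear(params, duration, dt, r0 = fp$R, r_I0 = fp$R_I,
                              noise = list(E = NE, I = NI))
    nf <- simulate_normal_form(model, theta = theta, tau = params$tau,
                               sigma = params$sigma, dt = dt, t_max = duration,
                               epsilon = epsilon, R0 = fp$R,
                               threshold = "rate", return_path = TRUE,
                               noise = NE)
    # network winner: first rate to reach theta
    cross <- which(net$rates >= theta, arr.ind = TRUE)
    if (nrow(cross)) {
      tfirst <- min(cross[, 1])
      cand <- cross[cross[, 1] == tfirst, , drop = FALSE]
      ov <- net$rates[tfirst, cand[, 2]] - theta
      winner_net <- cand[which.max(ov), 2]
      rt_net <- net$times[tfirst]
    } else {
      winner_net <- NA_integer_; rt_net <- NA_real_
    }
    winner_nf <- nf$choice
    rt_nf <- if (nf$decided) nf$rt else NA_real_
    # deviation up to the earlier decision
    tstop <- min(nrow(nf$path), nrow(net$rates))
    recon <- fp$R + epsilon * (nf$path[seq_len(tstop), , drop = FALSE] %*% basis$E)
    dev <- max(abs(net$rates[seq_len(tstop), , drop = FALSE] - recon))
    rows[[tr]] <- data.frame(winner_network = winner_net, winner_nf = winner_nf,
                             rt_network = rt_net, rt_nf = rt_nf,
                             deviation = dev)
  }
  tab <- do.call(rbind, rows)
  both <- !is.na(tab$winner_network) & !is.na(tab$winner_nf)
  structure(list(
    trials = tab,
    agreement = if (any(both)) mean(tab$winner_network[both] == tab$winner_nf[both])
                else NA_real_,
    n_both_decided = sum(both),
    mean_rt_diff = mean(tab$rt_nf[both] - tab$rt_network[both]),
    max_deviation = max(tab$deviation),
    fixed_point = fp, model = model),
    class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat(sprintf(
    "Network vs normal form over %d trials: winner agreement %.1f%% (%d trials decided in both)\n",
    nrow(x$trials), 100 * x$agreement, x$n_both_decided))
  cat(sprintf("  mean RT difference %.3g ms, max rate deviation %.4g\n",
              x$mean_rt_diff, x$max_deviation))
  invisible(x)
}
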