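# Shared fixtures: parameter sets and small numeric utilities used across tests.

# Network with the expansive-saturating transfer function at its
# winner-take-all bifurcation (common input 1/2, symmetric rate 1/4).
wta_network <- function(n = 3, sigma = 0, I = 0.5) {
  network_params(n = n, tau = 20, tau_I = 10, s = 1, c = 1, g = 1,
                 I = I, I_I = 0, sigma = sigma,
                 phi = transfer_piecewise_sqrt(), phi_I = transfer_identity())
}

# smooth strictly monotone transfer function with analytic derivatives,
# used where tests need a generic nonlinearity
tf_softplus <- function(gain = 1) {
  transfer_fn(
    value = function(x) log1p(exp(gain * x)),
    d1 = function(x) gain * stats::plogis(gain * x),
    d2 = function(x) gain^2 * stats::plogis(gain * x) * (1 - stats::plogis(gain * x)),
    d3 = function(x) {
      s <- stats::plogis(gain * x)
      gain^3 * s * (1 - s) * (1 - 2 * s)
    })
}

# random smooth nonlinear network with a guaranteed symmetric fixed point:
# the excitatory loop gain s * phi' stays below 1 at every drive, so the
# self-consistency map is eventually contracting and a root exists
rand_network <- function() {
  s <- stats::runif(1, 0.2, 1.4)
  network_params(n = sample(2:6, 1), tau = stats::runif(1, 5, 40),
                 tau_I = stats::runif(1, 2, 20), s = s,
                 c = stats::runif(1, 0.2, 2), g = stats::runif(1, 0.2, 2),
                 I = stats::runif(1, -0.5, 1), I_I = stats::runif(1, -0.3, 0.3),
                 phi = tf_softplus(stats::runif(1, 0.5, 0.95) / s),
                 phi_I = tf_softplus(stats::runif(1, 0.5, 2)))
}

# dense Jacobian of the (n+1)-dimensional rate system at a symmetric state,
# built independently of the closed forms under test
network_jacobian <- function(params, dphi = 1, dphi_I = 1) {
  n <- params$n
  J <- matrix(0, n + 1L, n + 1L)
  for (i in seq_len(n)) {
    J[i, i] <- (params$s * dphi - 1) / params$tau
    J[i, n + 1L] <- -params$c * dphi / params$tau
  }
  J[n + 1L, seq_len(n)] <- params$g / n * dphi_I / params$tau_I
  J[n + 1L, n + 1L] <- -1 / params$tau_I
  J
}

# closed-form first-passage results for the 1-D projected two-alternative
# process: drift m = mu/tau, variance rate v = sigma^2/(2 tau^2), symmetric
# bounds +/- theta, start at 0 (standard Wald formulas; validated against a
# fine-dt simulation during development)
wald_accuracy <- function(mu, sigma, tau, theta) {
  1 / (1 + exp(-4 * mu * theta * tau / sigma^2))
}
wald_mean_dt <- function(mu, sigma, tau, theta) {
  m <- mu / tau
  v <- sigma^2 / (2 * tau^2)
  (theta / m) * tanh(m * theta / v)
}

# central-difference gradient
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
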