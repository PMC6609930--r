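#' Transfer functions for firing-rate networks
#'
#' A transfer function bundles the input-output nonlinearity `phi` with its
#' first three derivatives, which the stability analysis and normal-form
#' coefficient formulas need at the network's symmetric fixed point.
#'
#' `transfer_fn()` builds one from user-supplied closures. `transfer_identity()`
#' is `phi(x) = x` (used for the linear network and as the default inhibitory
#' nonlinearity). `transfer_piecewise_sqrt()` is the expansive-then-saturating
#' piecewise function `phi(x) = 0` for `x < 0`, `x^2` for `0 <= x <= 1`, and
#' `2*sqrt(x - 3/4)` for `x > 1`; it is continuously differentiable at the
#' knots but its second and third derivatives are one-sided there (taken from
#' the active piece, with the quadratic piece owning both knots).
#'
#' @param value,d1,d2,d3 vectorized functions of one numeric argument:
#'   `phi` and its first, second and third derivatives.
#' @param cpp_code internal integer tag selecting a compiled implementation of
#'   the same function for the simulation inner loops (`NA` = evaluate the R
#'   closures; only functions shipped with the package have compiled forms).
#' @return An object of class `transfer_fn`.
#' @export
transfer_fn <- function(value, d1, d2, d3, cpp_code = NA_integer_) {
  stopifnot(is.function(value), is.function(d1), is.function(d2),
            is.function(d3))
  structure(list(value = value, d1 = d1, d2 = d2, d3 = d3,
                 cpp_code = as.integer(cpp_code)),
            class = "transfer_fn")
}

#' @rdname transfer_fn
#' @export
transfer_identity <- function() {
  transfer_fn(value = function(x) x,
              d1 = function(x) rep(1, length(x)),
              d2 = function(x) rep(0, length(x)),
              d3 = function(x) rep(0, length(x)),
              cpp_code = 0L)
}

#' @rdname transfer_fn
#' @export
transfer_piecewise_sqrt <- function() {
  piecewise <- function(mid, upper) {
    force(mid); force(upper)
    function(x) {
      out <- numeric(length(x))
      q <- x >= 0 & x <= 1
      s <- x > 1
      out[q] <- mid(x[q])
      out[s] <- upper(x[s])
      out
    }
  }
  transfer_fn(
    value = piecewise(function(x) x^2, function(x) 2 * sqrt(x - 0.75)),
    d1 = piecewise(function(x) 2 * x, function(x) 1 / sqrt(x - 0.75)),
    d2 = piecewise(function(x) rep(2, length(x)),
                   function(x) -0.5 * (x - 0.75)^(-1.5)),
    d3 = piecewise(function(x) rep(0, length(x)),
                   function(x) 0.75 * (x - 0.75)^(-2.5)),
    cpp_code = 1L)
}

#' @export
print.transfer_fn <- function(x, ...) {
  cat("Transfer function (phi with derivatives phi', phi'', phi''')\n")
  invisible(x)
}

#' Network parameters for the winner-take-all rate models
#'
#' Parameter container for the n excitatory populations plus one global
#' inhibitory population. The excitatory populations obey
#' `tau * dr_i = (-r_i + phi(s*r_i - c*r_I + I_i)) dt + xi_i` and the
#' inhibitory population `tau_I * dr_I = (-r_I + phi_I(g/n * sum(r) + I_I)) dt
#' + xi_I`, with delta-correlated Gaussian noise of intensity `sigma^2`
#' (`sigma_I^2`). With identity transfer functions this is the linear model.
#'
#' The noise enters the written equations inside `tau * dr`, so an
#' Euler-Maruyama step perturbs each rate by `sigma * sqrt(dt) / tau`
#' (and `sigma_I * sqrt(dt) / tau_I` for inhibition); reaction-time scales
#' depend on this convention.
#'
#' @param n number of excitatory populations (alternatives), >= 2.
#' @param tau,tau_I excitatory / inhibitory time constants (ms), > 0.
#' @param s excitatory self-coupling strength (s = 1 is the balanced point at
#'   which the linear competition modes are pure drift-diffusion processes).
#' @param c inhibition strength.
#' @param g excitatory-to-inhibitory gain (each population drives inhibition
#'   with weight g/n).
#' @param I external input, scalar (recycled) or length-n vector.
#' @param I_I external input to the inhibitory population.
#' @param sigma,sigma_I rate-noise intensity scales (sigma_I defaults to sigma).
#' @param phi,phi_I [transfer_fn()] objects; identity by default.
#' @return An object of class `network_params`.
#' @export
network_params <- function(n, tau = 20, tau_I = 10, s = 1, c = 1, g = 1,
                           I = 0, I_I = 0, sigma = 0, sigma_I = sigma,
                           phi = transfer_identity(),
                           phi_I = transfer_identity()) {
  if (length(n) != 1L || n != round(n) || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (tau <= 0 || tau_I <= 0) stop("time constants must be positive", call. = FALSE)
  if (sigma < 0 || sigma_I < 0) stop("noise scales must be non-negative", call. = FALSE)
  n <- as.integer(n)
  I <- rep_len(as.numeric(I), n)
  stopifnot(inherits(phi, "transfer_fn"), inherits(phi_I, "transfer_fn"))
  structure(list(n = n, tau = tau, tau_I = tau_I, s = s, c = c, g = g,
                 I = I, I_I = I_I, sigma = sigma, sigma_I = sigma_I,
                 phi = phi, phi_I = phi_I),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "Rate-network parameters: n = %d, tau = %g ms, tau_I = %g ms\n  s = %g, c = %g, g = %g, I_I = %g, sigma = %g, sigma_I = %g\n  I = (%s)\n",
    x$n, x$tau, x$tau_I, x$s, x$c, x$g, x$I_I, x$sigma, x$sigma_I,
    paste(signif(x$I, 4), collapse = ", ")))
  invisible(x)
}
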