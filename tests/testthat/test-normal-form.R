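# transfer function with prescribed derivatives at x = 0 for coefficient checks
tf_poly <- function(c1, c2, c3) {
  transfer_fn(value = function(x) c1 * x + c2 * x^2 / 2 + c3 * x^3 / 6,
              d1 = function(x) c1 + c2 * x + c3 * x^2 / 2,
              d2 = function(x) c2 + c3 * x,
              d3 = function(x) rep(c3, length(x)))
}
fp_at <- function(R, arg_E, R_I = R, arg_I = arg_E) {
  structure(list(R = R, R_I = R_I, arg_E = arg_E, arg_I = arg_I),
            class = "fixed_point")
}

test_that("two-alternative cubic coefficients follow the closed forms", {
  # phi'' = 0 at the fixed point: mu vanishes, gamma = s^3 phi''' / 6
  p1 <- network_params(n = 2, s = 2, c = 1, g = 1, I = 0, phi = tf_poly(1, 0, 1))
  cf1 <- nf_coefficients_2afc(p1, fp_at(0, 0))
  expect_equal(cf1$mu, 0)
  expect_equal(cf1$gamma, 2^3 / 6)
  expect_equal(cf1$criticality, "subcritical")
  # expansive branch at the published operating point (phi' = 1, phi'' = 2,
  # phi''' = 0, s = c = g = 1, identity inhibition): mu = 2, gamma degenerate
  p2 <- network_params(n = 2, s = 1, c = 1, g = 1, I = 0.5,
                       phi = transfer_piecewise_sqrt())
  cf2 <- nf_coefficients_2afc(p2, fp_at(0.25, 0.5, 0.25, 0.25))
  expect_equal(cf2$eta, 0.5)
  expect_equal(cf2$mu, 2)
  expect_equal(cf2$gamma, 0)
  expect_equal(cf2$criticality, "degenerate")
  # negative phi''' with phi'' = 0 gives a supercritical bifurcation
  cf3 <- nf_coefficients_2afc(
    network_params(n = 2, s = 1, I = 0, phi = tf_poly(1, 0, -2)), fp_at(0, 0))
  expect_lt(cf3$gamma, 0)
  expect_equal(cf3$criticality, "supercritical")
  expect_error(nf_coefficients_2afc(
    network_params(n = 2, s = 1, c = 0, I = 0), fp_at(0, 0)), "singular")
})

test_that("the quadratic drift reduces to the printed three-alternative form", {
  set.seed(61)
  a <- 0.8; b <- 1.7
  Ibar <- c(0.2, -0.1, -0.1)
  m <- potential_model(3, a, b, Ibar)
  for (i in 1:20) {
    X <- stats::rnorm(2)
    d <- nf_drift(X, m)
    expect_equal(d[1], a / 2 * (Ibar[1] - Ibar[2]) + b * X[1] * X[2],
                 tolerance = 1e-12)
    expect_equal(d[2], a / 6 * (Ibar[1] + Ibar[2] - 2 * Ibar[3]) +
                   b / 6 * (X[1]^2 - 3 * X[2]^2), tolerance = 1e-12)
  }
  # n = 2: the quadratic part vanishes identically
  m2 <- potential_model(2, a, b, c(0.3, -0.3))
  for (x in c(-2, -0.5, 0.7, 3))
    expect_equal(nf_drift(x, m2), a * 0.6 / 2, tolerance = 1e-12)
  # third decision variable for larger n matches the printed coefficient row
  m6 <- potential_model(6, a, b, rep(0, 6))
  for (i in 1:20) {
    X <- stats::rnorm(5)
    d <- nf_drift(X, m6)
    expect_equal(d[3],
                 b / 12 * (X[1]^2 + 3 * X[2]^2 - 12 * X[3]^2 +
                             12 * X[3] * (X[4] + X[5])), tolerance = 1e-12)
  }
})

test_that("the drift field is the scaled negative gradient of the potential", {
  set.seed(71)
  draws <- 0
  for (n in 2:7) {
    for (rep in 1:34) {
      m <- potential_model(n, a = stats::runif(1, 0.2, 2),
                           b = stats::runif(1, -2, 2),
                           I_bar = stats::rnorm(n, sd = 0.3))
      X <- stats::rnorm(n - 1)
      grad <- num_grad(function(x) nf_potential(x, m), X)
      k <- seq_len(n - 1)
      expect_equal(nf_drift(X, m), -grad / (k + k^2),
                   tolerance = 1e-5)
      draws <- draws + 1
    }
  }
  expect_gte(draws, 200)
})

test_that("noise-free trajectories descend the potential", {
  set.seed(81)
  for (n in 2:6) {
    m <- potential_model(n, a = 1, b = 1.5, I_bar = stats::rnorm(n, sd = 0.05))
    tr <- simulate_normal_form(m, theta = 5, tau = 20, sigma = 0, dt = 0.02,
                               t_max = 400, threshold = "X",
                               x0 = stats::rnorm(n - 1, sd = 0.05),
                               cap = 50, return_path = TRUE)
    f <- apply(tr$path, 1, nf_potential, model = m)
    expect_true(all(diff(f) <= 1e-10))
    # strictly decreasing away from critical points
    moving <- vapply(seq_len(nrow(tr$path)),
                     function(i) sum(abs(nf_drift(tr$path[i, ], m))) > 1e-6,
                     logical(1))
    expect_true(all(diff(f)[moving[-length(moving)]] < 0))
  }
})

test_that("the origin is a fixed point of the unforced normal form", {
  m <- potential_model(4, a = 1, b = 2, I_bar = 0)
  tr <- simulate_normal_form(m, theta = 1, tau = 20, sigma = 0, dt = 0.1,
                             t_max = 200, threshold = "X", x0 = 0,
                             return_path = TRUE)
  expect_false(tr$decided)
  expect_true(all(tr$path == 0))
})

test_that("zero-coherence winner statistics respect the permutation symmetry", {
  m <- potential_model(3, a = 1, b = 2, I_bar = 0)
  set.seed(91)
  blk <- run_nf_block(m, 3000, theta = 0.5, tau = 20, sigma = 0.01, dt = 0.1,
                      t_max = 16000, threshold = "rate", R0 = 0.25)
  expect_gte(blk$n_decided, 2900)
  tab <- tabulate(blk$trials$choice, nbins = 3)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("trajectories stay in the triangular decision region until crossing", {
  m <- potential_model(3, a = 1, b = 2, I_bar = 0)
  basis <- competition_basis(3)
  for (seed in 1:10) {
    tr <- simulate_normal_form(m, theta = 0.5, tau = 20, sigma = 0.01,
                               dt = 0.1, t_max = 20000, threshold = "rate",
                               R0 = 0.25, seed = 400 + seed,
                               return_path = TRUE)
    expect_true(tr$decided)
    pre <- tr$path[seq_len(nrow(tr$path) - 1L), , drop = FALSE]
    recon <- 0.25 + pre %*% basis$E
    expect_true(all(recon < 0.5))
  }
})

test_that("the cubic form saturates when supercritical and escapes when subcritical", {
  sup <- structure(list(eta = 0.5, mu = 1, gamma = -1,
                        criticality = "supercritical"),
                   class = "nf_coefficients2")
  tr <- simulate_normal_form(sup, theta = 100, tau = 20, sigma = 0.05,
                             dt = 0.1, t_max = 4000, threshold = "X",
                             x0 = 0.2, cap = 5, seed = 3, return_path = TRUE)
  expect_false(tr$capped)
  expect_lt(max(abs(tr$path)), 2.5)
  sub <- structure(list(eta = 0.5, mu = 1, gamma = 1,
                        criticality = "subcritical"),
                   class = "nf_coefficients2")
  tr2 <- simulate_normal_form(sub, theta = 100, tau = 20, sigma = 0,
                              dt = 0.1, t_max = 1e4, threshold = "X",
                              x0 = 0.2, cap = 5)
  expect_true(tr2$capped)
  expect_lt(tr2$rt, 1e4)
})

test_that("network tracking: deterministic winners agree and deviation scales with input", {
  run_det <- function(delta, duration) {
    p <- wta_network(sigma = 0)
    p$I <- 0.5 + c(delta, 0, 0)
    track_network(p, epsilon = 1, theta = 0.5, duration = duration, dt = 0.1,
                  n_trials = 1, seed = 1, lambda_tol = 1e-3)
  }
  small <- run_det(5e-4, 8000)
  large <- run_det(2e-3, 8000)
  expect_equal(small$trials$winner_network, 1L)
  expect_equal(small$trials$winner_nf, 1L)
  expect_equal(large$trials$winner_network, 1L)
  expect_equal(large$trials$winner_nf, 1L)
  # reduction error grows with the perturbation amplitude; compare over a
  # fixed pre-decision window so the saturated near-threshold regime (where
  # the asymptotics no longer apply) does not dominate the sup norm
  dev_small <- run_det(5e-4, 1200)$trials$deviation
  dev_large <- run_det(2e-3, 1200)$trials$deviation
  expect_gt(dev_large / dev_small, 2)
  # permutation equivariance: moving the input advantage relabels the winner
  p <- wta_network(sigma = 0)
  p$I <- 0.5 + c(0, 2e-3, 0)
  perm <- track_network(p, epsilon = 1, theta = 0.5, duration = 8000, dt = 0.1,
                        n_trials = 1, seed = 1, lambda_tol = 1e-3)
  expect_equal(perm$trials$winner_network, 2L)
  expect_equal(perm$trials$winner_nf, 2L)
})

test_that("the normal form tracks the stochastic network at its bifurcation", {
  p <- wta_network(sigma = 0.01)
  rep <- track_network(p, epsilon = 1, theta = 0.5, duration = 8000, dt = 0.1,
                       n_trials = 120, seed = 7)
  expect_gte(rep$n_both_decided, 95)
  expect_gte(rep$agreement, 0.9)
  # the network refuses to track away from the bifurcation
  off <- wta_network(sigma = 0.01, I = 0.3)
  expect_error(track_network(off, n_trials = 2), "bifurcation")
})
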