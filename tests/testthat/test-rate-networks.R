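test_that("shipped transfer functions agree with finite differences of their value", {
  for (tf in list(transfer_identity(), transfer_piecewise_sqrt(), tf_softplus(1.3))) {
    # probe points away from the piecewise knots at 0 and 1
    x <- c(0.15, 0.4, 0.85, 1.3, 2.1)
    h <- 1e-5
    d1_fd <- (tf$value(x + h) - tf$value(x - h)) / (2 * h)
    d2_fd <- (tf$d1(x + h) - tf$d1(x - h)) / (2 * h)
    d3_fd <- (tf$d2(x + h) - tf$d2(x - h)) / (2 * h)
    expect_equal(tf$d1(x), d1_fd, tolerance = 1e-5)
    expect_equal(tf$d2(x), d2_fd, tolerance = 1e-5)
    expect_equal(tf$d3(x), d3_fd, tolerance = 1e-4)
  }
})

test_that("noise-free linear network at s = 1: competition modes hold, common modes reach steady state", {
  params <- network_params(n = 3, s = 1, c = 1.2, g = 0.8, I = 0.4,
                          I_I = 0.1, sigma = 0)
  traj <- simulate_linear(params, duration = 50 * params$tau_I, dt = 0.1,
                          r0 = c(0.2, -0.1, 0.05), r_I0 = 0)
  modes <- trajectory_modes(traj)
  x0 <- project_modes(c(0.2, -0.1, 0.05), competition_basis(3))$X
  # at s = 1 the competition projections have zero deterministic drift
  expect_lt(max(abs(sweep(modes$X, 2, x0))), 1e-10)
  ss <- mode_steady_state(params)
  expect_equal(ss$M_C, mean(params$I) / (params$c * params$g) - params$I_I / params$g)
  expect_equal(ss$M_I, mean(params$I) / params$c)
  expect_equal(tail(modes$m_C, 1), ss$M_C, tolerance = 1e-6)
  expect_equal(tail(traj$r_inh, 1), ss$M_I, tolerance = 1e-6)
})

test_that("mode steady state matches direct substitution and the trivial cases", {
  p <- network_params(n = 2, c = 1, g = 1, I = c(1, 1), I_I = 0)
  ss <- mode_steady_state(p)
  expect_equal(ss$M_C, 1)
  expect_equal(ss$M_I, 1)
  p0 <- network_params(n = 4, I = 0, I_I = 0)
  expect_equal(mode_steady_state(p0)$M_C, 0)
  expect_equal(mode_steady_state(p0)$M_I, 0)
  expect_error(mode_steady_state(network_params(n = 2, c = 0, I = 1)), "singular")
})

test_that("linear-mode eigenvalue closed forms match a dense eigensolver", {
  p1 <- network_params(n = 5, s = 1, I = 0)
  st <- linear_mode_eigenvalues(p1)
  expect_equal(st$lambda_competition, 0)
  expect_equal(st$competition_multiplicity, 4L)
  # zero discriminant: the common/inhibitory pair coalesces at -1/(2 tau_I)
  p2 <- network_params(n = 3, s = 1, tau = 20, tau_I = 10, c = 1, g = 0.5, I = 0)
  st2 <- linear_mode_eigenvalues(p2)
  expect_equal(sort(Re(st2$lambda_common)), rep(-1 / (2 * p2$tau_I), 2))
  set.seed(11)
  for (i in 1:100) {
    p <- network_params(n = sample(2:6, 1), tau = stats::runif(1, 5, 40),
                        tau_I = stats::runif(1, 2, 20), s = stats::runif(1, 0.2, 1.5),
                        c = stats::runif(1, 0.2, 2), g = stats::runif(1, 0.2, 2),
                        I = 0)
    st <- linear_mode_eigenvalues(p)
    num <- eigen(network_jacobian(p), only.values = TRUE)$values
    expect_equal(sort(Re(num)), sort(Re(st$eigenvalues)), tolerance = 1e-8)
    expect_equal(sort(abs(Im(num))), sort(abs(Im(st$eigenvalues))), tolerance = 1e-8)
  }
})

test_that("competition projections of the s = 1 linear network equal the DDM step for step", {
  set.seed(21)
  n <- 4; nsteps <- 400; dt <- 0.1
  NE <- matrix(stats::rnorm(n * nsteps), n, nsteps)
  NI <- stats::rnorm(nsteps)
  I <- c(0.4, 0.1, 0, -0.2)
  params <- network_params(n = n, s = 1, c = 0.7, g = 1.3, I = I, I_I = 0.3,
                          sigma = 0.8)
  traj <- simulate_linear(params, duration = nsteps * dt, dt = dt,
                          noise = list(E = NE, I = NI))
  X_net <- trajectory_modes(traj)$X
  dp <- ddm_params(n = n, tau = params$tau, I = I, sigma = params$sigma,
                   theta = 1e6, dt = dt, t_max = nsteps * dt)
  trial <- simulate_ddm_trial(dp, return_path = TRUE, noise = NE)
  expect_lt(max(abs(X_net - trial$path)), 1e-10)
})

test_that("competition dynamics are blind to inhibition-side parameters (same noise)", {
  set.seed(31)
  n <- 3; nsteps <- 300; dt <- 0.1
  NE <- matrix(stats::rnorm(n * nsteps), n, nsteps)
  NI <- stats::rnorm(nsteps)
  base <- network_params(n = n, s = 1, c = 1, g = 1, I = c(0.3, 0, 0),
                        I_I = 0, sigma = 0.5)
  alt <- network_params(n = n, s = 1, c = 2.5, g = 1, I = c(0.3, 0, 0),
                       I_I = 0.8, sigma = 0.5)
  X1 <- trajectory_modes(simulate_linear(base, nsteps * dt, dt,
                                         noise = list(E = NE, I = NI)))$X
  X2 <- trajectory_modes(simulate_linear(alt, nsteps * dt, dt,
                                         noise = list(E = NE, I = NI)))$X
  expect_lt(max(abs(X1 - X2)), 1e-10)
})

test_that("symmetric fixed points solve both self-consistency equations", {
  # identity transfer, no coupling: R = I_0
  p1 <- network_params(n = 3, s = 0, c = 0, I = 0.3)
  fp1 <- find_fixed_point(p1)
  expect_equal(fp1$R, 0.3, tolerance = 1e-10)
  # expansive-saturating transfer at the published operating point
  fp2 <- find_fixed_point(wta_network())
  expect_equal(fp2$R, 0.25, tolerance = 1e-9)
  expect_equal(fp2$R_I, 0.25, tolerance = 1e-9)
  # generic smooth monotone transfer: residual check
  set.seed(5)
  for (i in 1:20) {
    p <- rand_network()
    fp <- find_fixed_point(p)
    expect_equal(fp$R, p$phi$value(fp$arg_E), tolerance = 1e-9)
    expect_equal(fp$R_I, p$phi_I$value(fp$arg_I), tolerance = 1e-9)
  }
})

test_that("nonlinear eigenvalue closed forms match the numerical Jacobian", {
  # at the bifurcation the competition eigenvalue vanishes with multiplicity n-1
  p <- wta_network()
  fp <- find_fixed_point(p)
  st <- nonlinear_eigenvalues(p, fp)
  expect_lt(abs(st$lambda_competition), 1e-12)
  expect_equal(st$competition_multiplicity, 2L)
  # identity transfer reduces to the linear closed forms
  pl <- network_params(n = 4, s = 0.7, I = 0.2)
  fpl <- find_fixed_point(pl)
  expect_equal(nonlinear_eigenvalues(pl, fpl)$eigenvalues,
               linear_mode_eigenvalues(pl)$eigenvalues)
  set.seed(13)
  for (i in 1:100) {
    p <- rand_network()
    fp <- find_fixed_point(p)
    st <- nonlinear_eigenvalues(p, fp)
    J <- network_jacobian(p, dphi = p$phi$d1(fp$arg_E),
                          dphi_I = p$phi_I$d1(fp$arg_I))
    num <- eigen(J, only.values = TRUE)$values
    expect_equal(sort(Re(num)), sort(Re(st$eigenvalues)), tolerance = 1e-8)
    expect_equal(sort(abs(Im(num))), sort(abs(Im(st$eigenvalues))), tolerance = 1e-8)
  }
})

test_that("the bifurcation point is located where s * phi' = 1", {
  p <- wta_network()
  I0 <- find_bifurcation(p, c(0.1, 0.9))
  expect_equal(I0, 0.5, tolerance = 1e-9)
  p$I <- rep(I0, 3)
  fp <- find_fixed_point(p)
  expect_lt(abs(nonlinear_eigenvalues(p, fp)$lambda_competition), 1e-7)
  # identity transfer with s < 1: phi' is constant, no sign change
  expect_error(find_bifurcation(network_params(n = 3, s = 0.5, I = 0),
                                c(-1, 1)),
               "no bifurcation")
})

test_that("noise-free nonlinear trajectories conserve the symmetric fixed point", {
  p <- wta_network(sigma = 0)
  fp <- find_fixed_point(p)
  traj <- simulate_nonlinear(p, duration = 200, dt = 0.1, r0 = fp$R, r_I0 = fp$R_I)
  expect_lt(max(abs(traj$rates - fp$R)), 1e-12)
  expect_lt(max(abs(traj$r_inh - fp$R_I)), 1e-12)
  # common-mode perturbations decay at the slow rate of the stable pair
  # (parameters chosen so the pair is real and well separated)
  p2 <- network_params(n = 3, s = 1, c = 0.5, g = 0.45, I = 0.2, sigma = 0)
  fp2 <- find_fixed_point(p2)
  st2 <- nonlinear_eigenvalues(p2, fp2)
  rate <- max(Re(st2$lambda_common))
  traj2 <- simulate_nonlinear(p2, duration = 220, dt = 0.01,
                              r0 = fp2$R + 0.01, r_I0 = fp2$R_I)
  dev <- abs(rowMeans(traj2$rates) - fp2$R)
  i1 <- which.min(abs(traj2$times - 120))
  i2 <- which.min(abs(traj2$times - 200))
  decay_obs <- log(dev[i2] / dev[i1]) / (traj2$times[i2] - traj2$times[i1])
  expect_equal(decay_obs, rate, tolerance = 0.05)
})

test_that("winner-take-all competition picks exactly one winner, uniformly at zero coherence", {
  p <- wta_network(sigma = 0.01)
  fp <- find_fixed_point(p)
  set.seed(9)
  winners <- integer(0)
  n_exceed <- integer(0)
  for (tr in 1:200) {
    traj <- simulate_nonlinear(p, duration = 9000, dt = 0.1,
                               r0 = fp$R, r_I0 = fp$R_I)
    final <- traj$rates[nrow(traj$rates), ]
    n_exceed[tr] <- sum(final > 0.5)
    if (n_exceed[tr] >= 1) winners <- c(winners, which.max(final))
  }
  # almost all trials end with exactly one population above threshold
  expect_gte(mean(n_exceed == 1), 0.95)
  # permutation symmetry: winner identity uniform
  tab <- tabulate(winners, nbins = 3)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("trajectory containers export cleanly and reject bad steps", {
  p <- network_params(n = 2, I = 0)
  expect_error(simulate_linear(p, duration = -5, dt = 0.1), "positive")
  expect_warning(simulate_linear(p, duration = 10, dt = 5), "tau_I")
  df <- as.data.frame(simulate_linear(p, duration = 1, dt = 0.1))
  expect_named(df, c("time_ms", "r_1", "r_2", "r_I"))
  expect_equal(nrow(df), 11L)
})
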