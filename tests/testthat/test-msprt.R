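test_that("log-posteriors stay exactly normalized and share competition projections with the evidence", {
  p <- msprt_params(n = 3, I = 0, sigma = 0.03, theta = 50, dt = 0.05,
                    t_max = 5000)                 # 1e5 steps, no decision
  tr <- simulate_bayesian_trial(p, seed = 3, return_path = TRUE)
  expect_false(tr$decided)
  expect_lt(max(abs(rowSums(exp(tr$L)) - 1)), 1e-10)
  basis <- competition_basis(3)
  XL <- tr$L %*% t(basis$E)
  Xy <- tr$y %*% t(basis$E)
  expect_lt(max(abs(XL - Xy)), 1e-12)             # logsumexp is common-mode only
})

test_that("noise-free common mode attains the closed-form long-time slope", {
  for (upd in c("euler", "exact")) {
    # theta is set unreachably high to observe the free dynamics; the
    # feasibility warning for the exact update is expected
    p <- suppressWarnings(
      msprt_params(n = 3, I = c(0.1, 0, 0), sigma = 0, theta = 50,
                   dt = 0.05, t_max = 2000, update = upd))
    tr <- simulate_bayesian_trial(p, return_path = TRUE)
    nt <- length(tr$M_C)
    i1 <- floor(nt / 2)
    slope <- (tr$M_C[nt] - tr$M_C[i1]) / (tr$times[nt] - tr$times[i1])
    expect_equal(slope, -(1 / 3) * sum(abs(p$I - 0.1)), tolerance = 0.02)
    # the favored alternative's posterior tends to 1
    expect_gt(exp(tr$L[nt, 1]), 0.999)
  }
})

test_that("tied noise-free evidence keeps the posterior uniform and never decides", {
  p <- msprt_params(n = 4, I = 0.05, sigma = 0, theta = 0.5, dt = 0.05,
                    t_max = 500)
  tr <- simulate_bayesian_trial(p, return_path = TRUE)
  expect_false(tr$decided)
  expect_lt(max(abs(tr$L + log(4))), 1e-12)
})

test_that("Bayesian test and moving-threshold DDM are identical trial by trial", {
  nsteps <- as.integer(4000 / 0.05)
  for (upd in c("euler", "exact")) {
    p <- msprt_params(n = 3, I = c(0.004, 0, 0), sigma = 0.03, theta = 1.05,
                      dt = 0.05, t_max = 4000, update = upd)
    set.seed(101)
    for (i in 1:25) {
      NE <- matrix(stats::rnorm(3 * nsteps), 3, nsteps)
      a <- simulate_bayesian_trial(p, noise = NE)
      b <- simulate_mt_ddm_trial(p, noise = NE)
      expect_identical(a$choice, b$choice)
      expect_equal(a$rt, b$rt)
    }
  }
})

test_that("a vanishing fixed threshold decides immediately at chance", {
  p <- msprt_params(n = 3, I = 0, sigma = 0.03, theta = 1.05, dt = 0.05,
                    t_max = 100)
  blk <- run_msprt_block(p, 3000, model = "fixed", seed = 7, theta = 1e-9,
                         correct_choice = 1L)
  expect_true(all(blk$trials$rt == p$dt))
  se <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_lt(abs(blk$accuracy - 1 / 3), 3 * se)
})

test_that("fixed-threshold reaction times do not depend on which alternative wins", {
  p <- msprt_params(n = 3, I = 0, sigma = 0.03, theta = 1.05, dt = 0.05,
                    t_max = 1e4)
  blk <- run_msprt_block(p, 6000, model = "fixed", seed = 13, theta = 1.073,
                         correct_choice = 1L)
  rt_c <- blk$trials$rt[blk$trials$correct %in% TRUE]
  rt_e <- blk$trials$rt[blk$trials$correct %in% FALSE]
  # discrete time grid produces ties; the KS p-value is still conservative
  expect_gt(suppressWarnings(stats::ks.test(rt_c, rt_e))$p.value, 0.001)
})

test_that("accuracy increases with the favored input's mean", {
  p0 <- msprt_params(n = 3, I = 0, sigma = 0.03, theta = 1.05, dt = 0.05,
                     t_max = 1e4)
  grid <- c(0, 0.004, 0.008, 0.012)
  acc <- se <- numeric(length(grid))
  for (g in seq_along(grid)) {
    p <- p0; p$I <- c(grid[g], 0, 0)
    blk <- run_msprt_block(p, 1500, model = "mt", seed = 300 + g,
                           correct_choice = 1L)
    acc[g] <- blk$accuracy
    se[g] <- sqrt(blk$accuracy * (1 - blk$accuracy) / blk$n_decided)
  }
  for (g in seq_len(length(grid) - 1))
    expect_gte(acc[g + 1], acc[g] - 2 * sqrt(se[g]^2 + se[g + 1]^2))
  expect_gt(acc[length(grid)], acc[1] + 0.1)
})

test_that("self-calibration returns the reference threshold", {
  p <- msprt_params(n = 3, I = 0, sigma = 0.03, theta = 1.05, dt = 0.05,
                    t_max = 1e4)
  cal <- calibrate_fixed_threshold(p, n_trials = 800, seed = 19,
                                   model = "fixed", tol = 2e-3,
                                   bracket = c(0.9, 1.2))
  expect_equal(cal$theta_fixed, 1.05, tolerance = 5e-3)
  expect_error(calibrate_fixed_threshold(
    msprt_params(n = 3, I = c(0.01, 0, 0)), n_trials = 10),
    "zero-coherence")
})

test_that("the three-model comparison table behaves at zero coherence", {
  p <- msprt_params(n = 3, I = 0, sigma = 0.03, theta = 1.05, dt = 0.05,
                    t_max = 6000)
  tab <- run_fig2_comparison(c(0, 0.01), p, n_trials = 400, seed = 55,
                             theta_fixed = 1.073)
  expect_equal(nrow(tab), 6L)
  z <- tab[tab$I1 == 0, ]
  expect_true(all(abs(z$accuracy - 1 / 3) < 3 * z$accuracy_sem + 0.02))
  # Bayesian and MT rows are generated from identical streams
  b <- tab[tab$model == "bayesian", ]
  m <- tab[tab$model == "mt", ]
  expect_equal(b$accuracy, m$accuracy)
  expect_equal(b$rt_mean, m$rt_mean)
})

test_that("exact-update posterior criterion is reachable only below ln(n)", {
  expect_warning(msprt_params(n = 3, theta = 1.2, update = "exact"), "ln")
  expect_silent(msprt_params(n = 3, theta = 1.05, update = "exact"))
  # under the exact update a decision carries posterior >= e^theta / n
  p <- msprt_params(n = 3, I = c(0.01, 0, 0), sigma = 0.03, theta = 1.05,
                    dt = 0.05, t_max = 1e4, update = "exact")
  tr <- simulate_bayesian_trial(p, seed = 77)
  expect_true(tr$decided)
  expect_gte(tr$posterior_at_decision, exp(p$theta) / 3 - 1e-9)
})
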