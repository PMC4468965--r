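test_that("expression mismatch Y follows its definition", {
  env <- environment_ensemble(rep(8, 5), tau = 0.5)
  expect_equal(mismatch_Y(env, 0.2), 0)

  # var(mu_e) = sigma2 + tau2  ->  Y = 1
  mu_e <- c(7, 8, 9)  # population variance 2/3
  env2 <- environment_ensemble(mu_e, tau = sqrt(2 / 3 - 0.1))
  expect_equal(mismatch_Y(env2, 0.1), 1)

  # three symmetric environments: Y^2 = (2 Delta^2 / 3) / (sigma2 + tau2)
  Delta <- 0.7
  env3 <- environment_ensemble(c(8 - Delta, 8, 8 + Delta), tau = 0.3)
  expect_equal(mismatch_Y(env3, 0.05)^2, (2 * Delta^2 / 3) / (0.05 + 0.09))
})

test_that("regulator correlation and signal-to-noise follow their definitions", {
  env <- environment_ensemble(c(6, 7.5, 8, 9.2), tau = 0.3)
  # affine in mu_e -> R = 1
  reg <- regulator_profile(2 * env$mu_e - 5, sigma_r2 = 0.1)
  rs <- regulator_RS(env, reg)
  expect_equal(rs$R, 1)
  # var(r_e) = 4 sigma_r2 -> S = 2
  r_e <- c(-1, 0, 0, 1) * sqrt(2)  # population variance 1
  reg2 <- regulator_profile(r_e + 8, sigma_r2 = 0.25)
  expect_equal(regulator_RS(env, reg2)$S, 2)
  # constructed orthogonal regulator -> R = 0
  gr <- gen_environment_and_regulator(n_environments = 30, target_R = 0,
                                      target_S = 1, seed = 2)
  expect_equal(gr$R, 0, tolerance = 1e-12)
  # constant regulator: R undefined, S = 0
  rs0 <- regulator_RS(env, regulator_profile(rep(1, 4), 0.1))
  expect_true(is.na(rs0$R))
  expect_equal(rs0$S, 0)
})

test_that("unregulated log-fitness matches the per-environment oracle", {
  # perfect promoter in a constant environment
  env0 <- environment_ensemble(rep(8, 3), tau = 0.2)
  expect_equal(logfitness_unregulated(8, 0, env0), 0)

  # closed form equals the weighted mean over environments of log fitness
  set.seed(31)
  for (i in 1:100) {
    n_e <- sample(2:10, 1)
    w <- runif(n_e); w <- w / sum(w)
    env <- environment_ensemble(runif(n_e, 5, 10), runif(1, 0.05, 1), w)
    mu <- runif(1, 5, 10); s2 <- runif(1, 0, 0.5)
    oracle <- sum(w * log(vapply(env$mu_e, function(m)
      genotype_fitness(mu, s2, selection_gate(m, env$tau)), numeric(1))))
    expect_equal(logfitness_unregulated(mu, s2, env), oracle,
                 tolerance = 1e-12)
  }
})

test_that("bet-hedging: numeric optimum of unregulated noise hits the closed form", {
  set.seed(32)
  for (i in 1:50) {
    env <- environment_ensemble(rnorm(sample(3:20, 1), 8, runif(1, 0.05, 1.5)),
                                tau = runif(1, 0.05, 1))
    target <- optimal_unregulated_noise(env)
    upper <- max(1, 3 * target)
    opt <- optimize(function(s2) logfitness_unregulated(mean(env$mu_e), s2, env),
                    c(0, upper), maximum = TRUE, tol = 1e-12)
    num <- if (logfitness_unregulated(mean(env$mu_e), 0, env) >= opt$objective)
      0 else opt$maximum
    expect_equal(num, target, tolerance = 1e-6)
  }
})

test_that("the reduced-form fitness gain equals the constructive difference", {
  for (i in 1:100) {
    sc <- random_scenario(i)
    st <- coupling_state(sc$sigma2, sc$c, sc$env, sc$reg)
    mbar <- sum(sc$env$weights * sc$env$mu_e)
    lhs <- dlogf(st$X, st$Y, st$R, st$S)
    rhs <- logfitness_coupled(NA, sc$sigma2, sc$c, sc$env, sc$reg,
                              optimize_mu = TRUE) -
      logfitness_unregulated(mbar, sc$sigma2, sc$env)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # no coupling, no change
  expect_equal(dlogf(0, 2, 0.5, 1), 0)
})

test_that("coupled log-fitness limits: zero coupling and perfect tracking", {
  sc <- random_scenario(404)
  mbar <- sum(sc$env$weights * sc$env$mu_e)
  expect_equal(logfitness_coupled(mbar, sc$sigma2, 0, sc$env, sc$reg),
               logfitness_unregulated(mbar, sc$sigma2, sc$env))

  # R = 1 regulator with matched gain and vanishing regulator noise:
  # log f -> (1/2) log(tau^2 / (tau^2 + sigma2))
  env <- environment_ensemble(c(7, 8, 9), tau = 0.2)
  s2 <- 0.05
  reg <- regulator_profile(0.5 * env$mu_e, sigma_r2 = 1e-12)
  lf <- logfitness_coupled(NA, s2, 2, env, reg, optimize_mu = TRUE)
  expect_equal(lf, 0.5 * log(0.04 / (0.04 + s2)), tolerance = 1e-9)
})

test_that("closed-form optima agree with joint numeric maximization", {
  # evaluation of the printed closed forms
  expect_equal(optimal_coupling(2, 0)^2, 3)
  expect_equal(optimal_coupling(4, 0.64)^2, (1 - 0.4096) * 16 - 1)
  expect_equal(optimal_coupling(1, 1), 0)
  expect_equal(optimal_signal_to_noise(0.95, 4, 1), 3.8)
  expect_equal(optimal_signal_to_noise(0, 3, 0.5), 0)
  expect_error(optimal_signal_to_noise(0.5, 3, 0), "diverges")

  set.seed(33)
  for (i in 1:25) {
    Y <- runif(1, 0.3, 5); R <- runif(1, 0, 0.95)
    m <- maximize_dlogf(Y, R)
    Xs <- optimal_coupling(Y, R)
    expect_equal(m$X^2, Xs^2, tolerance = 1e-5)
    if (Xs > 1e-3) {
      expect_equal(m$S, optimal_signal_to_noise(R, Y, Xs), tolerance = 1e-4)
      # and the profile in S at the optimum is maximized at S* = RY/X
      gs <- seq(0, 3 * abs(R) * Y / Xs + 1, length.out = 4001)
      vals <- dlogf(Xs, Y, R, gs)
      expect_equal(gs[which.max(vals)], R * Y / Xs,
                   tolerance = 1e-2)
    }
  }
})

test_that("optimal total noise is continuous and matches explicit optimization", {
  env <- environment_ensemble(c(7, 8, 9), tau = 0.2)  # var(mu_e) = 2/3
  s2 <- 0.05
  # basal regime at R close to 1
  expect_equal(predicted_total_noise(0.99, env, s2), s2)
  # environment-driven regime at R = 0: var - tau^2
  expect_equal(predicted_total_noise(0, env, s2), 2 / 3 - 0.04)
  # continuity across the boundary (1 - R^2) Y^2 = 1
  vm <- 2 / 3
  Rb <- sqrt(1 - (s2 + 0.04) / vm)
  eps <- 1e-9
  expect_equal(predicted_total_noise(Rb - eps, env, s2),
               predicted_total_noise(Rb + eps, env, s2), tolerance = 1e-6)
  # R = 0, var(mu_e) = 10 tau^2, sigma2 = tau^2 -> 9 tau^2
  tau <- 0.2
  env10 <- environment_ensemble(c(-1, 0, 1) * sqrt(15) * tau, tau)
  expect_equal(predicted_total_noise(0, env10, tau^2), 9 * tau^2)

  # environment-driven regime: sigma2 + c*^2 sigma_r2 from explicit joint
  # optimization of the constructive log-fitness equals the prediction
  gr <- gen_environment_and_regulator(n_environments = 40, mu_e_spread = 0.8,
                                      tau = 0.2, target_R = 0.5, target_S = 2,
                                      seed = 12)
  s2b <- 0.03
  obj <- function(par) { # par = (c, log sigma_r2): S varies with sigma_r2
    reg <- regulator_profile(gr$reg$r_e, exp(par[2]))
    -logfitness_coupled(NA, s2b, par[1], gr$env, reg, optimize_mu = TRUE)
  }
  o <- optim(c(0.5, log(gr$reg$sigma_r2)), obj, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 2000))
  tot <- s2b + o$par[1]^2 * exp(o$par[2])
  vm2 <- sum(gr$env$weights * (gr$env$mu_e - sum(gr$env$weights * gr$env$mu_e))^2)
  expect_equal(tot, (1 - 0.25) * vm2 - 0.04, tolerance = 1e-4)

  # bet-hedging consistency at R = 0: total variance = var(mu_e) - tau^2
  gr0 <- gen_environment_and_regulator(n_environments = 40, mu_e_spread = 0.8,
                                       tau = 0.2, target_R = 0, target_S = 1,
                                       seed = 13)
  st <- coupling_state(s2b, 1, gr0$env, gr0$reg)
  Xs <- optimal_coupling(st$Y, 0)
  vm0 <- sum(gr0$env$weights *
               (gr0$env$mu_e - sum(gr0$env$weights * gr0$env$mu_e))^2)
  expect_equal(s2b + Xs^2 * (s2b + 0.04), vm0 - 0.04, tolerance = 1e-10)
})

test_that("composite regulators combine means and variances as printed", {
  env_n <- 5
  r1 <- regulator_profile(1:5, 0.2)
  r2 <- regulator_profile(c(2, 1, 4, 3, 5), 0.3)

  # single regulator is the identity
  cz <- composite_regulator(list(r1), couplings = 1.5)
  expect_equal(cz$profile$r_e, r1$r_e)
  expect_equal(cz$c, 1.5)

  # independent regulators: variances add
  ci <- composite_regulator(list(r1, r2), c(1, 1))
  expect_equal(ci$profile$sigma_r2, 0.2 + 0.3)
  expect_equal(ci$profile$r_e, (r1$r_e + r2$r_e) / sqrt(2))

  # perfectly correlated equal-noise pair, per the printed cross term
  r3 <- regulator_profile(c(5, 4, 3, 2, 1), 0.2)
  cc <- composite_regulator(list(r1, r3), c(1, 1),
                            cross_correlations = matrix(c(1, 1, 1, 1), 2))
  expect_equal(cc$profile$sigma_r2, 0.2 + 0.2 + 2 * 0.2)

  # c_i c_j-weighted variant reduces to the variance of the combination / c^2
  cw <- composite_regulator(list(r1, r2), c(2, -1), cross_weighted = TRUE)
  expect_equal(cw$profile$sigma_r2, (4 * 0.2 + 1 * 0.3) / cw$c^2)

  expect_error(composite_regulator(list(r1, r2), c(1, 1),
                                   cross_correlations = matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})

test_that("iterating the argument reproduces residual mismatch exactly", {
  sc <- random_scenario(77)
  # zero gain leaves the state unchanged
  it0 <- iterate_regulation(sc$env, sc$reg, sc$sigma2, 0)
  expect_equal(it0$env$mu_e, sc$env$mu_e)
  expect_equal(it0$Y_new, mismatch_Y(sc$env, sc$sigma2))

  # a perfect regulator with matched gain removes all mismatch
  env <- environment_ensemble(c(7, 8, 9), tau = 0.2)
  reg <- regulator_profile(0.5 * env$mu_e + 1, 0.01)
  itp <- iterate_regulation(env, reg, 0.05, 2)
  expect_equal(var(itp$env$mu_e), 0)
  expect_equal(itp$Y_new, 0)

  # random draw: residual mismatch recomputed from the definition
  it <- iterate_regulation(sc$env, sc$reg, sc$sigma2, sc$c)
  res <- sc$env$mu_e - sc$c * sc$reg$r_e
  w <- sc$env$weights
  vres <- sum(w * (res - sum(w * res))^2)
  s2n <- sc$sigma2 + sc$c^2 * sc$reg$sigma_r2
  expect_equal(it$Y_new^2, vres / (s2n + sc$env$tau^2), tolerance = 1e-12)
  expect_equal(it$sigma2_new, s2n)
})

test_that("the fitness landscape matches the reduced form and is ridge-consistent", {
  Y <- 3
  R_grid <- seq(0, 0.9, by = 0.3)
  S_grid <- seq(0, 4, by = 1)
  fl <- fitness_landscape(Y, R_grid, S_grid)

  # R = 0 column equals max over X of the reduced expression
  for (i in seq_along(S_grid)) {
    S <- S_grid[i]
    o <- optimize(function(X) 0.5 * X^2 * (Y^2 - S^2) / (1 + X^2) -
                    0.5 * log(1 + X^2), c(0, Y + 2), maximum = TRUE,
                  tol = 1e-10)
    expect_equal(fl$landscape[i, 1], max(o$objective, 0), tolerance = 1e-6)
  }

  # below the ridge the landscape is non-decreasing in R at fixed S
  below <- which(S_grid <= Y * min(R_grid[-1]))
  for (i in below) expect_true(all(diff(fl$landscape[i, ]) >= -1e-8))

  # ridge curve matches S* = R Y / X*
  Xs <- optimal_coupling(Y, R_grid)
  expect_equal(fl$ridge$S_star[Xs > 0], (R_grid * Y / Xs)[Xs > 0])

  # phase diagram: continuity across the boundary and regime values
  pd <- phase_diagram(Y_grid = c(0.5, 2), R_grid = c(0, 0.5), sigma2 = 0.02,
                      tau = 0.1)
  expect_equal(pd["0", "0.5"], 0.02)  # basal regime: (1-R^2) Y^2 = 0.25 < 1
  vm <- 4 * (0.02 + 0.01)
  expect_equal(pd["0", "2"], vm - 0.01)  # environment-driven regime
})
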