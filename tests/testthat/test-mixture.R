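test_that("mixture log-likelihood: analytic cases and the summation oracle", {
  set.seed(21)
  tg <- runif(40, -pi, pi)
  nt <- matrix(runif(80, -pi, pi), 40)
  tt <- vwm_trials(runif(40, -pi, pi), tg, nt)
  # pure uniform responding
  expect_equal(mixture_loglik(mixture_params(0, 0, kappa = 1), tt),
               40 * log(1 / (2 * pi)), tolerance = 1e-12)
  # kappa = 0 makes the target component itself uniform
  t1 <- vwm_trials(0.3, -2)
  expect_equal(mixture_loglik(mixture_params(1, 0, kappa = 0), t1),
               log(1 / (2 * pi)), tolerance = 1e-12)
  # hand-written trials vs literal term-by-term oracle
  t3 <- vwm_trials(response = c(0.2, -1.4, 3.0),
                   target = c(0.1, 0.5, -3.0),
                   nontargets = rbind(c(1, -2), c(-1.5, 2.2), c(0.4, 2.9)))
  expect_equal(mixture_loglik(mixture_params(0.6, 0.3, kappa = 4), t3),
               mixture_loglik_oracle(0.6, 0.3, 4, t3), tolerance = 1e-8)
  expect_error(mixture_loglik(mixture_params(0.5, 0.3, kappa = 2), t1),
               "invalid-model")
})

test_that("responsibilities are normalized posteriors with correct limits", {
  tt <- vwm_trials(response = c(0.0, 1.0), target = c(0.0, 0.2),
                   nontargets = rbind(c(pi, -pi / 2), c(-2, 2)))
  r_unif <- responsibilities(mixture_params(0, 0, kappa = 3), tt)
  expect_equal(unname(r_unif[, "uniform"]), c(1, 1), tolerance = 1e-12)
  # response at target, nontargets far, large kappa: target dominates
  tt2 <- vwm_trials(0, 0, matrix(c(pi, pi), 1))
  r <- responsibilities(mixture_params(0.5, 0.5, kappa = 30), tt2)
  expect_gt(r[1, "target"], 1 - 1e-9)
  set.seed(22)
  tt3 <- simulate_trials(50, 0.5, 0.3, 6, seed = 23)
  rr <- responsibilities(mixture_params(0.5, 0.3, kappa = 6), tt3)
  expect_equal(rowSums(rr), rep(1, 50), tolerance = 1e-12)
  expect_true(all(rr >= 0))
})

test_that("EM recovers generating parameters in clean regimes", {
  tt <- simulate_trials(2000, 1, 0, 15, m = 2, seed = 31)
  f <- fit_vm_mixture(tt)
  expect_gte(f$params$alpha, 0.97)
  expect_lt(abs(f$sigma - kappa_to_sd(15)), 0.02)
  # pure guessing
  set.seed(32)
  tg <- runif(2000, -pi, pi)
  nt <- matrix(runif(4000, -pi, pi), 2000)
  tt_u <- vwm_trials(runif(2000, -pi, pi), tg, nt)
  f_u <- fit_vm_mixture(tt_u)
  expect_gte(f_u$params$gamma, 0.95)
})

test_that("EM log-likelihood is non-decreasing within every start", {
  for (s in 1:5) {
    tt <- simulate_trials(150, runif(1, 0.3, 0.8), runif(1, 0, 0.2),
                          exp(runif(1, 0, 3)), m = 2, seed = 40 + s)
    f <- fit_vm_mixture(tt, trace = TRUE)
    for (tr in f$trace)
      expect_true(all(diff(tr) >= -1e-8))
  }
})

test_that("EM attains the exhaustive-grid maximum on random data sets", {
  for (s in 1:5) {
    tt <- simulate_trials(100, runif(1, 0.2, 0.9), runif(1, 0, 0.3),
                          exp(runif(1, -0.5, 3)), m = 2, seed = 50 + s)
    f <- fit_vm_mixture(tt)
    expect_gte(f$log_likelihood, grid_loglik_max(tt) - 1e-3)
  }
})

test_that("low-load fits are two-component with beta exactly zero", {
  set.seed(61)
  tg <- runif(200, -pi, pi)
  p <- mixture_params(0.85, 0, kappa = 10)
  tt <- vwm_trials(simulate_responses(p, tg), tg)
  f <- fit_vm_mixture(tt)
  expect_identical(f$params$beta, 0)
  expect_identical(f$params$gamma, 1 - f$params$alpha)
  expect_lt(abs(f$params$alpha - 0.85), 0.1)
})

test_that("near-uniform concentration only alpha + gamma is identifiable", {
  tt <- simulate_trials(1500, 0.6, 0, 0.05, m = 0, seed = 62)
  f <- fit_vm_mixture(tt)
  expect_equal(f$params$alpha + f$params$gamma, 1, tolerance = 1e-9)
})

test_that("fit warns on very small samples", {
  tt <- simulate_trials(10, 0.8, 0, 8, m = 0, seed = 63)
  expect_warning(fit_vm_mixture(tt), "unstable")
})

test_that("the model sampler honours component probabilities and the seed", {
  set.seed(71)
  tg <- runif(1e5, -pi, pi)
  nt <- matrix(runif(2e5, -pi, pi), 1e5)
  p <- mixture_params(0.6, 0.3, kappa = 8)
  s <- simulate_responses(p, tg, nt, seed = 72, return_components = TRUE)
  freq <- table(s$component) / 1e5
  expect_lt(abs(freq[["target"]] - 0.6), 0.01)
  expect_lt(abs(freq[["nontarget"]] - 0.3), 0.01)
  expect_lt(abs(freq[["uniform"]] - 0.1), 0.01)
  expect_identical(simulate_responses(p, tg, nt, seed = 72),
                   simulate_responses(p, tg, nt, seed = 72))
  # concentrated limit reproduces the targets
  tg2 <- runif(500, -pi, pi)
  r2 <- simulate_responses(mixture_params(1, 0, kappa = 1e6), tg2, seed = 73)
  expect_lt(sqrt(mean(wrap_angle(r2 - tg2)^2)), 0.01)
})
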