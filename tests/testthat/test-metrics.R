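test_that("recall error wraps the response-target difference", {
  expect_equal(recall_error(0.3, 0.1), 0.2)
  expect_equal(recall_error(-3, 3), 2 * pi - 6, tolerance = 1e-12)
  expect_equal(recall_error(1.234, 1.234), 0)
})

test_that("chance-corrected precision is centred on zero for guessers", {
  set.seed(81)
  ch <- chance_precision_level(1e4, n_reps = 2000)
  p <- precision(runif(1e4, -pi, pi), chance_level = ch)
  expect_lt(abs(p$precision), 0.02)
})

test_that("precision of von Mises errors matches the closed form", {
  set.seed(82)
  errs <- sample_vm(1e4, 0, 8)
  p <- precision(errs, n_chance_reps = 2000)
  expect_equal(p$precision, 1 / kappa_to_sd(8) - p$chance_level,
               tolerance = 0.05)
  expect_equal(p$raw, 1 / circ_sd(errs))
})

test_that("zero-dispersion samples saturate at the documented cap", {
  p <- precision(rep(0.4, 50), n_chance_reps = 500, seed = 83)
  expect_true(p$saturated)
  expect_equal(p$raw, 1000)
  expect_error(precision(0.2), "insufficient-data")
})

test_that("nontarget RMS deviation: independence null and exact-swap limits", {
  set.seed(91)
  # responses unrelated to nontargets: E[d^2] = pi^2/3
  tt <- vwm_trials(runif(1e5, -pi, pi), runif(1e5, -pi, pi),
                   matrix(runif(2e5, -pi, pi), 1e5))
  expect_equal(nontarget_rms_deviation(tt), pi / sqrt(3), tolerance = 0.01)
  # every response equal to the sole nontarget
  nt1 <- matrix(runif(100, -pi, pi), 100)
  tt2 <- vwm_trials(nt1[, 1], runif(100, -pi, pi), nt1)
  expect_equal(nontarget_rms_deviation(tt2), 0)
  expect_error(nontarget_rms_deviation(vwm_trials(1:3 / 10, 1:3 / 10)),
               "no-nontargets")
})

test_that("misbinding pulls the nontarget RMS below the chance value", {
  tt <- simulate_trials(1e5, 0.55, 0.4, 10, m = 2, seed = 92)
  v <- nontarget_rms_deviation(tt)
  expect_lt(v, pi / sqrt(3))
  # independent Monte-Carlo evaluation of the same generative mixture
  set.seed(93)
  n <- 1e5
  tg <- runif(n, -pi, pi); nt <- matrix(runif(2 * n, -pi, pi), n)
  u <- runif(n)
  centre <- ifelse(u < 0.55, tg,
                   ifelse(u < 0.95, nt[cbind(1:n, sample(2, n, TRUE))], NA))
  resp <- centre + sample_vm(n, 0, 10)
  resp[is.na(centre)] <- runif(sum(is.na(centre)), -pi, pi)
  resp <- wrap_angle(resp)
  oracle <- sqrt(mean(wrap_angle(resp - nt)^2))
  expect_equal(v, oracle, tolerance = 0.02)
})

test_that("the subject-level chance test behaves at and away from the null", {
  at_chance <- rep(pi / sqrt(3), 10)
  r <- chance_rms_test(at_chance)
  expect_equal(r$t, 0)
  expect_error(chance_rms_test(c(1, 2)), "insufficient-data")
  # power: 30 subjects generated with genuine misbinding
  set.seed(101)
  rms <- replicate(30, {
    tt <- simulate_trials(150, 0.6, 0.3, 8, m = 2)
    nontarget_rms_deviation(tt)
  })
  expect_lt(chance_rms_test(rms)$p, 0.001)
})

test_that("error-magnitude correlation: limits, independence, symmetry", {
  set.seed(111)
  e1 <- wrap_angle(rnorm(200, 0, 0.8))
  expect_equal(error_magnitude_correlation(e1, e1), 1)
  e2 <- wrap_angle(rnorm(1e4, 0, 0.8))
  e3 <- wrap_angle(rnorm(1e4, 0, 0.8))
  expect_lt(abs(error_magnitude_correlation(e2, e3)), 0.03)
  expect_equal(error_magnitude_correlation(e2, e3),
               error_magnitude_correlation(e3, e2))
  perm <- sample(1e4)
  expect_equal(error_magnitude_correlation(e2[perm], e3[perm]),
               error_magnitude_correlation(e2, e3))
  expect_error(error_magnitude_correlation(e1, e2), "unpaired-data")
})

test_that("shared per-trial concentration induces a positive magnitude correlation", {
  set.seed(112)
  n <- 1e4
  kap <- exp(runif(n, 0, 3))           # per-trial modulator shared by dimensions
  e1 <- vapply(kap, function(k) sample_vm(1, 0, k), 0)
  e2 <- vapply(kap, function(k) sample_vm(1, 0, k), 0)
  r <- error_magnitude_correlation(e1, e2)
  expect_gt(r, 0.1)
  # direct oracle on a fresh draw from the same generator
  e1b <- vapply(kap, function(k) sample_vm(1, 0, k), 0)
  e2b <- vapply(kap, function(k) sample_vm(1, 0, k), 0)
  r_oracle <- cor(abs(wrap_angle(e1b)), abs(wrap_angle(e2b)))
  expect_equal(r, r_oracle, tolerance = 0.05)
})

test_that("co-occurrence benchmark couples misreports at the marginal rates", {
  fit_like <- function(alpha, beta, kappa)
    structure(list(params = mixture_params(alpha, beta, kappa = kappa),
                   sigma = kappa_to_sd(kappa)), class = "mixture_fit")
  f0 <- fit_like(0.9, 0, 8)
  r0 <- expected_cooccurrence_correlation(f0, f0, m = 2, n_sim = 2e4, seed = 121)
  expect_lt(abs(r0), 0.03)
  f1 <- fit_like(0, 1, 50)
  r1 <- expected_cooccurrence_correlation(f1, f1, m = 2, n_sim = 2e4, seed = 122)
  expect_gt(r1, 0.3)   # certain co-occurring swaps: strongly coupled deviations
  # determinism
  expect_identical(
    expected_cooccurrence_correlation(f1, f0, m = 2, n_sim = 5e3, seed = 123),
    expected_cooccurrence_correlation(f1, f0, m = 2, n_sim = 5e3, seed = 123))
  # brute-force re-simulation of the same maximal coupling
  set.seed(124)
  n <- 2e4
  nt1 <- matrix(runif(2 * n, -pi, pi), n)
  nt2 <- matrix(runif(2 * n, -pi, pi), n)
  pick <- sample(2, n, TRUE)
  r1v <- wrap_angle(nt1[cbind(1:n, pick)] + sample_vm(n, 0, 50))
  r2v <- wrap_angle(nt2[cbind(1:n, pick)] + sample_vm(n, 0, 50))
  oracle <- cor(as.vector(abs(wrap_angle(r1v - nt1))),
                as.vector(abs(wrap_angle(r2v - nt2))))
  expect_lt(abs(r1 - oracle), 0.05)
})

test_that("precision increases monotonically with generating concentration", {
  set.seed(131)
  ch <- chance_precision_level(2000, n_reps = 2000)
  med_prec <- vapply(c(2, 4, 8, 16, 32), function(k) {
    median(replicate(3, {
      tt <- simulate_trials(2000, 0.95, 0, k, m = 0)
      err <- recall_error(tt$response, tt$target)
      precision(err, chance_level = ch)$precision
    }))
  }, 0)
  expect_true(all(diff(med_prec) > 0))
})
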