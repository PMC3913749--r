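test_that("memory arrays are uniform with a uniformly chosen target", {
  set.seed(141)
  a1 <- generate_array(1)
  expect_length(a1$orientation$nontargets, 0)
  expect_length(a1$colour$nontargets, 0)
  expect_error(generate_array(2), "invalid-design")
  n <- 2e4
  ti <- integer(n); vals <- numeric(n)
  for (i in seq_len(n)) {
    a <- generate_array(3)
    ti[i] <- a$target_index
    vals[i] <- a$orientation$target
  }
  expect_true(all(abs(table(ti) / n - 1 / 3) < 0.01))
  # circular uniformity of feature values (chi-squared over 20 bins)
  cnt <- table(cut(vals, breaks = seq(-pi, pi, length.out = 21)))
  expect_gt(chisq.test(as.vector(cnt))$p.value, 1e-3)
})

test_that("subject generation is seed-deterministic and fit-consistent", {
  params <- list(
    low = list(orientation = mixture_params(0.95, 0, kappa = 20),
               colour = mixture_params(0.95, 0, kappa = 20)),
    high = list(orientation = mixture_params(1, 0, kappa = 50),
                colour = mixture_params(0.7, 0.2, kappa = 8)))
  t1 <- generate_subject("s1", 30, 2000, params, seed = 151)
  t2 <- generate_subject("s1", 30, 2000, params, seed = 151)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 2 * (25 + 175))
  # fitted sigma in the alpha = 1 cell round-trips through the fitter
  big <- generate_subject("s2", 30, 2000, params, trials_high = 2000,
                          seed = 152)
  cell <- trials_for_cell(big, "s2", 3, "orientation")
  f <- fit_vm_mixture(cell)
  expect_lt(abs(f$sigma - kappa_to_sd(50)), 0.03)
})

test_that("cross-dimension coupling controls the deviation correlation", {
  params <- list(
    low = list(orientation = mixture_params(0.95, 0, kappa = 20),
               colour = mixture_params(0.95, 0, kappa = 20)),
    high = list(orientation = mixture_params(0.5, 0.5, kappa = 30),
                colour = mixture_params(0.5, 0.5, kappa = 30)))
  dev_cor <- function(coupling, seed) {
    tt <- generate_subject("s", 40, 2000, params, trials_low = 2,
                           trials_high = 8000, coupling = coupling,
                           seed = seed)
    hi <- tt[tt$load == 3, ]
    d1 <- hi[hi$dimension == "orientation", ]
    d2 <- hi[hi$dimension == "colour", ]
    nontarget_dev_correlation(d1$response, cbind(d1$nontarget1, d1$nontarget2),
                              d2$response, cbind(d2$nontarget1, d2$nontarget2))
  }
  expect_lt(abs(dev_cor(0, 161)), 0.03)
  r_coupled <- dev_cor(1, 162)
  expect_gt(r_coupled, 0.1)
  # internal consistency with the model-based co-occurrence benchmark
  fit_like <- structure(list(params = mixture_params(0.5, 0.5, kappa = 30),
                             sigma = kappa_to_sd(30)), class = "mixture_fit")
  bench <- expected_cooccurrence_correlation(fit_like, fit_like, m = 2,
                                             n_sim = 2e4, seed = 163)
  expect_lt(abs(r_coupled - bench), 0.05)
})

test_that("cohorts are reproducible with valid angles and simplexes", {
  spec <- cohort_spec(n_subjects = 8, trials_high = 50, seed = 171)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$subjects, c2$subjects)
  ang <- unlist(c1$trials[, c("target", "nontarget1", "nontarget2", "response")])
  ang <- ang[!is.na(ang)]
  expect_true(all(ang > -pi & ang <= pi))
  for (l in c("low", "high")) for (d in c("orientation", "colour")) {
    cols <- paste("true", l, d, c("alpha", "beta", "gamma"), sep = "_")
    s <- rowSums(c1$subjects[, cols])
    expect_equal(s, rep(1, 8), tolerance = 1e-9)
  }
  expect_true(all(c1$subjects$true_low_orientation_beta == 0))
  # per-subject row counts: 2 dimensions x (25 + 50) trials
  expect_true(all(table(c1$trials$subject_id) == 2 * (25 + 50)))
})

test_that("exposure groups are matched for age", {
  co <- generate_cohort(cohort_spec(seed = 181))
  ks <- suppressWarnings(
    ks.test(co$subjects$age[co$subjects$exposure == 200],
            co$subjects$age[co$subjects$exposure == 2000]))
  expect_gt(ks$p.value, 0.05)
})

test_that("fitted parameters recover the generating age structure", {
  co <- generate_cohort(cohort_spec(seed = 191))
  est <- fit_cohort(co$trials, co$subjects, n_chance_reps = 1000)
  hi <- est[est$load == 3, ]
  true_sigma <- ifelse(hi$dimension == "orientation",
                       hi$true_high_orientation_sigma,
                       hi$true_high_colour_sigma)
  true_beta <- ifelse(hi$dimension == "orientation",
                      hi$true_high_orientation_beta,
                      hi$true_high_colour_beta)
  # sigma: regression of fitted on true near the identity
  fit <- lm(hi$sigma ~ true_sigma)
  expect_gt(coef(fit)[2], 0.9)
  expect_lt(coef(fit)[2], 1.1)
  expect_gt(cor(hi$sigma, true_sigma), 0.9)
  # beta: mean absolute error at 175 high-load trials
  expect_lt(mean(abs(hi$beta - true_beta)), 0.05)
})

test_that("null age maps yield no systematic age trends", {
  maps <- default_age_maps()
  for (l in names(maps)) for (d in names(maps[[l]]))
    for (p in names(maps[[l]][[d]])) maps[[l]][[d]][[p]][2] <- 0
  hits <- 0L
  n_rep <- 20
  for (s in seq_len(n_rep)) {
    co <- generate_cohort(cohort_spec(n_subjects = 30, trials_high = 60,
                                      age_maps = maps, seed = 200 + s))
    est <- fit_cohort(co$trials, co$subjects, n_chance_reps = 200,
                      seed = 300 + s)
    hi <- est[est$load == 3 & est$dimension == "orientation", ]
    r <- regress_on_age(hi$sigma, hi$age)
    if (r$p < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 4)  # ~binomial(20, 0.05); 5+ false trends is implausible
})
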