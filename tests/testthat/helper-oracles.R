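# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Bessel functions by direct power series, mixture
# likelihoods by literal term-by-term summation, and the EM cross-check by
# exhaustive grid search.

# modified Bessel function of the first kind, integer order, by power series
bessel_series <- function(x, nu = 0, n_terms = 60) {
  k <- 0:(n_terms - 1)
  sum((x / 2)^(2 * k + nu) / (factorial(k) * factorial(k + nu)))
}

# von Mises density evaluated from the series oracle
vm_pdf_series <- function(x, mu, kappa) {
  exp(kappa * cos(x - mu)) / (2 * pi * bessel_series(kappa, 0))
}

# circular SD implied by kappa, from the series oracle
kappa_to_sd_series <- function(kappa) {
  sqrt(-2 * log(bessel_series(kappa, 1) / bessel_series(kappa, 0)))
}

# literal Eq-style mixture log-likelihood: loop over trials and components
mixture_loglik_oracle <- function(alpha, beta, kappa, trials) {
  gamma <- 1 - alpha - beta
  total <- 0
  for (i in seq_len(trials$n)) {
    lik <- alpha * vm_pdf_series(trials$response[i], trials$target[i], kappa) +
      gamma / (2 * pi)
    if (trials$m > 0)
      for (j in seq_len(trials$m))
        lik <- lik + (beta / trials$m) *
          vm_pdf_series(trials$response[i], trials$nontargets[i, j], kappa)
    total <- total + log(lik)
  }
  total
}

# exhaustive grid maximum of the mixture log-likelihood: alpha, beta on a
# 0.05 lattice (alpha + beta <= 1), kappa on 30 log-spaced values
grid_loglik_max <- function(trials, kappas = exp(seq(log(0.1), log(100),
                                                     length.out = 30))) {
  ab <- expand.grid(alpha = seq(0, 1, 0.05), beta = seq(0, 1, 0.05))
  ab <- ab[ab$alpha + ab$beta <= 1 + 1e-12, ]
  if (trials$m == 0) ab <- ab[ab$beta == 0, ]
  gam <- pmax(0, 1 - ab$alpha - ab$beta)   # guard lattice rounding
  dev <- cbind(wrap_angle(trials$response - trials$target),
               if (trials$m > 0) wrap_angle(trials$response - trials$nontargets))
  best <- -Inf
  for (k in kappas) {
    dens <- exp(k * (cos(dev) - 1)) / (2 * pi * besselI(k, 0, expon.scaled = TRUE))
    dt <- dens[, 1]
    db <- if (trials$m > 0) rowMeans(dens[, -1, drop = FALSE]) else 0
    ll <- colSums(log(outer(dt, ab$alpha) + outer(db, ab$beta) +
                        matrix(gam / (2 * pi),
                               nrow = trials$n, ncol = nrow(ab), byrow = TRUE)))
    best <- max(best, max(ll))
  }
  best
}

# simulate a trial set from known mixture parameters over uniform arrays
simulate_trials <- function(n, alpha, beta, kappa, m = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tg <- runif(n, -pi, pi)
  nt <- if (m > 0) matrix(runif(n * m, -pi, pi), n) else NULL
  p <- mixture_params(alpha, beta, kappa = kappa)
  vwm_trials(simulate_responses(p, tg, nt), tg, nt)
}
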