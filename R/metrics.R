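#' Recall error
#'
#' Angular deviation between the reported and true target feature value,
#' wrapped onto \eqn{(-\pi, \pi]}.
#'
#' @param response,target Angles in radians (vectors of equal length).
#' @return Wrapped errors in radians.
#' @export
recall_error <- function(response, target) {
  wrap_angle(response - target)
}

#' Monte-Carlo chance level for recall precision
#'
#' The expected value of 1 / circular SD for a sample of `n` responses drawn
#' uniformly on the circle: what an observer responding at random would score.
#' Depends only on the sample size, so the value can be cached and reused
#' across subjects with equal trial counts.
#'
#' @param n Sample size the chance level is conditioned on.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param seed Optional integer seed.
#' @return Chance level in 1/radians.
#' @export
chance_precision_level <- function(n, n_reps = 1e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- 0
  done <- 0L
  chunk <- max(1L, floor(2e6 / n))
  while (done < n_reps) {
    k <- min(chunk, n_reps - done)
    u <- matrix(stats::runif(n * k, -pi, pi), nrow = n)
    rbar <- sqrt(colMeans(cos(u))^2 + colMeans(sin(u))^2)
    sdv <- sqrt(-2 * log(rbar))
    total <- total + sum(1 / sdv)
    done <- done + k
  }
  total / n_reps
}

#' Chance-corrected recall precision
#'
#' Precision is the reciprocal of the circular standard deviation of recall
#' error, minus the value expected by chance for the same number of trials
#' (Monte-Carlo estimate, see [chance_precision_level()]). Zero therefore
#' indicates chance performance. A zero-dispersion sample (all errors equal)
#' would give infinite raw precision; it is reported as a large finite cap
#' (1000 per radian) with `saturated = TRUE` so cohort regressions remain
#' defined.
#'
#' @param errors Wrapped recall errors, radians (at least 2).
#' @param n_chance_reps Monte-Carlo replicates for the chance level.
#' @param seed Optional integer seed for the chance simulation.
#' @param chance_level Optionally, a precomputed chance level for
#'   `length(errors)` trials (bypasses the Monte-Carlo step).
#' @return A list of class `precision_estimate`: `precision` (1/radians,
#'   chance-corrected), `raw` (uncorrected 1/SD), `chance_level`, `n_trials`,
#'   `saturated`.
#' @export
precision <- function(errors, n_chance_reps = 1e4, seed = NULL,
                      chance_level = NULL) {
  if (length(errors) < 2)
    stop("insufficient-data: precision requires at least 2 errors")
  sdv <- circ_sd(errors)
  saturated <- sdv == 0
  raw <- if (saturated) 1000 else 1 / sdv
  if (is.null(chance_level))
    chance_level <- chance_precision_level(length(errors), n_chance_reps, seed)
  structure(list(precision = raw - chance_level, raw = raw,
                 chance_level = chance_level, n_trials = length(errors),
                 saturated = saturated),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("<precision_estimate> %.3f /rad (raw %.3f, chance %.3f, n=%d%s)\n",
              x$precision, x$raw, x$chance_level, x$n_trials,
              if (x$saturated) ", saturated" else ""))
  invisible(x)
}

#' Root-mean-square deviation of responses from nontarget features
#'
#' Model-free index of misbinding: the r.m.s. of the wrapped deviation between
#' each response and each nontarget feature value. If responses are generated
#' only from the target and/or at random, deviations from nontargets are
#' uniform and the expectation is \eqn{\pi/\sqrt 3 \approx 1.814} rad; genuine
#' nontarget responses pull the value below that.
#'
#' @param trials A [vwm_trials()] object with `m >= 1`.
#' @return RMS deviation in radians.
#' @export
nontarget_rms_deviation <- function(trials) {
  stopifnot(inherits(trials, "vwm_trials"))
  if (trials$m < 1)
    stop("no-nontargets: trials must have at least one nontarget")
  dev <- wrap_angle(trials$response - trials$nontargets)
  sqrt(mean(dev^2))
}

#' Test per-subject nontarget RMS deviations against chance
#'
#' One-sample t test of subject-level RMS deviations against the value
#' expected when responses are unrelated to nontargets,
#' \eqn{\pi/\sqrt 3}. A significantly lower mean indicates that nontarget
#' features contributed to responses (misbinding).
#'
#' @param per_subject_rms Numeric vector of per-subject RMS deviations
#'   (radians), at least 3 subjects.
#' @return A list: `t`, `df`, `p` (two-sided), `mean_rms`, `chance`.
#' @export
chance_rms_test <- function(per_subject_rms) {
  if (length(per_subject_rms) < 3)
    stop("insufficient-data: need at least 3 subjects")
  chance <- pi / sqrt(3)
  n <- length(per_subject_rms)
  if (stats::sd(per_subject_rms) == 0) {
    # degenerate: identical subjects; at the chance value t is 0 by definition
    dev <- mean(per_subject_rms) - chance
    tval <- if (dev == 0) 0 else sign(dev) * Inf
    return(list(t = tval, df = n - 1,
                p = if (dev == 0) 1 else 0,
                mean_rms = mean(per_subject_rms), chance = chance))
  }
  tt <- stats::t.test(per_subject_rms, mu = chance)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_rms = mean(per_subject_rms), chance = chance)
}

#' Cross-feature correlation of error magnitudes
#'
#' Pearson correlation, across trials, of the absolute wrapped recall error
#' in one feature dimension with that in the other. Independence of the two
#' feature memories predicts zero.
#'
#' @param errors_dim1,errors_dim2 Wrapped errors in the two dimensions,
#'   paired by trial (equal length, n >= 3).
#' @return Pearson correlation coefficient.
#' @export
error_magnitude_correlation <- function(errors_dim1, errors_dim2) {
  if (length(errors_dim1) != length(errors_dim2))
    stop("unpaired-data: dimensions must have equal trial counts")
  if (length(errors_dim1) < 3)
    stop("insufficient-data: need at least 3 paired trials")
  stats::cor(abs(wrap_angle(errors_dim1)), abs(wrap_angle(errors_dim2)))
}

#' Cross-feature correlation of nontarget deviations
#'
#' The misbinding analogue of [error_magnitude_correlation()]: for every
#' trial and every nontarget item, the absolute wrapped deviation of the
#' response from that item's feature value is computed in each dimension;
#' deviations are paired by item (the nontargets correspond across
#' dimensions, being features of the same array objects) and Pearson
#' correlated over all trial-by-item pairs. If misreports strike the same
#' item in both dimensions, both deviations are small together and the
#' correlation is positive; independent misreports predict zero.
#'
#' @param response1,response2 Responses in the two dimensions, paired by
#'   trial.
#' @param nontargets1,nontargets2 n x m matrices of nontarget values in the
#'   two dimensions, columns paired by item.
#' @return Pearson correlation over the n x m deviation pairs.
#' @export
nontarget_dev_correlation <- function(response1, nontargets1,
                                      response2, nontargets2) {
  d1 <- abs(wrap_angle(response1 - nontargets1))
  d2 <- abs(wrap_angle(response2 - nontargets2))
  if (!all(dim(d1) == dim(d2))) stop("unpaired-data")
  stats::cor(as.vector(d1), as.vector(d2))
}

#' Expected nontarget-deviation correlation under full co-occurrence
#'
#' Benchmark for the joint-error analysis: the correlation between the two
#' dimensions' deviation-from-nontarget magnitudes that would be expected if
#' misbinding errors in the two feature dimensions always occurred together.
#' Component indicators are maximally coupled — one shared latent draw per
#' trial, so both dimensions misreport simultaneously with probability
#' min(beta1, beta2) while each dimension keeps its fitted marginal rate —
#' and when both misreport they use the same nontarget index. Estimated by
#' Monte Carlo with the fitted kappa of each dimension.
#'
#' @param fit_dim1,fit_dim2 `mixture_fit` objects for the two dimensions.
#' @param m Number of nontargets per trial (>= 1).
#' @param n_sim Number of simulated trials.
#' @param seed Optional integer seed.
#' @return The [nontarget_dev_correlation()] of the simulated cohort.
#' @export
expected_cooccurrence_correlation <- function(fit_dim1, fit_dim2, m = 2,
                                              n_sim = 1e4, seed = NULL) {
  if (m < 1) stop("invalid-design: m must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p1 <- fit_dim1$params; p2 <- fit_dim2$params
  # feature values, independent per dimension
  t1 <- stats::runif(n_sim, -pi, pi); t2 <- stats::runif(n_sim, -pi, pi)
  nt1 <- matrix(stats::runif(n_sim * m, -pi, pi), n_sim)
  nt2 <- matrix(stats::runif(n_sim * m, -pi, pi), n_sim)
  # one shared uniform draw per trial: dimension d misreports iff u < beta_d,
  # reports the target iff u in [beta_d, beta_d + alpha_d), else guesses --
  # marginals preserved, misreports coupled at min(beta1, beta2)
  u <- stats::runif(n_sim)
  pick <- sample.int(m, n_sim, replace = TRUE)
  sim_dim <- function(p, tg, nt, kappa) {
    comp <- ifelse(u < p$beta, "nontarget",
                   ifelse(u < p$beta + p$alpha, "target", "uniform"))
    centre <- tg
    idx <- comp == "nontarget"
    centre[idx] <- nt[cbind(which(idx), pick[idx])]
    resp <- wrap_angle(centre + sample_vm(n_sim, 0, kappa))
    idx_u <- comp == "uniform"
    resp[idx_u] <- wrap_angle(stats::runif(sum(idx_u), -pi, pi))
    resp
  }
  r1 <- sim_dim(p1, t1, nt1, p1$kappa)
  r2 <- sim_dim(p2, t2, nt2, p2$kappa)
  nontarget_dev_correlation(r1, nt1, r2, nt2)
}
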