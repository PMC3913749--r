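#' Three-component mixture parameters
#'
#' The generative model of a continuous-report response: with probability
#' `alpha` the response is von Mises-distributed (concentration `kappa`)
#' around the target feature value; with probability `beta` around one of the
#' m nontarget values (each equally likely) — a misbinding / swap response;
#' with probability `gamma = 1 - alpha - beta` it is uniform on the circle
#' (random guessing). A single `kappa` is shared between the target and
#' nontarget components.
#'
#' @param alpha Probability of reporting the target, in `[0, 1]`.
#' @param beta Probability of reporting a nontarget, in `[0, 1]`.
#' @param kappa von Mises concentration, `kappa >= 0`.
#' @return An object of class `mixture_params` with fields `alpha`, `beta`,
#'   `gamma`, `kappa`.
#' @export
mixture_params <- function(alpha, beta = 0, kappa) {
  if (any(c(alpha, beta) < -1e-12) || any(c(alpha, beta) > 1 + 1e-12))
    stop("invalid-model: alpha and beta must lie in [0, 1]")
  if (alpha + beta > 1 + 1e-9)
    stop("invalid-model: alpha + beta must not exceed 1")
  if (kappa < 0) stop("invalid-concentration: kappa must be non-negative")
  alpha <- min(max(alpha, 0), 1)
  beta <- min(max(beta, 0), 1)
  structure(list(alpha = alpha, beta = beta,
                 gamma = 1 - alpha - beta, kappa = kappa),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf(
    "<mixture_params> alpha=%.3f beta=%.3f gamma=%.3f kappa=%.3f (sigma=%.3f rad)\n",
    x$alpha, x$beta, x$gamma, x$kappa, kappa_to_sd(x$kappa)))
  invisible(x)
}

check_params_for_trials <- function(params, trials) {
  if (trials$m == 0 && params$beta > 0)
    stop("invalid-model: beta > 0 with no nontargets (m = 0)")
  if (trials$m > 8) stop("invalid-design: at most 8 nontargets supported")
  invisible(TRUE)
}

#' Mixture log-likelihood
#'
#' Sum over trials of the log of
#' \eqn{\alpha \phi_\kappa(\hat\theta - \theta) +
#'      (\beta/m) \sum_i \phi_\kappa(\hat\theta - \varphi_i) + \gamma/(2\pi)}.
#'
#' @param params A [mixture_params()] object.
#' @param trials A [vwm_trials()] object.
#' @return Log-likelihood in nats.
#' @export
mixture_loglik <- function(params, trials) {
  check_params_for_trials(params, trials)
  dev <- trial_deviations(trials)
  dt <- vm_pdf(dev[, 1], 0, params$kappa)
  lik <- params$alpha * dt + params$gamma / (2 * pi)
  if (trials$m > 0) {
    for (j in seq_len(trials$m))
      lik <- lik + (params$beta / trials$m) * vm_pdf(dev[, j + 1], 0, params$kappa)
  }
  sum(log(lik))
}

#' Posterior component responsibilities
#'
#' The E-step quantities of the EM fit: the posterior probability that each
#' response was generated by the target component, by each nontarget
#' component, or by the uniform component.
#'
#' @inheritParams mixture_loglik
#' @return An n x (m + 2) matrix with columns `target`, `nontarget1..m`,
#'   `uniform`; rows sum to 1.
#' @export
responsibilities <- function(params, trials) {
  check_params_for_trials(params, trials)
  dev <- trial_deviations(trials)
  w <- matrix(0, trials$n, trials$m + 2)
  w[, 1] <- params$alpha * vm_pdf(dev[, 1], 0, params$kappa)
  if (trials$m > 0)
    for (j in seq_len(trials$m))
      w[, j + 1] <- (params$beta / trials$m) * vm_pdf(dev[, j + 1], 0, params$kappa)
  w[, trials$m + 2] <- params$gamma / (2 * pi)
  r <- w / rowSums(w)
  colnames(r) <- c("target",
                   if (trials$m > 0) paste0("nontarget", seq_len(trials$m)),
                   "uniform")
  r
}

# default multi-start grid; the alpha=0.9 x beta=0.2 cells are infeasible
# (sum > 1) so beta is clipped to half the remaining mass there
em_start_grid <- function(m) {
  if (m > 0) {
    g <- expand.grid(alpha = c(0.3, 0.6, 0.9), beta = c(0, 0.2),
                     kappa = c(1, 4, 16))
    over <- g$alpha + g$beta >= 1
    g$beta[over] <- (1 - g$alpha[over]) / 2
  } else {
    g <- expand.grid(alpha = c(0.3, 0.6, 0.9), beta = 0, kappa = c(1, 4, 16))
  }
  as.matrix(g)
}

#' Fit the mixture model by multi-start EM
#'
#' Maximum-likelihood estimation of (`alpha`, `beta`, `gamma`, `kappa`) by
#' expectation-maximization, restarted from a fixed grid of initial values
#' (plus random extra starts if requested) to guard against local maxima.
#' Within each start the log-likelihood is non-decreasing across iterations;
#' the best start wins, ties broken by lowest start index. With m = 0
#' (low-load trials) the nontarget component is structurally absent and
#' `beta` is fixed at 0.
#'
#' @param trials A [vwm_trials()] object. Fewer than 20 trials triggers a
#'   warning (estimates will be unstable).
#' @param n_starts Number of EM starts. Up to the grid size (18 for m > 0,
#'   9 for m = 0) starts are taken from the deterministic grid, any excess
#'   drawn at random.
#' @param tol Convergence tolerance: stop when the log-likelihood improves by
#'   less than `tol` nats.
#' @param max_iter Iteration cap per start.
#' @param seed Optional integer seed (used only for random extra starts).
#' @param trace If `TRUE`, keep the per-iteration log-likelihood sequence of
#'   every start (for diagnostics).
#' @return An object of class `mixture_fit`: `params` ([mixture_params()]),
#'   `sigma` (circular SD implied by the fitted `kappa`), `log_likelihood`,
#'   `n_iterations`, `converged`, `n_starts`, `n_trials`, and `trace` when
#'   requested.
#' @export
fit_vm_mixture <- function(trials, n_starts = NULL, tol = 1e-6,
                           max_iter = 1e4, seed = NULL, trace = FALSE) {
  stopifnot(inherits(trials, "vwm_trials"))
  if (trials$m > 8) stop("invalid-design: at most 8 nontargets supported")
  if (trials$n < 20)
    warning(sprintf("only %d trials: mixture estimates may be unstable", trials$n))
  grid <- em_start_grid(trials$m)
  if (is.null(n_starts)) n_starts <- nrow(grid)
  if (n_starts < 1) stop("n_starts must be >= 1")
  starts <- grid[seq_len(min(n_starts, nrow(grid))), , drop = FALSE]
  if (n_starts > nrow(grid)) {
    if (!is.null(seed)) set.seed(seed)
    extra <- n_starts - nrow(grid)
    a0 <- stats::runif(extra)
    b0 <- if (trials$m > 0) stats::runif(extra, 0, 1 - a0) else rep(0, extra)
    k0 <- exp(stats::runif(extra, log(0.5), log(50)))
    starts <- rbind(starts, cbind(alpha = a0, beta = b0, kappa = k0))
  }
  dev <- trial_deviations(trials)
  res <- .em_fit_core(dev, starts, tol, as.integer(max_iter), trace)
  params <- mixture_params(res$alpha, res$beta, res$kappa)
  structure(list(
    params = params,
    sigma = kappa_to_sd(res$kappa),
    log_likelihood = res$log_likelihood,
    n_iterations = res$n_iterations,
    converged = res$converged,
    start_index = res$start_index,
    n_starts = res$n_starts,
    n_trials = trials$n,
    m = trials$m,
    trace = if (trace) res$trace else NULL
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<mixture_fit> n=%d m=%d  alpha=%.3f beta=%.3f gamma=%.3f ",
           "kappa=%.2f sigma=%.3f  logLik=%.2f  %s (%d iter, %d starts)\n"),
    x$n_trials, x$m, x$params$alpha, x$params$beta, x$params$gamma,
    x$params$kappa, x$sigma, x$log_likelihood,
    if (x$converged) "converged" else "NOT converged",
    x$n_iterations, x$n_starts))
  invisible(x)
}

#' Flatten a mixture fit to a one-row data frame
#'
#' @param fit A `mixture_fit` object.
#' @param ... Named scalar annotations (e.g. subject id, dimension, load)
#'   prepended as columns.
#' @return A one-row `data.frame`.
#' @export
fit_as_row <- function(fit, ...) {
  ann <- list(...)
  data.frame(c(ann, list(
    alpha = fit$params$alpha, beta = fit$params$beta,
    gamma = fit$params$gamma, kappa = fit$params$kappa,
    sigma = fit$sigma, log_likelihood = fit$log_likelihood,
    converged = fit$converged)), stringsAsFactors = FALSE)
}

#' Simulate responses from the mixture model
#'
#' Inverse of the fit: for each trial, choose a component with probabilities
#' (`alpha`, `beta`, `gamma`); target and nontarget responses are von Mises
#' around the chosen feature value with concentration `kappa` (the nontarget
#' drawn uniformly among the m); uniform responses are uniform on the circle.
#'
#' @param params A [mixture_params()] object; `beta` must be 0 when
#'   `nontargets` is `NULL`.
#' @param targets Vector of target feature values, radians.
#' @param nontargets `NULL` or an n x m matrix of nontarget values.
#' @param seed Optional integer seed.
#' @param return_components If `TRUE`, also return the latent component label
#'   of each trial (`"target"`, `"nontarget"`, `"uniform"`).
#' @return A vector of wrapped responses, or a list `(response, component)`.
#' @export
simulate_responses <- function(params, targets, nontargets = NULL,
                               seed = NULL, return_components = FALSE) {
  stopifnot(inherits(params, "mixture_params"))
  n <- length(targets)
  m <- if (is.null(nontargets)) 0L else ncol(as.matrix(nontargets))
  if (m == 0 && params$beta > 0)
    stop("invalid-model: beta > 0 with no nontargets")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  comp <- ifelse(u < params$alpha, "target",
                 ifelse(u < params$alpha + params$beta, "nontarget", "uniform"))
  centre <- wrap_angle(targets)
  if (m > 0) {
    nt <- as.matrix(nontargets)
    pick <- sample.int(m, n, replace = TRUE)
    idx <- comp == "nontarget"
    centre[idx] <- nt[cbind(which(idx), pick[idx])]
  }
  noise <- sample_vm(n, mu = 0, kappa = max(params$kappa, 0))
  resp <- wrap_angle(centre + noise)
  idx_u <- comp == "uniform"
  resp[idx_u] <- wrap_angle(stats::runif(sum(idx_u), -pi, pi))
  if (return_components) list(response = resp, component = comp) else resp
}
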