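#' Construct a set of continuous-report trials
#'
#' One record per trial in a single feature dimension: the reported value
#' (response), the true target value, and the feature values of the m
#' nontarget items in the memory array. All trials in a set share the same m:
#' m = 0 for low-load (single item) trials, m = 2 for the three-item high-load
#' condition. All angles are wrapped onto \eqn{(-\pi, \pi]} on construction.
#'
#' @param response Numeric vector of reported feature values, radians.
#' @param target Numeric vector of true target values, radians.
#' @param nontargets `NULL` (m = 0) or an n x m numeric matrix of nontarget
#'   feature values, radians.
#' @return An object of class `vwm_trials`: a list with elements `response`,
#'   `target`, `nontargets` (matrix or `NULL`), `n`, `m`.
#' @export
vwm_trials <- function(response, target, nontargets = NULL) {
  n <- length(response)
  if (length(target) != n)
    stop("response and target must have equal length")
  response <- wrap_angle(response)
  target <- wrap_angle(target)
  m <- 0L
  if (!is.null(nontargets)) {
    nontargets <- as.matrix(nontargets)
    if (nrow(nontargets) != n)
      stop("heterogeneous-trials: nontargets must have one row per trial")
    if (ncol(nontargets) > 0) {
      nontargets <- wrap_angle(nontargets)
      dim(nontargets) <- c(n, length(nontargets) / n)
      m <- ncol(nontargets)
    } else {
      nontargets <- NULL
    }
  }
  structure(list(response = response, target = target,
                 nontargets = nontargets, n = n, m = m),
            class = "vwm_trials")
}

#' @export
print.vwm_trials <- function(x, ...) {
  cat(sprintf("<vwm_trials> %d trials, %d nontarget(s) per trial\n", x$n, x$m))
  invisible(x)
}

#' @export
length.vwm_trials <- function(x) x$n

# deviations of the response from target and each nontarget: n x (1 + m)
trial_deviations <- function(trials) {
  d <- wrap_angle(trials$response - trials$target)
  if (trials$m > 0) {
    dn <- wrap_angle(trials$response - trials$nontargets)
    dim(dn) <- c(trials$n, trials$m)
    d <- cbind(d, dn)
  } else {
    d <- matrix(d, ncol = 1)
  }
  d
}
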