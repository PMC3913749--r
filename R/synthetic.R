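#' Generate one memory array
#'
#' Feature values for a single trial: `load` items per feature dimension,
#' each value drawn independently and uniformly on the circle, with one item
#' designated target uniformly at random (the same item index across
#' dimensions, as a location probe selects a whole object).
#'
#' @param load Number of items, 1 (low load) or 3 (high load).
#' @param dimensions Character vector naming the feature dimensions.
#' @return A list per dimension with elements `target` (scalar) and
#'   `nontargets` (numeric vector, length `load - 1`), plus `target_index`.
#' @export
generate_array <- function(load, dimensions = c("orientation", "colour")) {
  if (!load %in% c(1, 3))
    stop("invalid-design: load must be 1 or 3")
  ti <- sample.int(load, 1)
  out <- lapply(dimensions, function(d) {
    vals <- wrap_angle(stats::runif(load, -pi, pi))
    list(target = vals[ti], nontargets = vals[-ti])
  })
  names(out) <- dimensions
  c(out, list(target_index = ti))
}

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Cohort specification for the synthetic generator
#'
#' Describes a synthetic aging cohort with the study's design: two memory
#' loads (1 and 3 items), two feature dimensions per trial, two
#' between-subject exposure groups (2 s vs 200 ms) matched for age, 25
#' low-load and 175 high-load trials per subject, ages spread evenly over
#' 19-77 years. Per-subject mixture parameters are drawn from linear age
#' maps: by default the circular SD sigma and the misreport rate beta
#' increase with age while the uniform rate gamma is flat, and brief (200 ms)
#' exposure multiplies sigma and adds to high-load gamma, leaving beta
#' untouched.
#'
#' `age_maps` is a named list per (load, dimension) cell, each holding
#' `sigma = c(intercept, slope)`, `beta = c(intercept, slope)` (high load
#' only), `gamma = c(intercept, slope)`; intercepts apply at age 19 and
#' slopes are per year. `noise` holds between-subject SDs around those maps.
#'
#' @param n_subjects Number of subjects.
#' @param trials_low,trials_high Trials per subject in the 1-item and 3-item
#'   conditions.
#' @param age_range Age span, years.
#' @param age_maps Linear age-to-parameter maps (see Details); `NULL` for the
#'   defaults described above.
#' @param noise Between-subject parameter noise SDs
#'   (`sigma`, `beta`, `gamma`).
#' @param exposure_sigma_mult Multiplier on sigma in the 200 ms group.
#' @param exposure_gamma_add Additive increment on high-load gamma in the
#'   200 ms group.
#' @param coupling Probability in `[0, 1]` that the two dimensions share
#'   their latent component indicator (and nontarget index) on a trial;
#'   0 = fully independent dimensions.
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 60, trials_low = 25, trials_high = 175,
                        age_range = c(19, 77), age_maps = NULL,
                        noise = c(sigma = 0.13, beta = 0.02, gamma = 0.03),
                        exposure_sigma_mult = 1.25,
                        exposure_gamma_add = 0.05,
                        coupling = 0, seed = 1L) {
  if (is.null(age_maps)) age_maps <- default_age_maps()
  structure(list(n_subjects = n_subjects, trials_low = trials_low,
                 trials_high = trials_high, age_range = age_range,
                 age_maps = age_maps, noise = noise,
                 exposure_sigma_mult = exposure_sigma_mult,
                 exposure_gamma_add = exposure_gamma_add,
                 coupling = coupling, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_age_maps <- function() {
  list(
    high = list(
      orientation = list(sigma = c(0.38, 0.0045), beta = c(0.04, 0.0026),
                         gamma = c(0.08, 0)),
      colour = list(sigma = c(0.42, 0.004), beta = c(0.01, 0.0006),
                    gamma = c(0.08, 0))),
    low = list(
      orientation = list(sigma = c(0.28, 0.0025), beta = c(0, 0),
                         gamma = c(0.05, 0)),
      colour = list(sigma = c(0.30, 0.0025), beta = c(0, 0),
                    gamma = c(0.05, 0)))
  )
}

# per-subject mixture parameters for one (load, dimension) cell
draw_cell_params <- function(map, age, age0, noise, exposure,
                             sigma_mult, gamma_add, load) {
  a <- age - age0
  sigma <- map$sigma[1] + map$sigma[2] * a + stats::rnorm(1, 0, noise["sigma"])
  beta <- if (load == 1) 0 else
    clip01(map$beta[1] + map$beta[2] * a + stats::rnorm(1, 0, noise["beta"]))
  gamma <- clip01(map$gamma[1] + map$gamma[2] * a +
                    stats::rnorm(1, 0, noise["gamma"]), lo = 0.01)
  if (exposure == 200) {
    sigma <- sigma * sigma_mult
    if (load == 3) gamma <- clip01(gamma + gamma_add, lo = 0.01)
  }
  sigma <- max(sigma, 0.12)
  if (beta + gamma > 0.95) { # keep a valid simplex with alpha >= 0.05
    sc <- 0.95 / (beta + gamma)
    beta <- beta * sc; gamma <- gamma * sc
  }
  mixture_params(alpha = 1 - beta - gamma, beta = beta,
                 kappa = sd_to_kappa(sigma))
}

#' Generate the trial rows for one subject
#'
#' Composes [generate_array()] with [simulate_responses()]: every trial draws
#' fresh uniform feature values, the response in each (dimension x load) cell
#' follows that cell's mixture parameters, and with probability `coupling`
#' the two dimensions share their latent component (and nontarget index) on
#' a trial.
#'
#' @param subject_id Identifier copied into every row.
#' @param age,exposure Covariates copied into every row.
#' @param cell_params Nested list `[[load]][[dimension]]` of
#'   [mixture_params()], loads `"low"` and `"high"`.
#' @param trials_low,trials_high Trial counts.
#' @param coupling Cross-dimension component coupling in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A `data.frame`, one row per trial x dimension, with columns
#'   `subject_id, age, exposure, load, trial, dimension, target, nontarget1,
#'   nontarget2, response` (nontargets `NA` at load 1).
#' @export
generate_subject <- function(subject_id, age, exposure, cell_params,
                             trials_low = 25, trials_high = 175,
                             coupling = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- c("orientation", "colour")
  rows <- list()
  for (load_name in c("low", "high")) {
    load <- if (load_name == "low") 1L else 3L
    n <- if (load_name == "low") trials_low else trials_high
    m <- load - 1L
    tg <- matrix(NA_real_, n, 2, dimnames = list(NULL, dims))
    nt <- array(NA_real_, c(n, 2, 2), dimnames = list(NULL, dims, NULL))
    for (i in seq_len(n)) {
      arr <- generate_array(load, dims)
      for (d in dims) {
        tg[i, d] <- arr[[d]]$target
        if (m > 0) nt[i, d, ] <- arr[[d]]$nontargets
      }
    }
    # latent components: shared across dimensions with probability `coupling`
    share <- stats::runif(n) < coupling
    u_shared <- stats::runif(n)
    pick_shared <- if (m > 0) sample.int(m, n, replace = TRUE) else rep(1L, n)
    resp <- matrix(NA_real_, n, 2, dimnames = list(NULL, dims))
    for (d in dims) {
      p <- cell_params[[load_name]][[d]]
      u <- ifelse(share, u_shared, stats::runif(n))
      comp <- ifelse(u < p$beta, "nontarget",
                     ifelse(u < p$beta + p$alpha, "target", "uniform"))
      centre <- tg[, d]
      if (m > 0) {
        pick <- ifelse(share, pick_shared, sample.int(m, n, replace = TRUE))
        idx <- comp == "nontarget"
        centre[idx] <- nt[cbind(which(idx), match(d, dims), pick[idx])]
      }
      r <- wrap_angle(centre + sample_vm(n, 0, p$kappa))
      idx_u <- comp == "uniform"
      r[idx_u] <- wrap_angle(stats::runif(sum(idx_u), -pi, pi))
      resp[, d] <- r
    }
    for (d in dims) {
      rows[[paste(load_name, d)]] <- data.frame(
        subject_id = subject_id, age = age, exposure = exposure,
        load = load, trial = seq_len(n), dimension = d,
        target = tg[, d],
        nontarget1 = if (m > 0) nt[, d, 1] else NA_real_,
        nontarget2 = if (m > 0) nt[, d, 2] else NA_real_,
        response = resp[, d], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic cohort
#'
#' Ages are spread evenly over the age range; exposure groups (2000 ms vs
#' 200 ms) are assigned alternately along the age ranking so their age
#' distributions match. Per-subject mixture parameters are drawn from the
#' spec's linear age maps plus between-subject noise; span scores are
#' generated with a negative age trend and a positive education trend.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `vwm_cohort`: `trials` (trial table
#'   `data.frame`), `subjects` (covariates plus the true generating
#'   parameters per cell, one row per subject), `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  ages <- round(seq(spec$age_range[1], spec$age_range[2], length.out = n) +
                  stats::runif(n, -0.5, 0.5), 1)
  ages <- pmin(pmax(ages, spec$age_range[1]), spec$age_range[2])
  # alternate exposure assignment along the age ranking -> matched age dists
  exposure <- ifelse(seq_len(n) %% 2 == 1, 2000, 200)
  # education declines modestly across birth cohorts; span scores rise with
  # education and carry only a weak direct age effect, so the span-age
  # association is largely mediated by education (directional structure only)
  education <- round(clip01(
    stats::rnorm(n, 17 - 0.06 * (ages - 19), 2.5), 8, 24))
  span_total <- round(clip01(
    24 + 0.8 * (education - 15) - 0.03 * (ages - 19) + stats::rnorm(n, 0, 2.2),
    10, 40))
  subj_rows <- vector("list", n)
  trial_rows <- vector("list", n)
  for (i in seq_len(n)) {
    cell_params <- list(
      low = list(
        orientation = draw_cell_params(spec$age_maps$low$orientation, ages[i],
                                       spec$age_range[1], spec$noise,
                                       exposure[i], spec$exposure_sigma_mult,
                                       spec$exposure_gamma_add, 1),
        colour = draw_cell_params(spec$age_maps$low$colour, ages[i],
                                  spec$age_range[1], spec$noise, exposure[i],
                                  spec$exposure_sigma_mult,
                                  spec$exposure_gamma_add, 1)),
      high = list(
        orientation = draw_cell_params(spec$age_maps$high$orientation, ages[i],
                                       spec$age_range[1], spec$noise,
                                       exposure[i], spec$exposure_sigma_mult,
                                       spec$exposure_gamma_add, 3),
        colour = draw_cell_params(spec$age_maps$high$colour, ages[i],
                                  spec$age_range[1], spec$noise, exposure[i],
                                  spec$exposure_sigma_mult,
                                  spec$exposure_gamma_add, 3)))
    sid <- sprintf("S%03d", i)
    trial_rows[[i]] <- generate_subject(
      sid, ages[i], exposure[i], cell_params,
      trials_low = spec$trials_low, trials_high = spec$trials_high,
      coupling = spec$coupling)
    flat <- unlist(lapply(c("low", "high"), function(l)
      lapply(c("orientation", "colour"), function(d) {
        p <- cell_params[[l]][[d]]
        stats::setNames(c(p$alpha, p$beta, p$gamma, kappa_to_sd(p$kappa)),
                        paste("true", l, d, c("alpha", "beta", "gamma", "sigma"),
                              sep = "_"))
      })))
    subj_rows[[i]] <- data.frame(
      subject_id = sid, age = ages[i], exposure = exposure[i],
      education_years = education[i], span_total = span_total[i],
      as.list(flat), stringsAsFactors = FALSE)
  }
  structure(list(trials = do.call(rbind, trial_rows),
                 subjects = do.call(rbind, subj_rows),
                 spec = spec),
            class = "vwm_cohort")
}

#' @export
print.vwm_cohort <- function(x, ...) {
  cat(sprintf("<vwm_cohort> %d subjects, %d trial rows (seed %d)\n",
              nrow(x$subjects), nrow(x$trials), x$spec$seed))
  invisible(x)
}

#' Extract one subject's cell of trials
#'
#' @param trials Trial table (as produced by [generate_cohort()]).
#' @param subject_id,load,dimension Cell selectors.
#' @return A [vwm_trials()] object.
#' @export
trials_for_cell <- function(trials, subject_id, load, dimension) {
  sel <- trials$subject_id == subject_id & trials$load == load &
    trials$dimension == dimension
  tt <- trials[sel, , drop = FALSE]
  if (load == 1)
    vwm_trials(tt$response, tt$target)
  else
    vwm_trials(tt$response, tt$target, cbind(tt$nontarget1, tt$nontarget2))
}
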