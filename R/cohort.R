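#' Fit every subject x dimension x load cell of a cohort
#'
#' Runs the mixture fit and the descriptive metrics for each cell of a trial
#' table: mixture parameters (alpha, beta, gamma, kappa, sigma),
#' chance-corrected precision (the Monte-Carlo chance level is conditioned
#' on the cell's trial count and cached per unique count), and, for
#' multi-item cells, the RMS deviation of responses from nontargets.
#'
#' @param trials Trial table `data.frame` (columns as produced by
#'   [generate_cohort()] / [read_trial_table()]).
#' @param subjects Optional subject covariate table merged into the output
#'   by `subject_id`.
#' @param n_starts,tol,max_iter EM settings, see [fit_vm_mixture()].
#' @param n_chance_reps Monte-Carlo replicates for the precision chance
#'   level.
#' @param seed Integer seed for the chance simulation.
#' @return A `data.frame`, one row per subject x dimension x load, with the
#'   fitted parameters, `precision`, `chance_level`, `rms_nontarget_dev`
#'   (`NA` at load 1), `n_trials`, `converged`, plus any covariates.
#' @export
fit_cohort <- function(trials, subjects = NULL, n_starts = NULL, tol = 1e-6,
                       max_iter = 1e4, n_chance_reps = 1e4, seed = 100) {
  set.seed(seed)
  chance_cache <- new.env(parent = emptyenv())
  chance_for <- function(n) {
    key <- as.character(n)
    if (is.null(chance_cache[[key]]))
      chance_cache[[key]] <- chance_precision_level(n, n_chance_reps)
    chance_cache[[key]]
  }
  cells <- unique(trials[, c("subject_id", "dimension", "load")])
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sid <- cells$subject_id[i]; dm <- cells$dimension[i]; ld <- cells$load[i]
    tt <- trials_for_cell(trials, sid, ld, dm)
    fit <- fit_vm_mixture(tt, n_starts = n_starts, tol = tol,
                          max_iter = max_iter)
    err <- recall_error(tt$response, tt$target)
    prec <- precision(err, chance_level = chance_for(tt$n))
    rows[[i]] <- fit_as_row(
      fit, subject_id = sid, dimension = dm, load = ld)
    rows[[i]]$precision <- prec$precision
    rows[[i]]$chance_level <- prec$chance_level
    rows[[i]]$rms_nontarget_dev <-
      if (tt$m > 0) nontarget_rms_deviation(tt) else NA_real_
    rows[[i]]$n_trials <- tt$n
  }
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  if (!is.null(subjects))
    est <- merge(est, subjects, by = "subject_id", sort = FALSE)
  est[order(est$subject_id, est$dimension, est$load), ]
}

# wide per-subject view of one outcome: subject rows, one column per
# dimension x load cell, plus covariates
spread_outcome <- function(estimates, outcome) {
  subj <- unique(estimates[, intersect(
    c("subject_id", "age", "exposure", "education_years", "span_total"),
    names(estimates)), drop = FALSE])
  for (dm in unique(estimates$dimension))
    for (ld in unique(estimates$load)) {
      cell <- estimates[estimates$dimension == dm & estimates$load == ld,
                        c("subject_id", outcome)]
      names(cell)[2] <- paste(outcome, dm, ld, sep = "_")
      subj <- merge(subj, cell, by = "subject_id", sort = FALSE)
    }
  subj
}

#' Cohort-level analysis report
#'
#' The full inferential pipeline over a table of per-subject estimates:
#' per-cell single-pass outlier screening (3 SD), linear regressions of each
#' parameter on age, repeated-measures ANCOVA (load x feature with age as a
#' continuous covariate) for precision and each mixture parameter, the
#' Hotelling-Williams comparison of the age-precision correlation between
#' loads, age-quartile summaries, between-group exposure contrasts, the
#' nonparametric nontarget-deviation test, and (partial) correlations with
#' span scores when present.
#'
#' @param estimates Output of [fit_cohort()] (covariates merged in).
#' @param outlier_k SD multiplier for the outlier screen.
#' @return A list of class `vwm_report`; see the elements `age_regressions`,
#'   `ancova`, `precision_load_comparison`, `quartiles`,
#'   `exposure_contrasts`, `nontarget_deviation`, `span_correlations`,
#'   `outlier_log`, `estimates_screened`.
#' @export
analyze_cohort <- function(estimates, outlier_k = 3) {
  outcomes <- c("precision", "sigma", "alpha", "beta", "gamma")
  est <- estimates
  # outlier screen per outcome x dimension x load cell, across subjects
  log_rows <- list()
  est$.outlier <- FALSE
  for (oc in outcomes) {
    for (dm in unique(est$dimension)) for (ld in unique(est$load)) {
      sel <- which(est$dimension == dm & est$load == ld)
      scr <- remove_outliers(est[[oc]][sel], k = outlier_k)
      bad <- sel[!scr$keep]
      est[[paste0(oc, "_ok")]] <- if (is.null(est[[paste0(oc, "_ok")]]))
        TRUE else est[[paste0(oc, "_ok")]]
      est[[paste0(oc, "_ok")]][bad] <- FALSE
      log_rows[[length(log_rows) + 1]] <- data.frame(
        outcome = oc, dimension = dm, load = ld,
        n = length(sel), n_removed = scr$n_removed,
        stringsAsFactors = FALSE)
    }
  }
  outlier_log <- do.call(rbind, log_rows)
  outlier_log_total <- sum(outlier_log$n_removed) / sum(outlier_log$n)

  # age regressions per outcome x dimension x load (screened values)
  reg_rows <- list()
  for (oc in outcomes) {
    ok <- est[[paste0(oc, "_ok")]]
    for (dm in unique(est$dimension)) for (ld in unique(est$load)) {
      if (oc == "beta" && ld == 1) next     # structurally zero at low load
      sel <- est$dimension == dm & est$load == ld & ok
      r <- regress_on_age(est[[oc]][sel], est$age[sel])
      reg_rows[[length(reg_rows) + 1]] <- data.frame(
        outcome = oc, dimension = dm, load = ld, slope = r$slope,
        r = r$r, p = r$p, n = r$n, stringsAsFactors = FALSE)
    }
  }
  age_regressions <- do.call(rbind, reg_rows)

  # repeated-measures ANCOVA per outcome (load x feature, age covariate)
  anc <- lapply(stats::setNames(nm = c("precision", "sigma", "gamma")),
                function(oc)
                  ancova_age(est, oc, within = c("load", "dimension")))
  anc$beta <- {  # beta exists at high load only: feature as sole within factor
    hi <- est[est$load == max(est$load), , drop = FALSE]
    ancova_age(hi, "beta", within = "dimension")
  }

  # age-precision correlation by load (subject means across dimensions)
  pw <- spread_outcome(est, "precision")
  loads <- sort(unique(est$load))
  prec_low <- rowMeans(pw[, paste("precision", unique(est$dimension),
                                  loads[1], sep = "_"), drop = FALSE])
  prec_high <- rowMeans(pw[, paste("precision", unique(est$dimension),
                                   loads[2], sep = "_"), drop = FALSE])
  cmp <- compare_dependent_correlations(prec_high, prec_low, pw$age)
  precision_load_comparison <- c(cmp, list(
    r_age_high = cmp$r1, r_age_low = cmp$r2))

  # quartile summaries of subject-mean precision and high-load parameters
  subj_level <- data.frame(pw[, c("subject_id", "age")],
                           precision_low = prec_low,
                           precision_high = prec_high)
  hi <- est[est$load == loads[2], , drop = FALSE]
  for (oc in c("sigma", "beta", "gamma")) {
    agg <- stats::aggregate(hi[[oc]], list(subject_id = hi$subject_id), mean)
    names(agg)[2] <- paste0(oc, "_high")
    subj_level <- merge(subj_level, agg, by = "subject_id", sort = FALSE)
  }
  quartiles <- quartile_summary(
    subj_level, c("precision_low", "precision_high",
                  "sigma_high", "beta_high", "gamma_high"))

  # cohort-level age trends of the subject-mean outcomes (both dimensions
  # averaged): the headline statement of the aging signature
  subject_age_trends <- do.call(rbind, lapply(
    c("precision_low", "precision_high", "sigma_high", "beta_high",
      "gamma_high"),
    function(oc) {
      r <- regress_on_age(subj_level[[oc]], subj_level$age)
      data.frame(outcome = oc, slope = r$slope, r = r$r, p = r$p,
                 stringsAsFactors = FALSE)
    }))

  expo <- if (length(unique(est$exposure)) > 1)
    exposure_contrasts(est, c("precision", "sigma", "beta", "gamma"))
  else NULL

  # nonparametric misreport validation on per-subject high-load RMS
  rms <- stats::aggregate(rms_nontarget_dev ~ subject_id + age,
                          data = est[est$load == loads[2], ], FUN = mean)
  nt_dev <- c(chance_rms_test(rms$rms_nontarget_dev),
              list(age_trend = regress_on_age(rms$rms_nontarget_dev, rms$age)))

  span <- NULL
  if ("span_total" %in% names(est)) {
    sl <- merge(subj_level,
                unique(est[, c("subject_id", "education_years", "span_total")]),
                by = "subject_id", sort = FALSE)
    r_age <- stats::cor.test(sl$span_total, sl$age)
    r_edu <- stats::cor.test(sl$span_total, sl$education_years)
    span <- list(
      span_age = list(r = unname(r_age$estimate), p = r_age$p.value),
      span_education = list(r = unname(r_edu$estimate), p = r_edu$p.value),
      span_age_partial_education =
        partial_correlation(sl$span_total, sl$age, sl$education_years),
      span_precision_high =
        stats::cor(sl$span_total, sl$precision_high),
      span_precision_high_partial_age =
        partial_correlation(sl$span_total, sl$precision_high, sl$age),
      span_precision_low = stats::cor(sl$span_total, sl$precision_low))
  }

  structure(list(
    age_regressions = age_regressions,
    subject_age_trends = subject_age_trends,
    ancova = anc,
    precision_load_comparison = precision_load_comparison,
    quartiles = quartiles,
    exposure_contrasts = expo,
    nontarget_deviation = nt_dev,
    span_correlations = span,
    outlier_log = outlier_log,
    outlier_fraction = outlier_log_total,
    estimates_screened = est,
    subject_level = subj_level
  ), class = "vwm_report")
}

#' @export
print.vwm_report <- function(x, ...) {
  cat("<vwm_report>\n")
  cat(sprintf("  age-precision r: high load %.3f, low load %.3f (Williams t(%d)=%.2f, p=%.3g)\n",
              x$precision_load_comparison$r_age_high,
              x$precision_load_comparison$r_age_low,
              x$precision_load_comparison$df,
              x$precision_load_comparison$t,
              x$precision_load_comparison$p))
  cat(sprintf("  nontarget RMS deviation: %.3f rad vs chance %.3f (t(%d)=%.2f, p=%.3g)\n",
              x$nontarget_deviation$mean_rms, x$nontarget_deviation$chance,
              x$nontarget_deviation$df, x$nontarget_deviation$t,
              x$nontarget_deviation$p))
  cat(sprintf("  outliers removed: %.2f%% of estimates\n",
              100 * x$outlier_fraction))
  cat("  elements: ", paste(names(unclass(x)), collapse = ", "), "\n")
  invisible(x)
}
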