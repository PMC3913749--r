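#' Single-pass outlier screen
#'
#' Flags values more than `k` standard deviations from the mean, with mean
#' and SD computed once from the full sample (single pass, not iterated).
#'
#' @param values Numeric vector (>= 3 values).
#' @param k SD multiplier (default 3).
#' @return A list: `keep` (logical mask), `n_removed`, `fraction_removed`.
#' @export
remove_outliers <- function(values, k = 3) {
  if (length(values) < 3) stop("insufficient-data: need at least 3 values")
  mu <- mean(values)
  sdv <- stats::sd(values)
  keep <- if (sdv == 0) rep(TRUE, length(values))
          else abs(values - mu) <= k * sdv
  list(keep = keep, n_removed = sum(!keep),
       fraction_removed = mean(!keep))
}

#' Linear regression of an outcome on age
#'
#' Ordinary least squares of `values` on `ages`, returning the slope, the
#' Pearson correlation, and the two-sided p value for a zero slope. A
#' degenerate (zero-variance) outcome is flagged rather than an error.
#'
#' @param values Outcome, one per subject.
#' @param ages Ages in years, paired with `values` (n >= 3).
#' @return A list: `slope`, `intercept`, `r`, `p`, `n`, `degenerate`.
#' @export
regress_on_age <- function(values, ages) {
  if (length(values) != length(ages)) stop("unpaired-data")
  if (length(values) < 3) stop("insufficient-data: need n >= 3")
  if (stats::sd(values) == 0 || stats::sd(ages) == 0)
    return(list(slope = 0, intercept = mean(values), r = NA_real_,
                p = NA_real_, n = length(values), degenerate = TRUE))
  fit <- stats::lm(values ~ ages)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(sign(stats::coef(fit)[2]) * sqrt(s$r.squared)),
       p = s$coefficients[2, 4], n = length(values), degenerate = FALSE)
}

#' Repeated-measures ANCOVA with age as a continuous covariate
#'
#' Classical univariate repeated-measures analysis: within-subject factors
#' (e.g. load, feature dimension) are crossed with the continuous
#' between-subject covariate age, using `aov` error strata
#' `Error(subject/(f1*f2))`. Between-subject terms (age) are tested against
#' subject-level error with df (1, n - 2); within terms and their age
#' interactions against the matching within stratum.
#'
#' @param estimates Long `data.frame` of per-subject cell values.
#' @param outcome Name of the outcome column.
#' @param within Character vector of within-subject factor columns.
#' @param covariate Name of the continuous covariate column (default
#'   `"age"`).
#' @param subject Name of the subject id column.
#' @return A `data.frame` with one row per term: `term`, `df1`, `df2`, `F`,
#'   `p`.
#' @export
ancova_age <- function(estimates, outcome, within, covariate = "age",
                       subject = "subject_id") {
  d <- estimates
  d$.subj <- factor(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  cells <- table(d$.subj)
  if (length(unique(cells)) != 1)
    stop("unbalanced-design: every subject needs complete within cells")
  d$.y <- d[[outcome]]
  d$.cov <- d[[covariate]]
  rhs <- paste0(".cov * ", paste(within, collapse = " * "))
  err <- paste0("Error(.subj/(", paste(within, collapse = "*"), "))")
  f <- stats::as.formula(paste(".y ~", rhs, "+", err))
  fit <- stats::aov(f, data = d)
  sm <- summary(fit)
  ss_floor <- 1e-12 * stats::var(d$.y) * nrow(d)  # zero-variation guard
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- rownames(tab)
    res_row <- grep("Residuals", terms)
    if (!length(res_row)) next
    df2 <- tab[res_row, "Df"]
    for (i in seq_len(nrow(tab))) {
      if (i %in% res_row) next
      ss <- tab[i, "Sum Sq"]
      Fv <- tab[i, "F value"]; pv <- tab[i, "Pr(>F)"]
      if (is.na(ss) || ss < ss_floor) { Fv <- 0; pv <- 1 }  # 0/0 stratum
      out[[length(out) + 1]] <- data.frame(
        term = gsub("\\.cov", covariate, trimws(terms[i])),
        df1 = tab[i, "Df"], df2 = df2, sum_sq = ss,
        F = Fv, p = pv,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare two dependent correlations sharing one variable
#'
#' Hotelling-Williams test for the difference between corr(x1, y) and
#' corr(x2, y) computed on the same subjects, with df = n - 3.
#'
#' @param x1,x2,y Paired numeric vectors (n >= 5).
#' @return A list: `t`, `df`, `p` (two-sided), `r1`, `r2`.
#' @export
compare_dependent_correlations <- function(x1, x2, y) {
  n <- length(y)
  if (length(x1) != n || length(x2) != n) stop("unpaired-data")
  if (n < 5) stop("insufficient-data: need n >= 5")
  r1 <- stats::cor(x1, y)
  r2 <- stats::cor(x2, y)
  r12 <- stats::cor(x1, x2)
  detR <- 1 - r1^2 - r2^2 - r12^2 + 2 * r1 * r2 * r12
  rbar <- (r1 + r2) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r12)^3
  tval <- (r1 - r2) * sqrt((n - 1) * (1 + r12) / denom)
  df <- n - 3
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df), r1 = r1, r2 = r2)
}

#' Partial correlation of two variables controlling a third
#'
#' \eqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) /
#' \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}, with a two-sided p value from
#' \eqn{t = r\sqrt{(n-3)/(1-r^2)}} on n - 3 df.
#'
#' @param x,y,z Paired numeric vectors (n >= 4).
#' @return A list: `r`, `t`, `df`, `p`, `degenerate`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("unpaired-data")
  if (n < 4) stop("insufficient-data: need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    return(list(r = NA_real_, t = NA_real_, df = n - 3, p = NA_real_,
                degenerate = TRUE))
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  df <- n - 3
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       degenerate = FALSE)
}

#' Age-quartile summary
#'
#' Splits subjects into four equal-count age groups — the youngest n/4, the
#' next n/4, and so on, remainders going to the younger groups, ties broken
#' by input (subject) order — and tabulates mean and SD of each outcome per
#' group.
#'
#' @param estimates One row per subject; must contain an `age` column.
#' @param outcomes Character vector of outcome column names.
#' @return A `data.frame`, one row per quartile x outcome: `quartile`, `n`,
#'   `age_min`, `age_max`, `outcome`, `mean`, `sd`.
#' @export
quartile_summary <- function(estimates, outcomes) {
  n <- nrow(estimates)
  if (n < 4) stop("insufficient-data: need at least 4 subjects")
  ord <- order(estimates$age)         # stable: ties keep input order
  sizes <- rep(n %/% 4, 4) + c(rep(1, n %% 4), rep(0, 4 - n %% 4))
  q <- rep(seq_len(4), times = sizes)
  est <- estimates[ord, , drop = FALSE]
  out <- list()
  for (k in 1:4) {
    g <- est[q == k, , drop = FALSE]
    for (oc in outcomes) {
      out[[length(out) + 1]] <- data.frame(
        quartile = k, n = nrow(g),
        age_min = min(g$age), age_max = max(g$age),
        outcome = oc, mean = mean(g[[oc]]), sd = stats::sd(g[[oc]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Between-group exposure contrasts
#'
#' Two-sample t tests of each outcome between the 200 ms and 2 s exposure
#' groups, separately per memory load.
#'
#' @param estimates Long `data.frame` with columns `exposure`, `load`, and
#'   the outcomes.
#' @param outcomes Character vector of outcome column names.
#' @return A `data.frame`: `outcome`, `load`, `t`, `df`, `p`,
#'   `mean_short`, `mean_long` (200 ms vs 2 s group means).
#' @export
exposure_contrasts <- function(estimates, outcomes) {
  if (length(unique(estimates$exposure)) < 2)
    stop("single-group: both exposure groups must be present")
  out <- list()
  for (ld in sort(unique(estimates$load))) {
    d <- estimates[estimates$load == ld, , drop = FALSE]
    for (oc in outcomes) {
      a <- d[[oc]][d$exposure == 200]
      b <- d[[oc]][d$exposure == 2000]
      tt <- stats::t.test(a, b, var.equal = TRUE)
      out[[length(out) + 1]] <- data.frame(
        outcome = oc, load = ld, t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value,
        mean_short = mean(a), mean_long = mean(b),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
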