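#' Read a trial table from delimited text
#'
#' Comma-separated, one header line, one row per trial x feature dimension.
#' Required columns: `subject_id`, `load`, `dimension`, `target`, `response`;
#' `nontarget1`/`nontarget2` may be empty (load-1 rows). Angles are wrapped
#' onto \eqn{(-\pi, \pi]} on load. With `units = "degrees"` the orientation
#' columns are interpreted as 0-180 degree orientations and mapped to the
#' full circle via [orientation_to_angle()].
#'
#' @param path File path.
#' @param units `"radians"` (default) or `"degrees"` (orientation dialect).
#' @return A `data.frame` trial table. Rows with non-numeric angles are
#'   dropped and reported in the `"bad_rows"` attribute (row numbers).
#' @export
read_trial_table <- function(path, units = c("radians", "degrees")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "load", "dimension", "target", "response")
  missing <- setdiff(required, names(tt))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  angle_cols <- intersect(c("target", "nontarget1", "nontarget2", "response"),
                          names(tt))
  bad <- rep(FALSE, nrow(tt))
  for (cl in angle_cols) {
    v <- suppressWarnings(as.numeric(tt[[cl]]))
    bad <- bad | (is.na(v) & !(cl %in% c("nontarget1", "nontarget2") &
                                 (is.na(tt[[cl]]) | tt[[cl]] == "")))
    tt[[cl]] <- v
  }
  bad_rows <- which(bad)
  if (length(bad_rows)) {
    warning(sprintf("%d malformed row(s) dropped (lines %s)",
                    length(bad_rows),
                    paste(utils::head(bad_rows + 1, 5), collapse = ", ")))
    tt <- tt[!bad, , drop = FALSE]
  }
  for (cl in angle_cols) {
    v <- tt[[cl]]
    ok <- !is.na(v)
    if (units == "degrees") {
      is_ori <- tt$dimension == "orientation"
      v[ok & is_ori] <- orientation_to_angle(v[ok & is_ori] %% 180)
      v[ok & !is_ori] <- wrap_angle(v[ok & !is_ori] * pi / 180)
    } else {
      v[ok] <- wrap_angle(v[ok])
    }
    tt[[cl]] <- v
  }
  attr(tt, "bad_rows") <- bad_rows
  tt
}

#' Write a trial table (or any analysis table) as delimited text
#'
#' Comma-separated, UTF-8, one header line, full double precision.
#'
#' @param x A `data.frame`.
#' @param path Output path.
#' @param force Overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  utils::write.csv(format(x, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / restore a cohort manifest
#'
#' The manifest records the full [cohort_spec()] (including the seed) as
#' key-value text, so a cohort can be regenerated exactly.
#'
#' @param spec A [cohort_spec()].
#' @param path Manifest path.
#' @return For `write_cohort_manifest`, `path` invisibly; for
#'   `read_cohort_manifest`, the reconstructed [cohort_spec()].
#' @export
write_cohort_manifest <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  flat <- c(
    n_subjects = spec$n_subjects, trials_low = spec$trials_low,
    trials_high = spec$trials_high,
    age_min = spec$age_range[1], age_max = spec$age_range[2],
    noise_sigma = unname(spec$noise["sigma"]),
    noise_beta = unname(spec$noise["beta"]),
    noise_gamma = unname(spec$noise["gamma"]),
    exposure_sigma_mult = spec$exposure_sigma_mult,
    exposure_gamma_add = spec$exposure_gamma_add,
    coupling = spec$coupling, seed = spec$seed)
  for (ld in names(spec$age_maps))
    for (dm in names(spec$age_maps[[ld]]))
      for (par in names(spec$age_maps[[ld]][[dm]])) {
        v <- spec$age_maps[[ld]][[dm]][[par]]
        flat[paste("map", ld, dm, par, "intercept", sep = "_")] <- v[1]
        flat[paste("map", ld, dm, par, "slope", sep = "_")] <- v[2]
      }
  writeLines(sprintf("%s = %.17g", names(flat), flat), path)
  invisible(path)
}

#' @rdname write_cohort_manifest
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                          vapply(kv, `[[`, "", 1))
  maps <- list()
  for (ld in c("high", "low")) for (dm in c("orientation", "colour"))
    for (par in c("sigma", "beta", "gamma"))
      maps[[ld]][[dm]][[par]] <- unname(c(
        vals[paste("map", ld, dm, par, "intercept", sep = "_")],
        vals[paste("map", ld, dm, par, "slope", sep = "_")]))
  cohort_spec(
    n_subjects = vals[["n_subjects"]], trials_low = vals[["trials_low"]],
    trials_high = vals[["trials_high"]],
    age_range = c(vals[["age_min"]], vals[["age_max"]]),
    age_maps = maps,
    noise = c(sigma = vals[["noise_sigma"]], beta = vals[["noise_beta"]],
              gamma = vals[["noise_gamma"]]),
    exposure_sigma_mult = vals[["exposure_sigma_mult"]],
    exposure_gamma_add = vals[["exposure_gamma_add"]],
    coupling = vals[["coupling"]], seed = vals[["seed"]])
}
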