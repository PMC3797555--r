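#' Repeated-measures study design
#'
#' Describes the pre/post-surgical scanning design: two pre-surgical sessions
#' (S2, S4) and two post-surgical sessions (S3, S5), each comprising a fixed
#' number of perfusion scans, for a group of subjects who each undergo two
#' extractions (one per side). The screening visit carries no imaging data
#' and is not modelled.
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param scans_per_session Number of perfusion scans per session (at least 2).
#' @param vol_dim Integer vector of length 3; voxel grid dimensions of the
#'   simulated volumes.
#' @param side_order Character vector of length `n_subjects` with values
#'   `"left_first"` or `"right_first"`, giving which side was extracted first
#'   for each subject. Defaults to an alternating (balanced) assignment; the
#'   two counts may differ by at most 1.
#'
#' @return An object of class `study_design`: a list with fields
#'   `n_subjects`, `scans_per_session`, `vol_dim`, `sessions` (a tibble with
#'   columns `session` and `state`) and `side_order`.
#' @examples
#' d <- study_design(n_subjects = 8, vol_dim = c(4, 4, 2))
#' d$sessions
#' @export
study_design <- function(n_subjects = 16,
                         scans_per_session = 6,
                         vol_dim = c(8L, 8L, 6L),
                         side_order = NULL) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 ||
      is.na(n_subjects) || n_subjects < 2) {
    abort("`n_subjects` must be a single number >= 2.")
  }
  if (!is.numeric(scans_per_session) || length(scans_per_session) != 1 ||
      is.na(scans_per_session) || scans_per_session < 2) {
    abort("`scans_per_session` must be a single number >= 2.")
  }
  if (!is.numeric(vol_dim) || length(vol_dim) != 3 || any(is.na(vol_dim)) ||
      any(vol_dim < 1) || any(vol_dim != round(vol_dim))) {
    abort("`vol_dim` must be three positive integers.")
  }
  n_subjects <- as.integer(n_subjects)
  if (is.null(side_order)) {
    side_order <- rep_len(c("left_first", "right_first"), n_subjects)
  }
  if (length(side_order) != n_subjects ||
      !all(side_order %in% c("left_first", "right_first"))) {
    abort("`side_order` must be 'left_first'/'right_first', one per subject.")
  }
  n_left <- sum(side_order == "left_first")
  if (abs(n_left - (n_subjects - n_left)) > 1) {
    abort("`side_order` must be balanced: counts may differ by at most 1.")
  }
  sessions <- tibble(
    session = c("S2", "S3", "S4", "S5"),
    state   = c("pre", "post", "pre", "post")
  )
  structure(
    list(
      n_subjects        = n_subjects,
      scans_per_session = as.integer(scans_per_session),
      vol_dim           = as.integer(vol_dim),
      sessions          = sessions,
      side_order        = side_order
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Repeated-measures study design\n")
  cat("  subjects:         ", x$n_subjects, "\n")
  cat("  sessions:         ", paste0(x$sessions$session, " (", x$sessions$state, ")",
                                     collapse = ", "), "\n")
  cat("  scans per session:", x$scans_per_session, "\n")
  cat("  volume grid:      ", paste(x$vol_dim, collapse = " x "), "\n")
  invisible(x)
}

#' Surgery side of each post-surgical session
#'
#' @param design A [study_design()].
#' @return A tibble with columns `subject`, `session` and `side`
#'   (`"left"`/`"right"`), one row per subject and post-surgical session.
#' @export
session_sides <- function(design) {
  stopifnot(inherits(design, "study_design"))
  post <- design$sessions$session[design$sessions$state == "post"]
  first <- ifelse(design$side_order == "left_first", "left", "right")
  second <- ifelse(first == "left", "right", "left")
  tibble(
    subject = rep(seq_len(design$n_subjects), times = 2),
    session = rep(post, each = design$n_subjects),
    side    = c(first, second)
  )
}

#' Ground-truth variance components of the CBF generator
#'
#' The simulated CBF value at a voxel decomposes into a grand mean, a
#' per-subject per-voxel baseline (variance `sigma_b2`), a session effect
#' shared by all scans of a session (variance `sigma_s2`), scan-to-scan noise
#' (variance `sigma_w2`), and — inside the pain network during post-surgical
#' sessions only — an additive state response `delta` with per-subject
#' heterogeneity of variance `sigma_g2`. All units are ml blood/100 g/min
#' (variances squared units).
#'
#' @param grand_mean Grand mean CBF.
#' @param sigma_b2 Between-subject variance of the stable baseline.
#' @param sigma_s2 Between-session variance.
#' @param sigma_g2 Between-subject variance of the pain-response magnitude.
#' @param sigma_w2 Within-session scan-to-scan variance.
#' @param delta Mean pain-network CBF increase (post minus pre), >= 0.
#' @return An object of class `variance_components`.
#' @examples
#' variance_components(sigma_b2 = 9, sigma_s2 = 1, sigma_w2 = 0)
#' @export
variance_components <- function(grand_mean = 50,
                                sigma_b2 = 25,
                                sigma_s2 = 9,
                                sigma_g2 = 4,
                                sigma_w2 = 4,
                                delta = 10) {
  vals <- c(sigma_b2 = sigma_b2, sigma_s2 = sigma_s2,
            sigma_g2 = sigma_g2, sigma_w2 = sigma_w2)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("All variance components must be finite and >= 0.")
  }
  if (!is.finite(delta) || delta < 0) abort("`delta` must be finite and >= 0.")
  if (!is.finite(grand_mean)) abort("`grand_mean` must be finite.")
  structure(
    list(grand_mean = grand_mean, sigma_b2 = sigma_b2, sigma_s2 = sigma_s2,
         sigma_g2 = sigma_g2, sigma_w2 = sigma_w2, delta = delta),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (CBF ml/100g/min)\n")
  cat(sprintf("  grand mean %.3g | sigma_b2 %.3g | sigma_s2 %.3g | sigma_g2 %.3g | sigma_w2 %.3g | delta %.3g\n",
              x$grand_mean, x$sigma_b2, x$sigma_s2, x$sigma_g2, x$sigma_w2,
              x$delta))
  invisible(x)
}

#' Closed-form expected ICC for a network voxel
#'
#' Expected consistency ICC(3,1) at a pain-network voxel under the
#' session-mean measurement model, in which scan noise is averaged into an
#' effective per-session error variance
#' `sigma_e2 = sigma_s2 + sigma_w2 / scans_per_session`.
#'
#' The five comparison levels are: the pre- or post-surgical state (repeats
#' are the two same-state session means); and the change-in-CBF under the
#' three baseline schemes. For a difference score, any error shared between
#' the two replicates (a common baseline) migrates into the between-target
#' variance, which is why a single fixed baseline yields the highest expected
#' ICC and paired subtraction the lowest:
#' \describe{
#'   \item{pre_state}{`sigma_b2 / (sigma_b2 + sigma_e2)`}
#'   \item{post_state}{`(sigma_b2 + sigma_g2) / (sigma_b2 + sigma_g2 + sigma_e2)`}
#'   \item{delta_pair}{`sigma_g2 / (sigma_g2 + 2 sigma_e2)`}
#'   \item{delta_mean}{`(sigma_g2 + sigma_e2/2) / (sigma_g2 + 3 sigma_e2/2)`}
#'   \item{delta_single}{`(sigma_g2 + sigma_e2) / (sigma_g2 + 2 sigma_e2)`}
#' }
#' When `sigma_e2 == 0` every level returns 1.
#'
#' @param components A [variance_components()].
#' @param level Character vector of comparison levels (default: all five).
#' @param scans_per_session Number of scans averaged into each session mean.
#' @return Named numeric vector of expected ICCs in (-1, 1].
#' @examples
#' vc <- variance_components(sigma_b2 = 1, sigma_s2 = 1, sigma_g2 = 1,
#'                           sigma_w2 = 0)
#' expected_icc(vc) # delta_pair 1/3, delta_mean 0.6, delta_single 2/3
#' @export
expected_icc <- function(components,
                         level = c("pre_state", "post_state", "delta_pair",
                                   "delta_mean", "delta_single"),
                         scans_per_session = 6) {
  stopifnot(inherits(components, "variance_components"))
  all_levels <- c("pre_state", "post_state", "delta_pair", "delta_mean",
                  "delta_single")
  bad <- setdiff(level, all_levels)
  if (length(bad) > 0) {
    abort(paste0("Unknown ICC level(s): ", paste(bad, collapse = ", "),
                 ". Valid levels: ", paste(all_levels, collapse = ", "), "."))
  }
  b <- components$sigma_b2
  g <- components$sigma_g2
  e <- components$sigma_s2 + components$sigma_w2 / scans_per_session
  out <- vapply(level, function(l) {
    if (e == 0) return(1)
    switch(l,
      pre_state    = b / (b + e),
      post_state   = (b + g) / (b + g + e),
      delta_pair   = g / (g + 2 * e),
      delta_mean   = (g + e / 2) / (g + 1.5 * e),
      delta_single = (g + e) / (g + 2 * e)
    )
  }, numeric(1))
  setNames(out, level)
}
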