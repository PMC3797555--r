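#' Session-mean volumes
#'
#' Voxelwise arithmetic mean over the scans of each session — the first-level
#' "mean image" input to all second-level stages. Works on a simulated
#' [simulate_study()] dataset or on a long data frame with columns
#' `subject`, `session`, `scan`, `voxel`, `cbf`.
#'
#' @param x A `study_dataset` or long data frame.
#' @param ... Passed to methods.
#' @return An object of class `session_means`: a list with `values`
#'   (voxel x subject x session array), `sessions` (session/state tibble)
#'   and any masks carried from the dataset.
#' @export
session_means <- function(x, ...) UseMethod("session_means")

#' @export
session_means.study_dataset <- function(x, ...) {
  if (dim(x$cbf)[4] < 1) abort("No scans present.")
  vals <- rowMeans(x$cbf, dims = 3) # average over the scan dimension
  new_session_means(vals, x$design$sessions, design = x$design,
                    gm_mask = x$gm_mask, network_mask = x$network_mask,
                    roi_masks = x$roi_masks)
}

#' @param session_states Named character vector mapping session labels to
#'   `"pre"`/`"post"`. Defaults to the standard S2/S3/S4/S5 mapping when the
#'   labels match, otherwise it must be supplied.
#' @rdname session_means
#' @export
session_means.data.frame <- function(x, session_states = NULL, ...) {
  need <- c("subject", "session", "scan", "voxel", "cbf")
  if (!all(need %in% names(x))) {
    abort(paste0("Long CBF data must have columns: ", paste(need, collapse = ", "), "."))
  }
  if (nrow(x) == 0) abort("No scans present.")
  labs <- sort(unique(x$session))
  if (is.null(session_states)) {
    std <- c(S2 = "pre", S3 = "post", S4 = "pre", S5 = "post")
    if (!all(labs %in% names(std))) {
      abort("Non-standard session labels: supply `session_states`.")
    }
    session_states <- std[labs]
  }
  arr <- tapply(x$cbf, list(factor(x$voxel, levels = sort(unique(x$voxel))),
                            factor(x$subject, levels = sort(unique(x$subject))),
                            factor(x$session, levels = labs)),
                mean)
  if (anyNA(arr)) abort("Incomplete grid: every (subject, session, voxel) needs data.")
  sessions <- tibble(session = labs, state = unname(session_states[labs]))
  new_session_means(unname(unclass(arr)), sessions)
}

new_session_means <- function(values, sessions, design = NULL, gm_mask = NULL,
                              network_mask = NULL, roi_masks = NULL) {
  structure(
    list(values = values, sessions = sessions, design = design,
         gm_mask = gm_mask, network_mask = network_mask,
         roi_masks = roi_masks),
    class = "session_means"
  )
}

#' @export
print.session_means <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Session-mean volumes: %d voxels x %d subjects x %d sessions (%s)\n",
              d[1], d[2], d[3],
              paste(x$sessions$session, collapse = ", ")))
  invisible(x)
}

#' Voxelwise two-way state-contrast ANOVA
#'
#' At each voxel, a two-way ANOVA of the subject x session table of
#' session-mean CBF with subjects as blocks and sessions as treatments. The
#' post-minus-pre contrast uses weights `+1/2` for each post-surgical and
#' `-1/2` for each pre-surgical session (sum zero; the estimate is the
#' post-minus-pre mean CBF difference). The one-sided t statistic is
#' `t = (sum_s c_s ybar_.s) / sqrt(EMS * sum(c^2) / n)` on
#' `(n - 1)(s - 1)` error degrees of freedom — 45 for the default 16
#' subjects x 4 sessions. Voxels with zero residual variance are flagged
#' undefined (`t = NA`).
#'
#' @param sm A [session_means()] object with a complete subject x session grid.
#' @param mask Logical analysis mask (default: the GM mask if carried, else
#'   the whole grid).
#' @param contrast Optional per-session weights (must sum to zero); default
#'   is the post-minus-pre contrast derived from the session states.
#' @return An object of class `tmap`: `t` (vector over voxels, `NA` outside
#'   the mask/undefined), `dof`, `contrast`, `estimate` (contrast value in
#'   CBF units), `ems`, `mask`, `undefined`, `n_subjects`.
#' @export
voxelwise_state_anova <- function(sm, mask = NULL, contrast = NULL) {
  stopifnot(inherits(sm, "session_means"))
  vals <- sm$values
  V <- dim(vals)[1]; n <- dim(vals)[2]; S <- dim(vals)[3]
  if (n < 2 || S < 2) abort("Need at least 2 subjects and 2 sessions.")
  if (anyNA(vals)) abort("Missing cells in the subject x session grid.")
  states <- sm$sessions$state
  if (is.null(contrast)) {
    contrast <- ifelse(states == "post", 1 / sum(states == "post"),
                       -1 / sum(states == "pre"))
  }
  if (length(contrast) != S) abort("`contrast` must have one weight per session.")
  if (abs(sum(contrast)) > 1e-8) abort("`contrast` weights must sum to zero.")
  mask <- mask %||% sm$gm_mask %||% rep(TRUE, V)
  mvec <- as.vector(mask)
  if (length(mvec) != V) abort("`mask` does not match the voxel grid.")

  grand <- rowMeans(vals, dims = 1)                  # V
  subj  <- rowMeans(vals, dims = 2)                  # V x n (mean over sessions)
  sess  <- colMeans(aperm(vals, c(2, 1, 3)))         # V x S (mean over subjects)
  resid <- vals - as.vector(subj) -
    aperm(array(sess, c(V, S, n)), c(1, 3, 2)) + as.vector(grand)
  dof <- (n - 1) * (S - 1)
  ems <- rowSums(resid^2, dims = 1) / dof
  est <- as.vector(sess %*% contrast)
  se <- sqrt(ems * sum(contrast^2) / n)
  tval <- est / se
  undefined <- mvec & (ems <= 0)
  tval[!mvec | undefined] <- NA_real_
  if (any(undefined)) {
    inform(sprintf("%d voxel(s) with zero residual variance: t undefined.",
                   sum(undefined)))
  }
  structure(
    list(t = tval, dof = dof,
         contrast = setNames(contrast, sm$sessions$session),
         estimate = est, ems = ems, mask = mask, undefined = undefined,
         n_subjects = n),
    class = "tmap"
  )
}

#' @export
print.tmap <- function(x, ...) {
  cat(sprintf("State-contrast t map: %d voxels in mask, dof = %d\n",
              sum(as.vector(x$mask)), x$dof))
  cat("  contrast:", paste(sprintf("%s=%+.2g", names(x$contrast), x$contrast),
                           collapse = " "), "\n")
  invisible(x)
}

#' Critical values of the one-sided state contrast
#'
#' Upper-tail quantiles used to threshold the contrast map: `critical_t()`
#' is the inverse upper tail of Student's t (2.41 at p = 0.01 with 45 df),
#' `critical_z()` of the standard normal (2.3 at p = 0.01).
#'
#' @param p One-sided tail probability in (0, 1).
#' @param dof Error degrees of freedom (>= 1).
#' @return The threshold value.
#' @examples
#' round(critical_t(0.01, 45), 2)
#' round(critical_z(0.01), 1)
#' @export
critical_t <- function(p, dof) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) abort("`p` must lie in (0, 1).")
  if (any(dof < 1)) abort("`dof` must be >= 1.")
  qt(p, df = dof, lower.tail = FALSE)
}

#' @rdname critical_t
#' @export
critical_z <- function(p) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) abort("`p` must lie in (0, 1).")
  qnorm(p, lower.tail = FALSE)
}

#' Threshold a t map into a network mask
#'
#' A voxel enters the network when its t statistic reaches the critical
#' value and it lies inside the analysis mask. The retained voxel count is
#' reported.
#'
#' @param tmap A [voxelwise_state_anova()] result.
#' @param t_crit Threshold; default `critical_t(p, tmap$dof)`.
#' @param p One-sided tail probability used when `t_crit` is not given.
#' @return Logical mask (same shape as the analysis mask).
#' @export
threshold_network <- function(tmap, t_crit = NULL, p = 0.01) {
  stopifnot(inherits(tmap, "tmap"))
  t_crit <- t_crit %||% critical_t(p, tmap$dof)
  if (is.na(t_crit)) abort("`t_crit` must not be NA.")
  sel <- as.vector(tmap$mask) & !is.na(tmap$t) & tmap$t >= t_crit
  out <- tmap$mask
  out[] <- sel
  inform(sprintf("Network mask: %d of %d mask voxels at t >= %.3f.",
                 sum(sel), sum(as.vector(tmap$mask)), t_crit))
  out
}

#' @rdname voxelwise_state_anova
#' @param x A `tmap`.
#' @param ... Unused.
#' @export
as_tibble.tmap <- function(x, ...) {
  tibble(voxel = seq_along(x$t), t = x$t,
         estimate = x$estimate, in_mask = as.vector(x$mask),
         undefined = x$undefined)
}
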