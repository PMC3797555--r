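#' Inter-subject voxelwise ICC map
#'
#' At each voxel, assembles the subjects x 2 table of the two repeated
#' measurements and computes ICC(3,1) with subjects as targets (k = 2).
#' Voxels whose data are constant across subjects are flagged undefined and
#' excluded (never zero-filled); their count is reported.
#'
#' @param repeat1,repeat2 Voxel x subject matrices holding the same subjects
#'   in the same column order (e.g. the two same-state session means, or the
#'   two delta replicates).
#' @param mask Logical analysis mask (default: all voxels).
#' @return An object of class `icc_map`: `icc` (vector over voxels, `NA`
#'   outside mask or undefined), `defined`, `mask`, `n_targets`, `k`,
#'   `n_undefined`.
#' @export
inter_subject_icc_map <- function(repeat1, repeat2, mask = NULL) {
  if (!is.matrix(repeat1) || !is.matrix(repeat2) ||
      !identical(dim(repeat1), dim(repeat2))) {
    abort("`repeat1` and `repeat2` must be voxel x subject matrices of equal shape.")
  }
  if (ncol(repeat1) < 2) abort("At least 2 subjects are required.")
  V <- nrow(repeat1)
  mask <- mask %||% rep(TRUE, V)
  mvec <- as.vector(mask)
  if (length(mvec) != V) abort("`mask` does not match the voxel grid.")
  res <- icc31_pairs(repeat1, repeat2)
  defined <- mvec & !res$undefined
  icc <- res$icc
  icc[!defined] <- NA_real_
  n_undef <- sum(mvec & res$undefined)
  if (n_undef > 0) {
    inform(sprintf("%d voxel(s) with no between-subject variance: ICC undefined.",
                   n_undef))
  }
  structure(
    list(icc = icc, defined = defined, mask = mask,
         n_targets = res$n_targets, k = res$k, n_undefined = n_undef),
    class = "icc_map"
  )
}

#' @export
print.icc_map <- function(x, ...) {
  cat(sprintf("Voxelwise ICC(3,1) map: %d defined voxels (%d undefined), n = %d, k = %d\n",
              sum(x$defined), x$n_undefined, x$n_targets, x$k))
  invisible(x)
}

#' @rdname inter_subject_icc_map
#' @param x An `icc_map`.
#' @param ... Unused.
#' @export
as_tibble.icc_map <- function(x, ...) {
  tibble(voxel = seq_along(x$icc), icc = x$icc,
         in_mask = as.vector(x$mask), defined = x$defined)
}

#' ICC map of a pre- or post-surgical state
#'
#' Convenience wrapper: the two repeats are the session means of the two
#' same-state sessions.
#'
#' @param sm A [session_means()] object.
#' @param state `"pre"` or `"post"`.
#' @param mask Analysis mask (default: the GM mask if carried).
#' @return An `icc_map` (see [inter_subject_icc_map()]).
#' @export
state_icc_map <- function(sm, state = c("pre", "post"), mask = NULL) {
  stopifnot(inherits(sm, "session_means"))
  state <- match.arg(state)
  idx <- which(sm$sessions$state == state)
  if (length(idx) != 2) abort("State ICC maps need exactly two same-state sessions.")
  V <- dim(sm$values)[1]; n <- dim(sm$values)[2]
  inter_subject_icc_map(matrix(sm$values[, , idx[1]], V, n),
                        matrix(sm$values[, , idx[2]], V, n),
                        mask = mask %||% sm$gm_mask)
}

#' ICC map of a delta-CBF scheme
#'
#' The two repeats are the two delta replicates of [compute_delta()].
#'
#' @param dm A `delta_maps` object.
#' @param mask Analysis mask (default: the GM mask if carried).
#' @return An `icc_map`.
#' @export
delta_icc_map <- function(dm, mask = NULL) {
  stopifnot(inherits(dm, "delta_maps"))
  V <- dim(dm$values)[1]; n <- dim(dm$values)[2]
  inter_subject_icc_map(matrix(dm$values[, , 1], V, n),
                        matrix(dm$values[, , 2], V, n),
                        mask = mask %||% dm$gm_mask)
}

#' Median ICC of a stratum
#'
#' The median of the defined voxelwise ICCs inside a stratum mask — the
#' inter-subject summary statistic ("med ICC").
#'
#' @param map An `icc_map`.
#' @param stratum_mask Logical mask (default: all defined voxels).
#' @return A single number.
#' @export
median_icc <- function(map, stratum_mask = NULL) {
  stopifnot(inherits(map, "icc_map"))
  sel <- map$defined
  if (!is.null(stratum_mask)) sel <- sel & as.vector(stratum_mask)
  if (!any(sel)) abort("Empty stratum: no defined ICC voxels.")
  median(map$icc[sel])
}

#' ICC distribution profile
#'
#' Normalized histogram of the voxelwise ICCs in a stratum (fractions of
#' defined voxels summing to 1), with the median and the sample skewness.
#' Reliable measurements concentrate the mass near 1, giving a pronounced
#' negative skew.
#'
#' @param map An `icc_map`.
#' @param stratum_mask Logical mask (default: all defined voxels).
#' @param bins Number of equal-width bins on `[-1, 1]` (default 50).
#' @param stratum Label carried into the output (e.g. `"gm"`, `"network"`).
#' @return An object of class `icc_distribution`: `bins` (tibble with
#'   `lower`, `upper`, `mid`, `fraction`), `median`, `skewness`,
#'   `n_voxels`, `stratum`.
#' @export
icc_distribution <- function(map, stratum_mask = NULL, bins = 50,
                             stratum = "all") {
  stopifnot(inherits(map, "icc_map"))
  sel <- map$defined
  if (!is.null(stratum_mask)) sel <- sel & as.vector(stratum_mask)
  vals <- map$icc[sel]
  if (length(vals) < 2) abort("Need at least 2 defined voxels in the stratum.")
  breaks <- seq(-1, 1, length.out = bins + 1)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  structure(
    list(bins = tibble(lower = breaks[-length(breaks)], upper = breaks[-1],
                       mid = h$mids, fraction = h$counts / length(vals)),
         median = median(vals), skewness = sample_skewness(vals),
         n_voxels = length(vals), stratum = stratum),
    class = "icc_distribution"
  )
}

#' @export
print.icc_distribution <- function(x, ...) {
  cat(sprintf("ICC distribution (%s): %d voxels, median %.3f, skewness %.3f\n",
              x$stratum, x$n_voxels, x$median, x$skewness))
  invisible(x)
}

#' @rdname icc_distribution
#' @param x An `icc_distribution`.
#' @param ... Unused.
#' @export
tidy.icc_distribution <- function(x, ...) {
  dplyr::mutate(x$bins, stratum = x$stratum, median = x$median,
                skewness = x$skewness)
}

#' Within-subject intra-voxel ICC (ICC_v)
#'
#' Treats the voxels of an ROI as targets and two repeated measurements of
#' the same subject as raters (k = 2), and applies ICC(3,1) to the
#' voxels x 2 table. The SEM is attached using the pooled voxel SD
#' (`sem_from_icc`). Note that voxels are not spatially independent, so the
#' effective number of targets is inflated; no correction is applied.
#'
#' @param volume_a,volume_b Two volumes (vectors or arrays) of one subject.
#' @param roi_mask Logical mask selecting the ROI voxels (default: all).
#' @return An `icc_result` with the `sem` slot filled. Constant ROIs give an
#'   undefined result rather than a number.
#' @export
within_subject_iccv <- function(volume_a, volume_b, roi_mask = NULL) {
  a <- as.vector(volume_a)
  b <- as.vector(volume_b)
  if (length(a) != length(b)) abort("Volumes must have the same number of voxels.")
  if (!is.null(roi_mask)) {
    sel <- as.vector(roi_mask)
    if (length(sel) != length(a)) abort("`roi_mask` does not match the voxel grid.")
    a <- a[sel]
    b <- b[sel]
  }
  if (length(a) < 2) abort("ROI must contain at least 2 voxels.")
  res <- icc_31(cbind(a, b))
  res$sem <- if (isTRUE(res$undefined)) NA_real_ else
    sem_from_icc(sd(c(a, b)), res$icc)
  res
}

#' Inter-session ICC_v table
#'
#' Within-subject inter-session reliability: for each subject and ROI, the
#' ICC_v between the session means of the two same-state sessions.
#'
#' @param ds A [simulate_study()] dataset (or any `study_dataset`).
#' @param state `"post"` (default) or `"pre"`.
#' @param roi_masks Named list of logical masks (default: the dataset's).
#' @return A tibble with one row per (subject, ROI): `subject`, `state`,
#'   `roi`, `n_voxels`, `icc`, `sem`, `band`.
#' @export
inter_session_iccv <- function(ds, state = c("post", "pre"), roi_masks = NULL) {
  stopifnot(inherits(ds, "study_dataset"))
  state <- match.arg(state)
  roi_masks <- roi_masks %||% ds$roi_masks
  if (length(roi_masks) == 0) abort("No ROI masks supplied.")
  sm <- session_means(ds)
  idx <- which(sm$sessions$state == state)
  V <- dim(sm$values)[1]
  grid <- tidyr::expand_grid(subject = seq_len(ds$design$n_subjects),
                             roi = names(roi_masks))
  rows <- purrr::pmap(grid, function(subject, roi) {
    r <- within_subject_iccv(sm$values[, subject, idx[1]],
                             sm$values[, subject, idx[2]],
                             roi_masks[[roi]])
    tibble(subject = subject, state = state, roi = roi,
           n_voxels = r$n_targets, icc = r$icc, sem = r$sem,
           band = as.character(r$band))
  })
  dplyr::bind_rows(rows)
}

#' Intra-session ICC_v table
#'
#' Within-subject intra-session reliability: for each subject, post-surgical
#' session and ROI, the ICC_v between pairs of individual scans — by default
#' the first vs third and first vs sixth scan, spanning the start, midpoint
#' and end of the time series.
#'
#' @param ds A `study_dataset`.
#' @param sessions Session labels (default: the post-surgical sessions).
#' @param scan_pairs List of length-2 integer vectors of scan indices.
#' @param roi_masks Named list of logical masks (default: the dataset's).
#' @return A tibble with one row per (subject, session, ROI, pair):
#'   `subject`, `session`, `side`, `roi`, `pair`, `n_voxels`, `icc`, `sem`,
#'   `band`. Summarise over subjects with [summarise_iccv()].
#' @export
intra_session_iccv <- function(ds, sessions = NULL,
                               scan_pairs = list(c(1, 3), c(1, 6)),
                               roi_masks = NULL) {
  stopifnot(inherits(ds, "study_dataset"))
  sess_tbl <- ds$design$sessions
  sessions <- sessions %||% sess_tbl$session[sess_tbl$state == "post"]
  roi_masks <- roi_masks %||% ds$roi_masks
  if (length(roi_masks) == 0) abort("No ROI masks supplied.")
  M <- ds$design$scans_per_session
  for (p in scan_pairs) {
    if (length(p) != 2 || any(p < 1) || any(p > M)) {
      abort(sprintf("Scan pair (%s) outside the 1..%d scans of a session.",
                    paste(p, collapse = ","), M))
    }
  }
  sides <- session_sides(ds$design)
  grid <- tidyr::expand_grid(subject = seq_len(ds$design$n_subjects),
                             session = sessions, roi = names(roi_masks),
                             pair_id = seq_along(scan_pairs))
  rows <- purrr::pmap(grid, function(subject, session, roi, pair_id) {
    p <- scan_pairs[[pair_id]]
    s <- match(session, sess_tbl$session)
    r <- within_subject_iccv(ds$cbf[, subject, s, p[1]],
                             ds$cbf[, subject, s, p[2]],
                             roi_masks[[roi]])
    tibble(subject = subject, session = session, roi = roi,
           pair = paste0(p[1], "v", p[2]),
           n_voxels = r$n_targets, icc = r$icc, sem = r$sem,
           band = as.character(r$band))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(out, sides, by = c("subject", "session"))[,
    c("subject", "session", "side", "roi", "pair", "n_voxels",
      "icc", "sem", "band")]
}

#' Group summary of an ICC_v table
#'
#' Arithmetic mean of the per-subject ICC_v (and SEM) per grouping cell —
#' the group rows of the intra-session reliability table.
#'
#' @param tbl Output of [intra_session_iccv()] or [inter_session_iccv()].
#' @param by Grouping columns (default: whichever of `roi`, `pair`, `side`,
#'   `state` are present).
#' @return A tibble with `icc` (group mean), `sem` (group mean) and
#'   `n_subjects` per group.
#' @export
summarise_iccv <- function(tbl, by = intersect(c("roi", "pair", "side", "state"),
                                               names(tbl))) {
  dplyr::summarise(
    dplyr::group_by(tbl, dplyr::across(dplyr::all_of(by))),
    icc = mean(.data$icc, na.rm = TRUE),
    sem = mean(.data$sem, na.rm = TRUE),
    n_subjects = dplyr::n_distinct(.data$subject),
    .groups = "drop"
  )
}
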