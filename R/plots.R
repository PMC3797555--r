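#' @importFrom ggplot2 ggplot aes geom_raster geom_col geom_line geom_point
#'   geom_errorbar scale_fill_viridis_c labs facet_wrap theme_minimal
NULL

slice_df <- function(values, vol_dim, slice = NULL) {
  arr <- array(values, vol_dim)
  slice <- slice %||% ceiling(vol_dim[3] / 2)
  m <- arr[, , slice]
  tibble(
    x = rep(seq_len(vol_dim[1]), times = vol_dim[2]),
    y = rep(seq_len(vol_dim[2]), each = vol_dim[1]),
    value = as.vector(m),
    slice = slice
  )
}

#' Plot an axial slice of a t map
#'
#' @param object A `tmap`.
#' @param vol_dim Grid dimensions (taken from the mask when it is an array).
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tmap <- function(object, vol_dim = dim(object$mask), slice = NULL, ...) {
  if (is.null(vol_dim)) abort("Supply `vol_dim`: the mask carries no grid shape.")
  df <- slice_df(object$t, vol_dim, slice)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey90") +
    labs(title = sprintf("State-contrast t (dof = %d), slice %d",
                         object$dof, df$slice[1]),
         fill = "t") +
    theme_minimal()
}

#' Plot an axial slice of a voxelwise ICC map
#'
#' @param object An `icc_map`.
#' @param vol_dim Grid dimensions (taken from the mask when it is an array).
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.icc_map <- function(object, vol_dim = dim(object$mask), slice = NULL, ...) {
  if (is.null(vol_dim)) abort("Supply `vol_dim`: the mask carries no grid shape.")
  df <- slice_df(object$icc, vol_dim, slice)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(-1, 1), na.value = "grey90") +
    labs(title = sprintf("Voxelwise ICC(3,1), slice %d", df$slice[1]),
         fill = "ICC") +
    theme_minimal()
}

#' Plot an ICC distribution profile
#'
#' Relative number of voxels against ICC score.
#'
#' @param object An `icc_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.icc_distribution <- function(object, ...) {
  ggplot(object$bins, aes(x = .data$mid, y = .data$fraction)) +
    geom_col(width = diff(object$bins$lower[1:2]), fill = "steelblue") +
    labs(x = "ICC score", y = "fraction of voxels",
         title = sprintf("ICC distribution (%s): median %.2f, skew %.2f",
                         object$stratum, object$median, object$skewness)) +
    theme_minimal()
}

#' Plot VAS ratings by session
#'
#' Group mean with standard-error bars per session and scan, for pain and
#' alertness.
#'
#' @param vas A `vas_table`.
#' @return A ggplot.
#' @export
plot_vas <- function(vas) {
  check_vas(vas)
  long <- tidyr::pivot_longer(vas, c("pain", "alertness"),
                              names_to = "measure", values_to = "rating")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$measure, .data$session, .data$scan),
    mean = mean(.data$rating),
    sem = sd(.data$rating) / sqrt(dplyr::n()), .groups = "drop")
  ggplot(summ, aes(x = .data$scan, y = .data$mean,
                   colour = .data$session, group = .data$session)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.15) +
    facet_wrap(~.data$measure) +
    labs(x = "scan", y = "VAS rating (mm)") +
    theme_minimal()
}
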