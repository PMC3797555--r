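#' Two-way mean-squares decomposition
#'
#' Decomposes a complete targets x raters table into the between-targets
#' (BMS), between-raters (JMS) and residual (EMS) mean squares of the
#' standard additive two-way layout:
#' `SS_total = SS_targets + SS_raters + SS_error`, with
#' `BMS = SS_targets/(n-1)`, `JMS = SS_raters/(k-1)` and
#' `EMS = SS_error/((n-1)(k-1))`.
#'
#' @param x Either a numeric matrix with targets in rows and raters
#'   (repeated measurements) in columns, or a data frame with columns
#'   `target`, `rater` and `value` holding exactly one row per cell.
#' @return An object of class `mean_squares`: a list with `bms`, `jms`,
#'   `ems`, the sums of squares, `n_targets` and `k`.
#' @examples
#' two_way_mean_squares(matrix(c(1, 3, 5, 2, 4, 6), ncol = 2))
#' @export
two_way_mean_squares <- function(x) {
  m <- as_icc_matrix(x)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) abort("At least 2 targets are required.")
  if (k < 2) abort("At least 2 raters (repeated measurements) are required.")
  if (!all(is.finite(m))) abort("All measurements must be finite; missing cells are not supported.")
  grand <- mean(m)
  ss_targets <- k * sum((rowMeans(m) - grand)^2)
  ss_raters  <- n * sum((colMeans(m) - grand)^2)
  ss_total   <- sum((m - grand)^2)
  # cancellation can leave a tiny negative residual; clamp at zero
  ss_error <- max(ss_total - ss_targets - ss_raters, 0)
  structure(
    list(bms = ss_targets / (n - 1),
         jms = ss_raters / (k - 1),
         ems = ss_error / ((n - 1) * (k - 1)),
         ss_targets = ss_targets, ss_raters = ss_raters, ss_error = ss_error,
         n_targets = n, k = k),
    class = "mean_squares"
  )
}

as_icc_matrix <- function(x) {
  if (is.matrix(x) && is.numeric(x)) return(x)
  if (is.data.frame(x)) {
    need <- c("target", "rater", "value")
    if (!all(need %in% names(x))) {
      abort("Data-frame input must have columns `target`, `rater`, `value`.")
    }
    if (anyDuplicated(x[c("target", "rater")]) > 0) {
      abort("Duplicated (target, rater) cells in input table.")
    }
    tab <- tapply(x$value, list(factor(x$target), factor(x$rater)), identity)
    if (anyNA(tab)) abort("Missing cells: every target must be measured by every rater.")
    return(unclass(tab))
  }
  abort("`x` must be a numeric matrix or a target/rater/value data frame.")
}

#' @export
print.mean_squares <- function(x, ...) {
  cat(sprintf("Two-way mean squares (%d targets x %d raters)\n", x$n_targets, x$k))
  cat(sprintf("  BMS %.6g | JMS %.6g | EMS %.6g\n", x$bms, x$jms, x$ems))
  invisible(x)
}

new_icc_result <- function(icc, ms, undefined = FALSE, reason = NULL,
                           cv = NA_real_, sem = NA_real_) {
  structure(
    list(icc = icc,
         band = classify_icc_band(icc),
         ms = ms, n_targets = ms$n_targets, k = ms$k,
         cv = cv, sem = sem,
         undefined = undefined, reason = reason),
    class = "icc_result"
  )
}

#' Consistency intraclass correlation ICC(3,1)
#'
#' Computes the single-measurement consistency ICC for a two-way layout with
#' fixed raters, `(BMS - EMS) / (BMS + (k - 1) EMS)`. Negative estimates are
#' returned unclamped. When the denominator is not positive (all-constant
#' data) the reliability is undefined: the result carries `icc = NA`,
#' `undefined = TRUE` and a reason string rather than a number.
#'
#' Because the consistency form ignores the rater main effect, adding a
#' constant to one rater's column leaves the ICC unchanged.
#'
#' @param x A targets x raters matrix, a `target`/`rater`/`value` data frame,
#'   or a [two_way_mean_squares()] result.
#' @return An object of class `icc_result` with fields `icc`, `band`
#'   (poor/fair/good/excellent), `ms`, `n_targets`, `k`, and optional `cv`
#'   and `sem` slots filled by downstream helpers. [tidy()] returns the
#'   ANOVA-style term table, [glance()] a one-row summary.
#' @examples
#' icc_31(matrix(c(1, 3, 5, 2, 3, 6), ncol = 2))
#' @export
icc_31 <- function(x) {
  ms <- if (inherits(x, "mean_squares")) x else two_way_mean_squares(x)
  denom <- ms$bms + (ms$k - 1) * ms$ems
  if (!is.finite(denom) || denom <= 0) {
    return(new_icc_result(NA_real_, ms, undefined = TRUE,
                          reason = "zero total variance: all measurements constant"))
  }
  new_icc_result((ms$bms - ms$ems) / denom, ms)
}

#' Qualitative reliability band of an ICC value
#'
#' Maps ICC values to the conventional qualitative labels: below 0.4 poor,
#' 0.4 to below 0.6 fair, 0.6 to below 0.75 good, 0.75 and above excellent.
#' Half-open intervals are used so that every real value maps to exactly one
#' band. `NA` input gives `NA`.
#'
#' @param icc Numeric vector of ICC values (each <= 1).
#' @return A factor with levels poor < fair < good < excellent.
#' @examples
#' classify_icc_band(c(0.456, 0.664, -0.1, 0.9))
#' @export
classify_icc_band <- function(icc) {
  if (any(icc > 1 + 1e-8, na.rm = TRUE)) abort("ICC values must be <= 1.")
  cut(icc, breaks = c(-Inf, 0.4, 0.6, 0.75, Inf),
      labels = c("poor", "fair", "good", "excellent"),
      right = FALSE, ordered_result = TRUE)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean. A zero
#' mean leaves the ratio undefined; `NA` is returned with a warning as the
#' explicit undefined signal.
#'
#' @param x Numeric vector of at least 2 finite measurements.
#' @return A single unitless ratio, or `NA` when the mean is zero.
#' @examples
#' cv(c(2, 4)) # sqrt(2)/3
#' @export
cv <- function(x) {
  if (!is.numeric(x) || length(x) < 2) abort("`x` must be numeric with n >= 2.")
  if (!all(is.finite(x))) abort("`x` must be finite.")
  m <- mean(x)
  if (m == 0) {
    warn("Coefficient of variation undefined: mean is zero.")
    return(NA_real_)
  }
  sd(x) / m
}

#' Standard error of measurement from an ICC
#'
#' The psychometric definition `SEM = pooled_sd * sqrt(1 - ICC)`. For a
#' negative ICC the factor exceeds 1, which is allowed.
#'
#' @param pooled_sd Pooled standard deviation of the measurements
#'   (same units as the data), >= 0.
#' @param icc ICC value (<= 1); may be `NA`, giving `NA`.
#' @return SEM in data units.
#' @examples
#' sem_from_icc(2, 0.75) # 1
#' @export
sem_from_icc <- function(pooled_sd, icc) {
  if (any(pooled_sd < 0, na.rm = TRUE)) abort("`pooled_sd` must be >= 0.")
  if (any(icc > 1 + 1e-8, na.rm = TRUE)) abort("`icc` must be <= 1.")
  pooled_sd * sqrt(1 - icc)
}

#' @export
print.icc_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("ICC(3,1): undefined —", x$reason, "\n")
  } else {
    cat(sprintf("ICC(3,1) = %.4f (%s), n = %d targets, k = %d\n",
                x$icc, as.character(x$band), x$n_targets, x$k))
    if (!is.na(x$cv))  cat(sprintf("  CV  = %.4f\n", x$cv))
    if (!is.na(x$sem)) cat(sprintf("  SEM = %.4f\n", x$sem))
  }
  invisible(x)
}

#' @rdname icc_31
#' @param x,object An `icc_result`.
#' @param ... Unused.
#' @export
tidy.icc_result <- function(x, ...) {
  ms <- x$ms
  tibble(
    term   = c("between_targets", "between_raters", "error"),
    df     = c(ms$n_targets - 1, ms$k - 1, (ms$n_targets - 1) * (ms$k - 1)),
    sumsq  = c(ms$ss_targets, ms$ss_raters, ms$ss_error),
    meansq = c(ms$bms, ms$jms, ms$ems)
  )
}

#' @rdname icc_31
#' @export
glance.icc_result <- function(x, ...) {
  tibble(
    icc = x$icc, band = as.character(x$band), cv = x$cv, sem = x$sem,
    n_targets = x$n_targets, k = x$k,
    bms = x$ms$bms, jms = x$ms$jms, ems = x$ms$ems,
    undefined = x$undefined
  )
}

# Vectorised ICC(3,1) for k = 2 paired repeats: rows are voxels, columns
# targets. Returns per-row icc with undefined flags; used by the map stages.
icc31_pairs <- function(r1, r2) {
  if (!identical(dim(r1), dim(r2))) abort("Repeat matrices must share dimensions.")
  n <- ncol(r1)
  if (n < 2) abort("At least 2 targets are required.")
  tmean <- (r1 + r2) / 2
  m1 <- rowMeans(r1)
  m2 <- rowMeans(r2)
  g <- (m1 + m2) / 2
  ss_t <- 2 * rowSums((tmean - g)^2)
  ss_r <- n * ((m1 - g)^2 + (m2 - g)^2)
  ss_tot <- rowSums((r1 - g)^2) + rowSums((r2 - g)^2)
  ss_e <- pmax(ss_tot - ss_t - ss_r, 0)
  bms <- ss_t / (n - 1)
  ems <- ss_e / (n - 1)
  denom <- bms + ems
  undefined <- !is.finite(denom) | denom <= 0
  icc <- ifelse(undefined, NA_real_, (bms - ems) / denom)
  list(icc = icc, bms = bms, ems = ems, undefined = undefined,
       n_targets = n, k = 2L)
}

# Sample skewness g1 = m3 / m2^(3/2) with 1/n moments.
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(NA_real_)
  mean(d^3) / m2^1.5
}
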