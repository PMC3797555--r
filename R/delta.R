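#' Change-in-CBF maps under the four baseline-subtraction schemes
#'
#' Computes per-subject change-in-CBF (delta) volumes from session means.
#' With pre-surgical sessions P1, P2 and post-surgical sessions Q1, Q2 the
#' two replicates are:
#' \describe{
#'   \item{pairs}{`Q1 - P1` and `Q2 - P2` (paired subtraction within each
#'     surgery's session pair)}
#'   \item{mean}{`Q_r - (P1 + P2)/2` (mean of both baselines)}
#'   \item{s2}{`Q_r - P1` (first pre-surgical session as the fixed baseline)}
#'   \item{s4}{`Q_r - P2` (second pre-surgical session as the fixed baseline)}
#' }
#' The schemes satisfy `(delta_s2 + delta_s4)/2 == delta_mean` voxelwise and
#' all coincide when the two pre-surgical sessions are identical.
#'
#' @param sm A [session_means()] object with two pre and two post sessions.
#' @param scheme One of `"pairs"`, `"mean"`, `"s2"`, `"s4"`.
#' @return An object of class `delta_maps`: `values`
#'   (voxel x subject x 2 replicates, replicate r from the r-th
#'   post-surgical session), `scheme`, `replicate_sessions`, and any masks
#'   carried from the input.
#' @examples
#' ds <- simulate_study(study_design(4, 2, c(3, 3, 2)), seed = 1)
#' dm <- compute_delta(session_means(ds), "pairs")
#' dim(dm$values)
#' @export
compute_delta <- function(sm, scheme = c("pairs", "mean", "s2", "s4")) {
  stopifnot(inherits(sm, "session_means"))
  scheme <- match.arg(scheme)
  vals <- sm$values
  V <- dim(vals)[1]; n <- dim(vals)[2]
  pre <- which(sm$sessions$state == "pre")
  post <- which(sm$sessions$state == "post")
  if (length(pre) != 2 || length(post) != 2) {
    abort("Delta schemes require exactly two pre and two post sessions.")
  }
  slice <- function(i) matrix(vals[, , i], V, n)
  p1 <- slice(pre[1]); p2 <- slice(pre[2])
  q1 <- slice(post[1]); q2 <- slice(post[2])
  reps <- switch(scheme,
    pairs = list(q1 - p1, q2 - p2),
    mean  = { b <- (p1 + p2) / 2; list(q1 - b, q2 - b) },
    s2    = list(q1 - p1, q2 - p1),
    s4    = list(q1 - p2, q2 - p2)
  )
  structure(
    list(values = array(c(reps[[1]], reps[[2]]), dim = c(V, n, 2)),
         scheme = scheme,
         replicate_sessions = sm$sessions$session[post],
         design = sm$design, gm_mask = sm$gm_mask,
         network_mask = sm$network_mask, roi_masks = sm$roi_masks),
    class = "delta_maps"
  )
}

#' @export
print.delta_maps <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Delta-CBF maps (scheme '%s'): %d voxels x %d subjects x 2 replicates (%s)\n",
              x$scheme, d[1], d[2],
              paste(x$replicate_sessions, collapse = ", ")))
  invisible(x)
}

#' @rdname compute_delta
#' @param x A `delta_maps` object.
#' @param ... Unused.
#' @export
as_tibble.delta_maps <- function(x, ...) {
  d <- dim(x$values)
  tibble(
    voxel = rep(seq_len(d[1]), times = d[2] * 2),
    subject = rep(rep(seq_len(d[2]), each = d[1]), times = 2),
    replicate = rep(1:2, each = d[1] * d[2]),
    scheme = x$scheme,
    delta_cbf = as.vector(x$values)
  )
}
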