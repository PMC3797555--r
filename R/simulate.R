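#' Simulate a complete CBF study dataset
#'
#' Generates per-scan CBF volumes with the repeated-measures structure of the
#' pre/post-surgical design and known ground-truth variance components. The
#' value at voxel v for subject i, session s, scan t is
#'
#' `grand_mean + b[i,v] + (delta + g[i,v]) * post(s) * network(v) + e_sess[i,s,v] + e_scan[i,s,t,v]`
#'
#' where `b ~ N(0, sigma_b2)` is a stable per-subject per-voxel baseline,
#' `g ~ N(0, sigma_g2)` the subject's pain-response heterogeneity (constant
#' across both post-surgical sessions), `e_sess ~ N(0, sigma_s2)` is drawn
#' once per (subject, session, voxel) and shared by all scans of that
#' session, and `e_scan ~ N(0, sigma_w2)` is i.i.d. per scan. Voxels are
#' conditionally independent given the subject; no spatial autocorrelation
#' is imposed. The same seed reproduces the dataset exactly.
#'
#' @param design A [study_design()].
#' @param components A [variance_components()] (the stored ground truth).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param gm_mask Logical array of grey-matter voxels on `design$vol_dim`
#'   (default: the whole grid).
#' @param network_mask Logical array, subset of `gm_mask`, receiving the
#'   post-surgical state effect. Default: a contiguous block of
#'   `network_frac` of the GM voxels.
#' @param roi_masks Named list of logical arrays (subsets of the grid).
#'   Default: ten disjoint blocks named after pain-processing regions
#'   (ACC, PCC, aINS, pINS, S1, S2, THAL, HIP, AMY, BS).
#' @param network_frac Fraction of GM voxels in the default network mask.
#' @param keep_latent Keep the per-subject latent effect matrices in the
#'   `truth` slot (needed only for oracle checks).
#' @return An object of class `study_dataset`: a list with `design`,
#'   `components`, the 4-D array `cbf` (voxel x subject x session x scan),
#'   the masks, and `truth` (components plus latent effects).
#' @examples
#' ds <- simulate_study(study_design(4, 2, c(3, 3, 2)), seed = 1)
#' dim(ds$cbf)
#' @export
simulate_study <- function(design = study_design(),
                           components = variance_components(),
                           seed = NULL,
                           gm_mask = NULL,
                           network_mask = NULL,
                           roi_masks = NULL,
                           network_frac = 0.1,
                           keep_latent = TRUE) {
  stopifnot(inherits(design, "study_design"),
            inherits(components, "variance_components"))
  vol_dim <- design$vol_dim
  V <- prod(vol_dim)
  n <- design$n_subjects
  S <- nrow(design$sessions)
  M <- design$scans_per_session

  gm_mask <- gm_mask %||% array(TRUE, vol_dim)
  check_grid(gm_mask, vol_dim, "gm_mask")
  if (is.null(network_mask)) {
    network_mask <- default_network_mask(gm_mask, network_frac)
  }
  check_grid(network_mask, vol_dim, "network_mask")
  if (any(network_mask & !gm_mask)) {
    abort("`network_mask` must be a subset of `gm_mask`.")
  }
  if (is.null(roi_masks)) roi_masks <- default_roi_masks(gm_mask)
  for (nm in names(roi_masks)) check_grid(roi_masks[[nm]], vol_dim, paste0("roi_masks$", nm))

  if (!is.null(seed)) set.seed(as.integer(seed))
  sb <- sqrt(components$sigma_b2)
  ss <- sqrt(components$sigma_s2)
  sg <- sqrt(components$sigma_g2)
  sw <- sqrt(components$sigma_w2)
  net <- as.vector(network_mask)

  b <- matrix(rnorm(V * n, sd = sb), V, n)
  g <- matrix(0, V, n)
  if (any(net)) g[net, ] <- rnorm(sum(net) * n, sd = sg)
  state_add <- components$delta * net # length-V vector, recycled by column

  cbf <- array(NA_real_, dim = c(V, n, S, M))
  for (s in seq_len(S)) {
    base <- components$grand_mean + b +
      matrix(rnorm(V * n, sd = ss), V, n)
    if (design$sessions$state[s] == "post") base <- base + state_add + g
    for (t in seq_len(M)) {
      cbf[, , s, t] <- base + matrix(rnorm(V * n, sd = sw), V, n)
    }
  }
  dimnames(cbf) <- list(NULL, NULL, design$sessions$session, NULL)

  structure(
    list(design = design, components = components, cbf = cbf,
         gm_mask = gm_mask, network_mask = network_mask,
         roi_masks = roi_masks, seed = seed,
         truth = list(components = components,
                      b = if (keep_latent) b else NULL,
                      g = if (keep_latent) g else NULL)),
    class = "study_dataset"
  )
}

check_grid <- function(mask, vol_dim, name) {
  if (!is.logical(mask) || !identical(as.integer(dim(mask)), as.integer(vol_dim))) {
    abort(sprintf(
      "`%s` must be a logical array on the %s grid (got %s).",
      name, paste(vol_dim, collapse = "x"),
      paste(dim(mask) %||% length(mask), collapse = "x")))
  }
  invisible(mask)
}

# Contiguous run (in linear voxel order) of ~frac of the GM voxels.
default_network_mask <- function(gm_mask, frac = 0.1) {
  idx <- which(gm_mask)
  k <- max(1L, round(frac * length(idx)))
  out <- array(FALSE, dim(gm_mask))
  out[idx[seq_len(k)]] <- TRUE
  out
}

# Disjoint blocks spread over the GM voxels, named after the default
# pain-processing regions. Each block takes ~3% of GM (at least 2 voxels);
# on tiny grids fewer than ten regions are placed.
default_roi_masks <- function(gm_mask,
                              names = c("ACC", "PCC", "aINS", "pINS", "S1",
                                        "S2", "THAL", "HIP", "AMY", "BS")) {
  idx <- which(gm_mask)
  size <- max(2L, round(0.03 * length(idx)))
  n_roi <- min(length(names), floor(length(idx) / size))
  if (n_roi < 1) return(list())
  chunk <- floor(length(idx) / n_roi) # >= size by construction
  out <- lapply(seq_len(n_roi), function(i) {
    m <- array(FALSE, dim(gm_mask))
    m[idx[(i - 1) * chunk + seq_len(size)]] <- TRUE
    m
  })
  setNames(out, names[seq_len(n_roi)])
}

#' @export
print.study_dataset <- function(x, ...) {
  d <- x$design
  cat("Simulated CBF study dataset\n")
  print(d)
  cat("  GM voxels:     ", sum(x$gm_mask), "\n")
  cat("  network voxels:", sum(x$network_mask), "\n")
  cat("  ROIs:          ", length(x$roi_masks), "\n")
  invisible(x)
}

#' Long-format view of a study dataset
#'
#' @param ds A [simulate_study()] dataset.
#' @return A tibble with columns `subject`, `session`, `state`, `scan`,
#'   `voxel` (linear index) and `cbf`.
#' @export
cbf_long <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  dd <- dim(ds$cbf)
  V <- dd[1]; n <- dd[2]; S <- dd[3]; M <- dd[4]
  sess <- ds$design$sessions
  tibble(
    subject = rep(rep(seq_len(n), each = V), times = S * M),
    session = rep(rep(sess$session, each = V * n), times = M),
    state   = rep(rep(sess$state, each = V * n), times = M),
    scan    = rep(seq_len(M), each = V * n * S),
    voxel   = rep(seq_len(V), times = n * S * M),
    cbf     = as.vector(ds$cbf)
  )
}

#' VAS generator parameters for one measure
#'
#' @param mean Mean rating on the 0-100 mm scale.
#' @param sigma_b2,sigma_s2,sigma_w2 Between-subject, between-session and
#'   scan-to-scan variances (mm^2).
#' @return A `vas_params` list.
#' @export
vas_params <- function(mean, sigma_b2, sigma_s2, sigma_w2) {
  v <- c(sigma_b2, sigma_s2, sigma_w2)
  if (any(!is.finite(v)) || any(v < 0)) abort("VAS variances must be finite and >= 0.")
  if (!is.finite(mean)) abort("`mean` must be finite.")
  structure(list(mean = mean, sigma_b2 = sigma_b2, sigma_s2 = sigma_s2,
                 sigma_w2 = sigma_w2), class = "vas_params")
}

#' Simulate concurrent VAS ratings
#'
#' Generates one pain and one alertness rating per (subject, session, scan)
#' with subject, session and scan variance components, clipped to the
#' bounded 0-100 mm scale (the number of clipped values is attached as the
#' `"clipped"` attribute). With `floor_effect = TRUE` all pre-surgical pain
#' ratings are exactly zero — subjects are pain-free before surgery — which
#' is what precludes a change-in-VAS reliability analysis. The default pain
#' mean of 60 mm respects the scanning criterion that post-surgical ratings
#' exceed 30/100 mm.
#'
#' @param design A [study_design()].
#' @param pain,alertness [vas_params()] for each measure.
#' @param floor_effect Zero out pre-surgical pain ratings (default `TRUE`).
#' @param seed Integer seed.
#' @return A `vas_table` tibble with columns `subject`, `session`, `state`,
#'   `side` (surgery side for post sessions, `NA` pre), `scan`, `pain`,
#'   `alertness`.
#' @examples
#' vas <- simulate_vas(study_design(4), seed = 1)
#' dplyr::count(vas, state)
#' @export
simulate_vas <- function(design = study_design(),
                         pain = vas_params(60, 225, 25, 9),
                         alertness = vas_params(70, 100, 25, 9),
                         floor_effect = TRUE,
                         seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(pain, "vas_params"), inherits(alertness, "vas_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- design$n_subjects
  S <- nrow(design$sessions)
  M <- design$scans_per_session

  draw <- function(p) {
    subj <- rnorm(n, sd = sqrt(p$sigma_b2))
    sess <- matrix(rnorm(n * S, sd = sqrt(p$sigma_s2)), n, S)
    scan <- array(rnorm(n * S * M, sd = sqrt(p$sigma_w2)), c(n, S, M))
    raw <- p$mean + array(subj, c(n, S, M)) +
      array(sess, c(n, S, M)) + scan
    clipped <- sum(raw < 0 | raw > 100)
    list(values = pmin(pmax(raw, 0), 100), clipped = clipped)
  }
  pv <- draw(pain)
  av <- draw(alertness)

  sess <- design$sessions
  out <- tibble(
    subject = rep(seq_len(n), times = S * M),
    session = rep(rep(sess$session, each = n), times = M),
    state   = rep(rep(sess$state, each = n), times = M),
    scan    = rep(seq_len(M), each = n * S),
    pain      = as.vector(pv$values),
    alertness = as.vector(av$values)
  )
  if (floor_effect) out$pain[out$state == "pre"] <- 0

  sides <- session_sides(design)
  out <- dplyr::left_join(out, sides, by = c("subject", "session"))
  out <- dplyr::arrange(
    out[, c("subject", "session", "state", "side", "scan", "pain", "alertness")],
    .data$subject, .data$session, .data$scan)
  attr(out, "clipped") <- c(pain = pv$clipped, alertness = av$clipped)
  class(out) <- c("vas_table", class(out))
  out
}
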