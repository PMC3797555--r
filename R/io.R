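#' Read and write CBF volumes as NIfTI-1
#'
#' Thin wrappers around RNifti that enforce the pipeline's grid contract:
#' volumes must be 3-D and, when an expected shape is given, match it
#' exactly — a mismatch is a hard error naming both shapes, never a silent
#' resampling. Values round-trip at float32 precision; the affine transform
#' is carried through untouched.
#'
#' @param volume Numeric 3-D array.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param reference Optional NIfTI image or path supplying header/affine.
#' @return `read_cbf_volume()` returns the volume as a numeric array (an
#'   RNifti image, so the affine is retained); `write_cbf_volume()` returns
#'   the path invisibly.
#' @export
write_cbf_volume <- function(volume, path, reference = NULL) {
  if (is.null(dim(volume)) || length(dim(volume)) != 3) {
    abort("`volume` must be a 3-D array.")
  }
  img <- RNifti::asNifti(volume + 0, reference = reference) # +0: drop logical
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @param expect_dim Optional integer vector of length 3; the required grid.
#' @rdname write_cbf_volume
#' @export
read_cbf_volume <- function(path, expect_dim = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) {
    abort(sprintf("'%s' is %d-D; a 3-D volume is required.", path, length(d)))
  }
  if (!is.null(expect_dim) && !identical(as.integer(d), as.integer(expect_dim))) {
    abort(sprintf("Grid mismatch: '%s' is %s but the dataset grid is %s.",
                  path, paste(d, collapse = "x"),
                  paste(expect_dim, collapse = "x")))
  }
  img
}

#' Threshold a probabilistic atlas volume
#'
#' A voxel is included when its probability reaches the cutoff. Inputs on a
#' percent scale (maximum above 1) are detected automatically and divided
#' by 100.
#'
#' @param prob Numeric array of probabilities in `[0, 1]` or percent
#'   `[0, 100]`.
#' @param cutoff Probability cutoff in (0, 1); default 0.2.
#' @return Logical mask with the shape of `prob`.
#' @examples
#' threshold_atlas(array(c(0.19, 0.20, 0.95), c(3, 1, 1)), 0.2)
#' @export
threshold_atlas <- function(prob, cutoff = 0.2) {
  if (any(prob < 0, na.rm = TRUE)) abort("Probabilities must be >= 0.")
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff >= 1) {
    abort("`cutoff` must lie in (0, 1).")
  }
  mx <- max(prob, na.rm = TRUE)
  if (mx > 1) {
    if (mx > 100) abort("Probabilities must be in [0, 1] or percent [0, 100].")
    prob <- prob / 100
  }
  prob >= cutoff
}

#' Exclusive ROI masks from probabilistic atlas volumes
#'
#' Thresholds each probability volume with [threshold_atlas()] and resolves
#' overlaps so that every voxel belongs to at most one ROI: the ROI with the
#' higher probability wins, ties broken by alphabetical ROI name. The number
#' of reassigned overlap voxels is reported.
#'
#' @param prob_list Named list of probability arrays on a common grid.
#' @param cutoff Probability cutoff in (0, 1).
#' @return Named list of disjoint logical masks.
#' @export
exclusive_roi_masks <- function(prob_list, cutoff = 0.2) {
  if (is.null(names(prob_list)) || anyDuplicated(names(prob_list)) > 0 ||
      any(names(prob_list) == "")) {
    abort("`prob_list` must have unique non-empty names.")
  }
  dims <- lapply(prob_list, dim)
  if (length(unique(lapply(dims, as.integer))) != 1) {
    abort("All probability volumes must share one grid.")
  }
  ord <- order(names(prob_list))
  probs <- lapply(prob_list[ord], function(p) {
    if (max(p, na.rm = TRUE) > 1) p <- p / 100
    p
  })
  masks <- lapply(probs, threshold_atlas, cutoff = cutoff)
  pm <- do.call(cbind, lapply(probs, as.vector)) # voxels x ROIs (alpha order)
  mm <- do.call(cbind, lapply(masks, as.vector))
  any_in <- rowSums(mm) > 0
  n_overlap <- sum(rowSums(mm) > 1)
  # winner among thresholded ROIs; which.max takes the first (alphabetical) tie
  winner <- rep(NA_integer_, nrow(pm))
  winner[any_in] <- apply(ifelse(mm, pm, -Inf)[any_in, , drop = FALSE], 1, which.max)
  out <- lapply(seq_along(probs), function(j) {
    m <- array(FALSE, dim(prob_list[[1]]))
    m[which(winner == j)] <- TRUE
    m
  })
  names(out) <- names(probs)
  if (n_overlap > 0) {
    inform(sprintf("%d overlapping voxel(s) assigned to the higher-probability ROI.",
                   n_overlap))
  }
  out[names(prob_list)] # restore the caller's ordering
}

#' Read and write VAS tables as TSV
#'
#' Tab-separated, header row, UTF-8, '.' decimal. Ratings are validated to
#' lie in the 0-100 mm range with one row per (subject, session, scan).
#'
#' @param vas A `vas_table`.
#' @param path TSV file path.
#' @return `read_vas_table()` returns a `vas_table` tibble;
#'   `write_vas_table()` the path, invisibly.
#' @export
write_vas_table <- function(vas, path) {
  check_vas(vas)
  write.table(vas, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_vas_table
#' @export
read_vas_table <- function(path) {
  df <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8"))
  check_vas(df)
  for (m in c("pain", "alertness")) {
    if (any(df[[m]] < 0 | df[[m]] > 100, na.rm = TRUE)) {
      abort(sprintf("'%s' ratings outside the 0-100 mm scale.", m))
    }
  }
  if (anyDuplicated(df[c("subject", "session", "scan")]) > 0) {
    abort("Duplicate (subject, session, scan) rows in VAS table.")
  }
  class(df) <- c("vas_table", class(df))
  df
}

#' Read a run configuration from YAML
#'
#' Any stochastic stage requires a seed: a config without one is refused.
#'
#' @param path YAML file path.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) {
    abort("Config must specify `seed`: stochastic stages refuse to run without one.")
  }
  cfg
}

#' Write a simulated study to disk
#'
#' One NIfTI-1 volume per (subject, session, scan), plus the GM, network and
#' ROI masks, a JSON ground-truth/provenance record, and (if supplied) the
#' VAS table as TSV.
#'
#' @param ds A [simulate_study()] dataset.
#' @param dir Output directory.
#' @param vas Optional `vas_table` to include.
#' @return Invisibly, the directory.
#' @export
write_study <- function(ds, dir, vas = NULL) {
  stopifnot(inherits(ds, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vd <- ds$design$vol_dim
  dd <- dim(ds$cbf)
  for (i in seq_len(dd[2])) {
    for (s in seq_len(dd[3])) {
      for (t in seq_len(dd[4])) {
        write_cbf_volume(
          array(ds$cbf[, i, s, t], vd),
          file.path(dir, sprintf("sub-%02d_%s_scan-%d_cbf.nii.gz",
                                 i, ds$design$sessions$session[s], t)))
      }
    }
  }
  write_cbf_volume(array(as.numeric(ds$gm_mask), vd),
                   file.path(dir, "gm_mask.nii.gz"))
  write_cbf_volume(array(as.numeric(ds$network_mask), vd),
                   file.path(dir, "network_mask.nii.gz"))
  for (nm in names(ds$roi_masks)) {
    write_cbf_volume(array(as.numeric(ds$roi_masks[[nm]]), vd),
                     file.path(dir, sprintf("roi-%s_mask.nii.gz", nm)))
  }
  truth <- list(
    design = list(n_subjects = ds$design$n_subjects,
                  scans_per_session = ds$design$scans_per_session,
                  vol_dim = ds$design$vol_dim,
                  sessions = as.list(ds$design$sessions),
                  side_order = ds$design$side_order),
    components = unclass(ds$components),
    seed = ds$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(vas)) write_vas_table(vas, file.path(dir, "vas.tsv"))
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' Reassembles the dataset from the per-scan NIfTI volumes, masks and the
#' JSON truth record, enforcing a single grid across all files.
#'
#' @param dir Directory written by [write_study()].
#' @return A `study_dataset` (without latent effects).
#' @export
read_study <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  design <- study_design(
    n_subjects = truth$design$n_subjects,
    scans_per_session = truth$design$scans_per_session,
    vol_dim = truth$design$vol_dim,
    side_order = truth$design$side_order)
  comp <- do.call(variance_components, as.list(truth$components))
  vd <- design$vol_dim
  V <- prod(vd)
  S <- nrow(design$sessions)
  cbf <- array(NA_real_, c(V, design$n_subjects, S, design$scans_per_session))
  for (i in seq_len(design$n_subjects)) {
    for (s in seq_len(S)) {
      for (t in seq_len(design$scans_per_session)) {
        f <- file.path(dir, sprintf("sub-%02d_%s_scan-%d_cbf.nii.gz",
                                    i, design$sessions$session[s], t))
        cbf[, i, s, t] <- as.vector(read_cbf_volume(f, expect_dim = vd))
      }
    }
  }
  dimnames(cbf) <- list(NULL, NULL, design$sessions$session, NULL)
  as_mask <- function(f) array(as.vector(read_cbf_volume(f, expect_dim = vd)) > 0.5, vd)
  roi_files <- list.files(dir, pattern = "^roi-.*_mask\\.nii\\.gz$")
  roi_masks <- lapply(roi_files, function(f) as_mask(file.path(dir, f)))
  names(roi_masks) <- sub("^roi-(.*)_mask\\.nii\\.gz$", "\\1", roi_files)
  structure(
    list(design = design, components = comp, cbf = cbf,
         gm_mask = as_mask(file.path(dir, "gm_mask.nii.gz")),
         network_mask = as_mask(file.path(dir, "network_mask.nii.gz")),
         roi_masks = roi_masks, seed = truth$seed,
         truth = list(components = comp, b = NULL, g = NULL)),
    class = "study_dataset")
}
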