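#' Run the full multi-level reliability analysis
#'
#' Orchestrates the three reliability levels on one study dataset:
#' \enumerate{
#'   \item the voxelwise state-contrast ANOVA and the thresholded pain
#'     network;
#'   \item inter-subject voxelwise ICC maps and median summaries for the
#'     pre- and post-surgical states and each requested delta scheme, over
#'     the GM, network and ROI strata, with ICC distribution profiles;
#'   \item within-subject inter-session and intra-session ICC_v tables with
#'     group summaries;
#'   \item the VAS reliability table and the guarded change-in-VAS records,
#'     when a VAS table is supplied.
#' }
#'
#' @param ds A [simulate_study()] dataset.
#' @param vas Optional `vas_table`.
#' @param p_threshold One-sided tail probability for the network threshold.
#' @param schemes Delta schemes to analyse.
#' @param bins Histogram bins for the ICC distributions.
#' @param scan_pairs Scan pairs for the intra-session level.
#' @return An object of class `reliability_report`: a list with `tmap`,
#'   `network` (thresholded mask), `maps`, `med_icc` (tibble of median ICCs
#'   per analysis x stratum), `distributions`, `inter_session` /
#'   `intra_session` tables and summaries, `vas` results and the `params`
#'   echo. Serialize with [write_report()].
#' @export
run_reliability <- function(ds, vas = NULL, p_threshold = 0.01,
                            schemes = c("pairs", "mean", "s2", "s4"),
                            bins = 50, scan_pairs = list(c(1, 3), c(1, 6))) {
  stopifnot(inherits(ds, "study_dataset"))
  schemes <- match.arg(schemes, several.ok = TRUE)
  sm <- session_means(ds)
  tmap <- voxelwise_state_anova(sm)
  network <- threshold_network(tmap, p = p_threshold)

  maps <- list(pre = state_icc_map(sm, "pre"), post = state_icc_map(sm, "post"))
  for (sc in schemes) {
    maps[[paste0("delta_", sc)]] <- delta_icc_map(compute_delta(sm, sc))
  }

  strata <- c(list(gm = ds$gm_mask, network = network), ds$roi_masks)
  med <- tidyr::expand_grid(analysis = names(maps), stratum = names(strata))
  med_rows <- purrr::pmap(med, function(analysis, stratum) {
    map <- maps[[analysis]]
    sel <- map$defined & as.vector(strata[[stratum]])
    tibble(analysis = analysis, stratum = stratum,
           med_icc = if (any(sel)) median(map$icc[sel]) else NA_real_,
           n_voxels = sum(sel),
           n_undefined = sum(as.vector(strata[[stratum]]) &
                               as.vector(map$mask) & !map$defined))
  })
  med_icc <- dplyr::bind_rows(med_rows)

  dists <- list()
  for (analysis in names(maps)) {
    for (stratum in c("gm", "network")) {
      sel <- maps[[analysis]]$defined & as.vector(strata[[stratum]])
      if (sum(sel) >= 2) {
        dists[[paste(analysis, stratum, sep = ".")]] <-
          icc_distribution(maps[[analysis]], strata[[stratum]], bins = bins,
                           stratum = stratum)
      }
    }
  }

  inter_tbl <- intra_tbl <- NULL
  if (length(ds$roi_masks) > 0) {
    inter_tbl <- dplyr::bind_rows(inter_session_iccv(ds, "pre"),
                                  inter_session_iccv(ds, "post"))
    keep <- vapply(scan_pairs, function(p) all(p <= ds$design$scans_per_session),
                   logical(1))
    if (any(keep)) {
      intra_tbl <- intra_session_iccv(ds, scan_pairs = scan_pairs[keep])
    }
  }

  vas_out <- NULL
  if (!is.null(vas)) {
    vas_out <- list(
      table = vas_reliability_table(vas),
      delta_guard = list(pain = delta_vas_guard(vas, "pain"),
                         alertness = delta_vas_guard(vas, "alertness"))
    )
  }

  structure(
    list(tmap = tmap, network = network, maps = maps, med_icc = med_icc,
         distributions = dists,
         inter_session = inter_tbl,
         inter_session_summary = if (!is.null(inter_tbl)) summarise_iccv(inter_tbl),
         intra_session = intra_tbl,
         intra_session_summary = if (!is.null(intra_tbl)) summarise_iccv(intra_tbl),
         vas = vas_out,
         params = list(p_threshold = p_threshold, schemes = schemes,
                       bins = bins, scan_pairs = scan_pairs,
                       seed = ds$seed, design = ds$design,
                       components = ds$components)),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Multi-level CBF/VAS reliability report\n")
  cat(sprintf("  network voxels: %d (p < %.3g)\n",
              sum(as.vector(x$network)), x$params$p_threshold))
  cat("  median ICC by analysis (GM / network):\n")
  gm <- x$med_icc[x$med_icc$stratum == "gm", ]
  nw <- x$med_icc[x$med_icc$stratum == "network", ]
  for (a in unique(gm$analysis)) {
    cat(sprintf("    %-12s %6.3f / %s\n", a,
                gm$med_icc[gm$analysis == a],
                ifelse(is.na(nw$med_icc[nw$analysis == a]), "NA",
                       sprintf("%6.3f", nw$med_icc[nw$analysis == a]))))
  }
  if (!is.null(x$intra_session_summary)) {
    cat(sprintf("  intra-session ICC_v group mean: %.3f\n",
                mean(x$intra_session_summary$icc, na.rm = TRUE)))
  }
  if (!is.null(x$inter_session_summary)) {
    cat(sprintf("  inter-session ICC_v group mean: %.3f\n",
                mean(x$inter_session_summary$icc, na.rm = TRUE)))
  }
  if (!is.null(x$vas)) {
    cat("  VAS reliability table: 8 rows; delta-VAS pain",
        if (x$vas$delta_guard$pain$refused) "refused (floor effect)" else "computed",
        "\n")
  }
  invisible(x)
}

#' Serialize a reliability report
#'
#' Writes the report tables as TSV (tab-separated, header row, '.' decimal)
#' and, optionally, the t map, network mask and ICC maps as NIfTI-1
#' volumes. Given the same dataset (config and seed), the written tables
#' are byte-identical across runs.
#'
#' @param report A [run_reliability()] result.
#' @param dir Output directory (created if needed).
#' @param volumes Also write NIfTI volumes (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, volumes = TRUE) {
  stopifnot(inherits(report, "reliability_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wtsv(report$med_icc, "med_icc.tsv")
  if (length(report$distributions) > 0) {
    dist_long <- dplyr::bind_rows(
      purrr::imap(report$distributions,
                  function(d, nm) dplyr::mutate(tidy(d), analysis = nm)))
    wtsv(dist_long, "icc_distributions.tsv")
  }
  if (!is.null(report$inter_session)) {
    wtsv(report$inter_session, "inter_session_iccv.tsv")
    wtsv(report$inter_session_summary, "inter_session_iccv_summary.tsv")
  }
  if (!is.null(report$intra_session)) {
    wtsv(report$intra_session, "intra_session_iccv.tsv")
    wtsv(report$intra_session_summary, "intra_session_iccv_summary.tsv")
  }
  if (!is.null(report$vas)) {
    wtsv(report$vas$table, "vas_reliability.tsv")
    guard <- dplyr::bind_rows(lapply(report$vas$delta_guard, function(g) {
      tibble(measure = g$measure, refused = g$refused,
             reason = g$reason %||% "",
             icc = if (g$refused) NA_real_ else g$result$icc)
    }))
    wtsv(guard, "delta_vas_guard.tsv")
  }
  if (volumes) {
    vd <- report$params$design$vol_dim
    wvol <- function(v, name) {
      p <- file.path(dir, name)
      write_cbf_volume(array(v, vd), p)
      paths <<- c(paths, p)
    }
    wvol(replace(report$tmap$t, is.na(report$tmap$t), 0), "state_t.nii.gz")
    wvol(as.numeric(as.vector(report$network)), "network_mask.nii.gz")
    for (a in names(report$maps)) {
      wvol(replace(report$maps[[a]]$icc, is.na(report$maps[[a]]$icc), 0),
           paste0("icc_", a, ".nii.gz"))
    }
  }
  invisible(paths)
}
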