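#' Reliability of VAS ratings at one level
#'
#' Computes ICC(3,1) (with CV attached) for a pain or alertness measure at
#' one of the levels of the behavioural analysis. Subjects are the targets
#' throughout:
#' \describe{
#'   \item{inter_subject}{raters are the two post-surgical session means in
#'     chronological order (k = 2); with `layout = "all_scans"`, all
#'     individual post-surgical ratings (k = 2 x scans).}
#'   \item{inter_session}{raters are the left-side vs right-side
#'     post-surgical session means (k = 2).}
#'   \item{intra_session_left / intra_session_right}{raters are the
#'     individual ratings of that side's post-surgical session (k = scans).}
#' }
#' Ratings are session-averaged before the k = 2 comparisons to damp
#' scan-level noise, mirroring the session-mean CBF pipeline. The CV is
#' computed per subject across that level's raters and averaged over
#' subjects.
#'
#' @param vas A `vas_table` ([simulate_vas()] or [read_vas_table()]).
#' @param measure `"pain"` or `"alertness"`.
#' @param level One of the four levels above.
#' @param layout `"session_means"` (default) or `"all_scans"` for the
#'   inter-subject level, whose exact rater layout is ambiguous.
#' @return An `icc_result` with the `cv` slot filled.
#' @export
vas_reliability <- function(vas,
                            measure = c("pain", "alertness"),
                            level = c("inter_subject", "inter_session",
                                      "intra_session_left",
                                      "intra_session_right"),
                            layout = c("session_means", "all_scans")) {
  measure <- match.arg(measure)
  level <- match.arg(level)
  layout <- match.arg(layout)
  check_vas(vas)
  post <- vas[vas$state == "post", , drop = FALSE]
  if (nrow(post) == 0) abort("No post-surgical sessions in the VAS table.")
  if (length(unique(post$subject)) < 2) abort("At least 2 subjects are required.")

  m <- switch(level,
    inter_subject = if (layout == "all_scans") {
      vas_matrix(post, measure, c("session", "scan"))
    } else {
      vas_matrix(session_mean_vas(post, measure), "value", "session")
    },
    inter_session = vas_matrix(session_mean_vas(post, measure), "value", "side"),
    intra_session_left = vas_matrix(post[post$side == "left", ], measure, "scan"),
    intra_session_right = vas_matrix(post[post$side == "right", ], measure, "scan")
  )
  res <- icc_31(m)
  subject_cv <- apply(m, 1, function(r) if (mean(r) == 0) NA_real_ else sd(r) / mean(r))
  res$cv <- if (all(is.na(subject_cv))) NA_real_ else mean(subject_cv, na.rm = TRUE)
  res
}

check_vas <- function(vas) {
  need <- c("subject", "session", "state", "scan", "pain", "alertness")
  if (!is.data.frame(vas) || !all(need %in% names(vas))) {
    abort(paste0("A VAS table needs columns: ", paste(need, collapse = ", "), "."))
  }
  invisible(vas)
}

# Session-mean ratings of one measure; keeps side labels.
session_mean_vas <- function(post, measure) {
  dplyr::summarise(
    dplyr::group_by(post, .data$subject, .data$session, .data$side),
    value = mean(.data[[measure]]), .groups = "drop")
}

# Subjects x raters matrix; `cols` defines the rater ordering.
vas_matrix <- function(df, measure, cols) {
  key <- interaction(df[cols], drop = TRUE, lex.order = TRUE)
  tab <- tapply(df[[measure]], list(factor(df$subject), key), identity)
  if (anyNA(tab)) abort("Incomplete VAS table: missing (subject, session, scan) cells.")
  unclass(tab)
}

#' Table-style VAS reliability summary
#'
#' The eight-row reliability table: each measure (pain, alertness) at each
#' of the four levels, with ICC, CV and the qualitative band.
#'
#' @inheritParams vas_reliability
#' @return A tibble with columns `measure`, `level`, `icc`, `cv`, `band`,
#'   `n_targets`, `k`.
#' @export
vas_reliability_table <- function(vas, layout = c("session_means", "all_scans")) {
  layout <- match.arg(layout)
  grid <- tidyr::expand_grid(
    measure = c("pain", "alertness"),
    level = c("inter_subject", "inter_session", "intra_session_left",
              "intra_session_right"))
  rows <- purrr::pmap(grid, function(measure, level) {
    r <- vas_reliability(vas, measure, level, layout)
    tibble(measure = measure, level = level, icc = r$icc, cv = r$cv,
           band = as.character(r$band), n_targets = r$n_targets, k = r$k)
  })
  dplyr::bind_rows(rows)
}

#' Guarded change-in-VAS reliability
#'
#' The change-in-VAS (post minus pre) reliability is only meaningful when
#' the pre-surgical ratings carry variance. Under the floor effect — all
#' pre-surgical pain ratings exactly zero — the analysis is refused with a
#' structured record (not an error). Otherwise the paired-subtraction scheme
#' is applied to the session-mean ratings (replicate r = post session r
#' minus pre session r) and ICC(3,1) computed over subjects.
#'
#' @param vas A `vas_table`.
#' @param measure `"pain"` (default) or `"alertness"`.
#' @return An object of class `delta_vas`: a list with `measure`, `refused`
#'   (logical), `reason` (when refused) and `result` (an `icc_result`, when
#'   computed).
#' @export
delta_vas_guard <- function(vas, measure = c("pain", "alertness")) {
  measure <- match.arg(measure)
  check_vas(vas)
  pre_vals <- vas[[measure]][vas$state == "pre"]
  if (length(pre_vals) == 0) abort("No pre-surgical sessions in the VAS table.")
  if (var(pre_vals) == 0) {
    return(structure(
      list(measure = measure, refused = TRUE,
           reason = paste0("floor effect: pre-surgical ", measure,
                           " ratings have zero variance"),
           result = NULL),
      class = "delta_vas"))
  }
  sm <- dplyr::summarise(
    dplyr::group_by(vas, .data$subject, .data$session, .data$state),
    value = mean(.data[[measure]]), .groups = "drop")
  sm <- dplyr::arrange(sm, .data$subject, .data$session)
  pre_sess <- sort(unique(sm$session[sm$state == "pre"]))
  post_sess <- sort(unique(sm$session[sm$state == "post"]))
  if (length(pre_sess) != 2 || length(post_sess) != 2) {
    abort("Change-in-VAS needs exactly two pre and two post sessions.")
  }
  wide <- tidyr::pivot_wider(sm[, c("subject", "session", "value")],
                             names_from = "session", values_from = "value")
  d1 <- wide[[post_sess[1]]] - wide[[pre_sess[1]]]
  d2 <- wide[[post_sess[2]]] - wide[[pre_sess[2]]]
  structure(
    list(measure = measure, refused = FALSE, reason = NULL,
         result = icc_31(cbind(d1, d2))),
    class = "delta_vas")
}

#' @export
print.delta_vas <- function(x, ...) {
  if (x$refused) {
    cat(sprintf("Change-in-VAS (%s): refused — %s\n", x$measure, x$reason))
  } else {
    cat(sprintf("Change-in-VAS (%s):\n", x$measure))
    print(x$result)
  }
  invisible(x)
}
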