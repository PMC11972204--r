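#' Extract onset-locked trials from a cluster time course
#'
#' The cluster time course (voxel-pooled average) is cut into trials at
#' event onsets. Onsets snap to the nearest earlier TR sample (no temporal
#' interpolation); each trial is converted to percent signal change
#' relative to its onset sample, `(t - t0) / t0 * 100`, so every trial is 0
#' at offset 0. Trials whose onset value is 0 or whose window exceeds the
#' run are flagged invalid and dropped.
#'
#' @param timecourse Numeric cluster-average series (one value per volume).
#' @param events Events table rows to extract (one trial per row).
#' @param tr_s Repetition time (s).
#' @param window_tr Number of TR offsets after onset (trial length is
#'   `window_tr + 1` samples, offsets `0:window_tr`).
#' @return List with `psc` (trials x offsets matrix), `duration_s`,
#'   `condition` per trial, and `n_invalid`.
#' @export
extract_trials <- function(timecourse, events, tr_s, window_tr = 5) {
  n <- length(timecourse)
  if (any(events$onset < 0) || any(events$onset >= n * tr_s)) {
    stop("event onset outside run", call. = FALSE)
  }
  i0 <- floor(events$onset / tr_s) + 1L
  valid <- (i0 + window_tr) <= n
  keep <- which(valid)
  t0 <- timecourse[i0[keep]]
  good <- is.finite(t0) & t0 != 0
  n_t0 <- sum(!good)
  keep <- keep[good]
  idx <- outer(i0[keep], 0:window_tr, `+`)
  vals <- matrix(timecourse[idx], nrow = length(keep), ncol = window_tr + 1L)
  psc <- (vals - vals[, 1L]) / vals[, 1L] * 100
  colnames(psc) <- paste0("tr", 0:window_tr)
  list(psc = psc, duration_s = events$duration[keep],
       condition = events$trial_type[keep],
       n_invalid = sum(!valid) + n_t0)
}

#' Select trials by minimum duration
#'
#' Drops trials shorter than `min_duration_s` (default 10 s = 5 TR at TR
#' 2 s), so every retained trial spans the full analysis window; longer
#' trials are already truncated to the window by extraction, giving the
#' balanced average (equal trial count at every time point).
#'
#' @param trials From [extract_trials()].
#' @param min_duration_s Minimum trial duration (s).
#' @return Filtered trial set; errors if no trial survives.
#' @export
select_trials <- function(trials, min_duration_s = 10) {
  keep <- trials$duration_s >= min_duration_s
  if (!any(keep)) stop("no trials survive duration selection", call. = FALSE)
  list(psc = trials$psc[keep, , drop = FALSE],
       duration_s = trials$duration_s[keep],
       condition = trials$condition[keep],
       n_invalid = trials$n_invalid, n_excluded = sum(!keep))
}

#' Event-related averages pooled over cluster roles
#'
#' Pools trials into the preferred role (H cluster on horizontal trials
#' together with V cluster on vertical trials) and the not-preferred role
#' (the crossed pairs) and averages within role.
#'
#' @param trials_h,trials_v Selected trial sets of the H and V cluster
#'   time courses (each containing horizontal and vertical trials).
#' @return List of matrices `preferred` and `not_preferred` (pooled trials
#'   x offsets) and the per-role mean curves.
#' @export
pool_roles_and_average <- function(trials_h, trials_v) {
  pick <- function(tr, cond) tr$psc[tr$condition == cond, , drop = FALSE]
  pref <- rbind(pick(trials_h, "horizontal"), pick(trials_v, "vertical"))
  nonpref <- rbind(pick(trials_h, "vertical"), pick(trials_v, "horizontal"))
  if (nrow(pref) == 0L || nrow(nonpref) == 0L) {
    stop("missing role: a cluster contributed no trials", call. = FALSE)
  }
  list(preferred = pref, not_preferred = nonpref,
       curve_preferred = colMeans(pref),
       curve_not_preferred = colMeans(nonpref))
}

#' Group ERA curve with SEM over subjects
#'
#' @param subject_curves Matrix subjects x offsets.
#' @return Data frame: tr_offset, mean_psc, sem_psc, n.
#' @export
group_era_curve <- function(subject_curves) {
  data.frame(tr_offset = seq_len(ncol(subject_curves)) - 1L,
             mean_psc = colMeans(subject_curves),
             sem_psc = apply(subject_curves, 2, sem),
             n = nrow(subject_curves))
}

#' Temporal similarity of two ERA curves across subjects
#'
#' Per subject, the Spearman rank correlation between the paired curves on
#' the post-onset window (offset 0 is identically zero by construction and
#' is excluded); the resulting correlations are tested against zero with
#' the two-sided exact Wilcoxon signed-rank test. Subjects with a constant
#' curve (undefined rho) are dropped with a warning.
#'
#' @param curves_a,curves_b Matrices subjects x offsets (including offset
#'   0 as the first column).
#' @param drop_onset Exclude the offset-0 column before correlating.
#' @return List with `rho` (per subject), `mean_rho`, `p`, `statistic`,
#'   `n`, `method`.
#' @export
similarity_test <- function(curves_a, curves_b, drop_onset = TRUE) {
  stopifnot(nrow(curves_a) == nrow(curves_b), ncol(curves_a) == ncol(curves_b))
  cols <- if (drop_onset) -1L else seq_len(ncol(curves_a))
  rho <- vapply(seq_len(nrow(curves_a)), function(i) {
    spearman_rho(curves_a[i, cols], curves_b[i, cols])
  }, numeric(1))
  if (anyNA(rho)) {
    warning(sum(is.na(rho)), " subject(s) dropped: constant curve, rho undefined",
            call. = FALSE)
  }
  ok <- !is.na(rho)
  w <- wilcoxon_signed_rank(rho[ok])
  c(list(rho = rho, mean_rho = mean(rho[ok])), w)
}
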