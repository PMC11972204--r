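#' Winner-take-all cluster definition by contrast percentile
#'
#' Within an ROI (computed per hemisphere), voxels whose horizontal >
#' vertical contrast t exceeds the `pct`-th percentile of in-ROI t form the
#' horizontal cluster; by symmetry, voxels below the `(100 - pct)`-th
#' percentile form the vertical cluster (equivalently the same rule on the
#' vertical > horizontal contrast). Percentiles use linear interpolation
#' (type 7); threshold comparisons are strict, so ties at the threshold are
#' excluded and each cluster holds at most `100 - pct` percent of the ROI.
#'
#' @param tmap Numeric t values for H > V, one per in-ROI voxel.
#' @param pct Percentile threshold in (50, 100); default 95.
#' @return A `cluster_assignment` list: `label` (factor H/V/none per
#'   voxel), `threshold_hi`, `threshold_lo`, `pct`.
#' @export
define_clusters <- function(tmap, pct = 95) {
  stopifnot(pct > 50, pct < 100)
  n <- length(tmap)
  if (n < ceiling(1 / (1 - pct / 100))) {
    stop("degenerate clusters: ROI smaller than 1/(1 - pct/100) voxels",
         call. = FALSE)
  }
  if (diff(range(tmap)) < 1e-12) {
    stop("degenerate clusters: no percentile separation (all t equal)",
         call. = FALSE)
  }
  hi <- as.numeric(stats::quantile(tmap, pct / 100, type = 7))
  lo <- as.numeric(stats::quantile(tmap, 1 - pct / 100, type = 7))
  label <- rep("none", n)
  label[tmap > hi] <- "H"
  label[tmap < lo] <- "V"
  structure(list(label = label, threshold_hi = hi, threshold_lo = lo, pct = pct),
            class = "cluster_assignment")
}

#' Cluster-mean percent signal change per condition type
#'
#' For each cluster, the mean over member voxels of the preferred-condition
#' beta (horizontal beta for the H cluster, vertical for V), separately for
#' the physical and ambiguous condition types.
#'
#' @param assignment A [define_clusters()] result.
#' @param betas_physical,betas_ambiguous Voxel x condition PSC beta
#'   matrices from [task_betas()].
#' @return Data frame with columns cluster, condition_type, mean_psc,
#'   n_voxels (empty clusters yield NA with n_voxels = 0).
#' @export
summarize_cluster_psc <- function(assignment, betas_physical, betas_ambiguous) {
  pref <- c(H = "horizontal", V = "vertical")
  grid <- expand.grid(condition_type = c("physical", "ambiguous"),
                      cluster = c("H", "V"), stringsAsFactors = FALSE)
  vals <- mapply(function(cl, ct) {
    members <- assignment$label == cl
    B <- if (ct == "physical") betas_physical else betas_ambiguous
    c(if (any(members)) mean(B[members, pref[[cl]]]) else NA_real_,
      sum(members))
  }, grid$cluster, grid$condition_type)
  data.frame(cluster = grid$cluster, condition_type = grid$condition_type,
             mean_psc = vals[1, ], n_voxels = vals[2, ],
             stringsAsFactors = FALSE)
}

#' Paired group comparison of physical vs ambiguous summaries
#'
#' Two-sided Wilcoxon signed-rank test on paired per-(subject, hemisphere)
#' values; exact for N <= 25 (see [wilcoxon_signed_rank()]), normal
#' approximation above or on request.
#'
#' @param physical,ambiguous Paired numeric vectors, one value per
#'   measurement unit.
#' @param mode Passed to [wilcoxon_signed_rank()].
#' @return List with `p`, `statistic`, `n`, `method`, `defined`,
#'   `mean_physical`, `mean_ambiguous`.
#' @export
compare_conditions <- function(physical, ambiguous, mode = "auto") {
  if (length(physical) != length(ambiguous)) {
    stop("unpaired inputs", call. = FALSE)
  }
  ok <- is.finite(physical) & is.finite(ambiguous)
  w <- wilcoxon_signed_rank(physical[ok], ambiguous[ok], mode = mode)
  c(w, list(mean_physical = mean(physical[ok]),
            mean_ambiguous = mean(ambiguous[ok])))
}

#' Subject-level motion quality control
#'
#' A subject is excluded when any run's maximum absolute motion exceeds
#' twice the voxel size (strictly; motion exactly at the threshold is
#' retained).
#'
#' @param motion_max_mm Per-run maximum absolute motion (mm); must be
#'   complete.
#' @param voxel_size_mm Acquisition voxel size (mm), default 0.8.
#' @return TRUE to include the subject, FALSE to exclude.
#' @export
apply_subject_qc <- function(motion_max_mm, voxel_size_mm = 0.8) {
  if (length(motion_max_mm) == 0L || any(is.na(motion_max_mm))) {
    stop("missing motion record", call. = FALSE)
  }
  all(motion_max_mm <= 2 * voxel_size_mm)
}
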