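#' Equivolume depth tertile bins
#'
#' Default three-layer binning of equivolume depth into deep, middle and
#' superficial layers with equal-width edges on `[0, 1]`.
#'
#' @param n_bins Number of layers (default 3).
#' @return List with `edges` and `centers` (bin midpoints, the slope
#'   regressor).
#' @export
depth_bins <- function(n_bins = 3) {
  stopifnot(n_bins >= 3)
  edges <- seq(0, 1, length.out = n_bins + 1)
  list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2,
       labels = if (n_bins == 3) c("deep", "middle", "superficial")
                else paste0("layer", seq_len(n_bins)))
}

#' Extend clusters through the cortical depth, column-wise
#'
#' A cylinder of tangential radius `radius` (height = local thickness)
#' around each column center inherits a cluster label when any assigned
#' voxel lies within the radius in (u, v); the entire depth of the column
#' is then labeled. When both H and V voxels fall within the radius, the
#' nearest assigned voxel wins. With `radius = 0` only columns already
#' containing assigned voxels are labeled.
#'
#' @param assignment A [define_clusters()] result on the patch's voxels.
#' @param patch Patch from [make_patch()].
#' @param radius Tangential extension radius in (u, v) units; default 0.39.
#' @return A `cluster_assignment` with column-extended labels.
#' @export
extend_clusters_columnwise <- function(assignment, patch, radius = 0.39) {
  stopifnot(radius >= 0, length(assignment$label) == nrow(patch))
  assigned <- which(assignment$label != "none")
  label <- rep("none", nrow(patch))
  if (length(assigned)) {
    cols <- unique(patch$column)
    for (cid in cols) {
      in_col <- patch$column == cid
      cu <- patch$u0[in_col][1]; cv <- patch$v0[in_col][1]
      dd <- sqrt((patch$u[assigned] - cu)^2 + (patch$v[assigned] - cv)^2)
      near <- dd <= radius + 1e-12
      # radius 0: keep the limiting case of columns with their own voxels
      if (radius == 0) near <- assigned %in% which(in_col)
      if (any(near)) {
        pick <- assigned[near][which.min(dd[near])]
        label[in_col] <- assignment$label[pick]
      }
    }
  }
  structure(list(label = label, threshold_hi = assignment$threshold_hi,
                 threshold_lo = assignment$threshold_lo, pct = assignment$pct,
                 extended_radius = radius),
            class = "cluster_assignment")
}

#' Laminar profile of cluster PSC betas
#'
#' Layer means (and SEM, voxel counts) of the preferred-condition PSC beta
#' within each extended cluster, per condition type.
#'
#' @param assignment Extended [cluster_assignment].
#' @param patch Patch (provides equivolume depths).
#' @param betas_physical,betas_ambiguous Voxel x condition PSC betas.
#' @param bins From [depth_bins()].
#' @return Data frame: cluster, condition_type, layer, depth_center,
#'   mean_psc, sem_psc, n_voxels.
#' @export
laminar_profile <- function(assignment, patch, betas_physical, betas_ambiguous,
                            bins = depth_bins()) {
  pref <- c(H = "horizontal", V = "vertical")
  layer <- cut(patch$d_ev, breaks = bins$edges, labels = bins$labels,
               include.lowest = TRUE)
  nb <- length(bins$labels)
  cl_v <- ct_v <- lay_v <- character(0)
  dc_v <- mu_v <- se_v <- nn_v <- numeric(0)
  for (cl in c("H", "V")) {
    members <- assignment$label == cl
    if (!any(members)) next
    lay <- layer[members]
    for (ct in c("physical", "ambiguous")) {
      B <- if (ct == "physical") betas_physical else betas_ambiguous
      vals <- B[members, pref[[cl]]]
      for (li in seq_len(nb)) {
        sel <- lay == bins$labels[li]
        if (!any(sel)) {
          stop(sprintf("empty layer '%s' in cluster %s", bins$labels[li], cl),
               call. = FALSE)
        }
        cl_v <- c(cl_v, cl); ct_v <- c(ct_v, ct); lay_v <- c(lay_v, bins$labels[li])
        dc_v <- c(dc_v, bins$centers[li]); mu_v <- c(mu_v, mean(vals[sel]))
        se_v <- c(se_v, sem(vals[sel])); nn_v <- c(nn_v, sum(sel))
      }
    }
  }
  data.frame(cluster = cl_v, condition_type = ct_v, layer = lay_v,
             depth_center = dc_v, mean_psc = mu_v, sem_psc = se_v,
             n_voxels = nn_v, stringsAsFactors = FALSE)
}

#' Differential laminar profile (physical minus ambiguous)
#'
#' Layer-wise difference of the two condition types' profiles, with SEMs
#' propagated in quadrature.
#'
#' @param profile Output of [laminar_profile()] (both condition types), or
#'   two separate profiles via `profile_ambiguous`.
#' @param profile_ambiguous Optional separate ambiguous profile when
#'   `profile` holds only the physical one.
#' @return Data frame: cluster, layer, depth_center, diff_psc, sem_diff.
#' @export
differential_profile <- function(profile, profile_ambiguous = NULL) {
  if (is.null(profile_ambiguous)) {
    phys <- profile[profile$condition_type == "physical", ]
    amb <- profile[profile$condition_type == "ambiguous", ]
  } else {
    phys <- profile; amb <- profile_ambiguous
  }
  key <- function(d) paste(d$cluster, d$layer)
  if (!identical(sort(key(phys)), sort(key(amb)))) {
    stop("layer/cluster mismatch between condition types", call. = FALSE)
  }
  amb <- amb[match(key(phys), key(amb)), ]
  data.frame(cluster = phys$cluster, layer = phys$layer,
             depth_center = phys$depth_center,
             diff_psc = phys$mean_psc - amb$mean_psc,
             sem_diff = sqrt(ifelse(is.na(phys$sem_psc), 0, phys$sem_psc)^2 +
                             ifelse(is.na(amb$sem_psc), 0, amb$sem_psc)^2),
             stringsAsFactors = FALSE)
}

#' Slope of a differential laminar profile
#'
#' OLS slope of the layer differences against the bin centers in
#' normalized depth (1/6, 1/2, 5/6 for tertiles), so units are PSC per unit
#' cortical depth; exact for affine profiles.
#'
#' @param diff_psc Layer differences (deep to superficial).
#' @param centers Depth bin centers.
#' @return Slope (PSC / unit depth).
#' @export
profile_slope <- function(diff_psc, centers = depth_bins()$centers) {
  if (length(diff_psc) < 3L) stop("need at least 3 layers", call. = FALSE)
  stats::coef(stats::lm(diff_psc ~ centers))[["centers"]]
}

#' Group test of differential-profile slopes against zero
#'
#' Per subject, the differential-profile slope averaged across the two
#' clusters (and hemispheres); the resulting per-subject slopes are tested
#' against the null (median zero) with the two-sided exact Wilcoxon
#' signed-rank test.
#'
#' @param slopes Per-subject average slopes (one per subject per ROI).
#' @return List with `mean_slope`, `p`, `statistic`, `n`, `method`,
#'   `defined`.
#' @export
slope_test <- function(slopes) {
  slopes <- slopes[is.finite(slopes)]
  w <- wilcoxon_signed_rank(slopes)
  c(list(mean_slope = mean(slopes)), w)
}
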