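#' Equivolume depth from equidistant depth and local curvature
#'
#' Implements the equal-volume principle on a curved-ribbon (annulus)
#' model: at positive curvature the white-matter surface is the inner arc
#' of radius `1/curvature`, and the equivolume depth of a point at
#' equidistant depth `d` is its enclosed area fraction
#' `((r0 + d*t)^2 - r0^2) / ((r0 + t)^2 - r0^2)`. Negative curvature
#' (sulcal wall, pial side inner) mirrors the rule. At zero curvature the
#' equivolume depth equals the equidistant depth (flat-cortex limit).
#'
#' @param d Equidistant depth in `[0, 1]` (0 = white-matter side).
#' @param curvature Signed local curvature (1/thickness units).
#' @param thickness Local cortical thickness in the same units.
#' @return Equivolume depth in `[0, 1]`.
#' @export
equivolume_depth <- function(d, curvature, thickness = 1) {
  stopifnot(all(d >= 0 & d <= 1), thickness > 0)
  k <- rep_len(curvature, length(d))
  out <- numeric(length(d))
  ring <- function(dd, kk) {
    r0 <- 1 / abs(kk)
    ((r0 + dd * thickness)^2 - r0^2) / ((r0 + thickness)^2 - r0^2)
  }
  flat <- abs(k) < 1e-12
  out[flat] <- d[flat]
  pos <- !flat & k > 0
  out[pos] <- ring(d[pos], k[pos])
  neg <- !flat & k < 0
  out[neg] <- 1 - ring(1 - d[neg], k[neg])
  out
}

#' Generate a ground-truthed cortical patch
#'
#' Columns are laid out on a tangential (u, v) grid with unit spacing and
#' assigned interleaved horizontal/vertical preference labels in stripes
#' along u (with an optional unlabeled remainder). Each column holds
#' `voxels_per_column` voxels at jittered tangential positions and
#' equidistant depths spanning the full thickness; a per-column signed
#' curvature converts equidistant to equivolume depth. Cluster labels are
#' constant within a column, emulating the columnar functional
#' organization.
#'
#' @param n_columns Number of columns (laid out on a near-square grid).
#' @param voxels_per_column Voxels per column (>= 3 to span three layers).
#' @param cluster_fractions Named fractions for H and V columns (sum <= 1;
#'   the remainder is unlabeled).
#' @param roi ROI label ("V1" or "hMT").
#' @param curvature_sd SD of the per-column signed curvature.
#' @param uv_jitter_sd SD of the tangential voxel jitter (grid units).
#' @param gain_sd SD (log scale) of the per-voxel multiplicative response
#'   gain emulating vascular-density and partial-volume heterogeneity; the
#'   gain is a fixed voxel property shared by all conditions and runs
#'   (unit mean).
#' @param seed Integer seed.
#' @return Data frame (one row per voxel): voxel, column, u, v, u0, v0
#'   (column center), d_eq, d_ev, curvature, gain, roi, true_cluster.
#' @export
make_patch <- function(n_columns = 16, voxels_per_column = 6,
                       cluster_fractions = c(H = 0.5, V = 0.5),
                       roi = "V1", curvature_sd = 0.3,
                       uv_jitter_sd = 0.12, gain_sd = 0.3, seed = 1) {
  if (voxels_per_column < 3L) {
    stop("voxels_per_column must be >= 3 to span three layers", call. = FALSE)
  }
  if (sum(cluster_fractions) > 1 + 1e-9) {
    stop("cluster fractions must sum to <= 1", call. = FALSE)
  }
  n_h <- round(n_columns * cluster_fractions[["H"]])
  n_v <- round(n_columns * cluster_fractions[["V"]])
  if (n_h + n_v > n_columns) n_v <- n_columns - n_h
  labels <- rep("none", n_columns)
  # interleave H and V stripes over the first n_h + n_v columns
  hv <- rep(c("H", "V"), length.out = n_h + n_v)
  # rebalance the alternating pattern to honor the requested counts
  if (sum(hv == "H") != n_h) {
    hv <- c(rep(c("H", "V"), min(n_h, n_v)),
            rep(if (n_h > n_v) "H" else "V", abs(n_h - n_v)))
  }
  labels[seq_along(hv)] <- hv
  ncol_grid <- ceiling(sqrt(n_columns))
  gu <- ((seq_len(n_columns) - 1L) %% ncol_grid)
  gv <- ((seq_len(n_columns) - 1L) %/% ncol_grid)
  m <- voxels_per_column
  nv <- n_columns * m
  col_id <- rep(seq_len(n_columns), each = m)
  patch <- with_seed(seed, {
    curv <- pmax(pmin(stats::rnorm(n_columns, 0, curvature_sd), 0.8), -0.8)
    d_eq <- rep((seq_len(m) - 0.5) / m, n_columns) +
      stats::runif(nv, -0.2 / m, 0.2 / m)
    d_eq <- pmin(pmax(d_eq, 0), 1)
    gain <- stats::rlnorm(nv, meanlog = -gain_sd^2 / 2, sdlog = gain_sd)
    data.frame(
      voxel = seq_len(nv),
      column = col_id,
      u = gu[col_id] + stats::rnorm(nv, 0, uv_jitter_sd),
      v = gv[col_id] + stats::rnorm(nv, 0, uv_jitter_sd),
      u0 = gu[col_id], v0 = gv[col_id],
      d_eq = d_eq,
      d_ev = equivolume_depth(d_eq, curv[col_id]),
      curvature = curv[col_id],
      gain = gain,
      roi = roi,
      true_cluster = labels[col_id],
      stringsAsFactors = FALSE
    )
  })
  patch
}
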