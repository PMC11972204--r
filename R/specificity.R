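#' Voxel-wise condition specificity
#'
#' Cosine-similarity selectivity of a voxel's (horizontal, vertical) beta
#' pair for its winning condition. Negative betas are clamped to zero; `c`
#' is the cosine between the clamped pair and the winner's axis, rescaled
#' as `s = (c - cos 45) / (1 - cos 45)` so that an equal-response voxel
#' scores 0 and a purely selective voxel scores 1. The score is invariant
#' to positive scaling of the beta pair. Voxels with both betas <= 0 are
#' undefined (NA). The formula is isolated here so an alternative
#' definition can be swapped in without touching callers.
#'
#' @param beta_h,beta_v PSC betas (vectorized).
#' @param clamp Clamp negative betas to zero before the cosine (default);
#'   with `FALSE`, obtuse angles give negative scores truncated at 0.
#' @return Specificity in `[0, 1]` (NA where undefined), with attribute
#'   `winner` ("horizontal"/"vertical").
#' @export
voxel_specificity <- function(beta_h, beta_v, clamp = TRUE) {
  stopifnot(length(beta_h) == length(beta_v))
  undef <- beta_h <= 0 & beta_v <= 0
  h <- beta_h; v <- beta_v
  if (clamp) {
    h <- pmax(h, 0); v <- pmax(v, 0)
  }
  winner <- ifelse(h >= v, "horizontal", "vertical")
  norm <- sqrt(h^2 + v^2)
  cosine <- pmax(h, v) / norm
  c45 <- cos(pi / 4)
  s <- (cosine - c45) / (1 - c45)
  s <- pmin(pmax(s, 0), 1)
  s[undef | norm == 0] <- NA_real_
  attr(s, "winner") <- winner
  s
}

#' Cluster-mean specificity per condition type
#'
#' @param assignment A [define_clusters()] result.
#' @param betas_physical,betas_ambiguous Voxel x condition PSC betas.
#' @param clamp Passed to [voxel_specificity()].
#' @return Data frame with columns cluster, condition_type,
#'   mean_specificity, sem_specificity, n_voxels (defined voxels only).
#' @export
cluster_specificity <- function(assignment, betas_physical, betas_ambiguous,
                                clamp = TRUE) {
  grid <- expand.grid(condition_type = c("physical", "ambiguous"),
                      cluster = c("H", "V"), stringsAsFactors = FALSE)
  vals <- mapply(function(cl, ct) {
    members <- assignment$label == cl
    B <- if (ct == "physical") betas_physical else betas_ambiguous
    s <- voxel_specificity(B[members, "horizontal"], B[members, "vertical"],
                           clamp = clamp)
    s <- s[!is.na(s)]
    c(if (length(s)) mean(s) else NA_real_, sem(s), length(s))
  }, grid$cluster, grid$condition_type)
  data.frame(cluster = grid$cluster, condition_type = grid$condition_type,
             mean_specificity = vals[1, ], sem_specificity = vals[2, ],
             n_voxels = vals[3, ], stringsAsFactors = FALSE)
}
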