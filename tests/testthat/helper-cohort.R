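# Shared small-cohort fixtures, memoized so several test files can reuse
# the same analyzed hypothesis-2 pipeline run.

.fixtures <- new.env(parent = emptyenv())

demo_config <- function(...) {
  pipeline_config(seed = 42, runs_per_condition = 2, n_columns = 12,
                  voxels_per_column = 6, repetitions = 3, ...)
}

demo_result <- function() {
  if (is.null(.fixtures$demo)) .fixtures$demo <- run_pipeline(demo_config())
  .fixtures$demo
}

# power-study configuration: study cohort structure (8 subjects x 2
# hemispheres) at the simulation scale used for parameter-recovery checks
power_config <- function(seed, ...) {
  pipeline_config(seed = seed, runs_per_condition = 3, n_columns = 16,
                  voxels_per_column = 9, repetitions = 3, ...)
}

# small cohorts for replicate loops (type-I calibration)
calib_config <- function(seed, scenario, ...) {
  pipeline_config(seed = seed, scenario = scenario, runs_per_condition = 2,
                  n_columns = 8, voxels_per_column = 5, repetitions = 3, ...)
}

# ground-truth (selection-free) cluster assignment for a patch
truth_assignment <- function(patch) {
  structure(list(label = patch$true_cluster, threshold_hi = NA_real_,
                 threshold_lo = NA_real_, pct = NA_real_),
            class = "cluster_assignment")
}

# brute-force exact two-sided signed-rank p by full 2^N enumeration
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
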