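# Shared configuration for the analysis workflow.
#
# Cohort structure follows the study (8 subjects x 2 hemispheres, TR 2 s,
# 10-s motion blocks, 16-s flicker, 20-s fixation bookends); simulation
# sizes (runs, super-block repetitions, patch size) are scaled for desktop
# runtimes. Everything downstream is reproducible from this file.

library(layerquartet)

SEED <- 20260920
CONFIG <- pipeline_config(seed = SEED, scenario = "hypothesis2",
                          runs_per_condition = 3, n_columns = 16,
                          voxels_per_column = 9, repetitions = 3)

RESULTS <- "results"
FIGDIR <- file.path(RESULTS, "figures")
dir.create(FIGDIR, showWarnings = FALSE, recursive = TRUE)

# pipeline results are deterministic given CONFIG; later scripts re-run the
# pipeline rather than deserializing bulky intermediates
get_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(CONFIG)
    cache
  }
})
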