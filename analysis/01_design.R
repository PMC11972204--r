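#!/usr/bin/env Rscript
# Stimulus schedules for the physical and ambiguous motion quartet.
#
# Builds the frame timing and the block schedules, verifies the
# design arithmetic (2.3 Hz apparent-motion cycle, 80-s super-blocks,
# 48 motion blocks per run), simulates one percept-report stream and its
# switch-rate screening, and writes BIDS-dialect events tables.

source("analysis/00_config.R")

timing <- stimulus_timing()
phys <- build_physical_schedule()
amb <- build_ambiguous_schedule(seed = SEED)

arith <- data.frame(
  quantity = c("cycle_frequency_hz", "pair_flash_ms", "interstimulus_ms",
               "motion_superblock_s", "motion_blocks_per_run",
               "run_duration_s", "run_volumes"),
  value = c(cycle_frequency(timing),
            timing$pair_on_frames / timing$refresh_hz * 1000,
            round(timing$isi_frames / timing$refresh_hz * 1000),
            80, sum(phys$events$trial_type %in% c("horizontal", "vertical")),
            phys$total_s, phys$n_volumes))
write_table_tsv(arith, file.path(RESULTS, "design_arithmetic.tsv"))
print(arith)

write_events(phys$events, file.path(RESULTS, "events_physical.tsv"))
write_events(amb$events, file.path(RESULTS, "events_ambiguous.tsv"))

percepts <- amb$events[amb$events$source == "percept", ]
cat(sprintf("percept stream: %d percepts, dwell %.1f-%.1f s (mean %.1f s)\n",
            nrow(percepts), min(percepts$duration), max(percepts$duration),
            mean(percepts$duration)))
cat("switch-rate screening (<= 5 s between switches):",
    if (screen_switch_rate(amb$events)) "pass" else "fail", "\n")
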