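#!/usr/bin/env Rscript
# Laminar profiles, differential profiles, and slope tests.
#
# Averages per-unit laminar profiles to the group, computes the
# physical-minus-ambiguous differential profile per cluster, and tests the
# per-subject differential slope (averaged over clusters and hemispheres)
# against zero. The shared draining-vein component cancels in the
# differential; under hypothesis 2 the V1 differential keeps a positive
# slope (feedforward drainage present only in the physical condition at
# full amplitude) while hMT+ stays flat.

source("analysis/00_config.R")
library(ggplot2)

prof <- read_table_tsv(file.path(RESULTS, "unit_laminar_profiles.tsv"))
slopes <- read_table_tsv(file.path(RESULTS, "unit_slopes.tsv"))

grp <- aggregate(mean_psc ~ roi + cluster + condition_type + layer + depth_center,
                 prof, mean)
grp$sem_psc <- aggregate(mean_psc ~ roi + cluster + condition_type + layer +
                           depth_center, prof,
                         function(x) sd(x) / sqrt(length(x)))$mean_psc
write_table_tsv(grp, file.path(RESULTS, "group_laminar_profiles.tsv"))

rows <- list()
for (roi in unique(slopes$roi)) {
  s <- aggregate(slope ~ subject, slopes[slopes$roi == roi, ], mean)$slope
  t <- slope_test(s)
  rows[[length(rows) + 1L]] <- data.frame(
    roi = roi, n_subjects = t$n, mean_slope = t$mean_slope,
    statistic = t$statistic, p = t$p)
}
tests <- do.call(rbind, rows)
write_table_tsv(tests, file.path(RESULTS, "slope_group_tests.tsv"))
print(tests, digits = 3)

grp$layer <- factor(grp$layer, c("deep", "middle", "superficial"))
gp <- ggplot(grp, aes(layer, mean_psc, group = condition_type,
                      linetype = condition_type)) +
  geom_line() +
  geom_pointrange(aes(ymin = mean_psc - sem_psc, ymax = mean_psc + sem_psc),
                  size = 0.2) +
  facet_grid(roi ~ cluster) +
  labs(x = NULL, y = "mean PSC (%)",
       title = "Group laminar profiles by condition type") +
  theme_minimal()
ggsave(file.path(FIGDIR, "laminar_profiles.pdf"), gp, width = 6.5, height = 5)
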