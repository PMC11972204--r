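#!/usr/bin/env Rscript
# Voxel selectivity (cosine specificity) by condition type.
#
# Averages the rescaled-cosine specificity over cluster voxels, then over
# clusters and hemispheres, giving one value per subject, ROI and condition
# type; compares condition types with the exact Wilcoxon signed-rank test.
# Under hypothesis 2 both V1 clusters respond equally during ambiguity, so
# ambiguous specificity collapses toward 0 while physical stays near 1.

source("analysis/00_config.R")
library(ggplot2)

spec <- read_table_tsv(file.path(RESULTS, "unit_specificity.tsv"))

subject_mean <- function(d) {
  agg <- aggregate(mean_specificity ~ subject, d, mean)
  agg[order(agg$subject), "mean_specificity"]
}

rows <- list()
for (roi in unique(spec$roi)) {
  d <- spec[spec$roi == roi, ]
  p <- subject_mean(d[d$condition_type == "physical", ])
  a <- subject_mean(d[d$condition_type == "ambiguous", ])
  t <- compare_conditions(p, a)
  rows[[length(rows) + 1L]] <- data.frame(
    roi = roi, n_subjects = t$n, mean_physical = t$mean_physical,
    sem_physical = sd(p) / sqrt(length(p)),
    mean_ambiguous = t$mean_ambiguous,
    sem_ambiguous = sd(a) / sqrt(length(a)),
    statistic = t$statistic, p = t$p)
}
tests <- do.call(rbind, rows)
write_table_tsv(tests, file.path(RESULTS, "specificity_group_tests.tsv"))
print(tests, digits = 3)

spec$condition_type <- factor(spec$condition_type, c("physical", "ambiguous"))
gp <- ggplot(spec, aes(condition_type, mean_specificity, fill = condition_type)) +
  geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
  facet_wrap(~roi) +
  labs(x = NULL, y = "cluster mean specificity",
       title = "Condition specificity by condition type") +
  theme_minimal()
ggsave(file.path(FIGDIR, "specificity.pdf"), gp, width = 6, height = 3.5)
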