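#!/usr/bin/env Rscript
# Event-related averages and temporal-similarity tests.
#
# Averages per-unit ERA curves over hemispheres to one curve per subject,
# role (preferred / not-preferred) and condition type, then (a) tests the
# Spearman similarity of preferred vs not-preferred ambiguous curves per
# ROI, and (b) the cross-area similarity of role-averaged ambiguous curves
# (V1 vs hMT+), each with the exact Wilcoxon signed-rank test on the
# per-subject correlations.

source("analysis/00_config.R")
library(ggplot2)

era <- read_table_tsv(file.path(RESULTS, "unit_era_curves.tsv"))

curve_mat <- function(roi, ct, role) {
  d <- era[era$roi == roi & era$condition_type == ct & era$role == role, ]
  agg <- aggregate(psc ~ subject + tr_offset, d, mean)
  agg <- agg[order(agg$subject, agg$tr_offset), ]
  matrix(agg$psc, nrow = length(unique(agg$subject)), byrow = TRUE)
}

group_rows <- list(); test_rows <- list()
for (roi in unique(era$roi)) {
  for (ct in c("physical", "ambiguous")) {
    for (role in c("preferred", "not_preferred")) {
      gc <- group_era_curve(curve_mat(roi, ct, role))
      group_rows[[length(group_rows) + 1L]] <-
        cbind(roi = roi, condition_type = ct, role = role, gc)
    }
  }
  t <- similarity_test(curve_mat(roi, "ambiguous", "preferred"),
                       curve_mat(roi, "ambiguous", "not_preferred"))
  test_rows[[length(test_rows) + 1L]] <- data.frame(
    comparison = paste0(roi, ": preferred vs not-preferred (ambiguous)"),
    n_subjects = t$n, mean_rho = t$mean_rho, statistic = t$statistic, p = t$p)
}
avg <- function(roi) (curve_mat(roi, "ambiguous", "preferred") +
                        curve_mat(roi, "ambiguous", "not_preferred")) / 2
t <- similarity_test(avg("V1"), avg("hMT"))
test_rows[[length(test_rows) + 1L]] <- data.frame(
  comparison = "V1 vs hMT+ (role-averaged, ambiguous)",
  n_subjects = t$n, mean_rho = t$mean_rho, statistic = t$statistic, p = t$p)

curves <- do.call(rbind, group_rows)
tests <- do.call(rbind, test_rows)
write_table_tsv(curves, file.path(RESULTS, "group_era_curves.tsv"))
write_table_tsv(tests, file.path(RESULTS, "era_similarity_tests.tsv"))
print(tests, digits = 3)

gp <- ggplot(curves, aes(tr_offset * CONFIG$tr_s, mean_psc, colour = role)) +
  geom_line() +
  geom_pointrange(aes(ymin = mean_psc - sem_psc, ymax = mean_psc + sem_psc),
                  size = 0.2) +
  facet_grid(roi ~ condition_type) +
  labs(x = "time from onset (s)", y = "PSC (%)",
       title = "Event-related averages by cluster role") +
  theme_minimal()
ggsave(file.path(FIGDIR, "era_curves.pdf"), gp, width = 6.5, height = 5)
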