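#!/usr/bin/env Rscript
# Figures: longitudinal morphometry of both phenotypes (cluster area with
# SEM, dispersal distance in both references, area moment, vessel density)
# and a mask/skeleton overlay for one timepoint.
# Requires analysis/02_process_series.R to have been run.

library(windowquant)
library(ggplot2)

figdir <- "results/figures"
dir.create(figdir, recursive = TRUE, showWarnings = FALSE)

summaries <- do.call(rbind, lapply(c("migrating", "stationary"), function(s) {
  df <- read.csv(file.path("results", s, "summary.csv"))
  df$scenario <- s
  df
}))

long <- rbind(
  data.frame(t = summaries$timepoint_hours, scenario = summaries$scenario,
             quantity = "mean cluster area (mm^2)",
             value = summaries$mean_area_mm2, sem = summaries$sem_area_mm2),
  data.frame(t = summaries$timepoint_hours, scenario = summaries$scenario,
             quantity = "mean distance to implantation site (mm)",
             value = summaries$mean_distance_origin_mm,
             sem = summaries$sem_distance_origin_mm),
  data.frame(t = summaries$timepoint_hours, scenario = summaries$scenario,
             quantity = "mean distance to center of mass (mm)",
             value = summaries$mean_distance_mm, sem = summaries$sem_distance_mm),
  data.frame(t = summaries$timepoint_hours, scenario = summaries$scenario,
             quantity = "mean area moment (mm^3)",
             value = summaries$mean_moment_mm3, sem = summaries$sem_moment_mm3))

p <- ggplot(long, aes(t, value, color = scenario)) +
  geom_line() + geom_point(size = 1.5) +
  geom_errorbar(aes(ymin = value - sem, ymax = value + sem), width = 2) +
  facet_wrap(~quantity, scales = "free_y") +
  labs(x = "hours post-implantation", y = NULL,
       title = "Longitudinal tumor-cluster morphometry, synthetic phenotypes") +
  theme_minimal()
ggsave(file.path(figdir, "longitudinal_morphometry.png"), p,
       width = 9, height = 6, dpi = 150)

vess <- do.call(rbind, lapply(c("migrating", "stationary"), function(s) {
  df <- read.csv(file.path("results", s, "vessel_density.csv"))
  df$scenario <- s
  df
}))
pv <- ggplot(vess, aes(timepoint_hours, density_per_mm, color = scenario)) +
  geom_line() + geom_point() +
  labs(x = "hours post-implantation", y = "linear vessel density (1/mm)",
       title = "Skeletonized lymphatic vessel density") +
  theme_minimal()
ggsave(file.path(figdir, "vessel_density.png"), pv,
       width = 6, height = 4, dpi = 150)

# mask overlay for the last migrating timepoint
man <- read_manifest("results/demo/migrating/manifest.yaml")
tp <- man$timepoints[[length(man$timepoints)]]
res <- suppressWarnings(
  process_timepoint(lapply(tp$channels, read_stack), man$config))
write_mask(res$tumor_mask, file.path(figdir, "tumor_mask_final.png"))
cat("figures written under", figdir, "\n")
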