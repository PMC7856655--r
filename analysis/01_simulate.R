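#!/usr/bin/env Rscript
# Generate the synthetic three-arm cohort and report what was planted.

source("analysis/00_config.R")

sim <- study_cohort()
ds <- sim$dataset

message(sprintf("cohort: %d subjects x %d in-mask voxels (%.1f%% clipped)",
                nrow(ds$matrix), ncol(ds$matrix),
                100 * sim$clipped_fraction))

counts <- table(ds$voxel_index$label)
regions <- data.frame(
  region = c(names(lobe_ids()), names(structure_ids())),
  code = c(lobe_ids(), structure_ids()),
  voxels = as.integer(counts[as.character(c(lobe_ids(), structure_ids()))]))
write_tsv(regions, "region_sizes.tsv")

planted <- data.frame(
  effect = c("striatum motor coupling slope (GE_GTCS)",
             "striatum motor coupling slope (FE_FBTS)",
             "cerebellar atrophy slope (patients)"),
  value_per_month = c(sim$config$coupling_w1[1, 1, 2],
                      sim$config$coupling_w1[2, 1, 2],
                      sim$config$atrophy_slope[1, 8]))
write_tsv(planted, "planted_effects.tsv")
message("planted effects:")
print(planted)
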