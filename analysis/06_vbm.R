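#!/usr/bin/env Rscript
# Voxelwise morphometry: three-group ANOVA, duration correlation within
# each patient group, group-by-duration slope interaction, all with
# permutation cluster-extent correction at voxel p < .01, cluster p < .05.

source("analysis/00_config.R")

sim <- study_cohort()
ds <- sim$dataset

fmap <- voxelwise_group_anova(ds)
fclu <- cluster_correct(fmap, ds, list(type = "group_anova"),
                        voxel_p = 0.01, n_perm = N_PERM, seed = SEED)
write_tsv(fclu$clusters, "vbm_anova_clusters.tsv")
message(sprintf("group ANOVA: %d cluster(s), smallest corrected p %.4f",
                nrow(fclu$clusters),
                if (nrow(fclu$clusters)) min(fclu$clusters$p_corrected)
                else NA))

for (g in c("GE_GTCS", "FE_FBTS")) {
  rmap <- voxelwise_duration_corr(ds, g)
  rclu <- cluster_correct(rmap, ds, list(type = "duration_corr", group = g),
                          voxel_p = 0.01, n_perm = N_PERM, seed = SEED)
  write_tsv(rclu$clusters, paste0("vbm_duration_clusters_", g, ".tsv"))
  cer <- region_columns(ds, structure_ids()["cerebellum"])
  message(sprintf(
    "%s duration correlation: mean r %.3f in cerebellum, %.3f elsewhere; %d cluster(s)",
    g, mean(rmap$values[cer]), mean(rmap$values[-cer]), nrow(rclu$clusters)))
}

tmap <- slope_interaction_map(ds)
tclu <- cluster_correct(tmap, ds, list(type = "slope_interaction"),
                        voxel_p = 0.01, n_perm = N_PERM, seed = SEED)
write_tsv(tclu$clusters, "vbm_interaction_clusters.tsv")
message(sprintf("slope interaction: %d cluster(s)", nrow(tclu$clusters)))
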