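#!/usr/bin/env Rscript
# Winner-take-all structural-covariance maps per group and structure:
# voxel counts per winning lobe, radar-normalised patient/control ratios,
# territory recovery against ground truth, and pairwise permutation
# comparisons of the maps.

source("analysis/00_config.R")

sim <- study_cohort()
ds <- sim$dataset
maps <- study_maps(ds)
groups <- names(maps)
strs <- names(structure_ids())

counts <- do.call(rbind, lapply(groups, function(g)
  do.call(rbind, lapply(strs, function(s)
    data.frame(group = g, structure = s, lobe = names(lobe_ids()),
               count = as.integer(count_labels(maps[[g]][[s]])))))))
write_tsv(counts, "map_counts.tsv")

recovery <- do.call(rbind, lapply(groups, function(g)
  data.frame(group = g, structure = strs,
             agreement = vapply(strs, function(s)
               mean(maps[[g]][[s]]$winner_label == true_territory(sim, s)),
               numeric(1)))))
write_tsv(recovery, "territory_recovery.tsv")
message("territory recovery by group/structure:")
print(recovery)

radar <- do.call(rbind, lapply(c("GE_GTCS", "FE_FBTS"), function(g)
  do.call(rbind, lapply(strs, function(s)
    data.frame(group = g, structure = s, lobe = names(lobe_ids()),
               ratio_vs_hc = radar_normalize(
                 count_labels(maps[[g]][[s]]),
                 count_labels(maps[["HC"]][[s]])))))))
write_tsv(radar, "radar_counts.tsv")

pairs <- list(c("GE_GTCS", "HC"), c("FE_FBTS", "HC"),
              c("GE_GTCS", "FE_FBTS"))
cmp <- do.call(rbind, lapply(pairs, function(pr)
  do.call(rbind, lapply(strs, function(s) {
    res <- permutation_map_test(ds, pr[1], pr[2], s, n_perm = N_PERM,
                                seed = SEED)
    cbind(comparison = paste(pr, collapse = "_vs_"), res$table)
  }))))
write_tsv(cmp, "map_comparisons.tsv")
message(sprintf("map comparisons: %d of %d lobe tests at p < .05",
                sum(cmp$p_perm < 0.05), nrow(cmp)))
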