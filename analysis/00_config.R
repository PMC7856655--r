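# Shared settings for the analysis scripts. The cohort emulates the study
# conditions at desk scale: three arms, latent lobe factors, territory
# coupling, duration-dependent modulation in the patient groups and mild
# group atrophy. Scripts cache the generated cohort under scratch/ so the
# chain can be run piecewise.

library(scnwta)

RESULTS <- "results/analysis"
SCRATCH <- "scratch/analysis"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)

N_PERM <- 499L       # permutations per comparison (study scale: 5000)
SEED <- 20260929L

study_config <- function() {
  # planted structure: motor-lobe striatal coupling decays with duration in
  # both patient arms (faster in GE_GTCS), plus cerebellar atrophy with
  # duration in both arms
  w0 <- array(0.06, c(3, 3, 5)); w0[, 1, 2] <- 0.12
  w1 <- array(0, c(3, 3, 5))
  w1[1, 1, 2] <- -1.0e-4    # GE_GTCS
  w1[2, 1, 2] <- -0.5e-4    # FE_FBTS
  atr <- array(0, c(3, 8))
  atr[1:2, 8] <- 2e-4       # cerebellar GMV loss per month in patients
  generator_config(grid = 24, n_per_group = 60,
                   coupling_w0 = w0, coupling_w1 = w1, atrophy_slope = atr,
                   seed = SEED)
}

study_cohort <- function() {
  cache <- file.path(SCRATCH, "cohort.rds")
  if (file.exists(cache)) return(readRDS(cache))
  sim <- generate_cohort(study_config())
  saveRDS(sim, cache)
  sim
}

study_maps <- function(ds) {
  cache <- file.path(SCRATCH, "wta_maps.rds")
  if (file.exists(cache)) return(readRDS(cache))
  maps <- lapply(c("GE_GTCS", "FE_FBTS", "HC"), function(g) {
    m <- lapply(names(structure_ids()), function(s)
      wta_structure_map(ds, s, group = g))
    names(m) <- names(structure_ids())
    m
  })
  names(maps) <- c("GE_GTCS", "FE_FBTS", "HC")
  saveRDS(maps, cache)
  maps
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  path
}
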