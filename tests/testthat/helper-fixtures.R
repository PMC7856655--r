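# Shared fixtures. Small cohorts are cached per test run so several test
# files can reuse the same generated data.

small_config <- function(seed = 3, n = 20, ...) {
  generator_config(grid = 16, n_per_group = n, seed = seed, ...)
}

# low signal-to-noise config used for null-calibration studies: weak,
# group-identical coupling so winner-take-all labels genuinely fluctuate
calib_config <- function(seed) {
  generator_config(grid = 16, n_per_group = 20,
                   coupling_w0 = array(0.02, c(3, 3, 5)),
                   noise_sd = 0.06, seed = seed)
}

# voxelwise-independent config: no latent factor structure, no coupling,
# unsmoothed noise — every in-mask voxel is an independent Gaussian around
# its regional mean (used for distributional calibration and localized
# effect recovery)
indep_config <- function(seed, n = 20, ...) {
  generator_config(grid = 16, n_per_group = n,
                   coupling_w0 = array(0, c(3, 3, 5)),
                   factor_loading = 0,
                   smooth_noise_fwhm_mm = 0.01,
                   seed = seed, ...)
}

# planted duration modulation: striatum motor-lobe territory coupling decays
# with duration in the patient groups (baseline raised so coupling stays
# positive over the duration range)
modulation_config <- function(seed, w1_ge = -1e-4, w1_fe = -1e-4, n = 111) {
  w0 <- array(0.06, c(3, 3, 5))
  w0[, 1, 2] <- 0.12
  w1 <- array(0, c(3, 3, 5))
  w1[1, 1, 2] <- w1_ge
  w1[2, 1, 2] <- w1_fe
  generator_config(grid = 16, n_per_group = n, coupling_w0 = w0,
                   coupling_w1 = w1, seed = seed)
}

local({
  cache <- new.env(parent = emptyenv())
  shared_sim <<- function(seed = 3, n = 20) {
    key <- paste0("s", seed, "_", n)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_cohort(small_config(seed = seed, n = n))
    cache[[key]]
  }
})

# deterministic toy dataset: explicit volumes through the public constructor
toy_dataset <- function(n = 12, seed = 99) {
  cfg <- small_config(seed = seed, n = max(4L, ceiling(n / 3)))
  sim <- generate_cohort(cfg)
  sim$dataset
}
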