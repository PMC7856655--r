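#' Synthetic cohort generator configuration
#'
#' The generator emulates the study conditions of a three-arm structural
#' covariance study: per-subject gray-matter probability volumes on a common
#' grid whose cortical lobes fluctuate around latent per-subject "lobe
#' factors", and whose subcortical territories covary with an assigned lobe
#' with group- and duration-dependent coupling. Ground truth (territory
#' assignments, coupling and atrophy actually used) is returned for recovery
#' tests.
#'
#' Voxel model, subject s in group g with disease duration d (months, 0 for
#' controls), latent lobe factors f ~ MVN(0, `lobe_factor_corr`):
#' \itemize{
#'   \item cortical voxel in lobe l:
#'     `mu_cortex + factor_loading * f_l + tiv_slope * (TIV - tiv_mean)
#'      - atrophy_slope[g, l] * d + eps`
#'   \item subcortical voxel in territory (structure r, lobe l):
#'     `mu_subcortex + (w0[g, r, l] + w1[g, r, l] * d) * f_l
#'      + tiv_slope * (TIV - tiv_mean) - atrophy_slope[g, r] * d + eps`
#' }
#' where `eps` is spatially smoothed Gaussian noise with marginal SD
#' `noise_sd`, and values are clipped to \[0, 1\] last.
#'
#' @param grid Integer length-3 grid size (default 32^3; each axis >= 16).
#' @param voxel_mm Isotropic voxel size, mm (default 1.5).
#' @param n_per_group Subjects per arm (default 40; study scale is 111).
#' @param lobe_factor_corr 5x5 positive-definite correlation of the latent
#'   lobe factors (default exchangeable 0.3 off-diagonal).
#' @param coupling_w0 3x3x5 array (group x structure x lobe) of baseline
#'   territory-to-lobe coupling; default 0.06 everywhere.
#' @param coupling_w1 Same shape; per-month duration slope of the coupling;
#'   default 0.
#' @param atrophy_slope 3x8 array (group x region, regions = 5 lobes then
#'   3 structures) of GMV loss per month of duration; default 0.
#' @param tiv_mean,tiv_sd Total intracranial volume distribution, ml
#'   (1500/120).
#' @param duration_mean,duration_sd Disease duration distribution, months
#'   (83/94), truncated below at 1.
#' @param age_mean,age_sd Age distribution, years (26/7.5), truncated below
#'   at 18.
#' @param male_fraction Fraction of male subjects per arm (71/111).
#' @param mu_cortex,mu_subcortex Baseline gray-matter probability (0.55/0.50).
#' @param factor_loading Cortical loading on the lobe factor (0.05).
#' @param tiv_slope Head-size confound slope, per ml (2e-4).
#' @param noise_sd Marginal SD of the voxel noise field (0.04).
#' @param smooth_noise_fwhm_mm FWHM of the noise smoothing kernel, mm (6).
#' @param seed Integer RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(grid = c(32L, 32L, 32L),
                             voxel_mm = 1.5,
                             n_per_group = 40L,
                             lobe_factor_corr = NULL,
                             coupling_w0 = NULL,
                             coupling_w1 = NULL,
                             atrophy_slope = NULL,
                             tiv_mean = 1500, tiv_sd = 120,
                             duration_mean = 83, duration_sd = 94,
                             age_mean = 26, age_sd = 7.5,
                             male_fraction = 71 / 111,
                             mu_cortex = 0.55, mu_subcortex = 0.50,
                             factor_loading = 0.05,
                             tiv_slope = 2e-4,
                             noise_sd = 0.04,
                             smooth_noise_fwhm_mm = 6,
                             seed = 1L) {
  grid <- as.integer(rep(grid, length.out = 3))
  if (any(grid < 16L)) stop("grid must be >= 16 on every axis")
  if (n_per_group < 4L) stop("n_per_group must be >= 4")
  groups <- c("GE_GTCS", "FE_FBTS", "HC")
  lobes <- names(lobe_ids())
  strs <- names(structure_ids())
  if (is.null(lobe_factor_corr)) {
    lobe_factor_corr <- matrix(0.3, 5, 5)
    diag(lobe_factor_corr) <- 1
  }
  lobe_factor_corr <- as.matrix(lobe_factor_corr)
  stopifnot(all(dim(lobe_factor_corr) == c(5, 5)))
  if (max(abs(lobe_factor_corr - t(lobe_factor_corr))) > 1e-12)
    stop("lobe_factor_corr must be symmetric")
  if (min(eigen(lobe_factor_corr, symmetric = TRUE,
                only.values = TRUE)$values) <= 0)
    stop("lobe_factor_corr must be positive definite")
  dn3 <- list(groups, strs, lobes)
  if (is.null(coupling_w0))
    coupling_w0 <- array(0.06, c(3, 3, 5), dimnames = dn3)
  if (is.null(coupling_w1))
    coupling_w1 <- array(0, c(3, 3, 5), dimnames = dn3)
  if (is.null(atrophy_slope))
    atrophy_slope <- array(0, c(3, 8),
                           dimnames = list(groups, c(lobes, strs)))
  structure(list(
    grid = grid, voxel_mm = voxel_mm, n_per_group = as.integer(n_per_group),
    lobe_factor_corr = lobe_factor_corr,
    coupling_w0 = coupling_w0, coupling_w1 = coupling_w1,
    atrophy_slope = atrophy_slope,
    tiv_mean = tiv_mean, tiv_sd = tiv_sd,
    duration_mean = duration_mean, duration_sd = duration_sd,
    age_mean = age_mean, age_sd = age_sd,
    male_fraction = male_fraction,
    mu_cortex = mu_cortex, mu_subcortex = mu_subcortex,
    factor_loading = factor_loading, tiv_slope = tiv_slope,
    noise_sd = noise_sd, smooth_noise_fwhm_mm = smooth_noise_fwhm_mm,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Deterministic per-subject sub-seed so earlier subjects are invariant to n.
.subject_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483629) + 1L
}

#' Generate a synthetic atlas with ground-truth territories
#'
#' Builds a spherical cortical shell split into five contiguous angular
#' sectors (the lobes) and three interior ellipsoids (striatum, thalamus,
#' cerebellum), each partitioned into five contiguous angular territories
#' assigned to the five lobes. Geometry is deterministic for a given config.
#'
#' @param config A [generator_config].
#' @return List with `atlas` (an [atlas]) and `territory` (integer
#'   [volume_image]: assigned lobe 1-5 over structure voxels, 0 elsewhere).
#' @export
generate_atlas <- function(config) {
  g <- config$grid
  gm <- min(g)
  ctr <- (g + 1) / 2
  idx <- arrayInd(seq_len(prod(g)), g)
  x <- idx[, 1] - ctr[1]; y <- idx[, 2] - ctr[2]; z <- idx[, 3] - ctr[3]
  r <- sqrt(x^2 + y^2 + z^2)
  r_out <- 0.46 * gm
  r_in <- 0.70 * r_out
  lab <- integer(prod(g))

  shell <- r >= r_in & r <= r_out
  theta <- atan2(y, x)
  sector <- pmin(5L, as.integer(floor((theta + pi) / (2 * pi / 5))) + 1L)
  lab[shell] <- sector[shell]

  ell <- function(cx, cy, cz, a, b, cc)
    ((x - cx) / a)^2 + ((y - cy) / b)^2 + ((z - cz) / cc)^2 <= 1
  sc <- gm / 32
  blobs <- list(
    striatum   = ell(-4.5 * sc, 0, 1.0 * sc, 4.2 * sc, 3.4 * sc, 3.0 * sc),
    thalamus   = ell(4.5 * sc, 0, 1.0 * sc, 4.2 * sc, 3.4 * sc, 3.0 * sc),
    cerebellum = ell(0, 0, -6.2 * sc, 5.2 * sc, 4.4 * sc, 3.4 * sc)
  )
  terr <- integer(prod(g))
  for (s in names(blobs)) {
    vox <- which(blobs[[s]] & lab == 0L & r < r_in)
    if (length(vox) < 5L)
      stop("grid too small: structure ", s, " has < 5 voxels")
    if (any(lab[vox] != 0L)) stop("structure ", s, " overlaps another region")
    lab[vox] <- structure_ids()[[s]]
    # contiguous angular territories around the blob centre, rank-split so
    # all five are non-empty
    th <- atan2(idx[vox, 2] - ctr[2] - mean(idx[vox, 2] - ctr[2]),
                idx[vox, 1] - ctr[1] - mean(idx[vox, 1] - ctr[1]))
    rk <- rank(th, ties.method = "first")
    terr[vox] <- as.integer(ceiling(rk / length(vox) * 5))
  }
  lab_arr <- array(lab, g)
  terr_arr <- array(terr, g)
  aff <- diag(c(rep(config$voxel_mm, 3), 1))
  list(atlas = atlas(volume_image(lab_arr, affine = aff)),
       territory = volume_image(terr_arr, affine = aff))
}

# internal: dataset constructor from a prebuilt matrix
.gmv_dataset_from_matrix <- function(mat, voxel_index, cohort, atl, dims) {
  structure(list(matrix = mat, voxel_index = voxel_index, cohort = cohort,
                 atlas = atl, dims = dims),
            class = "gmv_dataset")
}

#' Generate a synthetic cohort
#'
#' Draws subjects for the three arms and synthesises their gray-matter
#' volumes under the model documented in [generator_config()]. Deterministic
#' for a given seed; each subject consumes an independent sub-stream so
#' earlier subjects are unchanged when `n_per_group` grows.
#'
#' @param config A [generator_config].
#' @param atl An [atlas] from [generate_atlas()] (regenerated when `NULL`).
#' @param territory Territory label volume from [generate_atlas()].
#' @return List of class `synthetic_cohort`: `dataset` (a [gmv_dataset]),
#'   `cohort`, `truth` (territory volume + parameter arrays used), `factors`
#'   (subjects x 5 latent lobe factors), `clipped_fraction`.
#' @export
generate_cohort <- function(config, atl = NULL, territory = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(atl) || is.null(territory)) {
    ga <- generate_atlas(config)
    atl <- ga$atlas; territory <- ga$territory
  }
  g <- config$grid
  lab <- atl$labels$data
  inmask <- which(lab > 0L)
  ijk <- arrayInd(inmask, g) - 1L
  ord <- order(ijk[, 1], ijk[, 2], ijk[, 3])
  inmask <- inmask[ord]; ijk <- ijk[ord, , drop = FALSE]
  col_label <- lab[inmask]
  col_terr <- territory$data[inmask]
  nvox <- length(inmask)

  lobes <- names(lobe_ids()); strs <- names(structure_ids())
  is_cort <- col_label <= 5L
  # per-column lobe index driving the latent factor (own lobe, or territory)
  col_lobe <- ifelse(is_cort, col_label, col_terr)
  col_struct <- match(col_label, structure_ids())  # NA for cortex

  groups <- c("GE_GTCS", "FE_FBTS", "HC")
  n <- config$n_per_group
  N <- 3L * n
  Lc <- chol(config$lobe_factor_corr)

  # noise smoothing kernel and variance-restoring factor
  sig_vox <- fwhm_to_sigma(config$smooth_noise_fwhm_mm, config$voxel_mm)
  kern <- .gauss_kernel(sig_vox)
  var_fac <- sum(kern^2)^(3 / 2)

  mat <- matrix(NA_real_, N, nvox)
  factors <- matrix(NA_real_, N, 5)
  coh <- data.frame(subject_id = sprintf("s%03d", seq_len(N)),
                    group = rep(groups, each = n),
                    duration_months = NA_real_, tiv = NA_real_,
                    age = NA_real_, sex = NA_character_,
                    stringsAsFactors = FALSE)
  n_male <- round(n * config$male_fraction)
  clipped <- 0

  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    for (si in seq_len(n)) {
      row <- (gi - 1L) * n + si
      set.seed(.subject_seed(config$seed, row))
      dur <- if (grp == "HC") NA_real_ else {
        d <- stats::rnorm(1, config$duration_mean, config$duration_sd)
        while (d < 1) d <- stats::rnorm(1, config$duration_mean,
                                        config$duration_sd)
        d
      }
      tiv <- stats::rnorm(1, config$tiv_mean, config$tiv_sd)
      age <- max(18, stats::rnorm(1, config$age_mean, config$age_sd))
      f <- drop(stats::rnorm(5) %*% Lc)
      eps <- array(stats::rnorm(prod(g)), g)
      for (ax in 1:3) eps <- .conv_axis(eps, kern, ax)
      eps <- eps[inmask] / sqrt(var_fac) * config$noise_sd

      d0 <- if (is.na(dur)) 0 else dur
      fl <- f[col_lobe]
      tiv_term <- config$tiv_slope * (tiv - config$tiv_mean)
      v <- numeric(nvox)
      v[is_cort] <- config$mu_cortex +
        config$factor_loading * fl[is_cort] + tiv_term -
        config$atrophy_slope[gi, col_label[is_cort]] * d0
      sub <- !is_cort
      w <- config$coupling_w0[cbind(gi, col_struct[sub], col_lobe[sub])] +
        config$coupling_w1[cbind(gi, col_struct[sub], col_lobe[sub])] * d0
      v[sub] <- config$mu_subcortex + w * fl[sub] + tiv_term -
        config$atrophy_slope[gi, 5L + col_struct[sub]] * d0
      v <- v + eps
      clipped <- clipped + sum(v < 0 | v > 1)
      v <- pmin(1, pmax(0, v))

      mat[row, ] <- v
      factors[row, ] <- f
      coh$duration_months[row] <- dur
      coh$tiv[row] <- tiv
      coh$age[row] <- age
      coh$sex[row] <- if (si <= n_male) "M" else "F"
    }
  }
  clip_frac <- clipped / (as.numeric(N) * nvox)
  if (clip_frac >= 0.5)
    stop("config clips ", round(100 * clip_frac), "% of voxels to [0,1]")
  if (clip_frac >= 0.05)
    warning("config clips ", round(100 * clip_frac, 1),
            "% of voxels to [0,1]; linear recovery may be biased")

  cohort <- cohort_table(coh)
  rownames(mat) <- cohort$subject_id
  vi <- data.frame(col = seq_len(nvox), i = ijk[, 1], j = ijk[, 2],
                   k = ijk[, 3], label = col_label)
  ds <- .gmv_dataset_from_matrix(mat, vi, cohort, atl, g)
  truth <- list(territory = territory,
                coupling_w0 = config$coupling_w0,
                coupling_w1 = config$coupling_w1,
                atrophy_slope = config$atrophy_slope)
  structure(list(dataset = ds, cohort = cohort, truth = truth,
                 factors = factors, clipped_fraction = clip_frac,
                 config = config),
            class = "synthetic_cohort")
}

#' Territory lobe assignment for one structure, in dataset column order
#'
#' @param sim A `synthetic_cohort` (or a list with `dataset` and `truth`).
#' @param structure Structure name ("striatum", "thalamus", "cerebellum").
#' @return Integer vector of true lobe assignments (1-5), parallel to
#'   `region_columns(sim$dataset, structure_ids()[structure])`.
#' @export
true_territory <- function(sim, structure) {
  ds <- sim$dataset
  cols <- region_columns(ds, structure_ids()[[structure]])
  vi <- ds$voxel_index[cols, ]
  lin <- cbind(vi$i + 1L, vi$j + 1L, vi$k + 1L)
  sim$truth$territory$data[lin]
}

#' Write / read a cohort directory
#'
#' Serialises a synthetic cohort as `atlas.nii.gz`, `territory.nii.gz`,
#' `cohort.tsv`, `truth.json` (parameter arrays), `config.yaml` and one
#' `sNNN_gmv.nii.gz` per subject.
#'
#' @param sim A `synthetic_cohort`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly (writer); a list like [generate_cohort()]'s
#'   minus factors (reader).
#' @export
write_cohort_dir <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- sim$dataset
  write_volume(ds$atlas$labels, file.path(dir, "atlas.nii.gz"))
  write_volume(sim$truth$territory, file.path(dir, "territory.nii.gz"))
  write_cohort(ds$cohort, file.path(dir, "cohort.tsv"))
  jsonlite::write_json(list(coupling_w0 = sim$truth$coupling_w0,
                            coupling_w1 = sim$truth$coupling_w1,
                            atrophy_slope = sim$truth$atrophy_slope),
                       file.path(dir, "truth.json"), digits = NA)
  cfg <- sim$config
  cfg$lobe_factor_corr <- as.vector(cfg$lobe_factor_corr)
  cfg$coupling_w0 <- as.vector(cfg$coupling_w0)
  cfg$coupling_w1 <- as.vector(cfg$coupling_w1)
  cfg$atrophy_slope <- as.vector(cfg$atrophy_slope)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  dims <- ds$dims
  for (s in seq_len(nrow(ds$matrix))) {
    vol <- array(0, dims)
    vol[cbind(ds$voxel_index$i + 1L, ds$voxel_index$j + 1L,
              ds$voxel_index$k + 1L)] <- ds$matrix[s, ]
    write_volume(volume_image(vol, affine = ds$atlas$labels$affine),
                 file.path(dir, sprintf("%s_gmv.nii.gz",
                                        ds$cohort$subject_id[s])))
  }
  invisible(dir)
}

#' @rdname write_cohort_dir
#' @export
read_cohort_dir <- function(dir) {
  atl <- atlas(read_volume(file.path(dir, "atlas.nii.gz")))
  territory <- read_volume(file.path(dir, "territory.nii.gz"))
  cohort <- read_cohort(file.path(dir, "cohort.tsv"))
  vols <- lapply(cohort$subject_id, function(id)
    read_volume(file.path(dir, sprintf("%s_gmv.nii.gz", id))))
  ds <- gmv_dataset(vols, cohort, atl)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$territory <- territory
  list(dataset = ds, cohort = cohort, truth = truth)
}
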