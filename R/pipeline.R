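#' Pipeline run configuration
#'
#' @param generator A [generator_config] describing the synthetic cohort, or
#'   `NULL` with `cohort_dir` pointing at a cohort directory on disk.
#' @param cohort_dir Optional directory from [write_cohort_dir()].
#' @param fwhm_mm Gaussian smoothing FWHM applied to each subject volume
#'   before analysis when reading a cohort directory (default 8; synthetic
#'   datasets already carry smooth noise and are analysed as generated).
#' @param n_perm Permutations for all comparison stages (study scale 5000).
#' @param alpha Edge/cluster significance level.
#' @param voxel_p Voxel-level threshold of the cluster stage.
#' @param seed Seed for all permutation streams.
#' @param absolute_wta Winner by `|r|` instead of signed r.
#' @param two_tailed Two-tailed modulation p-values.
#' @param run_vbm Include the voxelwise stage (slowest; default TRUE).
#' @param out_dir Output directory for report tables.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       cohort_dir = NULL,
                       fwhm_mm = 8, n_perm = 5000L, alpha = 0.05,
                       voxel_p = 0.01, seed = 1L,
                       absolute_wta = FALSE, two_tailed = FALSE,
                       run_vbm = TRUE, out_dir = "results/run") {
  stopifnot(n_perm >= 1L, alpha > 0, alpha < 1)
  structure(list(generator = generator, cohort_dir = cohort_dir,
                 fwhm_mm = fwhm_mm, n_perm = as.integer(n_perm),
                 alpha = alpha, voxel_p = voxel_p, seed = as.integer(seed),
                 absolute_wta = absolute_wta, two_tailed = two_tailed,
                 run_vbm = run_vbm, out_dir = out_dir),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full structural-covariance pipeline
#'
#' Generates (or loads) the cohort, then emits the study's report tables:
#' demographic balance, per-group WTA voxel counts with pairwise permutation
#' p-values, radar-normalised counts, the three 20x20 covariance networks
#' with pairwise permutation comparisons under false-positive adjustment,
#' the duration-modulation scan (within each patient group and between
#' groups), and optionally the voxelwise morphometry maps with cluster
#' correction. All randomness flows from `cfg$seed`; rerunning with the same
#' config reproduces every table byte for byte.
#'
#' @param cfg A [run_config].
#' @return Invisibly, a list with the computed objects and the output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_lines <- character(0)
  stage <- function(msg) {
    line <- sprintf("[%7.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    msg)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  stage("load/generate cohort")
  if (!is.null(cfg$cohort_dir)) {
    loaded <- read_cohort_dir(cfg$cohort_dir)
    ds <- loaded$dataset
    if (cfg$fwhm_mm > 0) {
      # re-smooth subject volumes on load
      vols <- lapply(seq_len(nrow(ds$matrix)), function(s) {
        vol <- array(0, ds$dims)
        vol[cbind(ds$voxel_index$i + 1L, ds$voxel_index$j + 1L,
                  ds$voxel_index$k + 1L)] <- ds$matrix[s, ]
        smooth_volume(volume_image(vol, affine = ds$atlas$labels$affine),
                      cfg$fwhm_mm)
      })
      ds <- gmv_dataset(vols, ds$cohort, ds$atlas)
    }
  } else {
    sim <- generate_cohort(cfg$generator)
    ds <- sim$dataset
  }
  groups <- c("GE_GTCS", "FE_FBTS", "HC")
  pairs <- list(c("GE_GTCS", "HC"), c("FE_FBTS", "HC"),
                c("GE_GTCS", "FE_FBTS"))

  stage("demographic balance")
  balance <- demographic_balance(ds$cohort)
  .write_tsv(balance_report_table(balance),
             file.path(cfg$out_dir, "demographics.tsv"))

  stage("winner-take-all maps")
  strs <- names(structure_ids())
  maps <- lapply(groups, function(g) {
    m <- lapply(strs, function(s)
      wta_structure_map(ds, s, group = g, absolute = cfg$absolute_wta))
    names(m) <- strs
    m
  })
  names(maps) <- groups
  counts <- do.call(rbind, lapply(groups, function(g)
    do.call(rbind, lapply(strs, function(s)
      data.frame(group = g, structure = s,
                 lobe = names(lobe_ids()),
                 count = as.integer(count_labels(maps[[g]][[s]])),
                 stringsAsFactors = FALSE)))))
  .write_tsv(counts, file.path(cfg$out_dir, "map_counts.tsv"))

  radar <- do.call(rbind, lapply(c("GE_GTCS", "FE_FBTS"), function(g)
    do.call(rbind, lapply(strs, function(s)
      data.frame(group = g, structure = s, lobe = names(lobe_ids()),
                 ratio_vs_hc = radar_normalize(
                   count_labels(maps[[g]][[s]]),
                   count_labels(maps[["HC"]][[s]])),
                 stringsAsFactors = FALSE)))))
  .write_tsv(radar, file.path(cfg$out_dir, "radar_counts.tsv"))

  stage("map permutation comparisons")
  map_cmp <- do.call(rbind, lapply(pairs, function(pr)
    do.call(rbind, lapply(strs, function(s) {
      cmp <- permutation_map_test(ds, pr[1], pr[2], s,
                                  n_perm = cfg$n_perm, seed = cfg$seed,
                                  absolute = cfg$absolute_wta)
      cbind(comparison = paste(pr, collapse = "_vs_"), structure = s,
            cmp$table)
    }))))
  .write_tsv(map_cmp, file.path(cfg$out_dir, "map_comparisons.tsv"))

  stage("covariance networks")
  networks <- lapply(groups, function(g)
    build_network(extract_node_signals(ds, maps[[g]], group_rows(ds, g)),
                  covariates = ds$cohort$tiv[group_rows(ds, g)], group = g))
  names(networks) <- groups
  for (g in groups)
    write_network_tsv(networks[[g]]$R,
                      file.path(cfg$out_dir, paste0("network_", g, ".tsv")))

  stage("network permutation comparisons")
  net_cmp <- lapply(pairs, function(pr)
    compare_networks(ds, pr[1], pr[2], n_perm = cfg$n_perm,
                     seed = cfg$seed, alpha = cfg$alpha))
  names(net_cmp) <- vapply(pairs, paste, "", collapse = "_vs_")
  net_tab <- do.call(rbind, lapply(names(net_cmp), function(nm)
    cbind(comparison = nm, network_comparison_table(net_cmp[[nm]]))))
  .write_tsv(net_tab, file.path(cfg$out_dir, "network_comparisons.tsv"))

  stage("duration modulation scan")
  mod_tab <- rbind(
    subnetwork_modulation_scan(ds, maps[["GE_GTCS"]], "within_group",
                               group = "GE_GTCS",
                               two_tailed = cfg$two_tailed),
    subnetwork_modulation_scan(ds, maps[["FE_FBTS"]], "within_group",
                               group = "FE_FBTS",
                               two_tailed = cfg$two_tailed),
    subnetwork_modulation_scan(ds, maps[["HC"]], "between_group",
                               two_tailed = cfg$two_tailed))
  .write_tsv(mod_tab, file.path(cfg$out_dir, "modulation.tsv"))

  vbm <- NULL
  if (cfg$run_vbm) {
    stage("voxelwise statistics + cluster correction")
    fmap <- voxelwise_group_anova(ds)
    fclu <- cluster_correct(fmap, ds, list(type = "group_anova"),
                            voxel_p = cfg$voxel_p, n_perm = cfg$n_perm,
                            seed = cfg$seed)
    .write_tsv(fclu$clusters, file.path(cfg$out_dir, "vbm_anova_clusters.tsv"))
    vbm <- list(f_map = fmap, f_clusters = fclu)
  }

  stage("manifest")
  manifest <- list(
    config = list(n_perm = cfg$n_perm, alpha = cfg$alpha,
                  voxel_p = cfg$voxel_p, seed = cfg$seed,
                  absolute_wta = cfg$absolute_wta,
                  two_tailed = cfg$two_tailed, fwhm_mm = cfg$fwhm_mm,
                  generator = if (is.null(cfg$generator)) NULL else
                    lapply(unclass(cfg$generator), function(x)
                      if (is.matrix(x) || is.array(x)) as.vector(x) else x)),
    n_subjects = nrow(ds$matrix),
    n_voxels = ncol(ds$matrix),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))

  invisible(list(dataset = ds, balance = balance, maps = maps,
                 counts = counts, map_comparisons = map_cmp,
                 networks = networks, network_comparisons = net_cmp,
                 modulation = mod_tab, vbm = vbm, out_dir = cfg$out_dir))
}
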