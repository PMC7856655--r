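#' Partial correlation given nuisance covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after ordinary
#' least squares regression of each on an intercept plus the covariate
#' columns `Z`. With empty `Z` this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length n.
#' @param Z Optional n x k covariate matrix; `n > k + 2` required.
#' @return Partial correlation coefficient in \[-1, 1\].
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  X <- if (is.null(Z) || NCOL(Z) == 0L || length(Z) == 0L) {
    matrix(1, n, 1)
  } else {
    cbind(1, as.matrix(Z))
  }
  if (n <= ncol(X) + 1L)
    stop("need n > k + 2 observations for ", ncol(X) - 1L, " covariates")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate design")
  if (stats::var(x) < 1e-24 || stats::var(y) < 1e-24)
    stop("degenerate input: zero residual variance")
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  # a variable fully absorbed by the covariates carries no partial signal
  if (sum(rx^2) < 1e-12 * length(x) * stats::var(x) ||
      sum(ry^2) < 1e-12 * length(y) * stats::var(y)) return(0)
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  min(1, max(-1, r))
}

# per-subject mean gray-matter signal of each lobe, all subjects (n x 5)
.lobe_mean_matrix <- function(ds) {
  vapply(lobe_ids(), function(l)
    rowMeans(ds$matrix[, region_columns(ds, l), drop = FALSE]),
    numeric(nrow(ds$matrix)))
}

# fast seeded-covariance coefficients for one structure over a subject
# subset: LM = n x 5 lobe means, Y = n x V structure voxels
.wta_all_r <- function(LM, tiv, Y, sub) {
  out <- matrix(NA_real_, ncol(Y), 5L)
  for (l in 1:5) {
    X <- cbind(1, LM[sub, -l, drop = FALSE], tiv[sub])
    qx <- qr(X)
    if (qx$rank < ncol(X)) stop("rank-deficient covariate design")
    rx <- qr.resid(qx, LM[sub, l])
    RY <- qr.resid(qx, Y[sub, , drop = FALSE])
    out[, l] <- .resid_cor(rx, RY)
  }
  out
}

# residualise a matrix (or vector) on [1, Z]; errors on rank deficiency
.residualize <- function(M, Z = NULL) {
  n <- NROW(M)
  X <- if (is.null(Z) || NCOL(Z) == 0L) matrix(1, n, 1) else
    cbind(1, as.matrix(Z))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate design")
  qr.resid(qx, M)
}

# correlation of a residualised vector with each column of a residualised
# matrix (both already centred by the same projection)
.resid_cor <- function(rx, RY) {
  num <- drop(crossprod(RY, rx))
  den <- sqrt(colSums(RY^2) * sum(rx^2))
  r <- num / den
  pmin(1, pmax(-1, r))
}

#' Seeded structural-covariance map of one structure
#'
#' For each voxel of the target structure, the partial correlation across
#' subjects between the seed lobe's mean gray-matter signal and the voxel's
#' gray-matter value, controlling the mean signals of the other four lobes
#' and total intracranial volume.
#'
#' @param ds A [gmv_dataset].
#' @param seed_lobe Lobe id 1-5 (or name).
#' @param structure Structure name ("striatum", "thalamus", "cerebellum").
#' @param subjects Row subset (indices); default all subjects.
#' @return Numeric vector of coefficients, parallel to
#'   `region_columns(ds, structure_ids()[structure])`.
#' @export
seed_structure_map <- function(ds, seed_lobe, structure, subjects = NULL) {
  stopifnot(inherits(ds, "gmv_dataset"))
  if (is.character(seed_lobe)) seed_lobe <- lobe_ids()[[seed_lobe]]
  if (is.null(subjects)) subjects <- seq_len(nrow(ds$matrix))
  if (length(subjects) <= 8L)
    stop("need more than 8 subjects for 6 covariate columns")
  scols <- region_columns(ds, structure_ids()[[structure]])
  if (length(scols) == 0L) stop("structure mask is empty: ", structure)
  lobe_means <- vapply(lobe_ids(), function(l)
    roi_mean_signal(ds, region_columns(ds, l), subjects), numeric(length(subjects)))
  x <- lobe_means[, seed_lobe]
  Z <- cbind(lobe_means[, -seed_lobe, drop = FALSE],
             tiv = ds$cohort$tiv[subjects])
  Y <- ds$matrix[subjects, scols, drop = FALSE]
  X <- cbind(1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate design")
  rx <- qr.resid(qx, x)
  RY <- qr.resid(qx, Y)
  .resid_cor(rx, RY)
}

#' Winner-take-all labeling of a structure
#'
#' Assigns each structure voxel to the cortical lobe whose seeded covariance
#' coefficient is highest. The default compares signed coefficients; set
#' `absolute = TRUE` to compare magnitudes. Exact ties go to the lowest lobe
#' id and are counted.
#'
#' @param all_r Voxels x 5 matrix of coefficients (columns = lobes 1-5),
#'   e.g. from [seed_structure_map()] per lobe.
#' @param group,structure Metadata carried on the result.
#' @param absolute Compare `|r|` instead of signed r (default `FALSE`).
#' @return Object of class `scn_map`: `winner_label`, `winner_r`, `all_r`,
#'   `n_ties`, `group`, `structure`, `absolute`.
#' @export
wta_label <- function(all_r, group = NA_character_,
                      structure = NA_character_, absolute = FALSE) {
  all_r <- as.matrix(all_r)
  stopifnot(ncol(all_r) == 5L)
  if (any(rowSums(is.finite(all_r)) == 0L))
    stop("voxel with no finite coefficient in any of the 5 maps")
  cmp <- if (absolute) abs(all_r) else all_r
  cmp[!is.finite(cmp)] <- -Inf
  winner <- max.col(cmp, ties.method = "first")
  rowmax <- cmp[cbind(seq_len(nrow(cmp)), winner)]
  n_ties <- sum(rowSums(cmp == rowmax) > 1L)
  structure(list(winner_label = winner,
                 winner_r = all_r[cbind(seq_len(nrow(all_r)), winner)],
                 all_r = all_r, n_ties = n_ties,
                 group = group, structure = structure, absolute = absolute),
            class = "scn_map")
}

#' Full winner-take-all map for one group and structure
#'
#' Convenience wrapper: seeds all five lobes and labels.
#'
#' @inheritParams seed_structure_map
#' @param group Group name used to pick subjects when `subjects` is `NULL`.
#' @param absolute Passed to [wta_label()].
#' @return An `scn_map`.
#' @export
wta_structure_map <- function(ds, structure, group = NULL, subjects = NULL,
                              absolute = FALSE) {
  if (is.null(subjects)) {
    if (is.null(group)) stop("give either group or subjects")
    subjects <- group_rows(ds, group)
  }
  all_r <- vapply(1:5, function(l)
    seed_structure_map(ds, l, structure, subjects),
    numeric(length(region_columns(ds, structure_ids()[[structure]]))))
  wta_label(all_r, group = if (is.null(group)) NA_character_ else group,
            structure = structure, absolute = absolute)
}

#' Voxel counts per winning lobe
#'
#' @param m An `scn_map`.
#' @return Named integer vector of length 5 (lobe names); sums to the
#'   structure voxel count.
#' @export
count_labels <- function(m) {
  stopifnot(inherits(m, "scn_map"))
  cnt <- tabulate(m$winner_label, nbins = 5L)
  names(cnt) <- names(lobe_ids())
  cnt
}

#' Radar normalisation of voxel counts
#'
#' Patient counts standardised by dividing by the healthy-control counts,
#' the scaling used on covariance-map radar plots.
#'
#' @param counts_patient,counts_hc Length-5 count vectors.
#' @return Length-5 ratio vector.
#' @export
radar_normalize <- function(counts_patient, counts_hc) {
  stopifnot(length(counts_patient) == 5L, length(counts_hc) == 5L)
  as.numeric(counts_patient) / as.numeric(counts_hc)
}

#' Permutation comparison of winner-take-all maps
#'
#' Observed statistic per lobe: difference in winning-voxel counts between
#' the two groups' own WTA maps. The null is built by randomly reassigning
#' the group labels (sizes preserved) and recomputing both maps per
#' permutation; two-sided p per lobe uses the add-one estimator
#' (1 + #\{|null| >= |obs|\}) / (n_perm + 1).
#'
#' @param ds A [gmv_dataset].
#' @param group_a,group_b Group names (disjoint subject sets, each >= 10).
#' @param structure Structure name.
#' @param n_perm Number of permutations (study scale 5000).
#' @param seed RNG seed for the permutation stream.
#' @param absolute Passed to [wta_label()].
#' @return Object of class `map_comparison`: data frame `table` (lobe,
#'   count_a, count_b, observed_diff, p_perm, direction), plus `structure`,
#'   `n_perm`, `seed`.
#' @export
permutation_map_test <- function(ds, group_a, group_b, structure,
                                 n_perm = 5000L, seed = 1L,
                                 absolute = FALSE) {
  rows_a <- group_rows(ds, group_a)
  rows_b <- group_rows(ds, group_b)
  if (length(intersect(rows_a, rows_b))) stop("groups overlap")
  if (length(rows_a) < 10L || length(rows_b) < 10L)
    stop("both groups need >= 10 subjects")
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse p-value grid")

  LM <- .lobe_mean_matrix(ds)
  Y <- ds$matrix[, region_columns(ds, structure_ids()[[structure]]),
                 drop = FALSE]
  tiv <- ds$cohort$tiv
  counts_for <- function(sub) {
    all_r <- .wta_all_r(LM, tiv, Y, sub)
    cmp <- if (absolute) abs(all_r) else all_r
    tabulate(max.col(cmp, ties.method = "first"), nbins = 5L)
  }
  ca <- counts_for(rows_a)
  cb <- counts_for(rows_b)
  obs <- ca - cb

  pool <- c(rows_a, rows_b)
  na <- length(rows_a)
  exceed <- integer(5)
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    perm <- sample(pool)
    d <- counts_for(perm[seq_len(na)]) - counts_for(perm[-seq_len(na)])
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  pvals <- (1 + exceed) / (n_perm + 1)
  tab <- data.frame(lobe = names(lobe_ids()),
                    count_a = as.integer(ca), count_b = as.integer(cb),
                    observed_diff = as.integer(obs), p_perm = pvals,
                    direction = ifelse(obs > 0, "increased",
                                       ifelse(obs < 0, "decreased", "equal")),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, structure = structure, group_a = group_a,
                 group_b = group_b, n_perm = n_perm, seed = seed),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat("WTA map comparison: ", x$group_a, " vs ", x$group_b, " (",
      x$structure, "), ", x$n_perm, " permutations\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Write an SCN map as a NIfTI label volume plus a coefficient table
#'
#' @param m An `scn_map`.
#' @param ds The [gmv_dataset] it was computed from.
#' @param prefix Output path prefix; writes `<prefix>_labels.nii.gz` and
#'   `<prefix>_coefficients.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_scn_map <- function(m, ds, prefix) {
  cols <- region_columns(ds, structure_ids()[[m$structure]])
  vi <- ds$voxel_index[cols, ]
  vol <- array(0L, ds$dims)
  vol[cbind(vi$i + 1L, vi$j + 1L, vi$k + 1L)] <- m$winner_label
  write_volume(volume_image(vol, affine = ds$atlas$labels$affine),
               paste0(prefix, "_labels.nii.gz"))
  tab <- data.frame(i = vi$i, j = vi$j, k = vi$k,
                    winner = m$winner_label, winner_r = m$winner_r)
  tab <- cbind(tab, stats::setNames(as.data.frame(m$all_r),
                                    paste0("r_", names(lobe_ids()))))
  utils::write.table(tab, paste0(prefix, "_coefficients.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
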