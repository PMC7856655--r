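#' Canonical 20-node labels
#'
#' Five cortical lobes followed by the five WTA subregions of the striatum,
#' thalamus and cerebellum, each named `structure(lobe)`.
#'
#' @return Character vector of length 20.
#' @export
network_node_labels <- function() {
  lobes <- names(lobe_ids())
  c(paste0("cortex(", lobes, ")"),
    paste0("striatum(", lobes, ")"),
    paste0("thalamus(", lobes, ")"),
    paste0("cerebellum(", lobes, ")"))
}

#' Extract the 20 node signals of the covariance network
#'
#' Node signals are per-subject mean gray-matter values: the five cortical
#' lobes, then for each structure the five subregions assigned to each lobe
#' by the group's winner-take-all map. A lobe that wins no voxels in a
#' structure yields a missing (all-`NA`) node, which is excluded from edges
#' downstream.
#'
#' @param ds A [gmv_dataset].
#' @param wta_maps Named list of `scn_map` for `striatum`, `thalamus`,
#'   `cerebellum` (computed from the same group as `subjects`).
#' @param subjects Row subset; default all.
#' @return Subjects x 20 matrix, columns in [network_node_labels()] order.
#' @export
extract_node_signals <- function(ds, wta_maps, subjects = NULL) {
  stopifnot(inherits(ds, "gmv_dataset"))
  if (is.null(subjects)) subjects <- seq_len(nrow(ds$matrix))
  strs <- names(structure_ids())
  stopifnot(all(strs %in% names(wta_maps)))
  out <- matrix(NA_real_, length(subjects), 20L,
                dimnames = list(NULL, network_node_labels()))
  for (l in 1:5)
    out[, l] <- roi_mean_signal(ds, region_columns(ds, l), subjects)
  for (si in seq_along(strs)) {
    cols <- region_columns(ds, structure_ids()[[strs[si]]])
    m <- wta_maps[[strs[si]]]
    stopifnot(length(m$winner_label) == length(cols))
    for (l in 1:5) {
      sub_cols <- cols[m$winner_label == l]
      col <- 5L * si + l
      if (length(sub_cols) == 0L) {
        # empty subregion: node stays NA, logged
        message("empty subregion: ", strs[si], " lobe ", l,
                " wins no voxels; node excluded")
      } else {
        out[, col] <- roi_mean_signal(ds, sub_cols, subjects)
      }
    }
  }
  out
}

#' Build the 20 x 20 partial-correlation covariance network
#'
#' Every edge is the pairwise partial correlation between two node signals
#' controlling the covariate columns (total intracranial volume by default),
#' i.e. the correlation of the two signals' residuals after regression on
#' `[1, covariates]`. The diagonal is 1; missing nodes give `NA` rows.
#'
#' @param signals Subjects x 20 node-signal matrix.
#' @param covariates Subjects x k covariate matrix (e.g. TIV).
#' @param group Optional group tag carried on the result.
#' @return Object of class `cov_network`: `R` (20 x 20), `node_labels`,
#'   `group`, `n`.
#' @export
build_network <- function(signals, covariates = NULL, group = NA_character_) {
  signals <- as.matrix(signals)
  n <- nrow(signals)
  k <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n <= 20L + k) stop("need more than 20 + k subjects")
  ok <- !apply(is.na(signals), 2, any)
  R <- matrix(NA_real_, ncol(signals), ncol(signals))
  res <- .residualize(signals[, ok, drop = FALSE], covariates)
  R[ok, ok] <- stats::cor(res)
  diag(R) <- ifelse(ok, 1, NA_real_)
  labels <- colnames(signals)
  if (is.null(labels)) labels <- network_node_labels()
  dimnames(R) <- list(labels, labels)
  structure(list(R = R, node_labels = labels, group = group, n = n),
            class = "cov_network")
}

#' @export
print.cov_network <- function(x, ...) {
  cat("<cov_network> 20 x 20, n = ", x$n,
      if (!is.na(x$group)) paste0(", group ", x$group), "\n", sep = "")
  invisible(x)
}

# network R matrix for a subject subset, recomputing WTA subregions for that
# subset (used by the permutation null); Ys = list of structure matrices
.group_network_R <- function(LM, tiv, Ys, sub) {
  sig <- matrix(NA_real_, length(sub), 20L)
  sig[, 1:5] <- LM[sub, , drop = FALSE]
  for (si in 1:3) {
    all_r <- .wta_all_r(LM, tiv, Ys[[si]], sub)
    winner <- max.col(all_r, ties.method = "first")
    Ysub <- Ys[[si]][sub, , drop = FALSE]
    for (l in 1:5) {
      w <- winner == l
      if (any(w))
        sig[, 5L * si + l] <- rowMeans(Ysub[, w, drop = FALSE])
    }
  }
  ok <- !apply(is.na(sig), 2, any)
  R <- matrix(NA_real_, 20L, 20L)
  res <- .residualize(sig[, ok, drop = FALSE], tiv[sub])
  R[ok, ok] <- stats::cor(res)
  diag(R) <- ifelse(ok, 1, NA_real_)
  R
}

#' Permutation comparison of two groups' covariance networks
#'
#' Edge statistic: Fisher z(R_A) - z(R_B). The null rebuilds everything per
#' permutation — pseudo-group WTA subregions, node signals and networks —
#' after shuffling the group labels, so the null is exchangeable. Two-sided
#' permutation p per edge with the add-one estimator; the result carries a
#' false-positive-adjustment record from [fpa_adjust()].
#'
#' @param ds A [gmv_dataset].
#' @param group_a,group_b Group names.
#' @param n_perm Number of permutations (study scale 5000).
#' @param seed RNG seed.
#' @param alpha Edge-level alpha for the FPA record (default 0.05).
#' @return Object of class `network_comparison`: `p_matrix` (20 x 20),
#'   `direction` (sign of the observed z difference), `observed` (z
#'   difference), `R_a`, `R_b`, `fpa`, `n_perm`, `seed`.
#' @export
compare_networks <- function(ds, group_a, group_b, n_perm = 5000L,
                             seed = 1L, alpha = 0.05) {
  rows_a <- group_rows(ds, group_a)
  rows_b <- group_rows(ds, group_b)
  if (length(rows_a) < 10L || length(rows_b) < 10L)
    stop("both groups need >= 10 subjects")
  LM <- .lobe_mean_matrix(ds)
  tiv <- ds$cohort$tiv
  Ys <- lapply(structure_ids(), function(code)
    ds$matrix[, region_columns(ds, code), drop = FALSE])

  zdiff <- function(sub_a, sub_b) {
    Ra <- .group_network_R(LM, tiv, Ys, sub_a)
    Rb <- .group_network_R(LM, tiv, Ys, sub_b)
    if (any(abs(c(Ra[upper.tri(Ra)], Rb[upper.tri(Rb)])) >= 1, na.rm = TRUE))
      stop("degenerate edge: |r| = 1 gives infinite Fisher z")
    list(z = atanh(Ra) - atanh(Rb), Ra = Ra, Rb = Rb)
  }
  obs <- zdiff(rows_a, rows_b)

  pool <- c(rows_a, rows_b)
  na <- length(rows_a)
  exceed <- matrix(0L, 20L, 20L)
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    perm <- sample(pool)
    zn <- zdiff(perm[seq_len(na)], perm[-seq_len(na)])$z
    exceed <- exceed + (abs(zn) >= abs(obs$z))
  }
  p_matrix <- (1 + exceed) / (n_perm + 1)
  diag(p_matrix) <- NA_real_
  p_matrix[is.na(obs$z)] <- NA_real_
  labels <- network_node_labels()
  dimnames(p_matrix) <- list(labels, labels)
  structure(list(p_matrix = p_matrix,
                 direction = sign(obs$z),
                 observed = obs$z, R_a = obs$Ra, R_b = obs$Rb,
                 group_a = group_a, group_b = group_b,
                 fpa = fpa_adjust(p_matrix, alpha),
                 n_perm = n_perm, seed = seed),
            class = "network_comparison")
}

#' False-positive adjustment of a network p-matrix
#'
#' Omnibus check that the number of suprathreshold edges among the 190
#' upper-triangle tests exceeds the count expected by chance
#' (`alpha * n_edges`); per-edge significance is only reported when the
#' omnibus passes.
#'
#' @param p_matrix Symmetric 20 x 20 matrix of edge p-values (diagonal
#'   ignored).
#' @param alpha Edge-level threshold in (0, 1).
#' @return List: `alpha`, `n_edges_tested`, `n_significant`,
#'   `expected_false`, `omnibus_pass`, `significant` (logical upper-triangle
#'   matrix, all `FALSE` unless the omnibus passes).
#' @export
fpa_adjust <- function(p_matrix, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  p_matrix <- as.matrix(p_matrix)
  ut <- upper.tri(p_matrix)
  pv <- p_matrix[ut]
  n_edges <- sum(!is.na(pv))
  n_sig <- sum(pv < alpha, na.rm = TRUE)
  expected <- alpha * n_edges
  pass <- n_sig > expected
  sig <- matrix(FALSE, nrow(p_matrix), ncol(p_matrix),
                dimnames = dimnames(p_matrix))
  if (pass) sig[ut] <- !is.na(p_matrix[ut]) & p_matrix[ut] < alpha
  list(alpha = alpha, n_edges_tested = n_edges, n_significant = n_sig,
       expected_false = expected, omnibus_pass = pass, significant = sig)
}

#' Network comparison summary table
#'
#' One row per upper-triangle edge, mirroring a published pairwise network
#' comparison table: seed node, target node, observed z difference, p,
#' direction.
#'
#' @param cmp A `network_comparison`.
#' @param only_significant Keep only FPA-significant edges (default FALSE).
#' @return Data frame.
#' @export
network_comparison_table <- function(cmp, only_significant = FALSE) {
  labels <- network_node_labels()
  ut <- which(upper.tri(cmp$p_matrix), arr.ind = TRUE)
  tab <- data.frame(
    node_a = labels[ut[, 1]], node_b = labels[ut[, 2]],
    z_diff = cmp$observed[ut], p_perm = cmp$p_matrix[ut],
    direction = ifelse(cmp$direction[ut] > 0, "increased", "decreased"),
    significant = cmp$fpa$significant[ut],
    stringsAsFactors = FALSE)
  if (only_significant) tab <- tab[tab$significant, , drop = FALSE]
  tab
}

#' Write a 20 x 20 matrix as TSV with node-label headers
#'
#' @param M Matrix (e.g. `cov_network$R` or a p-matrix).
#' @param path Output path.
#' @export
write_network_tsv <- function(M, path) {
  df <- data.frame(node = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
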