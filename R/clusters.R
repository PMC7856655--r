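# 26-connectivity components of a voxel subset given 0-based (i,j,k) coords;
# returns integer membership (1..n_components), order-invariant
.components26 <- function(coords) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  K <- max(coords) + 3
  key <- coords[, 1] + K * (coords[, 2] + K * coords[, 3])
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  offs <- offs[seq_len(13), ]  # half the offsets; edges are undirected
  from <- integer(0); to <- integer(0)
  for (o in seq_len(13)) {
    nb <- (coords[, 1] + offs$di[o]) +
      K * ((coords[, 2] + offs$dj[o]) + K * (coords[, 3] + offs$dk[o]))
    m <- match(nb, key)
    hit <- which(!is.na(m))
    from <- c(from, hit); to <- c(to, m[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # renumber by first appearance so traversal order cannot matter
  as.integer(factor(comp, levels = unique(comp)))
}

# suprathreshold logical vector for a stat vector
.supra <- function(values, kind, thr) {
  if (kind == "F") values >= thr else abs(values) >= thr
}

# critical value at voxel-level p for each map kind
.voxel_threshold <- function(kind, voxel_p, df) {
  switch(kind,
         F = stats::qf(voxel_p, df[1], df[2], lower.tail = FALSE),
         t = stats::qt(voxel_p / 2, df, lower.tail = FALSE),
         r = {
           tcrit <- stats::qt(voxel_p / 2, df, lower.tail = FALSE)
           tcrit / sqrt(df + tcrit^2)
         })
}

# design pieces for the permutable VBM models (Freedman-Lane residual
# permutation: refit reduced model, permute its residuals, re-test)
.cluster_design <- function(ds, design) {
  type <- design$type
  if (type == "group_anova") {
    subjects <- seq_len(nrow(ds$matrix))
    Z <- .nuisance_matrix(ds, subjects)
    G <- stats::model.matrix(~ group, data = ds$cohort)[, -1, drop = FALSE]
    X_full <- cbind(1, G, Z); X_red <- cbind(1, Z)
    stat_fun <- function(Y) .voxel_f(X_full, X_red, Y)$f
  } else if (type == "duration_corr") {
    subjects <- group_rows(ds, design$group)
    Z <- .nuisance_matrix(ds, subjects)
    dur <- ds$cohort$duration_months[subjects]
    X_red <- cbind(1, Z)
    qx <- qr(X_red)
    rx <- qr.resid(qx, dur)
    stat_fun <- function(Y) .resid_cor(rx, qr.resid(qx, Y))
  } else if (type == "slope_interaction") {
    subjects <- c(group_rows(ds, "GE_GTCS"), group_rows(ds, "FE_FBTS"))
    co <- ds$cohort[subjects, ]
    g <- as.integer(co$group == "GE_GTCS")
    Z <- .nuisance_matrix(ds, subjects)
    X_red <- cbind(intercept = 1, group = g, duration = co$duration_months,
                   Z)
    X_full <- cbind(X_red, group_x_duration = g * co$duration_months)
    stat_fun <- function(Y) .voxel_t(X_full, Y, "group_x_duration")$t
  } else stop("unknown design type: ", type)
  Y <- ds$matrix[subjects, , drop = FALSE]
  list(Y = Y, stat_fun = stat_fun, qred = qr(X_red), n = length(subjects))
}

#' Permutation cluster-extent correction of a statistic map
#'
#' Thresholds the map at a voxel-level p, finds 26-connected suprathreshold
#' clusters, and corrects each cluster's size against the permutation null
#' distribution of the maximum cluster size. Nuisance covariates are handled
#' by Freedman-Lane residual permutation: the reduced (nuisance-only) model
#' is fitted once, its residuals are row-permuted, and the statistic map is
#' recomputed on refitted data each permutation.
#'
#' @param map A `stat_map` from [voxelwise_group_anova()],
#'   [voxelwise_duration_corr()] or [slope_interaction_map()].
#' @param ds The [gmv_dataset] the map came from.
#' @param design List naming the permutable design: `list(type =
#'   "group_anova")`, `list(type = "duration_corr", group = ...)` or
#'   `list(type = "slope_interaction")`.
#' @param voxel_p Voxel-level threshold (e.g. 0.01); two-sided for t/r maps.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return Object of class `cluster_result`: `clusters` (data frame: id,
#'   size, peak i/j/k, peak value, p_corrected), `membership` (cluster id
#'   per mask voxel, 0 = subthreshold), `threshold`, `null_max`, `n_perm`,
#'   `seed`. Empty `clusters` when nothing survives the voxel threshold.
#' @export
cluster_correct <- function(map, ds, design, voxel_p = 0.01,
                            n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(map, "stat_map"))
  thr <- .voxel_threshold(map$kind, voxel_p, map$df)
  parts <- .cluster_design(ds, design)
  vi <- map$voxel_index

  clusters_of <- function(values) {
    sup <- which(.supra(values, map$kind, thr))
    if (length(sup) == 0L)
      return(list(sizes = integer(0), membership = integer(0), sup = sup))
    memb <- .components26(as.matrix(vi[sup, c("i", "j", "k")]))
    list(sizes = tabulate(memb), membership = memb, sup = sup)
  }

  obs <- clusters_of(map$values)

  # Freedman-Lane null
  fitted_red <- qr.fitted(parts$qred, parts$Y)
  resid_red <- qr.resid(parts$qred, parts$Y)
  null_max <- integer(n_perm)
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    perm <- sample.int(parts$n)
    Yp <- fitted_red + resid_red[perm, , drop = FALSE]
    cl <- clusters_of(parts$stat_fun(Yp))
    null_max[p] <- if (length(cl$sizes)) max(cl$sizes) else 0L
  }

  membership <- integer(nrow(vi))
  clusters <- data.frame(id = integer(0), size = integer(0),
                         peak_i = integer(0), peak_j = integer(0),
                         peak_k = integer(0), peak_value = numeric(0),
                         p_corrected = numeric(0))
  if (length(obs$sizes)) {
    membership[obs$sup] <- obs$membership
    rows <- lapply(seq_along(obs$sizes), function(ci) {
      vox <- obs$sup[obs$membership == ci]
      pk <- vox[which.max(abs(map$values[vox]))]
      data.frame(id = ci, size = obs$sizes[ci],
                 peak_i = vi$i[pk], peak_j = vi$j[pk], peak_k = vi$k[pk],
                 peak_value = map$values[pk],
                 p_corrected = (1 + sum(null_max >= obs$sizes[ci])) /
                   (n_perm + 1))
    })
    clusters <- do.call(rbind, rows)
  }
  structure(list(clusters = clusters, membership = membership,
                 voxel_p = voxel_p, threshold = thr, null_max = null_max,
                 n_perm = n_perm, seed = seed, kind = map$kind),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> voxel p ", x$voxel_p, " (", x$kind, " >= ",
      signif(x$threshold, 4), "), ", nrow(x$clusters), " cluster(s), ",
      x$n_perm, " permutations\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
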