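# design helpers ------------------------------------------------------------

# numeric covariate matrix [tiv, age, sexM] for a subject subset
.nuisance_matrix <- function(ds, subjects, tiv = TRUE, age = TRUE,
                             sex = TRUE) {
  co <- ds$cohort[subjects, , drop = FALSE]
  Z <- NULL
  if (tiv) Z <- cbind(Z, tiv = co$tiv)
  if (age) Z <- cbind(Z, age = co$age)
  if (sex) Z <- cbind(Z, sexM = as.integer(co$sex == "M"))
  Z
}

#' Statistic map container
#'
#' @param kind "F", "t" or "r".
#' @param values Numeric vector over the dataset's in-mask voxels.
#' @param df Degrees of freedom (length 2 for F).
#' @param ds The [gmv_dataset] defining the mask/coordinates.
#' @return Object of class `stat_map`.
#' @export
stat_map <- function(kind = c("F", "t", "r"), values, df, ds) {
  kind <- match.arg(kind)
  if (any(!is.finite(values)))
    stop("non-finite statistic inside the mask")
  structure(list(kind = kind, values = values, df = df,
                 voxel_index = ds$voxel_index, dims = ds$dims),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", x$kind, " over ", length(x$values), " voxels, df = ",
      paste(x$df, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Render a statistic map (or cluster mask) as a volume
#'
#' @param map A `stat_map`.
#' @param values Values to place at mask voxels (default the map statistic).
#' @return A [volume_image] (background 0).
#' @export
stat_map_volume <- function(map, values = map$values) {
  vol <- array(0, map$dims)
  vi <- map$voxel_index
  vol[cbind(vi$i + 1L, vi$j + 1L, vi$k + 1L)] <- values
  volume_image(vol)
}

# voxelwise OLS machinery ----------------------------------------------------

# RSS per voxel under a design
.rss <- function(qx, Y) colSums(qr.resid(qx, Y)^2)

# per-voxel F comparing full vs reduced design
.voxel_f <- function(X_full, X_red, Y) {
  qf_ <- qr(X_full)
  qr_ <- qr(X_red)
  if (qf_$rank < ncol(X_full)) stop("rank-deficient design")
  rss1 <- .rss(qf_, Y)
  rss0 <- .rss(qr_, Y)
  df1 <- ncol(X_full) - ncol(X_red)
  df2 <- nrow(X_full) - qf_$rank
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(f = pmax(f, 0), df = c(df1, df2))
}

# per-voxel t of one column of X
.voxel_t <- function(X, Y, term) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear design")
  B <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtX_inv <- chol2inv(qr.R(qx))
  j <- match(term, colnames(X))
  t <- B[j, ] / sqrt(sigma2 * XtX_inv[j, j])
  list(t = t, df = df)
}

#' Voxelwise three-group ANOVA of gray-matter volume
#'
#' Per voxel, the F statistic of the group factor in an OLS model with the
#' nuisance covariates TIV, age and sex.
#'
#' @param ds A [gmv_dataset] with all three groups (>= 3 subjects each).
#' @return A `stat_map` of kind "F" with df = (2, n - rank).
#' @export
voxelwise_group_anova <- function(ds) {
  n_by <- table(ds$cohort$group)
  if (any(n_by < 3L)) stop("need >= 3 subjects per group")
  subjects <- seq_len(nrow(ds$matrix))
  Z <- .nuisance_matrix(ds, subjects)
  G <- stats::model.matrix(~ group, data = ds$cohort)[, -1, drop = FALSE]
  X_full <- cbind(1, G, Z)
  X_red <- cbind(1, Z)
  res <- .voxel_f(X_full, X_red, ds$matrix)
  stat_map("F", res$f, res$df, ds)
}

#' Voxelwise partial correlation of gray matter with disease duration
#'
#' Per voxel, the partial correlation between gray-matter value and epilepsy
#' duration within one patient group, controlling TIV, sex and age.
#'
#' @param ds A [gmv_dataset].
#' @param group Patient group name (>= 10 subjects).
#' @return A `stat_map` of kind "r" with df = n - k - 2 (residual df of the
#'   correlation).
#' @export
voxelwise_duration_corr <- function(ds, group) {
  subjects <- group_rows(ds, group)
  if (length(subjects) < 10L) stop("need >= 10 subjects")
  dur <- ds$cohort$duration_months[subjects]
  if (anyNA(dur)) stop("duration missing for group ", group)
  Z <- .nuisance_matrix(ds, subjects)
  X <- cbind(1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate design")
  rx <- qr.resid(qx, dur)
  RY <- qr.resid(qx, ds$matrix[subjects, , drop = FALSE])
  r <- .resid_cor(rx, RY)
  stat_map("r", r, length(subjects) - ncol(X) - 1L, ds)
}

#' Voxelwise group-by-duration slope interaction
#'
#' Per voxel, the t statistic of the Group x Duration term in the OLS model
#' `GMV ~ Group + Duration + Group:Duration + TIV + age + sex` over the two
#' patient groups: where the duration slope differs between syndromes.
#'
#' @param ds A [gmv_dataset].
#' @return A `stat_map` of kind "t".
#' @export
slope_interaction_map <- function(ds) {
  subjects <- c(group_rows(ds, "GE_GTCS"), group_rows(ds, "FE_FBTS"))
  if (length(group_rows(ds, "GE_GTCS")) < 10L ||
      length(group_rows(ds, "FE_FBTS")) < 10L)
    stop("both patient groups need >= 10 subjects")
  co <- ds$cohort[subjects, ]
  g <- as.integer(co$group == "GE_GTCS")
  dur <- co$duration_months
  Z <- .nuisance_matrix(ds, subjects)
  X <- cbind(intercept = 1, group = g, duration = dur,
             group_x_duration = g * dur, Z)
  res <- .voxel_t(X, ds$matrix[subjects, , drop = FALSE],
                  "group_x_duration")
  stat_map("t", res$t, res$df, ds)
}
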