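#' One-tailed p-value of a t statistic
#'
#' Upper-tail probability of |t| under the t distribution with `df` degrees
#' of freedom, P(T >= |t|); the direction is carried by the sign of the
#' estimate, which is how published modulation tables pair a signed t with a
#' one-tailed p.
#'
#' @param t t statistic (any sign).
#' @param df Degrees of freedom (>= 1).
#' @return p in (0, 0.5\].
#' @export
one_tailed_p <- function(t, df) {
  stopifnot(df >= 1)
  stats::pt(abs(t), df, lower.tail = FALSE)
}

# OLS fit returning the t statistic of one term; X includes the intercept
.ols_term_t <- function(X, y, term) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear design")
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtX_inv))
  names(se) <- colnames(X)
  list(betas = beta, t = beta[term] / se[term], df = df, se = se)
}

#' Within-group duration-modulation model
#'
#' Fits, by ordinary least squares with an intercept,
#' `GM_target ~ GM_seed + Duration + GM_seed:Duration + TIV`
#' and tests the seed-by-duration interaction: a negative interaction means
#' the seed-target covariance weakens with disease duration. The p-value is
#' one-tailed in the direction of the estimate (two-tailed via
#' `two_tailed = TRUE`).
#'
#' @param gm_target,gm_seed,duration,tiv Numeric vectors of equal length n
#'   (> 6), no missing values.
#' @param two_tailed Report a two-tailed p instead (default `FALSE`).
#' @return Object of class `modulation_fit`: `betas`, `t_interaction`, `df`
#'   (n - 5), `p`, `direction`.
#' @export
fit_within_group <- function(gm_target, gm_seed, duration, tiv,
                             two_tailed = FALSE) {
  n <- length(gm_target)
  stopifnot(length(gm_seed) == n, length(duration) == n, length(tiv) == n)
  if (n <= 6L) stop("need n > 6")
  if (anyNA(c(gm_target, gm_seed, duration, tiv)))
    stop("missing values not allowed")
  X <- cbind(intercept = 1, gm_seed = gm_seed, duration = duration,
             seed_x_duration = gm_seed * duration, tiv = tiv)
  fit <- .ols_term_t(X, gm_target, "seed_x_duration")
  p <- if (two_tailed) 2 * one_tailed_p(fit$t, fit$df) else
    one_tailed_p(fit$t, fit$df)
  structure(list(betas = fit$betas, t_interaction = unname(fit$t),
                 df = fit$df, p = unname(p),
                 direction = sign(unname(fit$t)), scope = "within_group"),
            class = "modulation_fit")
}

#' Between-group duration-modulation model
#'
#' Fits, over both patient groups,
#' `GM_target ~ Group + GM_seed + Duration + Group:GM_seed +
#'  Group:Duration + GM_seed:Duration + Group:GM_seed:Duration + TIV`
#' with an intercept and Group coded 0/1 (GE_GTCS = 1), and tests the triple
#' interaction: how differently duration modulates the seed-target
#' covariance in the two groups.
#'
#' @param gm_target,gm_seed,duration,tiv Numeric vectors over both groups.
#' @param group Factor/character vector with both patient groups present;
#'   GE_GTCS is coded 1.
#' @param two_tailed Report a two-tailed p (default `FALSE`).
#' @return A `modulation_fit` with `df = n - 9`.
#' @export
fit_between_group <- function(gm_target, gm_seed, duration, tiv, group,
                              two_tailed = FALSE) {
  n <- length(gm_target)
  stopifnot(length(group) == n)
  if (n <= 10L) stop("need n > 10")
  g <- as.integer(as.character(group) == "GE_GTCS")
  if (length(unique(g)) < 2L) stop("both patient groups must be present")
  if (anyNA(c(gm_target, gm_seed, duration, tiv)))
    stop("missing values not allowed")
  X <- cbind(intercept = 1, group = g, gm_seed = gm_seed,
             duration = duration, group_x_seed = g * gm_seed,
             group_x_duration = g * duration,
             seed_x_duration = gm_seed * duration,
             group_x_seed_x_duration = g * gm_seed * duration, tiv = tiv)
  fit <- .ols_term_t(X, gm_target, "group_x_seed_x_duration")
  p <- if (two_tailed) 2 * one_tailed_p(fit$t, fit$df) else
    one_tailed_p(fit$t, fit$df)
  structure(list(betas = fit$betas, t_interaction = unname(fit$t),
                 df = fit$df, p = unname(p),
                 direction = sign(unname(fit$t)), scope = "between_group"),
            class = "modulation_fit")
}

#' @export
print.modulation_fit <- function(x, ...) {
  cat(sprintf("%s modulation: t = %.3f (df = %d), one-tailed p = %.4f\n",
              x$scope, x$t_interaction, x$df, x$p))
  invisible(x)
}

# node signal for (structure-or-cortex, lobe); cortex = the lobe mask itself
.subnet_signal <- function(ds, wta_maps, structure, lobe, subjects) {
  if (structure == "cortex")
    return(roi_mean_signal(ds, region_columns(ds, lobe), subjects))
  cols <- region_columns(ds, structure_ids()[[structure]])
  m <- wta_maps[[structure]]
  sub_cols <- cols[m$winner_label == lobe]
  if (length(sub_cols) == 0L) return(NULL)
  roi_mean_signal(ds, sub_cols, subjects)
}

#' Duration-modulation scan over the five lobe subnetworks
#'
#' For each lobe's subnetwork — the cortex node plus the three subcortical
#' subregions assigned to that lobe — fits the requested modulation model
#' for every ordered (seed, target) pair among cortex, striatum, thalamus
#' and cerebellum (12 directed pairs), 60 rows per scope. Comparisons stay
#' within one subnetwork because cross-lobe covariance is not modelled.
#'
#' @param ds A [gmv_dataset].
#' @param wta_maps Named list of `scn_map`s (striatum/thalamus/cerebellum)
#'   defining the subregions used as nodes.
#' @param scope `"within_group"` (fit one patient group) or
#'   `"between_group"` (both patient groups, triple interaction).
#' @param group Patient group for `within_group` scope.
#' @param two_tailed Passed to the fitters.
#' @return Data frame: subnetwork, seed_structure, target_structure, scope,
#'   n, t, df, p, direction (`NA` rows for empty subregions).
#' @export
subnetwork_modulation_scan <- function(ds, wta_maps,
                                       scope = c("within_group",
                                                 "between_group"),
                                       group = "GE_GTCS",
                                       two_tailed = FALSE) {
  scope <- match.arg(scope)
  subjects <- if (scope == "within_group") group_rows(ds, group) else
    c(group_rows(ds, "GE_GTCS"), group_rows(ds, "FE_FBTS"))
  dur <- ds$cohort$duration_months[subjects]
  tiv <- ds$cohort$tiv[subjects]
  grp <- ds$cohort$group[subjects]
  structures <- c("cortex", names(structure_ids()))
  pairs <- expand.grid(seed = structures, target = structures,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$seed != pairs$target, ]
  rows <- list()
  for (lobe in 1:5) {
    sig <- lapply(structures, function(s)
      .subnet_signal(ds, wta_maps, s, lobe, subjects))
    names(sig) <- structures
    for (pi in seq_len(nrow(pairs))) {
      s_seed <- sig[[pairs$seed[pi]]]
      s_tgt <- sig[[pairs$target[pi]]]
      fit <- NULL
      if (!is.null(s_seed) && !is.null(s_tgt)) {
        fit <- if (scope == "within_group")
          fit_within_group(s_tgt, s_seed, dur, tiv, two_tailed) else
            fit_between_group(s_tgt, s_seed, dur, tiv, grp, two_tailed)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subnetwork = names(lobe_ids())[lobe],
        seed_structure = pairs$seed[pi],
        target_structure = pairs$target[pi],
        scope = scope,
        group = if (scope == "within_group") group else "GE_GTCS_vs_FE_FBTS",
        n = length(subjects),
        t = if (is.null(fit)) NA_real_ else fit$t_interaction,
        df = if (is.null(fit)) NA_integer_ else fit$df,
        p = if (is.null(fit)) NA_real_ else fit$p,
        direction = if (is.null(fit)) NA_real_ else fit$direction,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
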