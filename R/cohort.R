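#' Cohort table
#'
#' Validates a subject-level cohort table for the three study arms: patients
#' with generalized tonic-clonic seizures of genetic generalized epilepsy
#' (GE_GTCS), patients with focal epilepsy and focal-to-bilateral
#' tonic-clonic seizures (FE_FBTS), and healthy controls (HC).
#'
#' @param df Data frame with columns `subject_id`, `group` (one of
#'   "GE_GTCS", "FE_FBTS", "HC"), `duration_months` (non-negative; `NA`
#'   allowed for HC only), `tiv` (total intracranial volume, ml, > 0),
#'   `age` (years, > 0), `sex` ("M"/"F").
#' @return The validated data frame with `group` and `sex` as factors, class
#'   `c("cohort_table", "data.frame")`.
#' @export
cohort_table <- function(df) {
  req <- c("subject_id", "group", "duration_months", "tiv", "age", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  if (anyDuplicated(df$subject_id)) stop("subject_id must be unique")
  df$group <- factor(as.character(df$group),
                     levels = c("GE_GTCS", "FE_FBTS", "HC"))
  if (anyNA(df$group)) stop("group must be one of GE_GTCS, FE_FBTS, HC")
  df$sex <- factor(as.character(df$sex), levels = c("M", "F"))
  if (anyNA(df$sex)) stop("sex must be M or F")
  bad_dur <- df$group != "HC" & (is.na(df$duration_months) |
                                   df$duration_months < 0)
  if (any(bad_dur)) stop("duration_months must be present and non-negative ",
                         "for every patient row")
  if (any(is.na(df$tiv) | df$tiv <= 0)) stop("tiv must be > 0")
  if (any(is.na(df$age) | df$age <= 0)) stop("age must be > 0")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read / write a cohort TSV
#'
#' Tab-separated with header `subject_id group duration_months tiv age sex`.
#'
#' @param path File path.
#' @return [cohort_table] for the reader; `path` invisibly for the writer.
#' @export
read_cohort <- function(path) {
  cohort_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @param cohort A [cohort_table].
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Demographic balance of the three study arms
#'
#' One-way ANOVA on age across the three groups, Pearson chi-square (no
#' continuity correction) on the 3x2 group-by-sex table, and a pooled-variance
#' two-sample t test on disease duration between the two patient groups.
#' All p values are two-tailed.
#'
#' @param cohort A [cohort_table] containing all three groups, each with at
#'   least 2 subjects.
#' @return A list of class `balance_report` with elements `age` (F, df1, df2,
#'   p), `sex` (chisq, df, p, table) and `duration` (t, df, p, means).
#' @export
demographic_balance <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  n_by <- table(cohort$group)
  if (length(n_by) != 3L || any(n_by == 0))
    stop("all three groups must be present")
  if (any(n_by < 2)) stop("every group needs >= 2 subjects")

  age_fit <- stats::oneway.test(age ~ group, data = cohort, var.equal = TRUE)
  sex_tab <- table(cohort$group, cohort$sex)
  sex_fit <- suppressWarnings(stats::chisq.test(sex_tab, correct = FALSE))
  pat <- cohort[cohort$group != "HC", , drop = FALSE]
  dur_fit <- stats::t.test(duration_months ~ droplevels(pat$group), data = pat,
                           var.equal = TRUE)

  structure(list(
    age = list(f = unname(age_fit$statistic),
               df1 = unname(age_fit$parameter[1]),
               df2 = unname(age_fit$parameter[2]),
               p = age_fit$p.value),
    sex = list(chisq = unname(sex_fit$statistic),
               df = unname(sex_fit$parameter),
               p = sex_fit$p.value, table = sex_tab),
    duration = list(t = unname(dur_fit$statistic),
                    df = unname(dur_fit$parameter),
                    p = dur_fit$p.value,
                    means = unname(dur_fit$estimate))
  ), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Demographic balance\n")
  cat(sprintf("  age      one-way ANOVA  F(%d, %d) = %.3f, p = %.3f\n",
              x$age$df1, x$age$df2, x$age$f, x$age$p))
  cat(sprintf("  sex      chi-square     X2(%d) = %.3f, p = %.3f\n",
              x$sex$df, x$sex$chisq, x$sex$p))
  cat(sprintf("  duration two-sample t   t(%d) = %.3f, p = %.3f\n",
              x$duration$df, x$duration$t, x$duration$p))
  invisible(x)
}

#' Balance report as a data frame
#'
#' @param report A `balance_report`.
#' @return One row per statistic: variable, test, statistic, df, p.
#' @export
balance_report_table <- function(report) {
  data.frame(
    variable = c("age", "sex", "duration"),
    test = c("one_way_anova", "chi_square", "two_sample_t"),
    statistic = c(report$age$f, report$sex$chisq, report$duration$t),
    df = c(paste(report$age$df1, report$age$df2, sep = ","),
           as.character(report$sex$df), as.character(report$duration$df)),
    p = c(report$age$p, report$sex$p, report$duration$p),
    stringsAsFactors = FALSE
  )
}

#' One-way ANOVA reconstructed from group summaries
#'
#' Rebuilds the standard one-way F statistic from per-group means, standard
#' errors of the mean and sizes: SD_i = SEM_i * sqrt(n_i), between and within
#' sums of squares from the usual decomposition, F = MS_between / MS_within
#' on (k - 1, N - k) degrees of freedom. Useful when only published summary
#' statistics are available.
#'
#' @param means,sems,ns Numeric vectors of equal length (>= 2 groups);
#'   `sems > 0`, `ns >= 2`.
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(means, sems, ns) {
  k <- length(means)
  stopifnot(length(sems) == k, length(ns) == k, k >= 2)
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (any(sems <= 0)) stop("sems must be > 0")
  sds <- sems * sqrt(ns)
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1L
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}
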