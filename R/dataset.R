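#' Subjects-by-voxels gray-matter dataset
#'
#' Flattens a list of aligned gray-matter probability volumes into one
#' subjects x in-mask-voxels matrix. The mask is the set of non-background
#' atlas voxels; columns are ordered lexicographically by 0-based voxel
#' index (i, then j, then k), so column order is deterministic for a given
#' atlas.
#'
#' @param volumes List of [volume_image], one per cohort row, all on the
#'   atlas grid.
#' @param cohort A [cohort_table] with one row per volume.
#' @param atl An [atlas].
#' @return Object of class `gmv_dataset`: `matrix` (subjects x voxels),
#'   `voxel_index` (data frame col, i, j, k, label), `cohort`, `atlas`.
#' @export
gmv_dataset <- function(volumes, cohort, atl) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(atl, "atlas"))
  if (length(volumes) != nrow(cohort))
    stop("need one volume per cohort row")
  dims <- dim(atl$labels$data)
  lab <- atl$labels$data
  inmask <- which(lab > 0L)
  ijk <- arrayInd(inmask, dims) - 1L
  ord <- order(ijk[, 1], ijk[, 2], ijk[, 3])
  inmask <- inmask[ord]
  ijk <- ijk[ord, , drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(cohort), ncol = length(inmask),
                dimnames = list(cohort$subject_id, NULL))
  for (s in seq_along(volumes)) {
    v <- volumes[[s]]
    stopifnot(inherits(v, "volume_image"))
    if (!all(dim(v$data) == dims))
      stop("volume ", s, " is not on the atlas grid")
    mat[s, ] <- v$data[inmask]
  }
  vi <- data.frame(col = seq_along(inmask), i = ijk[, 1], j = ijk[, 2],
                   k = ijk[, 3], label = lab[inmask])
  structure(list(matrix = mat, voxel_index = vi, cohort = cohort,
                 atlas = atl, dims = dims),
            class = "gmv_dataset")
}

#' @export
print.gmv_dataset <- function(x, ...) {
  cat("<gmv_dataset> ", nrow(x$matrix), " subjects x ", ncol(x$matrix),
      " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Columns of the dataset belonging to an atlas region
#'
#' @param ds A [gmv_dataset].
#' @param label Integer atlas code (see [lobe_ids()], [structure_ids()]).
#' @return Integer column indices.
#' @export
region_columns <- function(ds, label) {
  which(ds$voxel_index$label == label)
}

#' Mean regional signal per subject
#'
#' Arithmetic mean gray-matter value over a voxel set, per subject — the
#' averaged GMV sequence used as the seed signal of each cortical lobe.
#'
#' @param ds A [gmv_dataset].
#' @param voxel_set Non-empty integer vector of dataset columns.
#' @param subjects Optional row subset (indices or logical); default all.
#' @return Numeric vector, one value per (selected) subject.
#' @export
roi_mean_signal <- function(ds, voxel_set, subjects = NULL) {
  stopifnot(inherits(ds, "gmv_dataset"))
  if (length(voxel_set) == 0L) stop("voxel_set must be non-empty")
  if (any(voxel_set < 1L | voxel_set > ncol(ds$matrix)))
    stop("voxel_set out of range")
  m <- ds$matrix
  if (!is.null(subjects)) m <- m[subjects, , drop = FALSE]
  rowMeans(m[, voxel_set, drop = FALSE])
}

#' Row indices of a group
#'
#' @param ds A [gmv_dataset].
#' @param group Group name ("GE_GTCS", "FE_FBTS", "HC").
#' @return Integer row indices into the dataset.
#' @export
group_rows <- function(ds, group) {
  which(ds$cohort$group == group)
}
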