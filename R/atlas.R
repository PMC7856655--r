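#' Lobe and structure label codes
#'
#' The atlas divides the cortex into five non-overlapping lobes and carries
#' three subcortical/cerebellar target structures. Codes follow the map:
#' 1 frontal, 2 motor_premotor, 3 somatosensory, 4 parietal_occipital,
#' 5 temporal; 10 striatum, 11 thalamus, 12 cerebellum; 0 background.
#'
#' @name atlas-codes
#' @keywords internal
NULL

#' @export
lobe_ids <- function() {
  c(frontal = 1L, motor_premotor = 2L, somatosensory = 3L,
    parietal_occipital = 4L, temporal = 5L)
}

#' @export
structure_ids <- function() {
  c(striatum = 10L, thalamus = 11L, cerebellum = 12L)
}

#' Atlas container
#'
#' @param labels Integer [volume_image] whose values are the codes of
#'   [lobe_ids()] and [structure_ids()] plus 0 background.
#' @return Object of class `atlas` with `labels`, `lobe_ids`,
#'   `structure_ids`.
#' @export
atlas <- function(labels) {
  stopifnot(inherits(labels, "volume_image"))
  vals <- unique(as.vector(labels$data))
  known <- c(0L, lobe_ids(), structure_ids())
  if (!all(vals %in% known))
    stop("atlas contains unknown label codes: ",
         paste(setdiff(vals, known), collapse = ", "))
  for (s in names(structure_ids()))
    if (!any(labels$data == structure_ids()[[s]]))
      stop("structure mask is empty: ", s)
  for (l in names(lobe_ids()))
    if (!any(labels$data == lobe_ids()[[l]]))
      stop("lobe mask is empty: ", l)
  structure(list(labels = labels, lobe_ids = lobe_ids(),
                 structure_ids = structure_ids()),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cnt <- table(factor(as.vector(x$labels$data),
                      levels = c(x$lobe_ids, x$structure_ids)))
  names(cnt) <- c(names(x$lobe_ids), names(x$structure_ids))
  cat("<atlas> voxels per region:\n")
  print(cnt)
  invisible(x)
}
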