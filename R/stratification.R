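# Stratification of a cohort into stroma-balanced and stroma-unbalanced
# datasets. Cancer and normal samples are each sorted by stroma content;
# the balanced dataset joins the highest-stroma cancers with the
# lowest-stroma normals (equalizing average stroma between the classes),
# the unbalanced dataset joins the complementary halves (maximizing the
# difference). Equal group sizes in the two datasets keep statistical
# power, and hence p-values, directly comparable between them.

#' Split a cohort into balanced and unbalanced datasets by stroma content
#'
#' @param annotation Sample annotation data.frame (`sample_id`, `class`).
#' @param stroma_values Per-sample stroma measure: histopathology
#'   percentages or single-sample enrichment scores; aligned with
#'   `annotation` rows or named by sample id. Any monotone measure gives
#'   the same stratification.
#' @param fraction Fraction of each class assigned to each dataset
#'   (default 0.5: half-splits). With `k = floor(n_class * fraction)`
#'   samples per side, the middle `n_class - 2k` samples are excluded, so
#'   an odd class count under half-splitting drops its median sample.
#' @param stroma_source Label recording where the stroma values came from
#'   (`"histopathology"` or `"gsea"`).
#' @return A list of class `"stratification"`: `balanced_cancer`,
#'   `balanced_normal`, `unbalanced_cancer`, `unbalanced_normal`,
#'   `excluded` (sample id vectors) and `stroma_source`.
#' @export
split_by_stroma <- function(annotation, stroma_values, fraction = 0.5,
                            stroma_source = c("histopathology", "gsea")) {
  stroma_source <- match.arg(stroma_source)
  if (fraction <= 0 || fraction > 0.5)
    stop("`fraction` must lie in (0, 0.5]")
  stroma <- .aligned_stroma(annotation, stroma_values)
  can <- annotation$sample_id[annotation$class == "cancer"]
  nor <- annotation$sample_id[annotation$class == "normal"]
  if (!length(can) || !length(nor))
    stop("both cancer and normal samples are required")
  can <- can[order(stroma[can], can, method = "radix")]   # ascending stroma
  nor <- nor[order(stroma[nor], nor, method = "radix")]
  kc <- floor(length(can) * fraction)
  kn <- floor(length(nor) * fraction)
  if (kc < 1L || kn < 1L) stop("`fraction` leaves an empty group")
  structure(list(
    balanced_cancer = rev(can)[seq_len(kc)],        # highest-stroma cancers
    balanced_normal = nor[seq_len(kn)],             # lowest-stroma normals
    unbalanced_cancer = can[seq_len(kc)],
    unbalanced_normal = rev(nor)[seq_len(kn)],
    excluded = c(if (length(can) > 2L * kc) can[(kc + 1L):(length(can) - kc)],
                 if (length(nor) > 2L * kn) nor[(kn + 1L):(length(nor) - kn)]),
    stroma_source = stroma_source), class = "stratification")
}

#' Median split of samples into high- and low-stroma groups
#'
#' For cohorts without normal samples no balanced contrast can be built;
#' samples (typically the cancer class) are simply split at the median
#' stroma value. An odd count drops the median sample; fully tied stroma
#' values fall back to a deterministic split by sample id with a warning.
#'
#' @param annotation Annotation data.frame, or a character vector of
#'   sample ids.
#' @param stroma_values As in [split_by_stroma()].
#' @return A list with `low` and `high` sample id vectors.
#' @export
split_high_low <- function(annotation, stroma_values) {
  ids <- if (is.data.frame(annotation)) annotation$sample_id else annotation
  if (length(ids) < 2L) stop("need >= 2 samples to split")
  stroma <- .aligned_stroma(data.frame(sample_id = ids), stroma_values)
  if (length(unique(stroma[ids])) == 1L)
    warning("all stroma values tied; splitting deterministically by sample id",
            call. = FALSE)
  ids <- ids[order(stroma[ids], ids, method = "radix")]
  k <- floor(length(ids) / 2)
  list(low = ids[seq_len(k)], high = rev(ids)[seq_len(k)])
}

# Stroma values as a complete named vector over annotation$sample_id.
.aligned_stroma <- function(annotation, stroma_values) {
  ids <- annotation$sample_id
  if (is.null(names(stroma_values))) {
    if (length(stroma_values) != length(ids))
      stop("`stroma_values` must be named by sample id or aligned with the annotation")
    names(stroma_values) <- ids
  }
  miss <- ids[!(ids %in% names(stroma_values)) | is.na(stroma_values[ids])]
  if (length(miss))
    stop("missing stroma value for sample '", miss[[1L]], "'")
  stroma_values[ids]
}

#' Stratification as a per-sample table
#' @param x A `"stratification"`.
#' @param ... Unused.
#' @return data.frame with columns `sample_id`, `dataset` (`"balanced"`,
#'   `"unbalanced"` or `"excluded"`).
#' @export
as.data.frame.stratification <- function(x, ...) {
  df <- rbind(
    data.frame(sample_id = c(x$balanced_cancer, x$balanced_normal),
               dataset = "balanced", stringsAsFactors = FALSE),
    data.frame(sample_id = c(x$unbalanced_cancer, x$unbalanced_normal),
               dataset = "unbalanced", stringsAsFactors = FALSE),
    if (length(x$excluded))
      data.frame(sample_id = x$excluded, dataset = "excluded",
                 stringsAsFactors = FALSE))
  df[order(df$sample_id, method = "radix"), , drop = FALSE]
}
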