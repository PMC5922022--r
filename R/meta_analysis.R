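# Rank-based multi-cohort meta-analysis. Within each cohort every gene's
# expression is rank-normalized to 0-100 and mean-centered; the weighted
# variant centers on the equal-weight average of the two class means so
# that a cohort's (often extreme) cancer/normal imbalance cannot bias the
# centering. Cohorts are then concatenated and each gene is tested with a
# single pooled Mann-Whitney test over all covering cohorts.

#' Rank-normalize one gene's values to 0-100
#'
#' Average ranks for ties, mapped affinely so rank 1 -> 0 and rank n ->
#' 100. Invariant under any strictly monotone transform of the values.
#'
#' @param x Numeric vector (>= 2 values).
#' @return Scores in \[0, 100\].
#' @export
rank_normalize <- function(x) {
  n <- length(x)
  if (n < 2L) stop("rank normalization needs >= 2 samples")
  (rank(x) - 1) / (n - 1) * 100
}

#' Mean-center scores, optionally weighting classes equally
#'
#' With `weighted = TRUE` the centering value is the unweighted average of
#' the two class means, `(mean_cancer + mean_normal) / 2`, which makes the
#' centering invariant to the cancer/normal imbalance of the cohort (the
#' point of the weighting). With `weighted = FALSE` the plain grand mean
#' is subtracted -- required for cohorts lacking one class.
#'
#' @param scores Numeric vector.
#' @param classes Per-sample class labels (`"cancer"`/`"normal"`);
#'   required when `weighted = TRUE`.
#' @param weighted Logical.
#' @return Centered scores.
#' @export
weighted_mean_center <- function(scores, classes = NULL, weighted = TRUE) {
  if (weighted) {
    if (is.null(classes) || length(classes) != length(scores))
      stop("`classes` must label every score when weighted = TRUE")
    cls <- unique(classes)
    if (length(cls) != 2L)
      stop("weighted centering requires both classes present")
    center <- mean(vapply(cls, function(cl) mean(scores[classes == cl]),
                          numeric(1L)))
  } else {
    center <- mean(scores)
  }
  scores - center
}

#' Build a rank-normalized, centered meta-matrix from several cohorts
#'
#' Each gene is rank-normalized to 0-100 and centered independently within
#' each cohort, then cohorts are concatenated column-wise over the union
#' of their genes. Genes absent from a cohort are `NA` in that cohort's
#' columns; `coverage` records which cohorts contain each gene.
#'
#' @param matrices List of expression matrices (one per cohort).
#' @param annotations List of matching annotation data.frames (or one
#'   combined data.frame covering all samples).
#' @param weighted Use class-equal weighted centering (default); set
#'   `FALSE` when some cohorts lack a class.
#' @return A list of class `"meta_matrix"`: `values` (genes x all
#'   samples), `samples` (data.frame `sample_id`, `cohort_id`, `class`),
#'   `coverage` (named list of cohort ids per gene), `weighted`.
#' @export
build_meta_matrix <- function(matrices, annotations, weighted = TRUE) {
  if (is.data.frame(annotations)) {
    ann <- annotations
  } else {
    ann <- do.call(rbind, annotations)[, c("sample_id", "class", "cohort_id")]
  }
  all_samples <- unlist(lapply(matrices, colnames), use.names = FALSE)
  if (anyDuplicated(all_samples))
    stop("sample ids must be unique across cohorts")
  miss <- setdiff(all_samples, ann$sample_id)
  if (length(miss)) stop("sample '", miss[[1L]], "' lacks annotation")
  ann <- ann[match(all_samples, ann$sample_id), ]
  genes <- sort(unique(unlist(lapply(matrices, rownames))), method = "radix")
  values <- matrix(NA_real_, length(genes), length(all_samples),
                   dimnames = list(genes, all_samples))
  coverage <- stats::setNames(vector("list", length(genes)), genes)
  for (m in matrices) {
    cid <- cohort_id(m)
    cols <- colnames(m)
    cls <- ann$class[match(cols, ann$sample_id)]
    if (weighted && length(unique(cls)) != 2L)
      stop("cohort '", cid, "' lacks a class; use weighted = FALSE")
    centered <- t(apply(unclass(m), 1L, function(v)
      weighted_mean_center(rank_normalize(v), cls, weighted = weighted)))
    values[rownames(m), cols] <- centered
    for (g in rownames(m)) coverage[[g]] <- c(coverage[[g]], cid)
  }
  structure(list(values = values,
                 samples = data.frame(sample_id = all_samples,
                                      cohort_id = ann$cohort_id[match(all_samples, ann$sample_id)],
                                      class = ann$class[match(all_samples, ann$sample_id)],
                                      stringsAsFactors = FALSE),
                 coverage = coverage,
                 weighted = weighted), class = "meta_matrix")
}

#' Pooled Mann-Whitney differential expression over a meta-matrix
#'
#' Each gene is tested once on the concatenated centered scores of all
#' cohorts containing it, restricted to the requested samples (e.g. the
#' union of per-cohort balanced datasets). Genes with fewer than two
#' usable samples in either class are dropped with a warning. p-values
#' are BH-corrected at `m_total` and genes ranked by ascending p.
#'
#' @param meta A `"meta_matrix"`.
#' @param sample_ids Samples defining the contrast; `NULL` (default) uses
#'   all samples (the unstratified contrast).
#' @param m_total Total gene count for the FDR correction (default: genes
#'   in the meta-matrix).
#' @return DE result data.frame as in [mann_whitney_de()], plus `n_used`,
#'   the number of samples each gene's test used.
#' @export
meta_de <- function(meta, sample_ids = NULL, m_total = nrow(meta$values)) {
  stopifnot(inherits(meta, "meta_matrix"))
  if (is.null(sample_ids)) sample_ids <- meta$samples$sample_id
  miss <- setdiff(sample_ids, meta$samples$sample_id)
  if (length(miss)) stop("unknown sample id '", miss[[1L]], "'")
  vals <- meta$values[, sample_ids, drop = FALSE]
  cls <- meta$samples$class[match(sample_ids, meta$samples$sample_id)]
  idx_c <- which(cls == "cancer"); idx_n <- which(cls == "normal")
  if (length(idx_c) < 2L || length(idx_n) < 2L)
    stop("contrast needs >= 2 samples per class")
  res <- matrix(NA_real_, nrow(vals), 3L,
                dimnames = list(rownames(vals), c("p", "shift", "n_used")))
  lfc <- numeric(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    v <- vals[i, ]
    ok <- !is.na(v)
    i1 <- intersect(idx_c, which(ok)); i2 <- intersect(idx_n, which(ok))
    if (length(i1) < 2L || length(i2) < 2L) next
    mw <- .mw_p(v, i1, i2)
    res[i, ] <- c(mw[["p"]], mw[["shift"]], length(i1) + length(i2))
    lfc[i] <- mean(v[i1]) - mean(v[i2])
  }
  drop <- is.na(res[, "p"])
  if (any(drop))
    warning(sum(drop), " gene(s) with insufficient coverage excluded from ",
            "the meta-analysis", call. = FALSE)
  res <- res[!drop, , drop = FALSE]; lfc <- lfc[!drop]
  p <- pmin(pmax(res[, "p"], .Machine$double.xmin), 1)
  gene_id <- rownames(res)
  data.frame(gene_id = gene_id,
             direction = ifelse(res[, "shift"] > 0, "up",
                                ifelse(res[, "shift"] < 0, "down", "up")),
             p_value = p,
             q_value = bh_fdr(p, m_total = m_total),
             rank = .p_rank(p, gene_id),
             log_fold_change = lfc,
             n_used = as.integer(res[, "n_used"]),
             row.names = NULL, stringsAsFactors = FALSE)
}
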