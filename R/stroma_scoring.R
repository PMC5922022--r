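# Single-sample enrichment scoring of stroma content. Each sample's genes
# are ranked by within-sample expression and an unweighted Kolmogorov-
# Smirnov running-sum enrichment score is computed for the stroma-up and
# stroma-down sets at several set sizes; per size the up-minus-down score
# is normalized to 0-100 across the cohort's samples and the per-size
# scores are averaged into one stroma score per sample. The score is
# rank-based, hence invariant to any monotone per-sample transform, which
# is what makes it usable across platforms.

#' Single-sample enrichment score (unweighted KS running sum)
#'
#' Genes are ranked by descending expression within the sample (ties broken
#' by gene id); walking down the ranking, set members step the running sum
#' up by 1/|S| and non-members step it down by 1/(N - |S|). The score is
#' the signed maximum deviation from zero. A set concentrated at the top of
#' the ranking scores near +1, at the bottom near -1.
#'
#' @param values Named numeric vector: one sample's expression over the
#'   gene universe.
#' @param set_genes Character vector of set member gene ids; must be a
#'   non-empty strict subset of the universe.
#' @return The enrichment score in \[-1, 1\].
#' @export
single_sample_es <- function(values, set_genes) {
  ids <- names(values)
  if (is.null(ids)) stop("`values` must be named by gene id")
  n <- length(values)
  in_set <- ids %in% set_genes
  ns <- sum(in_set)
  if (ns == 0L) stop("gene-set has no member in the universe")
  if (ns == n) stop("gene-set equals the whole universe; miss step undefined")
  ord <- order(-values, ids, method = "radix")
  steps <- ifelse(in_set[ord], 1 / ns, -1 / (n - ns))
  rs <- cumsum(steps)
  rs[[which.max(abs(rs))]]
}

#' Stroma scores for every sample of a cohort
#'
#' For each sample and each set size k, the raw score is
#' `ES(top-k up-set) - ES(top-k down-set)` computed on the sample's
#' expression restricted to the shared gene universe. Per size, raw scores
#' are normalized affinely to 0-100 over the cohort's samples; the stroma
#' score is the mean of the per-size normalized scores. With a single
#' sample the normalization is degenerate and the score is fixed at 50
#' with a warning.
#'
#' @param x Expression matrix of the cohort.
#' @param sets A `"stroma_genesets"` object (or `list(up =, down =)` of
#'   character vectors ranked best-first).
#' @param sizes Integer vector of set sizes (default the 100...1000
#'   ladder). Every size must be available in both direction lists after
#'   restriction to the universe.
#' @param universe Character vector of shared genes to score on; must be a
#'   subset of the matrix genes and at least twice the largest size.
#' @return A data.frame of class `"stroma_score_table"`: `sample_id`, raw
#'   `es_<k>` and normalized `norm_<k>` columns per size, and
#'   `stroma_score` in \[0, 100\]. Attributes: `sizes`, `geneset_source`,
#'   `universe_size`.
#' @export
stroma_score_cohort <- function(x, sets,
                                sizes = c(100, 150, 200, 250, 300, 350,
                                          400, 450, 500, 1000),
                                universe = rownames(x)) {
  up <- if (inherits(sets, "stroma_genesets")) sets$up$genes else sets$up
  dn <- if (inherits(sets, "stroma_genesets")) sets$down$genes else sets$down
  src <- if (inherits(sets, "stroma_genesets")) sets$source else "sets"
  missing_u <- setdiff(universe, rownames(x))
  if (length(missing_u))
    stop("universe gene '", missing_u[[1L]], "' absent from matrix")
  up <- up[up %in% universe]
  dn <- dn[dn %in% universe]
  sizes <- sort(as.integer(sizes))
  if (length(universe) < 2L * max(sizes))
    stop("universe (", length(universe), " genes) smaller than twice the ",
         "largest set size (", max(sizes), ")")
  if (max(sizes) > length(up) || max(sizes) > length(dn))
    stop("size ", max(sizes), " exceeds available set length (up ",
         length(up), ", down ", length(dn), ") within the universe")
  sub <- unclass(x)[universe, , drop = FALSE]
  nsmp <- ncol(sub)
  raw <- matrix(NA_real_, nsmp, length(sizes),
                dimnames = list(colnames(sub), paste0("es_", sizes)))
  for (s in seq_len(nsmp)) {
    v <- sub[, s]
    for (j in seq_along(sizes)) {
      k <- sizes[[j]]
      raw[s, j] <- single_sample_es(v, up[seq_len(k)]) -
        single_sample_es(v, dn[seq_len(k)])
    }
  }
  norm <- apply(raw, 2L, function(col) {
    rng <- range(col)
    if (nsmp < 2L || rng[[1L]] == rng[[2L]]) {
      warning("degenerate 0-100 normalization (single sample or tied raw ",
              "scores); scores set to 50", call. = FALSE)
      rep(50, nsmp)
    } else {
      (col - rng[[1L]]) / (rng[[2L]] - rng[[1L]]) * 100
    }
  })
  norm <- matrix(norm, nrow = nsmp,
                 dimnames = list(colnames(sub), paste0("norm_", sizes)))
  out <- data.frame(sample_id = colnames(sub), raw, norm,
                    stroma_score = rowMeans(norm),
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "sizes") <- sizes
  attr(out, "geneset_source") <- src
  attr(out, "universe_size") <- length(universe)
  class(out) <- c("stroma_score_table", "data.frame")
  out
}

#' Per-sample stability of the stroma score across set sizes
#'
#' Sample standard deviation of the per-size 0-100 normalized scores for
#' each sample, plus the cohort mean -- a robustness diagnostic for the
#' choice of set size.
#'
#' @inheritParams stroma_score_cohort
#' @return A list: `per_sample` (data.frame `sample_id`, `sd`), `mean_sd`.
#' @export
score_stability <- function(x, sets,
                            sizes = c(100, 150, 200, 250, 300, 350,
                                      400, 450, 500, 1000),
                            universe = rownames(x)) {
  tab <- stroma_score_cohort(x, sets, sizes = sizes, universe = universe)
  norm <- as.matrix(tab[, grep("^norm_", colnames(tab)), drop = FALSE])
  sds <- apply(norm, 1L, stats::sd)
  list(per_sample = data.frame(sample_id = tab$sample_id, sd = sds,
                               row.names = NULL, stringsAsFactors = FALSE),
       mean_sd = mean(sds))
}

#' Calibrate stroma scores against histopathology
#'
#' Ordinary least-squares fit of histopathological stroma percentage on
#' the stroma score, reporting slope, intercept, Pearson correlation and
#' the mean absolute deviation of fitted vs observed percentages.
#' Predictions from the model are clipped to \[0, 100\].
#'
#' @param scores A `"stroma_score_table"` or numeric vector of stroma
#'   scores.
#' @param histo_stroma_pct Per-sample stroma percentages (aligned, or named
#'   by sample id).
#' @return A list of class `"stroma_calibration"` with `slope`,
#'   `intercept`, `pearson_r`, `mean_abs_deviation`.
#' @export
calibrate_to_histopathology <- function(scores, histo_stroma_pct) {
  if (inherits(scores, "stroma_score_table")) {
    if (!is.null(names(histo_stroma_pct)))
      histo_stroma_pct <- histo_stroma_pct[scores$sample_id]
    scores <- scores$stroma_score
  }
  ok <- is.finite(scores) & is.finite(histo_stroma_pct)
  scores <- scores[ok]; histo <- histo_stroma_pct[ok]
  if (length(scores) < 3L)
    stop("need >= 3 samples with both score and histopathology")
  if (stats::var(scores) == 0) stop("scores are constant; cannot calibrate")
  fit <- stats::lm(histo ~ scores)
  fitted <- stats::fitted(fit)
  structure(list(slope = unname(stats::coef(fit)[[2L]]),
                 intercept = unname(stats::coef(fit)[[1L]]),
                 pearson_r = stats::cor(scores, histo),
                 mean_abs_deviation = mean(abs(fitted - histo))),
            class = "stroma_calibration")
}

#' Predict stroma percentages from a calibration model
#' @param object A `"stroma_calibration"`.
#' @param newdata Numeric vector of stroma scores.
#' @param ... Unused.
#' @return Predicted stroma percentages, clipped to \[0, 100\].
#' @export
predict.stroma_calibration <- function(object, newdata, ...) {
  pmin(100, pmax(0, object$intercept + object$slope * newdata))
}
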