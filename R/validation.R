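# Validation utilities: overlap of independently derived gene-sets against
# a random baseline, and recovery metrics against the planted truth of
# synthetic cohorts.

#' Percent overlap of the top of two ranked gene lists
#'
#' `|top_n(a) (intersect) top_n(b)| / n_top * 100`. Symmetric in its
#' arguments for equal `n_top`.
#'
#' @param a,b Character vectors of gene ids, ranked best-first.
#' @param n_top Number of top genes compared; must be positive and at most
#'   the length of either list.
#' @return Overlap percentage in \[0, 100\].
#' @export
geneset_overlap <- function(a, b, n_top) {
  if (n_top < 1) stop("`n_top` must be >= 1")
  if (n_top > length(a) || n_top > length(b))
    stop("`n_top` exceeds a list length")
  length(intersect(utils::head(a, n_top), utils::head(b, n_top))) / n_top * 100
}

#' Expected overlap of random same-sized gene selections
#'
#' Mean overlap percentage over `n_draws` pairs of uniform random
#' `n_top`-subsets, one drawn from each universe. For a shared universe of
#' size N the expectation is the hypergeometric `n_top / N * 100`.
#'
#' @param universe_a,universe_b Gene id vectors to draw from.
#' @param n_top Subset size per draw.
#' @param n_draws Number of random draws (default 50).
#' @param seed Integer seed.
#' @return Mean overlap percentage.
#' @export
random_overlap_baseline <- function(universe_a, universe_b, n_top,
                                    n_draws = 50, seed = 1L) {
  if (n_top > length(universe_a) || n_top > length(universe_b))
    stop("`n_top` exceeds a universe size")
  set.seed(seed)
  mean(vapply(seq_len(n_draws), function(i) {
    geneset_overlap(sample(universe_a, n_top), sample(universe_b, n_top),
                    n_top)
  }, numeric(1L)))
}

#' Recovery of planted gene classes by a derived ranking
#'
#' Compares a derived gene ranking (a DE result, a stroma gene-set object,
#' or a plain ranked gene vector) against the planted truth of a synthetic
#' cohort. For each planted class: precision at top-k (fraction of the
#' top-k that belong to the class), recall at top-k (fraction of the class
#' found in the top-k) and the mean position of the class's genes in the
#' ranking. For a `"stroma_genesets"` input the full p_score ranking is
#' evaluated per direction against the matching planted class.
#'
#' @param derived A DE result data.frame (`gene_id`, `rank`), a
#'   `"stroma_genesets"`, or a character vector ranked best-first.
#' @param truth A `planted_truth` object covering all derived genes.
#' @param k Top-list size for precision/recall.
#' @return data.frame with one row per planted class: `class`, `n_class`,
#'   `precision_at_k`, `recall_at_k`, `mean_rank`. Classes with no planted
#'   genes are omitted.
#' @export
recovery_report <- function(derived, truth, k = 100) {
  stopifnot(inherits(truth, "planted_truth"))
  if (inherits(derived, "stroma_genesets")) {
    tab <- derived$table
    up <- tab$gene_id[tab$stroma_direction == "up"]
    dn <- tab$gene_id[tab$stroma_direction == "down"]
    return(rbind(.recover_one(up, truth, k, "stroma_up"),
                 .recover_one(dn, truth, k, "stroma_down")))
  }
  ranked <- if (is.data.frame(derived)) {
    derived$gene_id[order(derived$rank)]
  } else as.character(derived)
  classes <- setdiff(unique(truth$gene_class), "null")
  do.call(rbind, lapply(sort(classes, method = "radix"),
                        function(cl) .recover_one(ranked, truth, k, cl)))
}

.recover_one <- function(ranked, truth, k, cl) {
  unknown <- setdiff(ranked, names(truth$gene_class))
  if (length(unknown))
    stop("gene '", unknown[[1L]], "' not covered by the planted truth")
  members <- names(truth$gene_class)[truth$gene_class == cl]
  if (!length(members)) return(NULL)
  k <- min(k, length(ranked))
  top <- utils::head(ranked, k)
  pos <- match(members, ranked)
  data.frame(class = cl,
             n_class = length(members),
             precision_at_k = sum(top %in% members) / k,
             recall_at_k = sum(members %in% top) / length(members),
             mean_rank = mean(pos, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}
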