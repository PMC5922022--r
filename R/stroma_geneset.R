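# Derivation of stroma gene-sets from a histopathology cohort. The
# balanced contrast (stroma matched between classes) and the unbalanced
# contrast (stroma difference maximized) are tested separately; genes whose
# significance is driven by stroma content are significant in the
# unbalanced but not the balanced contrast. The ranking statistic
# p_score = p_unbal / p_bal^2 formalizes this: the squared denominator
# demands a disproportionally larger p-value gap from genes that are
# already highly significant in the balanced contrast.

#' Stroma-marker ranking score
#'
#' `p_score = p_unbal / p_bal^2`. Lower scores flag stronger stroma-marker
#' candidates: a gene at p = 1e-5 in the unbalanced contrast that is null
#' (p ~ 1) in the balanced contrast scores 1e-5, while a gene at 1e-20
#' unbalanced / 1e-15 balanced scores 1e10 despite the identical p ratio --
#' the former is the more credible stroma marker.
#'
#' @param p_unbal,p_bal p-values in (0, 1\] from the unbalanced and
#'   balanced contrasts (vectorized).
#' @return Positive numeric score(s); lower = better stroma-marker.
#' @export
p_score <- function(p_unbal, p_bal) {
  if (any(p_unbal <= 0 | p_bal <= 0) || any(p_unbal > 1 | p_bal > 1))
    stop("p-values must lie in (0, 1]")
  p_unbal / p_bal^2
}

#' Derive ranked stroma gene-sets from balanced/unbalanced DE results
#'
#' Genes are partitioned by their stroma direction -- the direction of the
#' shift toward the high-stroma group in the unbalanced contrast -- and
#' each partition is ranked by ascending [p_score()]. Excluded genes (e.g.
#' a pathway under study, to avoid circularity) are removed before
#' truncation, and the top `n_top` genes per direction are returned.
#'
#' @param de_balanced,de_unbalanced DE result data.frames from
#'   [mann_whitney_de()] over the same gene universe.
#' @param n_top Genes retained per direction (default 1000).
#' @param exclude Character vector of gene ids removed before ranking.
#' @param high_stroma `"reference"` (default) when the reference class of
#'   the unbalanced contrast is the high-stroma group (the usual design:
#'   high-stroma normals vs low-stroma cancers), `"case"` otherwise.
#' @param source Label recorded on the output sets.
#' @return A list of class `"stroma_genesets"`: `up` and `down`
#'   ([gene_set()] objects ordered by ascending p_score), `n_top`,
#'   `excluded`, and `table` (the full per-gene p_score table with columns
#'   `gene_id`, `p_unbal`, `p_bal`, `p_score`, `stroma_direction`).
#' @export
build_stroma_genesets <- function(de_balanced, de_unbalanced, n_top = 1000,
                                  exclude = character(0),
                                  high_stroma = c("reference", "case"),
                                  source = "cohort") {
  high_stroma <- match.arg(high_stroma)
  if (n_top < 1) stop("`n_top` must be >= 1")
  if (!setequal(de_balanced$gene_id, de_unbalanced$gene_id) ||
      nrow(de_balanced) != nrow(de_unbalanced))
    stop("balanced and unbalanced DE results must cover the same gene universe")
  ub <- de_unbalanced[match(de_balanced$gene_id, de_unbalanced$gene_id), ]
  dir_unbal <- ub$direction
  stroma_dir <- if (high_stroma == "reference") {
    ifelse(dir_unbal == "up", "down", "up")   # shift toward reference class
  } else dir_unbal
  tab <- data.frame(gene_id = de_balanced$gene_id,
                    p_unbal = ub$p_value,
                    p_bal = de_balanced$p_value,
                    p_score = p_score(ub$p_value, de_balanced$p_value),
                    stroma_direction = stroma_dir,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$p_score, tab$gene_id, method = "radix"), ]
  rownames(tab) <- NULL
  keep <- !(tab$gene_id %in% exclude)
  if (!any(keep)) stop("gene universe is empty after exclusion")
  ranked <- tab[keep, ]
  up_genes <- ranked$gene_id[ranked$stroma_direction == "up"]
  dn_genes <- ranked$gene_id[ranked$stroma_direction == "down"]
  if (!length(up_genes) || !length(dn_genes))
    stop("no genes available in one stroma direction after exclusion")
  structure(list(
    up = gene_set(paste0(source, "_stroma_up"),
                  utils::head(up_genes, n_top),
                  "stroma-enriched genes, ascending p_score"),
    down = gene_set(paste0(source, "_stroma_down"),
                    utils::head(dn_genes, n_top),
                    "stroma-depleted genes, ascending p_score"),
    n_top = as.integer(n_top),
    excluded = exclude,
    source = source,
    table = tab), class = "stroma_genesets")
}
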