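# Core rank statistics: per-gene two-group Mann-Whitney tests, BH FDR at a
# global gene count, and probe-to-gene collapse for multi-probe platforms.

# Two-sided Mann-Whitney p for one gene. idx1/idx2 index the two groups.
# Exact null distribution (pwilcox, or full label enumeration when ties are
# present and feasible) when either group has < 8 samples; tie-corrected
# normal approximation (no continuity correction) otherwise.
.mw_p <- function(x, idx1, idx2, exact_max_comb = 1e5) {
  x1 <- x[idx1]; x2 <- x[idx2]
  n1 <- length(x1); n2 <- length(x2); n <- n1 + n2
  r <- rank(c(x1, x2))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  if (length(ties) == 1L)            # all values identical
    return(c(p = 1, shift = 0))
  if (min(n1, n2) < 8L) {
    if (all(ties == 1L)) {
      p_lo <- stats::pwilcox(u, n1, n2)
      p_hi <- 1 - stats::pwilcox(u - 1, n1, n2)
      return(c(p = min(1, 2 * min(p_lo, p_hi)), shift = u - mu))
    }
    if (choose(n, n1) <= exact_max_comb) {
      combs <- utils::combn(n, n1)
      offset <- n1 * (n1 + 1) / 2
      us <- colSums(matrix(r[combs], nrow = n1)) - offset
      p_lo <- mean(us <= u)
      p_hi <- mean(us >= u)
      return(c(p = min(1, 2 * min(p_lo, p_hi)), shift = u - mu))
    }
  }
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(c(p = 1, shift = 0))
  z <- (u - mu) / sqrt(sigma2)
  c(p = min(1, 2 * stats::pnorm(-abs(z))), shift = u - mu)
}

# Significance ranks: ascending p, ties broken lexicographically by gene id.
.p_rank <- function(p, gene_id) {
  ord <- order(p, gene_id, method = "radix")
  rk <- integer(length(p))
  rk[ord] <- seq_along(p)
  rk
}

#' Per-gene Mann-Whitney differential expression
#'
#' Tests every gene of an expression matrix for a location shift between two
#' sample classes with the two-sided Mann-Whitney-Wilcoxon test. Small
#' groups (either class < 8 samples) use the exact null distribution;
#' larger groups use the tie-corrected normal approximation. Genes are
#' ranked by ascending p-value (rank 1 = most significant, p ties broken by
#' gene id) and corrected with Benjamini-Hochberg FDR at `m_total` genes.
#'
#' @param x Expression matrix (genes x samples) with dimnames.
#' @param classes Character vector of per-sample class labels, aligned with
#'   the columns of `x` (or named by sample id).
#' @param case,reference The two class labels to contrast; `direction` is
#'   the sign of the case-minus-reference shift.
#' @param m_total Total gene count for the FDR correction; defaults to the
#'   number of genes tested.
#' @return A data.frame with columns `gene_id`, `direction` (`"up"`/
#'   `"down"`), `p_value`, `q_value`, `rank`, `log_fold_change` (difference
#'   of class means on the matrix scale).
#' @export
mann_whitney_de <- function(x, classes, case = "cancer", reference = "normal",
                            m_total = nrow(x)) {
  if (!is.null(names(classes))) classes <- classes[colnames(x)]
  if (length(classes) != ncol(x))
    stop("`classes` must label every sample column")
  idx1 <- which(classes == case)
  idx2 <- which(classes == reference)
  if (length(idx1) < 2L || length(idx2) < 2L)
    stop("each class needs >= 2 samples (", case, ": ", length(idx1),
         ", ", reference, ": ", length(idx2), ")")
  res <- t(apply(x, 1L, .mw_p, idx1 = idx1, idx2 = idx2))
  p <- pmin(pmax(res[, "p"], .Machine$double.xmin), 1)
  lfc <- rowMeans(x[, idx1, drop = FALSE]) - rowMeans(x[, idx2, drop = FALSE])
  direction <- ifelse(res[, "shift"] > 0, "up",
                      ifelse(res[, "shift"] < 0, "down", "up"))
  gene_id <- rownames(x)
  data.frame(gene_id = gene_id,
             direction = direction,
             p_value = p,
             q_value = bh_fdr(p, m_total = m_total),
             rank = .p_rank(p, gene_id),
             log_fold_change = lfc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR at a global gene count
#'
#' Step-up BH correction where the multiplier is `m_total`, the total
#' number of genes analysed across the study, rather than the length of
#' `p`. With `m_total = length(p)` this is the standard BH procedure.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param m_total Total number of tests; must be >= `length(p)`.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p, m_total = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1]")
  if (m_total < length(p)) stop("`m_total` must be >= length(p)")
  stats::p.adjust(p, method = "BH", n = m_total)
}

#' Collapse probe-level rows to one probe per gene
#'
#' Multi-probe platforms measure some genes with several probes; exactly
#' one is retained per gene. `best_avg_de_rank` keeps the probe with the
#' best (numerically smallest) average significance rank over several
#' differential expression analyses (e.g. unstratified, balanced and
#' unbalanced contrasts); `best_de_rank` uses a single analysis;
#' `max_expression` keeps the probe with the highest mean expression.
#' Probes not present in the mapping are dropped.
#'
#' @param x Probe-level expression matrix (probes x samples).
#' @param probe_to_gene data.frame with columns `probe_id` and `gene_id`
#'   (each probe maps to at most one gene), or a named character vector
#'   probe -> gene.
#' @param strategy One of `"best_de_rank"`, `"best_avg_de_rank"`,
#'   `"max_expression"`.
#' @param de_context For the `best_*` strategies: a list of per-probe rank
#'   vectors named by probe id (a DE result data.frame with `gene_id` and
#'   `rank` columns per analysis is also accepted).
#' @return An [expression_matrix()] with gene identifiers as rownames.
#' @export
collapse_probes <- function(x, probe_to_gene,
                            strategy = c("best_avg_de_rank", "best_de_rank",
                                         "max_expression"),
                            de_context = NULL) {
  strategy <- match.arg(strategy)
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene$gene_id),
                           as.character(probe_to_gene$probe_id))
  } else {
    map <- probe_to_gene
  }
  map <- map[!is.na(map) & nzchar(map)]
  if (!length(map)) stop("empty probe-to-gene mapping")
  if (anyDuplicated(names(map)))
    stop("probe '", names(map)[duplicated(names(map))][[1L]],
         "' maps to more than one gene")
  probes <- intersect(rownames(x), names(map))
  if (!length(probes)) stop("no probe of the matrix appears in the mapping")

  if (strategy == "max_expression") {
    score <- rowMeans(x[probes, , drop = FALSE])
    better <- function(a, b) score[[a]] > score[[b]]
  } else {
    if (is.null(de_context))
      stop("strategy '", strategy, "' requires `de_context`")
    if (is.data.frame(de_context)) de_context <- list(de_context)
    ranks <- lapply(de_context, function(d) {
      if (is.data.frame(d)) stats::setNames(d$rank, d$gene_id) else d
    })
    if (strategy == "best_de_rank" && length(ranks) != 1L)
      stop("best_de_rank expects exactly one analysis in `de_context`")
    avg <- rowMeans(do.call(cbind, lapply(ranks, function(r) {
      if (!all(probes %in% names(r)))
        stop("de_context lacks ranks for some probes")
      r[probes]
    })))
    names(avg) <- probes
    better <- function(a, b) avg[[a]] < avg[[b]]
  }

  keep <- character(0)
  for (g in unique(map[probes])) {
    cand <- sort(probes[map[probes] == g], method = "radix")
    best <- cand[[1L]]
    for (p in cand[-1L]) if (better(p, best)) best <- p
    keep[g] <- best
  }
  out <- unclass(x)[unname(keep), , drop = FALSE]
  rownames(out) <- names(keep)
  expression_matrix(out, cohort_id = cohort_id(x))
}
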