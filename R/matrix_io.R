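# Containers and file I/O for expression matrices, sample annotations and
# gene-sets. All tables are plain TSV (UTF-8, tab-separated, no quoting,
# '.' decimal); gene-sets use the standard GMT format. Readers reject
# malformed input with coordinates rather than repairing it silently.

#' Construct an expression matrix
#'
#' An expression matrix is a numeric matrix with unique gene identifiers as
#' rownames, unique sample identifiers as colnames and a `cohort_id`
#' attribute. Values are expected on a log-like scale and must be finite:
#' missing values are not supported.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames and colnames set.
#' @param cohort_id Single string labelling the cohort.
#' @return The validated matrix with class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, cohort_id = "cohort") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    stop("duplicate gene identifier: ", dup_g[[1L]])
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample identifier: ", dup_s[[1L]])
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at gene '", rownames(values)[bad[[1L]]],
         "', sample '", colnames(values)[bad[[2L]]], "'")
  }
  if (!is.character(cohort_id) || length(cohort_id) != 1L)
    stop("`cohort_id` must be a single string")
  attr(values, "cohort_id") <- cohort_id
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Cohort identifier of an expression matrix
#' @param x An `expression_matrix`.
#' @return The cohort id string.
#' @export
cohort_id <- function(x) {
  id <- attr(x, "cohort_id")
  if (is.null(id)) "cohort" else id
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Duplicated identifiers and non-numeric cells are errors;
#' the error message names the offending gene/sample.
#'
#' @param path Path to a tab-separated file.
#' @param cohort_id Cohort label to attach.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, cohort_id = "cohort") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression matrix needs >=1 sample column: ", path)
  genes <- raw[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene identifier in ", path, ": ", dup[[1L]])
  samples <- colnames(raw)[-1L]
  dup <- samples[duplicated(samples)]
  if (length(dup)) stop("duplicate sample identifier in ", path, ": ", dup[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric value '", vals[bad[1L, , drop = FALSE]],
         "' at gene '", genes[bad[1L, 1L]], "', sample '",
         samples[bad[1L, 2L]], "' in ", path)
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop("missing value at gene '", genes[bad[1L, 1L]], "', sample '",
         samples[bad[1L, 2L]], "' in ", path)
  }
  dimnames(num) <- list(genes, samples)
  expression_matrix(num, cohort_id = cohort_id)
}

#' Write an expression matrix as TSV
#' @param x An [expression_matrix()] (or numeric matrix with dimnames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a per-sample annotation table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param class Per-sample class, `"cancer"` or `"normal"`.
#' @param cohort_id Cohort label (recycled).
#' @param stroma_pct,cancer_pct,epithelium_pct Optional histopathology tissue
#'   percentages in \[0, 100\]; when given, the three must sum to 100 +/- 0.5
#'   per sample.
#' @return A data.frame with one row per sample.
#' @export
sample_annotation <- function(sample_id, class, cohort_id = "cohort",
                              stroma_pct = NULL, cancer_pct = NULL,
                              epithelium_pct = NULL) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample identifier: ", sample_id[duplicated(sample_id)][[1L]])
  if (!all(class %in% c("cancer", "normal")))
    stop("`class` must be 'cancer' or 'normal'")
  n <- length(sample_id)
  ann <- data.frame(sample_id = as.character(sample_id),
                    class = as.character(class),
                    cohort_id = rep_len(as.character(cohort_id), n),
                    stringsAsFactors = FALSE)
  has_histo <- !is.null(stroma_pct)
  if (has_histo) {
    if (is.null(cancer_pct) || is.null(epithelium_pct))
      stop("histopathology requires all three of stroma/cancer/epithelium percentages")
    pct <- cbind(stroma_pct, cancer_pct, epithelium_pct)
    if (any(pct < 0 | pct > 100))
      stop("histopathology percentages must lie in [0, 100]")
    tot <- rowSums(pct)
    off <- which(abs(tot - 100) > 0.5)
    if (length(off))
      stop("tissue percentages for sample '", ann$sample_id[off[[1L]]],
           "' sum to ", tot[off[[1L]]], ", not 100 +/- 0.5")
    ann$stroma_pct <- as.numeric(stroma_pct)
    ann$cancer_pct <- as.numeric(cancer_pct)
    ann$epithelium_pct <- as.numeric(epithelium_pct)
  }
  ann
}

#' Read / write a sample annotation TSV
#'
#' Fixed column names: `sample_id`, `class`, `cohort_id` and optionally
#' `stroma_pct`, `cancer_pct`, `epithelium_pct`.
#'
#' @param path File path.
#' @return For the reader, a validated annotation data.frame.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "cohort_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("annotation ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  if ("stroma_pct" %in% colnames(df)) {
    sample_annotation(df$sample_id, df$class, df$cohort_id,
                      df$stroma_pct, df$cancer_pct, df$epithelium_pct)
  } else {
    sample_annotation(df$sample_id, df$class, df$cohort_id)
  }
}

#' @rdname read_sample_annotation
#' @param ann Annotation data.frame.
#' @export
write_sample_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a gene-set
#' @param name Set name.
#' @param genes Character vector of unique gene identifiers (non-empty).
#' @param description Free-text description.
#' @return A list with class `"gene_set"`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene-set '", name, "' is empty")
  if (anyDuplicated(genes))
    stop("duplicate gene '", genes[duplicated(genes)][[1L]],
         "' in gene-set '", name, "'")
  structure(list(name = as.character(name),
                 description = as.character(description),
                 genes = genes),
            class = "gene_set")
}

#' Read gene-sets from a GMT file
#'
#' One set per line: name, description, then gene identifiers, all
#' tab-separated. Order of sets and of genes within a set is preserved.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " in ", path, " has fewer than 3 fields")
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes))
      stop("GMT line ", i, " in ", path, ": duplicate gene '",
           genes[duplicated(genes)][[1L]], "'")
    sets[[i]] <- gene_set(fields[[1L]], genes, fields[[2L]])
  }
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  sets
}

#' Write gene-sets to a GMT file
#' @param sets A list of [gene_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Genes shared by a collection of cohorts
#'
#' Returns the intersection of the gene identifiers of all matrices, sorted
#' lexicographically (C locale) so the result does not depend on input
#' order. Used as the common gene universe for cross-cohort enrichment
#' scoring.
#'
#' @param matrices A list of expression matrices (or a single matrix).
#' @return Sorted character vector of shared gene identifiers.
#' @export
shared_genes <- function(matrices) {
  if (inherits(matrices, "expression_matrix") || is.matrix(matrices))
    matrices <- list(matrices)
  if (!length(matrices)) stop("need at least one matrix")
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(common)) stop("no genes shared by all matrices")
  sort(common, method = "radix")
}
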