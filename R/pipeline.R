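# End-to-end orchestration of the stroma-balancing workflow:
#   1. stratify histopathology cohorts by measured stroma percentage;
#   2. balanced/unbalanced differential expression in those cohorts;
#   3. derive stroma gene-sets from the p_score ranking;
#   4. enrichment-score stroma content for every sample of every cohort
#      on the shared gene universe;
#   5. stratify every cohort by its scores (median split of cancer
#      samples only where normals are absent);
#   6. per-cohort differential expression;
#   7. rank-based meta-analysis over the cohorts with both classes
#      (unstratified, balanced and unbalanced contrasts);
# plus gene-set overlap validation when two histopathology cohorts are
# available. All outputs are deterministic given the config.

# Small polynomial string hash; stamps outputs with the config they came
# from so result files can be traced back to their run.
.config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_tsv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# stromabalance config ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.load_cohort <- function(spec) {
  mat <- spec$matrix
  if (is.character(mat))
    mat <- read_expression_matrix(mat, cohort_id = spec$cohort_id)
  ann <- spec$annotation
  if (is.character(ann)) ann <- read_sample_annotation(ann)
  list(matrix = mat, annotation = ann,
       cohort_id = cohort_id(mat),
       histopathology = isTRUE(spec$histopathology))
}

#' Run the full stroma-balancing pipeline
#'
#' @param config A list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{cohorts}{list of cohort specs, each with `matrix` and
#'       `annotation` (paths or in-memory objects), `cohort_id`, and
#'       logical `histopathology` marking cohorts whose annotation
#'       carries measured tissue percentages. At least one
#'       histopathology cohort is required.}
#'     \item{n_top}{genes per direction in the derived stroma sets
#'       (default 1000).}
#'     \item{sizes}{set-size ladder for enrichment scoring (default
#'       100, 150, ..., 500, 1000).}
#'     \item{exclude}{gene ids (vector, or path to a one-id-per-line
#'       file) removed from the stroma sets before truncation.}
#'     \item{m_total}{global gene count for the meta-analysis FDR
#'       (default: union of all cohorts' genes).}
#'     \item{fraction}{per-class split fraction (default 0.5).}
#'     \item{seed}{integer seed for the random overlap baseline.}
#'     \item{out_dir}{optional output directory; when set, every
#'       intermediate and result table is written there.}
#'   }
#' @return Invisibly, a result bundle: `genesets` (per histopathology
#'   cohort), `scores`, `stratifications`, `hp_stratifications`,
#'   `cohort_de`, `meta_de` (unstratified/balanced/unbalanced),
#'   `overlap_report`, `universe`, `config_hash`, `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  n_top <- if (is.null(config$n_top)) 1000L else as.integer(config$n_top)
  sizes <- if (is.null(config$sizes))
    c(100, 150, 200, 250, 300, 350, 400, 450, 500, 1000) else
      sort(as.integer(config$sizes))
  fraction <- if (is.null(config$fraction)) 0.5 else config$fraction
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  exclude <- config$exclude
  if (is.character(exclude) && length(exclude) == 1L && file.exists(exclude))
    exclude <- readLines(exclude, warn = FALSE)
  if (is.null(exclude)) exclude <- character(0)
  hash <- .config_hash(config[setdiff(names(config), "out_dir")])
  log <- character(0)
  say <- function(...) {
    log <<- c(log, paste0(...))
    message("[stromabalance] ", paste0(...))
  }
  say("config hash ", hash, ", seed ", seed)

  cohorts <- lapply(config$cohorts, .load_cohort)
  names(cohorts) <- vapply(cohorts, `[[`, character(1L), "cohort_id")
  hp_ids <- names(cohorts)[vapply(cohorts, `[[`, logical(1L), "histopathology")]
  if (!length(hp_ids))
    stop("at least one histopathology cohort is required to derive gene-sets")
  for (co in cohorts)
    say("cohort ", co$cohort_id, ": ", nrow(co$matrix), " genes, ",
        sum(co$annotation$class == "cancer"), " cancer / ",
        sum(co$annotation$class == "normal"), " normal samples")

  universe <- shared_genes(lapply(cohorts, `[[`, "matrix"))
  say("shared gene universe: ", length(universe), " genes")

  # steps 1-3: histopathology stratification, DE, stroma gene-sets
  hp_strat <- list(); genesets <- list()
  for (cid in hp_ids) {
    co <- cohorts[[cid]]
    if (is.null(co$annotation$stroma_pct))
      stop("cohort '", cid, "' is marked histopathology but lacks stroma_pct")
    stroma <- stats::setNames(co$annotation$stroma_pct, co$annotation$sample_id)
    st <- split_by_stroma(co$annotation, stroma, fraction = fraction,
                          stroma_source = "histopathology")
    hp_strat[[cid]] <- st
    cls <- stats::setNames(co$annotation$class, co$annotation$sample_id)
    bal_ids <- c(st$balanced_cancer, st$balanced_normal)
    unb_ids <- c(st$unbalanced_cancer, st$unbalanced_normal)
    de_bal <- mann_whitney_de(co$matrix[, bal_ids, drop = FALSE], cls[bal_ids])
    de_unb <- mann_whitney_de(co$matrix[, unb_ids, drop = FALSE], cls[unb_ids])
    genesets[[cid]] <- build_stroma_genesets(de_bal, de_unb, n_top = n_top,
                                             exclude = exclude, source = cid)
    say("gene-sets from ", cid, ": ", length(genesets[[cid]]$up$genes),
        " up / ", length(genesets[[cid]]$down$genes), " down genes (",
        length(exclude), " excluded)")
  }
  primary_sets <- genesets[[hp_ids[[1L]]]]

  # step 4: stroma scores for every cohort on the shared universe
  scores <- lapply(cohorts, function(co)
    stroma_score_cohort(co$matrix, primary_sets, sizes = sizes,
                        universe = universe))
  say("scored ", length(scores), " cohort(s) with gene-set '",
      hp_ids[[1L]], "', sizes ", paste(sizes, collapse = ","))

  # step 5: score-based stratification
  strat <- list(); highlow <- list()
  for (cid in names(cohorts)) {
    co <- cohorts[[cid]]
    sc <- stats::setNames(scores[[cid]]$stroma_score, scores[[cid]]$sample_id)
    if (all(c("cancer", "normal") %in% co$annotation$class)) {
      strat[[cid]] <- split_by_stroma(co$annotation, sc, fraction = fraction,
                                      stroma_source = "gsea")
    } else {
      highlow[[cid]] <- split_high_low(co$annotation, sc)
      say("cohort ", cid, " lacks a class; median high/low split only")
    }
  }

  # step 6: per-cohort DE
  cohort_de <- list()
  for (cid in names(strat)) {
    co <- cohorts[[cid]]
    st <- strat[[cid]]
    cls <- stats::setNames(co$annotation$class, co$annotation$sample_id)
    bal_ids <- c(st$balanced_cancer, st$balanced_normal)
    unb_ids <- c(st$unbalanced_cancer, st$unbalanced_normal)
    cohort_de[[cid]] <- list(
      unstratified = mann_whitney_de(co$matrix, cls),
      balanced = mann_whitney_de(co$matrix[, bal_ids, drop = FALSE], cls[bal_ids]),
      unbalanced = mann_whitney_de(co$matrix[, unb_ids, drop = FALSE], cls[unb_ids]))
  }

  # step 7: meta-analysis over cohorts with both classes
  meta_ids <- names(strat)
  meta_results <- NULL
  if (length(meta_ids) >= 1L) {
    meta <- build_meta_matrix(lapply(cohorts[meta_ids], `[[`, "matrix"),
                              lapply(cohorts[meta_ids], `[[`, "annotation"),
                              weighted = TRUE)
    m_total <- if (is.null(config$m_total)) nrow(meta$values) else
      as.integer(config$m_total)
    bal_ids <- unlist(lapply(strat[meta_ids], function(s)
      c(s$balanced_cancer, s$balanced_normal)), use.names = FALSE)
    unb_ids <- unlist(lapply(strat[meta_ids], function(s)
      c(s$unbalanced_cancer, s$unbalanced_normal)), use.names = FALSE)
    meta_results <- list(
      unstratified = meta_de(meta, m_total = m_total),
      balanced = meta_de(meta, bal_ids, m_total = m_total),
      unbalanced = meta_de(meta, unb_ids, m_total = m_total))
    say("meta-analysis over ", length(meta_ids), " cohort(s): balanced ",
        length(bal_ids), " samples, unbalanced ", length(unb_ids),
        " samples, m_total ", m_total)
  }

  # validation: overlap of independently derived gene-sets
  overlap_report <- NULL
  if (length(hp_ids) >= 2L) {
    a <- genesets[[hp_ids[[1L]]]]; b <- genesets[[hp_ids[[2L]]]]
    n_cmp <- min(n_top, length(a$up$genes), length(b$up$genes),
                 length(a$down$genes), length(b$down$genes))
    rnd <- random_overlap_baseline(rownames(cohorts[[hp_ids[[1L]]]]$matrix),
                                   rownames(cohorts[[hp_ids[[2L]]]]$matrix),
                                   n_cmp, n_draws = 50, seed = seed + 1000L)
    overlap_report <- data.frame(
      direction = c("up", "down"),
      n_top = n_cmp,
      observed_overlap_pct = c(geneset_overlap(a$up$genes, b$up$genes, n_cmp),
                               geneset_overlap(a$down$genes, b$down$genes, n_cmp)),
      random_overlap_pct = rnd,
      n_random_draws = 50L,
      stringsAsFactors = FALSE)
    say("gene-set overlap (", hp_ids[[1L]], " vs ", hp_ids[[2L]], ", n=",
        n_cmp, "): up ", round(overlap_report$observed_overlap_pct[[1L]], 1),
        "% / down ", round(overlap_report$observed_overlap_pct[[2L]], 1),
        "% vs random ", round(rnd, 1), "%")
  }

  bundle <- list(genesets = genesets, scores = scores,
                 stratifications = strat, high_low = highlow,
                 hp_stratifications = hp_strat, cohort_de = cohort_de,
                 meta_de = meta_results, overlap_report = overlap_report,
                 universe = universe, config_hash = hash, log = log)
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir, hash)
  invisible(bundle)
}

.write_bundle <- function(bundle, out_dir, hash) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, paste0(...))
  for (cid in names(bundle$genesets)) {
    gs <- bundle$genesets[[cid]]
    write_gmt(list(gs$up, gs$down), fp(cid, "_stroma_sets.gmt"))
    .write_tsv(gs$table, fp(cid, "_pscore.tsv"), hash)
  }
  for (cid in names(bundle$scores))
    .write_tsv(as.data.frame(bundle$scores[[cid]]), fp(cid, "_scores.tsv"), hash)
  for (cid in names(bundle$stratifications))
    .write_tsv(as.data.frame(bundle$stratifications[[cid]]),
               fp(cid, "_stratification.tsv"), hash)
  for (cid in names(bundle$high_low)) {
    hl <- bundle$high_low[[cid]]
    .write_tsv(data.frame(sample_id = c(hl$low, hl$high),
                          group = rep(c("low", "high"),
                                      c(length(hl$low), length(hl$high))),
                          stringsAsFactors = FALSE),
               fp(cid, "_high_low.tsv"), hash)
  }
  for (cid in names(bundle$cohort_de))
    for (ds in names(bundle$cohort_de[[cid]]))
      .write_tsv(bundle$cohort_de[[cid]][[ds]], fp(cid, "_de_", ds, ".tsv"), hash)
  for (ds in names(bundle$meta_de))
    .write_tsv(bundle$meta_de[[ds]], fp("meta_de_", ds, ".tsv"), hash)
  if (!is.null(bundle$overlap_report))
    .write_tsv(bundle$overlap_report, fp("overlap_report.tsv"), hash)
  writeLines(bundle$universe, fp("universe.txt"))
  writeLines(bundle$log, fp("log.txt"))
  invisible(out_dir)
}

#' Write a simulated cohort to TSV files
#'
#' Writes `<prefix>_matrix.tsv`, `<prefix>_annotation.tsv` (tissue
#' fractions as histopathology percentages) and `<prefix>_truth.tsv` (the
#' planted gene table).
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param out_prefix Path prefix for the three files.
#' @return The three paths, invisibly.
#' @export
write_cohort <- function(cohort, out_prefix) {
  paths <- paste0(out_prefix, c("_matrix.tsv", "_annotation.tsv", "_truth.tsv"))
  write_expression_matrix(cohort$matrix, paths[[1L]])
  write_sample_annotation(cohort$annotation, paths[[2L]])
  utils::write.table(planted_de_table(cohort$truth), paths[[3L]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
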