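# Independent brute-force oracles used to validate the rank statistics.
# These deliberately share no code with the package implementation.

# Exact two-sided Mann-Whitney p by full enumeration of all group-1 label
# assignments over the pooled sample.
mw_enum_oracle <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- utils::combn(length(pooled), n1)
  us <- apply(assignments, 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Step-by-step KS running sum: rank genes by descending value (ties by
# id), walk the list accumulating +1/|S| on hits and -1/(N-|S|) on misses,
# return the signed maximum deviation from zero.
es_oracle <- function(values, set_genes) {
  ids <- names(values)
  ids_sorted <- ids[order(-values, ids, method = "radix")]
  ns <- sum(ids_sorted %in% set_genes)
  n <- length(ids_sorted)
  running <- 0
  best <- 0
  for (g in ids_sorted) {
    running <- running +
      if (g %in% set_genes) 1 / ns else -1 / (n - ns)
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# Tiny deterministic cohort for wiring tests: cheap relative to the
# package's reference conditions but with the same structure.
small_suite_config <- function(seed = 11) {
  cohort_config(n_genes = 400, n_cancer_samples = 40, n_normal_samples = 20,
                seed = seed)
}

# Pipeline config list for an in-memory suite; first two cohorts act as
# histopathology cohorts.
suite_pipeline_config <- function(suite, n_hp = 2, n_top = 50,
                                  sizes = c(25, 50), seed = 5,
                                  exclude = character(0), out_dir = NULL) {
  ids <- names(suite)
  list(cohorts = lapply(seq_along(suite), function(i)
    list(matrix = suite[[i]]$matrix,
         annotation = suite[[i]]$annotation,
         cohort_id = ids[[i]],
         histopathology = i <= n_hp)),
    n_top = n_top, sizes = sizes, seed = seed, exclude = exclude,
    out_dir = out_dir)
}
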