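# Synthetic tissue-mixture cohorts. Bulk prostate samples are modelled as
# convex mixtures of three latent tissue expression profiles (cancer,
# stroma, benign epithelium). Mixing happens on the linear scale -- bulk
# RNA from different tissue compartments adds physically -- and the mixture
# is then logged, matching the log-like scale of processed expression data.
# Normal samples contain only stroma + epithelium; cancer samples contain
# all three tissues. Normal samples draw systematically more stroma than
# cancer samples, reproducing the sampling bias that confounds
# cancer-vs-normal comparisons in real cohorts.

#' Configuration for a synthetic tissue-mixture cohort
#'
#' Defaults define the reference simulation conditions used throughout the
#' package's validation: 2000 genes, 100 cancer + 50 normal samples, 10%
#' planted stroma-enriched and 10% stroma-depleted genes, 5% genes with the
#' confounded cancer-vs-epithelium pattern (ordered epithelium > cancer >
#' stroma on the log scale, or its mirror image), mean stroma fraction 0.50
#' in normal vs 0.25 in cancer samples, and additive Gaussian noise with
#' sd 0.5 on the log2 scale.
#'
#' @param n_genes Number of genes.
#' @param n_cancer_samples,n_normal_samples Samples per class (each >= 1).
#' @param frac_stroma_up,frac_stroma_down Fractions of genes planted as
#'   stroma-enriched / stroma-depleted.
#' @param frac_cancer_de Fraction of genes planted with the confounded
#'   cancer-vs-epithelium pattern (split evenly between down- and
#'   up-in-cancer).
#' @param mean_stroma_normal,mean_stroma_cancer Mean stroma tissue fraction
#'   per class; the normal mean must exceed the cancer mean (the sampling
#'   bias).
#' @param proportion_concentration Dirichlet concentration controlling the
#'   spread of tissue fractions around their class means.
#' @param noise_sd Sd of additive Gaussian noise on the log2 scale.
#' @param baseline_shift Cohort-level offset added to every value,
#'   emulating between-cohort baseline differences.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @param delta_stroma Log2 shift of planted stroma genes in the stroma
#'   profile.
#' @param delta_cancer Log2 half-gap of the epithelium > cancer > stroma
#'   ordering for planted cancer-vs-epithelium genes.
#' @param cohort_id Cohort label.
#' @return A validated config list with class `"cohort_config"`.
#' @export
cohort_config <- function(n_genes = 2000,
                          n_cancer_samples = 100,
                          n_normal_samples = 50,
                          frac_stroma_up = 0.10,
                          frac_stroma_down = 0.10,
                          frac_cancer_de = 0.05,
                          mean_stroma_normal = 0.50,
                          mean_stroma_cancer = 0.25,
                          proportion_concentration = 10,
                          noise_sd = 0.5,
                          baseline_shift = 0,
                          seed = 1L,
                          delta_stroma = 2,
                          delta_cancer = 1.5,
                          cohort_id = "synthetic") {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cancer_samples = as.integer(n_cancer_samples),
              n_normal_samples = as.integer(n_normal_samples),
              frac_stroma_up = frac_stroma_up,
              frac_stroma_down = frac_stroma_down,
              frac_cancer_de = frac_cancer_de,
              mean_stroma_normal = mean_stroma_normal,
              mean_stroma_cancer = mean_stroma_cancer,
              proportion_concentration = proportion_concentration,
              noise_sd = noise_sd,
              baseline_shift = baseline_shift,
              seed = as.integer(seed),
              delta_stroma = delta_stroma,
              delta_cancer = delta_cancer,
              cohort_id = as.character(cohort_id))
  num <- cfg[!(names(cfg) %in% "cohort_id")]
  if (!all(vapply(num, function(v) is.numeric(v) && is.finite(v), logical(1L))))
    stop("all numeric config fields must be finite")
  fr <- c(cfg$frac_stroma_up, cfg$frac_stroma_down, cfg$frac_cancer_de)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("gene-class fractions must lie in [0,1] and sum to <= 1")
  if (cfg$mean_stroma_normal <= 0 || cfg$mean_stroma_normal >= 1 ||
      cfg$mean_stroma_cancer <= 0 || cfg$mean_stroma_cancer >= 1)
    stop("mean stroma fractions must lie in (0, 1)")
  if (cfg$mean_stroma_cancer >= cfg$mean_stroma_normal)
    stop("mean_stroma_cancer must be < mean_stroma_normal (sampling bias)")
  if (cfg$proportion_concentration <= 0)
    stop("proportion_concentration must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$n_cancer_samples < 1L || cfg$n_normal_samples < 1L)
    stop("both sample classes must be non-empty")
  class(cfg) <- "cohort_config"
  cfg
}

# Dirichlet draws, one row per sample; alpha = mean * concentration.
.rdirichlet <- function(n, mean, concentration) {
  alpha <- mean * concentration
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# Latent gene classes and tissue profiles (log2 scale). Null genes share
# one profile across tissues so that, absent planted effects, tissue
# composition carries no expression signal.
.draw_truth <- function(cfg) {
  g <- cfg$n_genes
  ids <- sprintf("g%05d", seq_len(g))
  n_up <- round(cfg$frac_stroma_up * g)
  n_dn <- round(cfg$frac_stroma_down * g)
  n_cde <- round(cfg$frac_cancer_de * g)
  n_cde_dn <- ceiling(n_cde / 2)
  cls <- rep("null", g)
  planted <- sample.int(g, n_up + n_dn + n_cde)
  cls[planted[seq_len(n_up)]] <- "stroma_up"
  cls[planted[n_up + seq_len(n_dn)]] <- "stroma_down"
  cls[planted[n_up + n_dn + seq_len(n_cde_dn)]] <- "cancer_de_down"
  if (n_cde > n_cde_dn)
    cls[planted[n_up + n_dn + n_cde_dn + seq_len(n_cde - n_cde_dn)]] <- "cancer_de_up"
  names(cls) <- ids

  mu <- stats::rnorm(g, mean = 7, sd = 1.5)
  prof <- cbind(cancer = mu, stroma = mu, epithelium = mu)
  rownames(prof) <- ids
  prof[cls == "stroma_up", "stroma"] <- mu[cls == "stroma_up"] + cfg$delta_stroma
  prof[cls == "stroma_down", "stroma"] <- mu[cls == "stroma_down"] - cfg$delta_stroma
  dn <- cls == "cancer_de_down"   # epithelium > cancer > stroma
  prof[dn, "epithelium"] <- mu[dn] + cfg$delta_cancer
  prof[dn, "stroma"] <- mu[dn] - cfg$delta_cancer
  up <- cls == "cancer_de_up"     # stroma > cancer > epithelium
  prof[up, "epithelium"] <- mu[up] - cfg$delta_cancer
  prof[up, "stroma"] <- mu[up] + cfg$delta_cancer

  list(gene_class = cls, latent_profiles = prof)
}

# Tissue fractions and mixed expression for one cohort given fixed truth.
.sample_cohort <- function(truth, cfg) {
  nc <- cfg$n_cancer_samples; nn <- cfg$n_normal_samples
  sid <- c(sprintf("%s_c%03d", cfg$cohort_id, seq_len(nc)),
           sprintf("%s_n%03d", cfg$cohort_id, seq_len(nn)))
  class <- c(rep("cancer", nc), rep("normal", nn))

  ms_c <- cfg$mean_stroma_cancer
  # non-stroma mass in cancer samples split 65:35 cancer:epithelium
  mean_c <- c(cancer = 0.65 * (1 - ms_c), stroma = ms_c,
              epithelium = 0.35 * (1 - ms_c))
  frac_c <- .rdirichlet(nc, mean_c, cfg$proportion_concentration)
  ms_n <- cfg$mean_stroma_normal
  frac_n2 <- .rdirichlet(nn, c(ms_n, 1 - ms_n), cfg$proportion_concentration)
  frac_n <- cbind(0, frac_n2)      # normal tissue has no cancer compartment
  fractions <- rbind(frac_c, frac_n)
  dimnames(fractions) <- list(sid, c("cancer", "stroma", "epithelium"))

  lin <- 2^truth$latent_profiles    # genes x 3, linear scale
  mix <- lin %*% t(fractions)       # genes x samples
  expr <- log2(mix) + cfg$baseline_shift
  if (cfg$noise_sd > 0)
    expr <- expr + matrix(stats::rnorm(length(expr), sd = cfg$noise_sd),
                          nrow = nrow(expr))
  dimnames(expr) <- list(rownames(truth$latent_profiles), sid)

  ann <- sample_annotation(sid, class, cohort_id = cfg$cohort_id,
                           stroma_pct = 100 * fractions[, "stroma"],
                           cancer_pct = 100 * fractions[, "cancer"],
                           epithelium_pct = 100 * fractions[, "epithelium"])
  list(matrix = expression_matrix(expr, cohort_id = cfg$cohort_id),
       annotation = ann,
       fractions = fractions)
}

#' Generate a synthetic cohort
#'
#' Draws latent tissue profiles with planted gene classes, per-sample
#' tissue fractions (Dirichlet around class-specific means) and the mixed,
#' noisy expression matrix. The annotation carries the true stroma /
#' cancer / epithelium fractions as histopathology percentages.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `matrix` ([expression_matrix()]),
#'   `annotation` (data.frame) and `truth` (class `"planted_truth"`: gene
#'   classes, per-sample tissue fractions, latent log2 profiles).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  truth <- .draw_truth(config)
  smp <- .sample_cohort(truth, config)
  truth <- structure(list(gene_class = truth$gene_class,
                          tissue_fractions = smp$fractions,
                          latent_profiles = truth$latent_profiles),
                     class = "planted_truth")
  list(matrix = smp$matrix, annotation = smp$annotation, truth = truth)
}

#' Generate a multi-cohort suite sharing one planted truth
#'
#' All cohorts share the latent profiles and gene classes (the biology);
#' samples, noise and the cohort-level baseline shift differ per cohort.
#' Cohort sampling seeds are derived from `config$seed`.
#'
#' @param config A [cohort_config()]; its `seed` drives the shared truth.
#' @param n_cohorts Number of cohorts.
#' @param baseline_shifts Numeric vector of per-cohort baseline offsets
#'   (recycled); default staggers cohorts by 0.5.
#' @return A list of per-cohort lists as returned by [generate_cohort()];
#'   all share an identical `truth$gene_class` / `latent_profiles`.
#' @export
generate_suite <- function(config, n_cohorts = 5,
                           baseline_shifts = 0.5 * (seq_len(n_cohorts) - 1)) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  baseline_shifts <- rep_len(baseline_shifts, n_cohorts)
  set.seed(config$seed)
  truth0 <- .draw_truth(config)
  out <- vector("list", n_cohorts)
  for (i in seq_len(n_cohorts)) {
    cfg_i <- config
    cfg_i$cohort_id <- sprintf("%s%d", config$cohort_id, i)
    cfg_i$baseline_shift <- baseline_shifts[[i]]
    set.seed(config$seed + i)
    smp <- .sample_cohort(truth0, cfg_i)
    out[[i]] <- list(matrix = smp$matrix, annotation = smp$annotation,
                     truth = structure(list(gene_class = truth0$gene_class,
                                            tissue_fractions = smp$fractions,
                                            latent_profiles = truth0$latent_profiles),
                                       class = "planted_truth"))
  }
  names(out) <- vapply(out, function(x) cohort_id(x$matrix), character(1L))
  out
}

#' Table of planted differentially expressed genes
#'
#' One row per planted (non-null) gene with its class and the true
#' cancer-vs-epithelium direction derived from the latent profiles
#' (`"down"` when the epithelium profile exceeds the cancer profile,
#' `"up"` for the reverse, `"none"` when they coincide, as for pure stroma
#' markers).
#'
#' @param truth A `planted_truth` object.
#' @return data.frame with columns `gene_id`, `class`, `direction`.
#' @export
planted_de_table <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  keep <- truth$gene_class != "null"
  ids <- names(truth$gene_class)[keep]
  d <- truth$latent_profiles[ids, "cancer"] - truth$latent_profiles[ids, "epithelium"]
  data.frame(gene_id = ids,
             class = unname(truth$gene_class[keep]),
             direction = ifelse(d < 0, "down", ifelse(d > 0, "up", "none")),
             row.names = NULL, stringsAsFactors = FALSE)
}
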