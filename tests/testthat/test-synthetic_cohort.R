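test_that("config validation enforces the tissue-mixture invariants", {
  expect_error(cohort_config(mean_stroma_cancer = 0.6, mean_stroma_normal = 0.5),
               "sampling bias")
  expect_error(cohort_config(frac_stroma_up = 0.6, frac_stroma_down = 0.5),
               "sum to <= 1")
  expect_error(cohort_config(n_normal_samples = 0), "non-empty")
  expect_error(cohort_config(noise_sd = -1), "non-negative")
  expect_error(cohort_config(noise_sd = NaN), "finite")
})

test_that("tissue fractions are convex and normals carry no cancer tissue", {
  co <- generate_cohort(cohort_config(n_genes = 100, n_cancer_samples = 10,
                                      n_normal_samples = 6, seed = 3))
  fr <- co$truth$tissue_fractions
  expect_true(all(fr >= 0))
  expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)))
  normals <- co$annotation$sample_id[co$annotation$class == "normal"]
  expect_equal(unname(fr[normals, "cancer"]), rep(0, length(normals)))
  expect_equal(co$annotation$stroma_pct,
               unname(100 * fr[co$annotation$sample_id, "stroma"]))
})

test_that("noise-free samples equal the logged convex mixture of profiles", {
  for (shift in c(0, 1.5)) {
    co <- generate_cohort(cohort_config(n_genes = 50, n_cancer_samples = 5,
                                        n_normal_samples = 4, noise_sd = 0,
                                        baseline_shift = shift, seed = 8))
    lin <- 2^co$truth$latent_profiles
    expected <- log2(lin %*% t(co$truth$tissue_fractions)) + shift
    expect_equal(unclass(co$matrix), expected[, colnames(co$matrix)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("normal samples draw more stroma than cancer samples on average", {
  co <- generate_cohort(cohort_config(n_genes = 50, n_cancer_samples = 200,
                                      n_normal_samples = 50,
                                      mean_stroma_normal = 0.5,
                                      mean_stroma_cancer = 0.25, seed = 21))
  fr <- co$truth$tissue_fractions
  cls <- setNames(co$annotation$class, co$annotation$sample_id)
  m_normal <- mean(fr[names(cls)[cls == "normal"], "stroma"])
  m_cancer <- mean(fr[names(cls)[cls == "cancer"], "stroma"])
  expect_gt(m_normal, m_cancer)
  expect_equal(m_normal, 0.5, tolerance = 0.1)
  expect_equal(m_cancer, 0.25, tolerance = 0.1)
})

test_that("generation is deterministic given the config seed", {
  cfg <- cohort_config(n_genes = 80, n_cancer_samples = 8,
                       n_normal_samples = 5, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$truth$gene_class, b$truth$gene_class)
  s1 <- generate_suite(cfg, n_cohorts = 2)
  s2 <- generate_suite(cfg, n_cohorts = 2)
  expect_identical(unclass(s1[[2]]$matrix), unclass(s2[[2]]$matrix))
})

test_that("suite cohorts share one planted truth but differ in samples", {
  suite <- generate_suite(small_suite_config(), n_cohorts = 3)
  expect_identical(suite[[1]]$truth$gene_class, suite[[3]]$truth$gene_class)
  expect_identical(suite[[1]]$truth$latent_profiles,
                   suite[[2]]$truth$latent_profiles)
  expect_false(identical(unclass(suite[[1]]$matrix)[, 1],
                         unclass(suite[[2]]$matrix)[, 1]))
})

test_that("planted_de_table reports classes, counts and true directions", {
  cfg <- cohort_config(n_genes = 200, n_cancer_samples = 5,
                       n_normal_samples = 5, frac_stroma_up = 0.1,
                       frac_stroma_down = 0.05, frac_cancer_de = 0.1,
                       seed = 4)
  co <- generate_cohort(cfg)
  tab <- planted_de_table(co$truth)
  counts <- table(tab$class)
  expect_equal(unname(counts[["stroma_up"]]), round(0.1 * 200))
  expect_equal(unname(counts[["stroma_down"]]), round(0.05 * 200))
  expect_equal(sum(grepl("^cancer_de", tab$class)), round(0.1 * 200))
  # directions follow the sign of the cancer-minus-epithelium profile gap
  prof <- co$truth$latent_profiles
  down <- tab$gene_id[tab$class == "cancer_de_down"]
  expect_true(all(prof[down, "epithelium"] > prof[down, "cancer"]))
  expect_true(all(tab$direction[tab$class == "cancer_de_down"] == "down"))
  expect_true(all(tab$direction[tab$class == "cancer_de_up"] == "up"))
  expect_true(all(tab$direction[grepl("^stroma", tab$class)] == "none"))

  null_cfg <- cohort_config(n_genes = 50, n_cancer_samples = 4,
                            n_normal_samples = 4, frac_stroma_up = 0,
                            frac_stroma_down = 0, frac_cancer_de = 0, seed = 2)
  empty <- planted_de_table(generate_cohort(null_cfg)$truth)
  expect_equal(nrow(empty), 0)
})
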