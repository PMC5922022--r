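test_that("enrichment score hits the KS extremes on tiny universes", {
  v <- c(gA = 4, gB = 3, gC = 2, gD = 1)
  expect_equal(single_sample_es(v, "gA"), 1)      # hit step peaks first
  expect_equal(single_sample_es(v, "gD"), -1)     # three misses reach -1
  expect_equal(single_sample_es(v, c("gA", "gB")), 1)
  # shifting all expression leaves the ranking, hence the score, unchanged
  expect_equal(single_sample_es(v + 100, "gA"), 1)
  expect_error(single_sample_es(v, c("gA", "gB", "gC", "gD")),
               "whole universe")
  expect_error(single_sample_es(v, "gZ"), "no member")
  expect_error(single_sample_es(unname(v), "gA"), "named")
})

test_that("enrichment score matches the brute-force running sum", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    ids <- sprintf("g%02d", seq_len(n))
    vals <- setNames(rnorm(n), ids)
    set <- sample(ids, sample(seq_len(n - 1), 1))
    expect_equal(single_sample_es(vals, set), es_oracle(vals, set),
                 tolerance = 1e-12)
  }
})

test_that("reversing a tie-free ranking negates the score", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    ids <- sprintf("g%02d", seq_len(n))
    vals <- setNames(sample(seq_len(n)), ids)   # tie-free
    set <- sample(ids, sample(2:(n - 2), 1))
    fwd <- single_sample_es(vals, set)
    rev_ <- single_sample_es(-vals, set)
    expect_equal(abs(rev_), abs(fwd), tolerance = 1e-12)
    # the walk can peak at +m and -m simultaneously, in which case the
    # returned sign is the first peak reached and reversal keeps it
    steps <- ifelse(ids[order(-vals, ids)] %in% set,
                    1 / length(intersect(ids, set)),
                    -1 / (n - length(intersect(ids, set))))
    rs <- cumsum(steps)
    if (sum(abs(abs(rs) - max(abs(rs))) < 1e-12 & sign(rs) != sign(fwd)) == 0)
      expect_equal(rev_, -fwd, tolerance = 1e-12)
  }
})

scoring_fixture <- function() {
  co <- generate_cohort(cohort_config(n_genes = 500, n_cancer_samples = 40,
                                      n_normal_samples = 20, seed = 41))
  stroma <- setNames(co$annotation$stroma_pct, co$annotation$sample_id)
  st <- split_by_stroma(co$annotation, stroma)
  cls <- setNames(co$annotation$class, co$annotation$sample_id)
  bal <- c(st$balanced_cancer, st$balanced_normal)
  unb <- c(st$unbalanced_cancer, st$unbalanced_normal)
  gs <- build_stroma_genesets(
    mann_whitney_de(co$matrix[, bal, drop = FALSE], cls[bal]),
    mann_whitney_de(co$matrix[, unb, drop = FALSE], cls[unb]),
    n_top = 50)
  list(co = co, gs = gs)
}

test_that("per-size scores normalize to 0-100 and average into the stroma score", {
  fx <- scoring_fixture()
  tab <- stroma_score_cohort(fx$co$matrix, fx$gs, sizes = c(25, 50))
  norm <- as.matrix(tab[, c("norm_25", "norm_50")])
  expect_equal(unname(apply(norm, 2, min)), c(0, 0))
  expect_equal(unname(apply(norm, 2, max)), c(100, 100))
  expect_equal(tab$stroma_score, rowMeans(norm))
  expect_true(all(tab$stroma_score >= 0 & tab$stroma_score <= 100))

  # two samples: the affine normalization is forced to {0, 100} per size
  two <- expression_matrix(unclass(fx$co$matrix)[, 1:2],
                           cohort_id = "two")
  t2 <- stroma_score_cohort(two, fx$gs, sizes = c(25, 50))
  expect_setequal(round(t2$norm_25), c(0, 100))
  expect_setequal(round(t2$norm_50), c(0, 100))

  one <- expression_matrix(unclass(fx$co$matrix)[, 1, drop = FALSE], "one")
  expect_warning(t1 <- stroma_score_cohort(one, fx$gs, sizes = 25),
                 "degenerate")
  expect_equal(t1$stroma_score, 50)

  expect_error(stroma_score_cohort(fx$co$matrix, fx$gs, sizes = 60),
               "exceeds available set length")
  expect_error(stroma_score_cohort(fx$co$matrix, fx$gs, sizes = 50,
                                   universe = rownames(fx$co$matrix)[1:80]),
               "smaller than twice")
})

test_that("stroma score tracks the true stroma fraction and is rank-invariant", {
  fx <- scoring_fixture()
  tab <- stroma_score_cohort(fx$co$matrix, fx$gs, sizes = c(25, 50))
  truth_fr <- fx$co$truth$tissue_fractions[tab$sample_id, "stroma"]
  expect_gt(cor(tab$stroma_score, truth_fr), 0.9)

  # any strictly monotone per-sample transform leaves the score unchanged
  warped <- expression_matrix(exp(unclass(fx$co$matrix) / 3) + 2, "warped")
  tab2 <- stroma_score_cohort(warped, fx$gs, sizes = c(25, 50))
  expect_equal(tab2$stroma_score, tab$stroma_score, tolerance = 1e-9)
})

test_that("score ordering is robust to the choice of the size ladder", {
  fx <- scoring_fixture()
  full <- stroma_score_cohort(fx$co$matrix, fx$gs,
                              sizes = c(10, 15, 20, 25, 30, 35, 40, 45, 50))
  coarse <- stroma_score_cohort(fx$co$matrix, fx$gs, sizes = c(10, 50))
  expect_gt(cor(full$stroma_score, coarse$stroma_score, method = "spearman"),
            0.95)
})

test_that("score stability summarises per-sample spread across sizes", {
  fx <- scoring_fixture()
  st <- score_stability(fx$co$matrix, fx$gs, sizes = c(10, 25, 50))
  tab <- stroma_score_cohort(fx$co$matrix, fx$gs, sizes = c(10, 25, 50))
  norm <- as.matrix(tab[, grep("^norm_", colnames(tab))])
  expect_equal(st$per_sample$sd, unname(apply(norm, 1, sd)))
  expect_equal(st$mean_sd, mean(st$per_sample$sd))
  # closed form on two sizes: normalized scores 40 and 60 have sd 14.14
  expect_equal(sd(c(40, 60)), 14.142136, tolerance = 1e-6)
  expect_true(all(st$per_sample$sd >= 0))
})

test_that("histopathology calibration recovers exact linear relations", {
  score <- c(10, 20, 30, 40, 55)
  cal <- calibrate_to_histopathology(score, 2 * score + 5)
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 5)
  expect_equal(cal$pearson_r, 1)
  expect_equal(cal$mean_abs_deviation, 0)
  expect_equal(predict(cal, c(10, 60)), c(25, 100))  # clipped to [0, 100]

  set.seed(33)
  indep <- calibrate_to_histopathology(runif(200, 0, 100), runif(200, 0, 100))
  expect_lt(abs(indep$pearson_r), 0.2)   # 3*SE bound at n = 200

  expect_error(calibrate_to_histopathology(rep(5, 10), rnorm(10)), "constant")
  expect_error(calibrate_to_histopathology(1:2, 1:2), ">= 3 samples")
})

test_that("calibration deviation on synthetic data is in a plausible band", {
  fx <- scoring_fixture()
  tab <- stroma_score_cohort(fx$co$matrix, fx$gs, sizes = c(25, 50))
  histo <- setNames(fx$co$annotation$stroma_pct, fx$co$annotation$sample_id)
  cal <- calibrate_to_histopathology(tab, histo)
  expect_gt(cal$pearson_r, 0.9)
  # scores explain stroma to within a few percentage points here; real
  # tissue shows larger deviations (~10 percentage points)
  expect_lt(cal$mean_abs_deviation, 20)
})
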