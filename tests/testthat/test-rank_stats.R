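mat1 <- function(x1, x2, gene = "g1") {
  m <- matrix(c(x1, x2), nrow = 1,
              dimnames = list(gene, sprintf("s%02d", seq_along(c(x1, x2)))))
  list(m = m, classes = rep(c("cancer", "normal"), c(length(x1), length(x2))))
}

test_that("small-sample Mann-Whitney p-values are exact", {
  # complete separation of 2 vs 2: 2 of the 6 equally likely rank splits
  # are as extreme, p = 1/3
  f <- mat1(c(5, 6), c(1, 2))
  de <- mann_whitney_de(f$m, f$classes)
  expect_equal(de$p_value, 1 / 3, tolerance = 1e-12)
  expect_identical(de$direction, "up")

  f <- mat1(c(1, 2), c(5, 6))
  expect_identical(mann_whitney_de(f$m, f$classes)$direction, "down")
})

test_that("degenerate genes get p = 1 and direction 'up' by convention", {
  f <- mat1(c(3, 3, 3), c(3, 3, 3))
  de <- mann_whitney_de(f$m, f$classes)
  expect_equal(de$p_value, 1)
  expect_identical(de$direction, "up")
  expect_equal(de$q_value, 1)
})

test_that("swapping class labels flips directions and keeps p-values", {
  set.seed(31)
  m <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  cls <- rep(c("cancer", "normal"), each = 10)
  a <- mann_whitney_de(m, cls)
  b <- mann_whitney_de(m, rev(cls))
  expect_equal(a$p_value, b$p_value)
  shifted <- a$p_value < 1      # p = 1 only for a dead-centered rank sum
  expect_true(all(a$direction[shifted] != b$direction[shifted]))
})

test_that("exact branch agrees with full enumeration, with and without ties", {
  set.seed(7)
  for (rep in 1:3) {
    for (n1 in 2:4) for (n2 in 2:5) {
      x1 <- sample(1:6, n1, replace = TRUE)   # coarse grid forces ties
      x2 <- sample(1:6, n2, replace = TRUE)
      f <- mat1(x1, x2)
      expect_equal(mann_whitney_de(f$m, f$classes)$p_value,
                   mw_enum_oracle(x1, x2), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
    }
  }
})

test_that("large-sample approximation matches the tie-corrected normal test", {
  set.seed(12)
  m <- matrix(round(rnorm(30 * 24), 1), 30, 24,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:24)))
  cls <- rep(c("cancer", "normal"), each = 12)
  de <- mann_whitney_de(m, cls)
  ref <- apply(m, 1, function(v)
    stats::wilcox.test(v[1:12], v[13:24], exact = FALSE,
                       correct = FALSE)$p.value)
  expect_equal(de$p_value, unname(ref), tolerance = 1e-10)
})

test_that("classes with fewer than two samples are rejected", {
  f <- mat1(c(1, 2, 3), 5)
  expect_error(mann_whitney_de(f$m, f$classes), ">= 2 samples")
})

test_that("significance ranks are a permutation with deterministic ties", {
  set.seed(5)
  m <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:12)))
  de <- mann_whitney_de(m, rep(c("cancer", "normal"), each = 6))
  expect_setequal(de$rank, 1:40)
  ord <- order(de$rank)
  expect_true(all(diff(de$p_value[ord]) >= 0))
})

test_that("BH correction at a global gene count matches the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03), 3), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.01, 1), 0.01)
  expect_equal(bh_fdr(1e-6, 25964), 0.025964)
  # original order restored, q >= p, capped at 1
  p <- c(0.5, 0.001, 0.9, 0.02)
  q <- bh_fdr(p, 100)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_equal(q[2], min(0.001 * 100 / 1, 0.02 * 100 / 2, 0.5 * 100 / 3, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "lie in \\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, 0.2), m_total = 1), "m_total")
})

test_that("BH correction is monotone in every p-value", {
  set.seed(9)
  p <- runif(50)
  q <- bh_fdr(p, 200)
  for (i in sample(50, 10)) {
    p2 <- p
    p2[i] <- min(1, p[i] + runif(1, 0, 1 - p[i]))
    expect_true(all(bh_fdr(p2, 200) >= q - 1e-12))
  }
})

test_that("probe collapse keeps the contracted best probe per gene", {
  m <- expression_matrix(matrix(c(3, 7, 5, 1, 6, 2), 3, 2,
                                dimnames = list(c("p1", "p2", "p3"),
                                                c("s1", "s2"))), "c1")
  map <- data.frame(probe_id = c("p1", "p2", "p3", "px"),
                    gene_id = c("GENE1", "GENE1", "GENE2", "GENE3"))
  # mean expression: p1 = 2, p2 = 6.5 -> p2 wins GENE1
  out <- collapse_probes(m, map, strategy = "max_expression")
  expect_setequal(rownames(out), c("GENE1", "GENE2"))
  expect_equal(unname(unclass(out)["GENE1", ]), c(7, 6))
  # single-probe gene retained under every strategy
  expect_equal(unname(unclass(out)["GENE2", ]), c(5, 2))

  # average significance rank over three analyses: (10+500+20)/3 = 176.7
  # vs (100+110+120)/3 = 110 -> the second probe wins
  ranks <- list(c(p1 = 10, p2 = 100, p3 = 1),
                c(p1 = 500, p2 = 110, p3 = 2),
                c(p1 = 20, p2 = 120, p3 = 3))
  out2 <- collapse_probes(m, map, strategy = "best_avg_de_rank",
                          de_context = ranks)
  expect_equal(unname(unclass(out2)["GENE1", ]), c(7, 6))
  out3 <- collapse_probes(m, map, strategy = "best_de_rank",
                          de_context = ranks[1])
  expect_equal(unname(unclass(out3)["GENE1", ]), c(3, 1))  # p1 ranked 10

  expect_error(collapse_probes(m, map[0, ]), "empty probe-to-gene mapping")
  expect_error(collapse_probes(m, map, strategy = "best_avg_de_rank"),
               "requires `de_context`")
})
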