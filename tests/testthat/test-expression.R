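test_that("size factors follow the median-of-ratios definition", {
  x <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(sprintf("g%d", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(x)), c(1, 1))

  y <- x
  y[, 2] <- 2 * y[, 1]
  expect_equal(unname(size_factors(y)), c(1 / sqrt(2), sqrt(2)))
})

test_that("genes with any zero are excluded from the size-factor reference", {
  x <- matrix(c(10, 0, 100, 10, 50, 100), ncol = 2,
              dimnames = list(sprintf("g%d", 1:3), c("s1", "s2")))
  # g2 must be ignored: both remaining genes are identical across samples
  expect_equal(unname(size_factors(x)), c(1, 1))
  allzero <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(size_factors(allzero), "no gene")
  expect_error(size_factors(-x), "non-negative")
})

test_that("size factors are invariant to global count scaling", {
  # the geometric-mean reference absorbs any global constant, so a uniform
  # rescaling of the whole matrix leaves the factors unchanged
  set.seed(5)
  x <- matrix(rpois(300, 50) + 1, nrow = 50)
  expect_equal(size_factors(3 * x), size_factors(x))
  # the normalized matrix is equivariant instead: normalizing 3x gives
  # exactly 3 times the normalized counts
  expect_equal(normalize_counts(3 * x), 3 * normalize_counts(x))
})

test_that("identical groups give zero fold changes; swapping groups mirrors", {
  set.seed(11)
  counts <- cbind(a = c(10, 50, 200), b = c(12, 48, 190),
                  c = c(10, 50, 200), d = c(12, 48, 190))
  rownames(counts) <- sprintf("g%d", 1:3)
  groups <- c("x", "x", "y", "y")
  res <- nb_wald_test(counts, groups, "x", "y")
  expect_equal(res$log2fc, rep(0, 3), tolerance = 1e-12)

  set.seed(12)
  counts2 <- matrix(rnbinom(400, mu = 100, size = 10), nrow = 50)
  rownames(counts2) <- sprintf("g%d", 1:50)
  g2 <- rep(c("x", "y"), each = 4)
  fwd <- nb_wald_test(counts2, g2, "x", "y")
  rev <- nb_wald_test(counts2, g2, "y", "x")
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  expect_error(nb_wald_test(counts2, c("x", rep("y", 7)), "x", "y"),
               ">= 2 samples")
})

test_that("BH adjustment matches the step-up formula and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.01)), "\\[0, 1\\]")
  set.seed(1)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_gte(min(adj), min(p))
  expect_true(all(adj <= 1))
  # order-preserving on the ranked scale
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("DEG calls apply the strict |log2FC| > 0.25, padj < 0.05 rule", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(0.3, 0.2, -0.3, 0.26),
                    padj = c(0.01, 0.001, 0.04, 0.2))
  deg <- call_degs(res)
  expect_identical(deg$up, "a")    # b below lfc threshold, d not significant
  expect_identical(deg$down, "c")
})

test_that("per-sample discretization tiers genes within a transcriptome", {
  x <- matrix(c(1:10, rep(5, 10)), ncol = 2,
              dimnames = list(letters[1:10], c("s1", "s2")))
  expect_warning(d <- discretize(x, by = "sample"), "degenerate")
  expect_identical(d[10, 1], 1L)   # strictly largest gene is high
  expect_identical(d[1, 1], -1L)
  expect_true(all(d[, 2] == 0L))   # all-equal sample is all moderate
})

test_that("per-sample discretization is invariant to monotone transforms", {
  set.seed(33)
  x <- matrix(rlnorm(500, 5, 1.5), ncol = 5)
  d1 <- discretize(x, by = "sample")
  d2 <- discretize(log1p(x), by = "sample")
  x3 <- sweep(x, 2, c(1, 2, 0.5, 10, 0.1), "*")  # per-sample rescaling
  d3 <- discretize(x3, by = "sample")
  expect_identical(d1, d2)
  expect_identical(d1, d3)
})

test_that("discretization marks ~25% of values high under continuous data", {
  set.seed(44)
  x <- matrix(rlnorm(10000, 5, 1.5), ncol = 4)
  for (mode in c("gene", "sample")) {
    d <- discretize(x, by = mode)
    expect_equal(mean(d == 1L), 0.25, tolerance = 0.02)
    expect_equal(mean(d == -1L), 0.25, tolerance = 0.02)
  }
})

test_that("per-gene discretization flags the samples where a gene runs high", {
  set.seed(55)
  base <- matrix(rlnorm(200, 5, 0.1), nrow = 10, ncol = 20)
  base[3, 16:20] <- base[3, 16:20] * 8   # gene 3 induced in samples 16-20
  d <- discretize(base, by = "gene")
  expect_true(all(d[3, 16:20] == 1L))
})

test_that("hypergeometric enrichment matches the closed form", {
  universe <- sprintf("g%d", 1:20)
  sets <- list(hit = universe[1:5], none = universe[6:10])
  res <- ora_hypergeometric(universe[1:5], sets, universe)
  expect_equal(res$p[res$set == "hit"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p[res$set == "none"], 1)      # zero overlap
  expect_equal(res$padj, bh_adjust(res$p))
  expect_error(ora_hypergeometric("g1", sets, character(0)), "empty universe")
  expect_error(ora_hypergeometric("zz", sets, universe), "universe")
})
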