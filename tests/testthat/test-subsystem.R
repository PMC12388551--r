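test_that("subsystem means average active reactions and flag empty cells", {
  map <- c(r1 = "ss1", r2 = "ss1", r3 = "ss2", r4 = "ss3")
  fl <- list(s1 = c(r1 = 2, r2 = 4, r3 = 1e-8, r4 = -3))
  tab <- subsystem_means(fl, map)
  expect_equal(tab$means["ss1", "s1"], 3)
  expect_true(is.na(tab$means["ss2", "s1"]))  # below inactivity threshold
  expect_equal(tab$means["ss3", "s1"], 3)     # |flux| by default
  expect_equal(tab$n_active["ss1", "s1"], 2L)

  signed <- subsystem_means(fl, map, use_abs = FALSE)
  expect_equal(signed$means["ss3", "s1"], -3)
  mixed <- subsystem_means(list(s1 = c(r1 = -2, r2 = 4)),
                           c(r1 = "ss1", r2 = "ss1"))
  expect_equal(mixed$means["ss1", "s1"], 3)
  expect_equal(subsystem_means(list(s1 = c(r1 = -2, r2 = 4)),
                               c(r1 = "ss1", r2 = "ss1"),
                               use_abs = FALSE)$means["ss1", "s1"], 1)
  expect_error(subsystem_means(list(s1 = c(zz = 1)), map), "without a")
})

test_that("pooled t-test matches its closed form and conventions", {
  p <- ttest_two_tailed(c(1, 2, 3), c(2, 3, 4))
  # closed form: t = -1.2247, df = 4
  expect_equal(p, 2 * pt(-abs(-1 / sqrt(2 / 3)), df = 4), tolerance = 1e-12)
  expect_equal(p, 0.2878641, tolerance = 1e-6)
  expect_equal(ttest_two_tailed(c(5, 5, 5), c(5, 5)), 1)
  expect_equal(ttest_two_tailed(c(5, 5, 5), c(7, 7)), 0)
  expect_equal(ttest_two_tailed(c(1, 2, 3), c(2, 3, 4)),
               ttest_two_tailed(c(2, 3, 4), c(1, 2, 3)))
  expect_error(ttest_two_tailed(1, c(1, 2)), ">= 2")
})

test_that("pooled t-test agrees with the textbook formula on random draws", {
  set.seed(77)
  for (i in 1:100) {
    a <- rnorm(sample(2:6, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -1, 1))
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    oracle <- 2 * pt(-abs(tstat), df = na + nb - 2)
    expect_equal(ttest_two_tailed(a, b), oracle, tolerance = 1e-10)
  }
})

test_that("classification follows the sign/significance rule exactly", {
  expect_identical(classify(2, 0.01), "activated")
  expect_identical(classify(-2, 0.20), "unchanged")
  expect_identical(classify(-2, 0.01), "suppressed")
  expect_identical(classify(0, 0.0001), "unchanged")
  expect_identical(classify(3, NA_real_), "unchanged")
  expect_identical(classify(c(1, -1), c(0.01, 0.02)),
                   c("activated", "suppressed"))
})

test_that("deltas difference group means against control", {
  means <- rbind(ss1 = c(3, 3, 5, 5), ss2 = c(1, 1, 1, 1))
  colnames(means) <- c("c1", "c2", "t1", "t2")
  tab <- structure(list(means = means,
                        n_active = matrix(1L, 2, 4,
                                          dimnames = dimnames(means))),
                   class = "subsystem_flux")
  ga <- c(c1 = "ctrl", c2 = "ctrl", t1 = "exp", t2 = "exp")
  dt <- delta_vs_control(tab, ga, "ctrl")
  expect_equal(dt$delta[dt$subsystem == "ss1"], 2)
  expect_equal(dt$delta[dt$subsystem == "ss2"], 0)
  # group identical to control -> all deltas zero, p = 1 by convention
  dt0 <- delta_vs_control(tab, c(c1 = "ctrl", c2 = "ctrl",
                                 t1 = "ctrl", t2 = "exp2"), "ctrl")
  expect_error(delta_vs_control(tab, ga, "nope"), "not present")
  # permuting sample order leaves deltas unchanged
  perm <- c(3, 1, 4, 2)
  tab2 <- tab
  tab2$means <- tab2$means[, perm]
  tab2$n_active <- tab2$n_active[, perm]
  dt2 <- delta_vs_control(tab2, ga, "ctrl")
  expect_equal(dt2$delta[order(dt2$subsystem)], dt$delta[order(dt$subsystem)])
})

test_that("missing cells enter the comparison as zero flux by default", {
  means <- rbind(ss1 = c(NA, NA, 10, 10))
  colnames(means) <- c("c1", "c2", "t1", "t2")
  tab <- structure(list(means = means,
                        n_active = matrix(0L, 1, 4,
                                          dimnames = dimnames(means))),
                   class = "subsystem_flux")
  ga <- c(c1 = "ctrl", c2 = "ctrl", t1 = "exp", t2 = "exp")
  dt <- delta_vs_control(tab, ga, "ctrl")
  expect_equal(dt$delta, 10)
  expect_identical(dt$class, "activated")   # activation from silence
  dt_na <- delta_vs_control(tab, ga, "ctrl", missing_as_zero = FALSE)
  expect_true(is.na(dt_na$delta))
  expect_identical(dt_na$class, "unchanged")
})

test_that("projective rescaling reaches unit row/column RMS and is invariant", {
  ones <- matrix(1, 4, 3)
  r <- projective_rescale(ones)
  expect_equal(r$rescaled, ones)
  expect_equal(r$row_scale, rep(1, 4))

  set.seed(9)
  x <- matrix(rlnorm(20, 0, 1), 5, 4)
  r1 <- projective_rescale(x)
  mask <- x > 0
  rr <- sqrt(rowSums(r1$rescaled^2 * mask) / rowSums(mask))
  cc <- sqrt(colSums(r1$rescaled^2 * mask) / colSums(mask))
  expect_lt(max(abs(c(rr, cc) - 1)), 1e-6)
  # reconstruction: original = diag(r) %*% rescaled %*% diag(c)
  expect_equal(diag(r1$row_scale) %*% r1$rescaled %*% diag(r1$col_scale), x,
               tolerance = 1e-8, ignore_attr = TRUE)
  # scale invariance: multiplying a row by c > 0 changes nothing downstream
  y <- x
  y[2, ] <- 7 * y[2, ]
  r2 <- projective_rescale(y)
  expect_equal(r2$rescaled, r1$rescaled, tolerance = 1e-6)
  # column scaling too
  z <- sweep(x, 2, c(2, 5, 0.1, 40), "*")
  r3 <- projective_rescale(z)
  expect_equal(r3$rescaled, r1$rescaled, tolerance = 1e-6)

  bad <- rbind(c(0, 0), c(1, 1))
  expect_error(projective_rescale(bad), "all-zero")
})
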