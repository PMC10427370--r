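test_that("size factors match the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)

  same <- cbind(m[, 1], m[, 1], m[, 1])
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(size_factors(same)), rep(1, 3))

  big <- toy_counts(500, 10, mu = 200, seed = 5)
  expect_equal(unname(size_factors(big)), unname(size_factors_brute(big)),
               tolerance = 1e-12)

  zeros <- m; zeros[, 1] <- 0
  expect_error(size_factors(zeros), class = "hmc_validation_error")
})

test_that("TPM columns are properly scaled", {
  one <- matrix(7L, 1, 2, dimnames = list("gA", c("s1", "s2")))
  expect_equal(unname(tpm_normalize(one, c(gA = 2))[1, ]), c(1e6, 1e6))

  two <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  t2 <- tpm_normalize(two, c(gA = 1, gB = 2))
  expect_equal(unname(t2[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  big <- toy_counts(300, 8, seed = 6)
  lens <- setNames(runif(300, 0.5, 10), rownames(big))
  expect_equal(unname(colSums(tpm_normalize(big, lens))), rep(1e6, 8),
               tolerance = 1e-6)
  expect_error(tpm_normalize(big, lens[-1]), class = "hmc_validation_error")
})

test_that("rlog approximation behaves at zero, under scaling and monotonically", {
  m <- toy_counts(200, 100, mu = 300, seed = 7)
  m[1, ] <- 0L
  m[2, ] <- sort(rnbinom(100, mu = 300, size = 50))
  r <- rlog_approx(m, sf = rep(1, 100))
  expect_equal(unname(r[1, ]), rep(0, 100))
  expect_true(all(diff(r[2, ]) >= 0))

  # doubling one sample's counts is absorbed by its size factor (up to the
  # slight shift of the geometric-mean reference, negligible at 100 samples)
  m2 <- m; m2[, 1] <- m2[, 1] * 2L
  r1 <- rlog_approx(m)
  r2 <- rlog_approx(m2)
  keep <- m[, 1] >= 100
  expect_equal(r1[keep, 1], r2[keep, 1], tolerance = 0.02)
})

test_that("NB Wald test is exact under degenerate designs", {
  m <- toy_counts(300, 3, mu = 150, seed = 8)
  dup <- cbind(m, m)
  colnames(dup) <- paste0("s", 1:6)
  res <- nb_wald_test(dup, paste0("s", 1:3), paste0("s", 4:6))
  expect_true(all(res$log2_fc == 0))

  expect_error(nb_wald_test(dup, paste0("s", 1:3), paste0("s", 3:6)),
               "overlap", class = "hmc_validation_error")
  expect_error(nb_wald_test(dup, "s1", paste0("s", 4:6)),
               class = "hmc_validation_error")

  # swapping groups flips the fold change exactly
  m2 <- toy_counts(300, 8, mu = 150, seed = 9)
  a <- paste0("s", 1:4); b <- paste0("s", 5:8)
  r_ab <- nb_wald_test(m2, a, b)
  r_ba <- nb_wald_test(m2, b, a)
  expect_equal(r_ab$log2_fc, -r_ba$log2_fc)
  expect_equal(r_ab$p, r_ba$p)
})

test_that("NB Wald test recovers planted fold changes", {
  set.seed(10)
  n_genes <- 2000
  mu <- rep(500, n_genes)
  planted <- 1:200
  m <- sapply(1:20, function(j) {
    mj <- mu
    if (j > 10) mj[planted] <- mj[planted] * 2
    rnbinom(n_genes, mu = mj, size = 100)
  })
  dimnames(m) <- list(sprintf("g%05d", 1:n_genes), paste0("s", 1:20))
  res <- nb_wald_test(m, paste0("s", 1:10), paste0("s", 11:20))
  lfc <- res$log2_fc[match(sprintf("g%05d", planted), res$gene)]
  expect_lt(median(abs(lfc - 1)), 0.1)
  degs <- filter_degs(res)
  sens <- mean(sprintf("g%05d", planted) %in% degs$up)
  expect_gt(sens, 0.9)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "hmc_validation_error")

  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(5:200, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  # permutation equivariance
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("DEG and DhMG filters apply their thresholds as stated", {
  res <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    log2_fc = c(0.5, 0.3, -0.8, 0.6, -0.9),
    p = c(0.001, 0.001, 0.01, 0.005, 0.2),
    padj = c(0.1, 0.05, 0.08, 0.05, 0.3))
  degs <- filter_degs(res)
  expect_true("a" %in% degs$all)    # padj = 0.1, lfc = 0.5: inclusive
  expect_false("b" %in% degs$all)   # lfc below threshold
  expect_true("c" %in% degs$down)
  expect_false("e" %in% degs$all)   # padj above threshold

  dh <- filter_dhmgs(res)
  expect_false("c" %in% dh$all)     # p = 0.01 exactly: strict
  expect_true("d" %in% dh$up)
  expect_false("e" %in% dh$all)
})

test_that("basic tests reproduce exact small-sample results", {
  idem <- basic_tests(c(1, 2, 3), c(1, 2, 3), "t_unpaired")
  expect_equal(idem$statistic, 0)
  expect_equal(idem$p, 1)

  w <- basic_tests(c(1, 2, 3), c(4, 5, 6), "wilcoxon_ranksum")
  expect_equal(w$p, 0.1)  # 2/20 orderings as extreme, two-sided

  set.seed(12)
  x <- rnorm(10)
  shifted <- x + 3 * sd(x) + rnorm(10, 0, 0.1 * sd(x))
  expect_lt(basic_tests(x, shifted, "t_paired")$p, 0.05)
  expect_error(basic_tests(1:4, 1:5, "t_paired"),
               class = "hmc_validation_error")
})
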