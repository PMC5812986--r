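test_that("coverage filter keeps exactly the all-sample-covered sites", {
  t <- matrix(10, nrow = 4, ncol = 4)
  t[2, 3] <- 9                     # one sample below threshold
  m <- matrix(5, nrow = 4, ncol = 4)
  tbl <- toy_meth(m, t, groups = rep(c("control", "low1C"), each = 2))
  out <- filter_by_coverage(tbl, 10)
  expect_equal(nrow(out$sites), 3L)
  expect_false(20L %in% out$sites$pos)   # site 2 (pos 20) removed
  # identity when everything passes, and idempotence
  t2 <- matrix(10, nrow = 4, ncol = 4)
  tbl2 <- toy_meth(m, t2, groups = rep(c("control", "low1C"), each = 2))
  expect_identical(filter_by_coverage(tbl2, 10)$sites, tbl2$sites)
  expect_identical(filter_by_coverage(out, 10), out)
})

test_that("coverage filter matches a brute-force per-site scan", {
  set.seed(42)
  n <- 200
  t <- matrix(rpois(n * 6, 12), nrow = n)
  m <- matrix(rbinom(n * 6, as.vector(t), 0.5), nrow = n)
  tbl <- toy_meth(m, t, groups = rep(c("control", "low1C"), each = 3))
  out <- filter_by_coverage(tbl, 10)
  keep_naive <- vapply(seq_len(n), function(i) all(t[i, ] >= 10), logical(1))
  expect_equal(nrow(out$sites), sum(keep_naive))
  expect_equal(out$sites$pos, tbl$sites$pos[keep_naive])
})

test_that("site f-statistic equals textbook one-way ANOVA", {
  expect_equal(as.numeric(site_fstat(list(c(0.2, 0.4), c(0.2, 0.4)))), 0)
  f <- site_fstat(list(c(0.1, 0.1, 0.1), c(0.9, 0.9, 0.9)))
  expect_equal(as.numeric(f), 1e8)
  expect_true(attr(f, "capped"))
  expect_error(site_fstat(list(c(0.1, 1.2), c(0.3, 0.4))), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:50) {
    a <- runif(sample(2:6, 1)); b <- runif(sample(2:6, 1))
    y <- c(a, b); g <- factor(rep(1:2, c(length(a), length(b))))
    f_ref <- anova(lm(y ~ g))[["F value"]][1]
    expect_equal(as.numeric(site_fstat(list(a, b))), f_ref, tolerance = 1e-10)
  }
})

test_that("track f-statistics agree with the scalar ANOVA at every site", {
  cfg <- small_cfg(seed = 31, n_cpg = 1200L)
  mod <- simulate_annotation(cfg)
  sim <- simulate_methylome(mod, cfg)
  tr <- compute_fstat_track(sim$table, min_cov = 10)
  tbl <- filter_by_coverage(sim$table, 10)
  p <- tbl$m / tbl$t
  g <- tbl$samples$group
  idx <- sample(nrow(tr$sites), 200)
  for (i in idx) {
    f_ref <- site_fstat(list(p[i, g == "control"], p[i, g == "low1C"]))
    expect_equal(tr$sites$f[i], as.numeric(f_ref), tolerance = 1e-10)
  }
  expect_true(all(tbl$t >= 10))
  expect_gt(tr$mean_f, 0)
})

test_that("dispersion shrinkage is a fixed point, a contraction, and recovers truth", {
  expect_equal(shrink_dispersion(rep(0.04, 10)), rep(0.04, 10))
  phi <- c(rep(0.05, 50), 0.5)
  shr <- shrink_dispersion(phi, total_cov = rep(300, 51))
  bar <- mean(phi, trim = 0.1)
  expect_lt(abs(shr[51] - bar), abs(0.5 - bar))
  expect_true(all(shrink_dispersion(c(-0.1, NA, 0.2)) >= 0))
  # recovery: beta-binomial data with known phi, coverage 30, n = 12
  set.seed(99)
  phi_true <- 0.08; n_site <- 400; nsamp <- 12; cov <- 30
  a <- 0.5 * (1 - phi_true) / phi_true
  pr <- matrix(rbeta(n_site * nsamp, a, a), nrow = n_site)
  m <- matrix(rbinom(n_site * nsamp, cov, pr), nrow = n_site)
  t <- matrix(cov, n_site, nsamp)
  tbl <- toy_meth(m, t, groups = rep(c("control", "low1C"), each = 6))
  res <- dml_test(tbl)
  expect_lt(abs(mean(res$phi_shrunk) - phi_true) / phi_true, 0.25)
})

test_that("beta-binomial Wald test is total, symmetric and monotone", {
  m <- rbind(c(5, 5, 5, 5), c(2, 3, 8, 9), c(0, 0, 0, 0))
  t <- matrix(10, 3, 4)
  tbl <- toy_meth(m, t, groups = rep(c("control", "low1C"), each = 2))
  res <- dml_test(tbl)
  expect_equal(res$stat[c(1, 3)], c(0, 0))
  expect_equal(res$p[c(1, 3)], c(1, 1))
  # larger mean difference at fixed counts gives a larger |stat|
  m2 <- rbind(c(4, 4, 6, 6), c(2, 2, 8, 8))
  tbl2 <- toy_meth(m2, matrix(10, 2, 4),
                   groups = rep(c("control", "low1C"), each = 2))
  res2 <- dml_test(tbl2)
  expect_gt(abs(res2$stat[2]), abs(res2$stat[1]))
  # zero coverage in one group is flagged, not an error
  t3 <- rbind(c(0, 0, 10, 10))
  tbl3 <- toy_meth(rbind(c(0, 0, 5, 5)), t3,
                   groups = rep(c("control", "low1C"), each = 2))
  expect_true(dml_test(tbl3)$skipped[1])
})

test_that("BH adjustment equals the step-up recursion", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(12)
  p <- runif(200)
  expect_equal(bh_fdr(p), bh_oracle(p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("methylation histogram handles the degenerate extremes", {
  t <- matrix(10, 3, 4)
  tbl_full <- toy_meth(t, t, groups = rep(c("control", "low1C"), each = 2))
  h <- methylation_histogram(tbl_full)
  expect_equal(h$fraction_high, 1)
  tbl_zero <- toy_meth(matrix(0, 3, 4), t,
                       groups = rep(c("control", "low1C"), each = 2))
  expect_equal(methylation_histogram(tbl_zero)$fraction_low, 1)
})
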