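make_tiny_model <- function() {
  tx <- data.frame(
    transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
    chrom = c("chr1", "chr1"), start = c(20000L, 1000L),
    end = c(25000L, 2000L), strand = c("+", "-"),
    tss = c(20000L, 2000L), stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = c("t1", "t1", "t2"),
                   chrom = "chr1",
                   start = c(20000L, 23000L, 1000L),
                   end = c(21000L, 25000L, 2000L), stringsAsFactors = FALSE)
  isl <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                    stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1",
                      pos = c(50L, 150L, 5000L, 9000L, 22000L, 40000L),
                      stringsAsFactors = FALSE)
  genome_model(c(chr1 = 100000L), tx, ex, isl, sites)
}

test_that("feature derivation follows the strand-aware definitions", {
  mod <- make_tiny_model()
  fs <- derive_feature_sets(mod)
  # minus-strand transcript [1000, 2000) -> promoter [2000, 7000)
  prom <- fs$promoter
  df <- data.frame(start = GenomicRanges::start(prom) - 1,
                   end = GenomicRanges::end(prom))
  expect_true(any(df$start == 2000 & df$end == 7000))
  # plus-strand transcript [20000, 25000) -> promoter [15000, 20000)
  expect_true(any(df$start == 15000 & df$end == 20000))
  # island [100, 200) -> shores [0, 100) and [200, 5200)
  sh <- fs$island_shore
  shd <- data.frame(start = GenomicRanges::start(sh) - 1,
                    end = GenomicRanges::end(sh))
  expect_true(any(shd$start == 0 & shd$end == 100))
  expect_true(any(shd$start == 200 & shd$end == 5200))
  # intron = transcript minus exons
  intr <- fs$intron
  expect_equal(GenomicRanges::start(intr) - 1, 21000)
  expect_equal(GenomicRanges::end(intr), 23000)
  # partition-style invariants
  expect_equal(length(GenomicRanges::intersect(fs$intron, fs$exon)), 0L)
  expect_equal(length(GenomicRanges::intersect(fs$island_shore, fs$cpg_island)), 0L)
})

test_that("feature membership matches a naive per-interval scan", {
  cfg <- small_cfg(seed = 19, n_chroms = 2L, chrom_length = 3e6,
                   n_transcripts = 20L, n_islands = 15L, n_cpg = 500L)
  mod <- simulate_annotation(cfg)
  fs <- derive_feature_sets(mod)
  probes <- mod$cpg_sites
  # naive membership from first principles
  tx <- mod$transcripts
  in_iv <- function(pos, chrom, iv_chrom, iv_s, iv_e)
    vapply(seq_along(pos), function(i)
      any(iv_chrom == chrom[i] & pos[i] >= iv_s & pos[i] < iv_e), logical(1))
  prom_s <- ifelse(tx$strand == "+", pmax(0, tx$tss - 5000), tx$tss)
  prom_e <- ifelse(tx$strand == "+", tx$tss, tx$tss + 5000)
  naive <- list(
    transcript = in_iv(probes$pos, probes$chrom, tx$chrom, tx$start, tx$end),
    exon = in_iv(probes$pos, probes$chrom, mod$exons$chrom,
                 mod$exons$start, mod$exons$end),
    promoter = in_iv(probes$pos, probes$chrom, tx$chrom, prom_s, prom_e),
    cpg_island = in_iv(probes$pos, probes$chrom, mod$cpg_islands$chrom,
                       mod$cpg_islands$start, mod$cpg_islands$end))
  naive$intron <- naive$transcript & !naive$exon
  isl <- mod$cpg_islands
  near_isl <- in_iv(probes$pos, probes$chrom, isl$chrom,
                    pmax(0, isl$start - 5000), isl$end + 5000)
  naive$island_shore <- near_isl & !naive$cpg_island
  pad <- in_iv(probes$pos, probes$chrom, tx$chrom,
               pmax(0, tx$start - 50000), tx$end + 50000)
  naive$intergenic <- !pad
  gr <- GenomicRanges::GRanges(probes$chrom,
                               IRanges::IRanges(probes$pos + 1, width = 1))
  for (f in names(naive)) {
    got <- GenomicRanges::countOverlaps(gr, fs[[f]]) > 0
    expect_equal(got, naive[[f]], label = f)
  }
})

test_that("feature enrichment has exact closed forms and Fisher agreement", {
  # all DML inside a feature holding 10% of sites -> log2 ratio = log2(10)
  sites <- data.frame(chrom = "chr1", pos = seq(0, 999) * 100L)
  is_dml <- sites$pos < 5000                       # 50 DML, all in feature
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
  fs <- structure(list(ten_pct = feat), class = c("feature_sets", "list"))
  er <- feature_enrichment(sites, is_dml, fs)
  expect_equal(er$log2_ratio, log2(10))
  # Fisher p equals enumeration for small tables
  set.seed(55)
  for (i in 1:40) {
    a <- sample(0:6, 1); b <- sample(0:6, 1)
    c_ <- sample(0:6, 1); d <- sample(0:6, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    expect_equal(fisher.test(matrix(c(a, b, c_, d), 2))$p.value,
                 fisher_oracle(a, c_, b, d), tolerance = 1e-9)
  }
  # empty features are skipped with a flag
  fs2 <- structure(list(empty = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(200000, 200100))), class = c("feature_sets", "list"))
  expect_true(feature_enrichment(sites, is_dml, fs2)$skipped)
})

test_that("TSS window enrichment applies Holm over non-empty windows", {
  expect_equal(p.adjust(c(0.01, 0.04), method = "holm"), c(0.02, 0.04))
  # no DML anywhere: all p = 1
  d <- runif(500, -5000, 5000)
  out <- tss_window_enrichment(d, rep(FALSE, 500))
  expect_true(all(out$p == 1))
  # planted excess within 1 kb upstream dominates
  set.seed(66)
  d2 <- runif(5000, -5000, 5000)
  dml <- runif(5000) < ifelse(d2 >= -1000 & d2 < 0, 0.3, 0.05)
  out2 <- tss_window_enrichment(d2, dml)
  best <- out2[which.min(out2$p_holm), ]
  expect_true(best$win_start >= -1000 && best$win_end <= 500)
  expect_lt(best$p_holm, 0.001)
})

test_that("distance profiles reduce to per-distance means", {
  d <- c(-10, -10, 0, 5, 5, 5)
  s <- c(1, 3, 2, 4, 4, 4)
  pr <- distance_stat_profile(d, s, bandwidth = 2)
  expect_equal(pr$distance, c(-10, 0, 5))
  expect_equal(pr$mean_stat, c(2, 2, 4))
  # constant statistics smooth to the constant
  pr2 <- distance_stat_profile(seq(-100, 100, by = 10), rep(3, 21),
                               bandwidth = 50)
  expect_equal(pr2$smoothed, rep(3, 21))
})

test_that("nested window means match a brute-force site assignment", {
  mod <- make_tiny_model()
  # sites at -1000 and -100 of t1's TSS (20000, +) and +500 of it
  sites_pos <- c(19000L, 19900L, 20500L)
  m <- rbind(c(10, 0, 10, 0), c(5, 5, 5, 5), c(2, 8, 2, 8))
  t <- matrix(10, 3, 4)
  tbl <- meth_table(rep("chr1", 3), sites_pos, m, t,
                    paste0("s", 1:4), rep(c("control", "low1C"), each = 2))
  win <- nested_window_methylation(tbl, mod, extents = c(600, 2400))
  # the only CpG within 600 bp upstream sits at -100 with level 0.5
  expect_equal(unname(win$summary["s1", "-600"]), 0.5)
  # extent 2400 upstream holds sites at -1000 and -100: mean of levels
  expect_equal(unname(win$summary["s1", "-2400"]), mean(c(1.0, 0.5)))
  expect_equal(unname(win$summary["s2", "-2400"]), mean(c(0.0, 0.5)))
  # downstream window [0, 600) holds the +500 site
  expect_equal(unname(win$summary["s1", "+600"]), 0.2)
  # widening an extent only adds CpGs (superset property)
  expect_true(all(!is.na(win$summary[, "-2400"])))
})

test_that("PCA segregation matches the covariance eigen-oracle and exact MWU", {
  set.seed(44)
  # two groups with disjoint constant profiles -> complete separation
  x <- rbind(matrix(rnorm(6 * 30, mean = 0, sd = 0.01), 6),
             matrix(rnorm(6 * 30, mean = 1, sd = 0.01), 6))
  g <- rep(c("control", "low1C"), each = 6)
  res <- pca_group_segregation(x, g)
  expect_true(res$separated)
  expect_equal(res$mwu_p, 2 / choose(12, 6), tolerance = 1e-12)
  # PC1 variance equals the leading covariance eigenvalue
  y <- matrix(rnorm(8 * 20), 8)
  res2 <- pca_group_segregation(y, rep(c("a", "b"), each = 4))
  ev <- eigen(cov(y), symmetric = TRUE)$values
  expect_equal(var(res2$scores), ev[1], tolerance = 1e-10)
  # no random unit direction explains more variance than PC1
  for (i in 1:20) {
    u <- rnorm(20); u <- u / sqrt(sum(u^2))
    expect_lte(var(y %*% u), ev[1] + 1e-10)
  }
  expect_error(pca_group_segregation(matrix(1, 4, 3),
                                     rep(c("a", "b"), each = 2)), "constant")
})

test_that("nearest gene assignment agrees with an all-pairs oracle", {
  cfg <- small_cfg(seed = 29, n_transcripts = 30L, n_cpg = 200L)
  mod <- simulate_annotation(cfg)
  set.seed(71)
  regions <- data.frame(
    chrom = sample(names(mod$chrom_sizes), 40, replace = TRUE),
    start = sample.int(2e6 - 200, 40))
  regions$end <- regions$start + sample(1:200, 40, replace = TRUE)
  got <- nearest_gene_assignment(regions, mod, max_dist = 40000)
  tx <- mod$transcripts
  for (i in seq_len(nrow(regions))) {
    cand <- tx[tx$chrom == regions$chrom[i], ]
    d <- pmax(cand$start - regions$end[i], regions$start[i] - cand$end, 0)
    if (!nrow(cand) || min(d) > 40000) {
      expect_true(is.na(got$gene_id[i]))
    } else {
      best <- cand[d == min(d), ]
      pick <- best$gene_id[which.min(best$start)]
      expect_equal(got$gene_id[i], pick, label = paste("region", i))
      expect_equal(got$distance[i], min(d))
    }
  }
  # region inside a gene -> that gene at distance 0
  inside <- data.frame(chrom = tx$chrom[1], start = tx$start[1] + 10,
                       end = tx$start[1] + 20)
  r0 <- nearest_gene_assignment(inside, mod)
  expect_equal(r0$distance, 0)
})

test_that("promoter methylation vs expression association recovers rank signal", {
  set.seed(13)
  n <- 500
  meth <- runif(n)
  expr <- -0.5 * scale(meth)[, 1] + rnorm(n, sd = sqrt(1 - 0.25))
  names(meth) <- names(expr) <- sprintf("g%03d", 1:n)
  res <- promoter_meth_expr_association(meth, expr, n_perm = 499, seed = 2)
  expect_lt(abs(res$rho - (-0.5)), 0.15)
  expect_lt(res$p, 0.05)
  # rank-correlation oracle on small input
  res2 <- promoter_meth_expr_association(meth[1:20], expr[1:20],
                                         n_perm = 199, seed = 3)
  expect_equal(res2$rho, cor(rank(meth[1:20]), rank(expr[1:20])),
               tolerance = 1e-12)
  # constant methylation is degenerate
  cm <- setNames(rep(0.5, 10), names(meth)[1:10])
  res3 <- promoter_meth_expr_association(cm, expr[1:10])
  expect_true(res3$degenerate)
  expect_equal(res3$rho, 0)
  expect_error(promoter_meth_expr_association(cm[1:2], expr[1:2]), "3 matched")
})
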