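#' Per-gene two-group differential expression
#'
#' Welch two-sample t-test on `log2(abundance + 1)` per gene with
#' Benjamini-Hochberg FDR. This is deliberately a plain, declared plumbing
#' test: the permutation machinery around it, not the per-gene model, is
#' what calibrates the discoveries. The fold change is the ratio of group
#' mean abundances (treatment over control, pseudocount 1).
#'
#' @param table an [expr_table()].
#' @param labels optional label vector overriding the table's groups (used
#'   by the permutation engine); group level order is taken from the table.
#' @return Data frame: `gene_id`, `log2fc`, `stat`, `p`, `q`.
#' @export
de_test <- function(table, labels = NULL) {
  g <- if (is.null(labels)) table$samples$group else as.character(labels)
  lv <- unique(table$samples$group)
  i1 <- which(g == lv[1]); i2 <- which(g == lv[2])
  if (length(i1) < 2 || length(i2) < 2) stop("need >= 2 samples per group")
  x <- log2(table$abundance + 1)
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- rowSums((x[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2), 0)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(stat), df), 1)
  p[v1 == 0 & v2 == 0] <- 1          # no within-group variance to test against
  a1 <- rowMeans(table$abundance[, i1, drop = FALSE])
  a2 <- rowMeans(table$abundance[, i2, drop = FALSE])
  data.frame(gene_id = rownames(table$abundance),
             log2fc = log2((a2 + 1) / (a1 + 1)),
             stat = stat, p = p, q = bh_fdr(p),
             stringsAsFactors = FALSE)
}

#' Volcano-plot classification of differential expression results
#'
#' Four-way classification per gene: fold change strictly greater than
#' `fc_threshold` only, q-value strictly below `q_threshold` only, both, or
#' neither.
#'
#' @param de data frame from [de_test()] (needs `log2fc`, `q`).
#' @param fc_threshold linear fold-change cutoff (default 2; strict).
#' @param q_threshold FDR cutoff (default 0.05; strict).
#' @return Factor with levels `none`, `fc_only`, `q_only`, `both`.
#' @export
classify_volcano <- function(de, fc_threshold = 2, q_threshold = 0.05) {
  fc <- 2^abs(de$log2fc) > fc_threshold
  qq <- de$q < q_threshold
  cls <- ifelse(fc & qq, "both",
                ifelse(fc, "fc_only", ifelse(qq, "q_only", "none")))
  factor(cls, levels = c("none", "fc_only", "q_only", "both"))
}

#' K-means clustering of expression profiles
#'
#' Clusters genes by their log-transformed expression across samples and
#' returns, per cluster, the mean profile min-max scaled by row as
#' displayed in expression heat maps.
#'
#' @param abundance gene x sample matrix of nonnegative abundances.
#' @param k number of clusters (default 12).
#' @param seed integer seed (k-means initialisation).
#' @param nstart random restarts (default 25).
#' @return List with `cluster` (named assignment vector), `sizes`,
#'   `profiles` (k x samples matrix of row-scaled cluster means).
#' @export
kmeans_expression_clusters <- function(abundance, k = 12, seed = 1,
                                       nstart = 25) {
  if (nrow(abundance) < k) stop("k exceeds the number of genes")
  x <- log2(as.matrix(abundance) + 1)
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)
  prof <- t(apply(km$centers, 1, function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  }))
  colnames(prof) <- colnames(abundance)
  list(cluster = km$cluster, sizes = as.integer(km$size), profiles = prof)
}

#' Directional hypergeometric gene-set enrichment
#'
#' Upper-tail probability of observing `k` or more significant
#' down-regulated (or any other directional class of) genes among the `K`
#' genes of a set, given `M` such genes in a background of `N`.
#'
#' @param K genes in the set present in the background.
#' @param k directional-significant genes in the set.
#' @param N background size.
#' @param M directional-significant genes in the background.
#' @return Upper-tail hypergeometric probability `P(X >= k)`.
#' @export
directional_enrichment <- function(K, k, N, M) {
  if (k > K || K > N || M > N || k > M || any(c(K, k, N, M) < 0))
    stop("inconsistent counts: need k <= min(K, M) and K, M <= N")
  stats::phyper(k - 1, M, N - M, K, lower.tail = FALSE)
}

#' Expression-matched background gene sampling
#'
#' Samples non-target genes so that the background mirrors the targets'
#' distribution of expression levels: the expression range is cut into
#' quantile bins of the universe and, within each bin, as many non-targets
#' are drawn as there are targets.
#'
#' @param targets character vector of target gene ids.
#' @param abundance named numeric vector of per-gene (mean) expression over
#'   the universe; names define the universe.
#' @param n_bins number of quantile bins (default 10).
#' @param seed integer seed.
#' @return Character vector of background gene ids, `length(targets)` long,
#'   disjoint from `targets` (sampled with replacement, with a warning, in
#'   bins with too few non-targets).
#' @export
expression_matched_background <- function(targets, abundance, n_bins = 10,
                                          seed = 1) {
  universe <- names(abundance)
  if (!all(targets %in% universe)) stop("targets must be part of the universe")
  set.seed(seed)
  br <- unique(stats::quantile(abundance, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(abundance, breaks = br, include.lowest = TRUE)
  out <- character(0)
  for (b in levels(bin)) {
    tgt_b <- sum(targets %in% universe[bin == b])
    if (tgt_b == 0) next
    pool <- setdiff(universe[bin == b], targets)
    if (length(pool) >= tgt_b) {
      out <- c(out, sample(pool, tgt_b))
    } else {
      warning("bin ", b, " has too few non-targets; sampling with replacement")
      out <- c(out, sample(pool, tgt_b, replace = TRUE))
    }
  }
  out
}
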