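.gr_from_df <- function(df, chrom_sizes, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (is.null(strand)) "*" else strand,
    seqlengths = chrom_sizes)
}

.gr_from_sites <- function(sites, chrom_sizes = NULL) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    seqlengths = chrom_sizes)
}

#' Derive genomic feature interval sets from a genome model
#'
#' Builds the labelled interval collections used to locate differential
#' methylation: transcripts, exons, introns (transcript minus exon space),
#' strand-aware promoters (`promoter_bp` upstream of each TSS), CpG
#' islands, island shores (within `shore_bp` of an island but outside any
#' island) and intergenic space (further than `intergenic_bp` from any
#' transcript). Categories may overlap by design (a promoter CpG can sit in
#' an island); enrichment is tested per category.
#'
#' @param model a [genome_model()].
#' @param promoter_bp upstream promoter extent (default 5000).
#' @param shore_bp island shore flank (default 5000).
#' @param intergenic_bp distance from a gene beyond which space counts as
#'   intergenic (default 50000).
#' @return Named list of `GRanges` of class `feature_sets` with elements
#'   `transcript`, `exon`, `intron`, `promoter`, `cpg_island`,
#'   `island_shore`, `intergenic`.
#' @export
derive_feature_sets <- function(model, promoter_bp = 5000, shore_bp = 5000,
                                intergenic_bp = 50000) {
  cs <- model$chrom_sizes
  tx_gr <- .gr_from_df(model$transcripts, cs, strand = model$transcripts$strand)
  ex_gr <- .gr_from_df(model$exons, cs)
  isl_gr <- .gr_from_df(model$cpg_islands, cs)
  tx_u <- GenomicRanges::reduce(tx_gr, ignore.strand = TRUE)
  ex_u <- GenomicRanges::reduce(ex_gr, ignore.strand = TRUE)
  intron <- GenomicRanges::setdiff(tx_u, ex_u, ignore.strand = TRUE)
  # promoters/shores can project past chromosome ends; they are clamped
  # (GenomicRanges warns about the transient out-of-bound ranges)
  prom <- suppressWarnings(GenomicRanges::trim(
    GenomicRanges::promoters(tx_gr, upstream = promoter_bp, downstream = 0)))
  isl_u <- GenomicRanges::reduce(isl_gr)
  shore <- suppressWarnings(GenomicRanges::setdiff(
    GenomicRanges::trim(GenomicRanges::reduce(
      c(GenomicRanges::flank(isl_u, shore_bp, start = TRUE),
        GenomicRanges::flank(isl_u, shore_bp, start = FALSE)))),
    isl_u))
  genome_gr <- GenomicRanges::GRanges(
    seqnames = names(cs), ranges = IRanges::IRanges(1L, unname(cs)),
    seqlengths = cs)
  padded <- suppressWarnings(GenomicRanges::trim(GenomicRanges::reduce(
    tx_u + intergenic_bp, ignore.strand = TRUE)))
  intergenic <- GenomicRanges::setdiff(genome_gr, padded)
  structure(list(transcript = tx_u, exon = ex_u, intron = intron,
                 promoter = GenomicRanges::reduce(prom, ignore.strand = TRUE),
                 cpg_island = isl_u, island_shore = shore,
                 intergenic = intergenic),
            class = c("feature_sets", "list"))
}

#' DML enrichment by genomic feature
#'
#' For each feature category, compares the fraction of differentially
#' methylated loci inside the feature with the fraction of all measured
#' sites inside it: `log2((k / n_dml) / (K / n_sites))`, with a two-sided
#' Fisher exact p-value on the 2x2 table (DML vs non-DML, inside vs
#' outside). Features without measured sites are flagged and skipped.
#'
#' @param sites data frame of all measured sites (`chrom`, `pos`).
#' @param is_dml logical vector flagging the differentially methylated
#'   sites among `sites`.
#' @param features a `feature_sets` list from [derive_feature_sets()].
#' @return Data frame: `feature`, `n_dml_in`, `n_sites_in`, `log2_ratio`,
#'   `p`, `skipped`.
#' @export
feature_enrichment <- function(sites, is_dml, features) {
  stopifnot(length(is_dml) == nrow(sites))
  gr <- .gr_from_sites(sites)
  n_dml <- sum(is_dml); n_all <- nrow(sites)
  rows <- lapply(names(features), function(f) {
    inside <- GenomicRanges::countOverlaps(gr, features[[f]]) > 0
    K <- sum(inside)
    if (K == 0)
      return(data.frame(feature = f, n_dml_in = 0L, n_sites_in = 0L,
                        log2_ratio = NA_real_, p = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    k <- sum(inside & is_dml)
    lr <- if (k > 0) log2((k / n_dml) / (K / n_all)) else -Inf
    tab <- matrix(c(k, n_dml - k, K - k, n_all - n_dml - (K - k)), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    data.frame(feature = f, n_dml_in = k, n_sites_in = K, log2_ratio = lr,
               p = p, skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Signed distance from each CpG to its nearest TSS
#'
#' Strand-oriented: negative distances are upstream of the TSS. Ties
#' between equidistant TSSs resolve toward the smaller TSS coordinate.
#'
#' @param sites data frame `chrom`, `pos`.
#' @param model a [genome_model()] (uses its transcripts).
#' @return Numeric vector (NA where the chromosome holds no TSS).
#' @export
signed_tss_distance <- function(sites, model) {
  .signed_tss_distance(sites, model$transcripts)
}

#' DML enrichment in windows around TSSs
#'
#' Overlapping fixed-width windows are tiled on both sides of the TSS (by
#' signed distance); each window's DML count is tested against the global
#' DML rate with an upper-tail hypergeometric probability, and the window
#' p-values are adjusted with Holm's method over the non-empty windows.
#'
#' @param tss_dist signed distances of all measured sites to their nearest
#'   TSS ([signed_tss_distance()]).
#' @param is_dml logical DML flags, same length.
#' @param window_bp window width (default 1000).
#' @param span windows cover `[-span, span]` (default 5000).
#' @param step window start spacing; `window_bp / 2` gives the default
#'   half-overlapping tiling.
#' @return Data frame: `win_start`, `win_end` (signed offsets), `n_sites`,
#'   `n_dml`, `p`, `p_holm`, ordered by window start; empty windows are
#'   dropped.
#' @export
tss_window_enrichment <- function(tss_dist, is_dml, window_bp = 1000,
                                  span = 5000, step = window_bp / 2) {
  ok <- !is.na(tss_dist)
  tss_dist <- tss_dist[ok]; is_dml <- is_dml[ok]
  N <- length(tss_dist); M <- sum(is_dml)
  starts <- seq(-span, span - window_bp, by = step)
  rows <- lapply(starts, function(s0) {
    inw <- tss_dist >= s0 & tss_dist < s0 + window_bp
    K <- sum(inw)
    if (K == 0) return(NULL)
    k <- sum(inw & is_dml)
    p <- stats::phyper(k - 1, M, N - M, K, lower.tail = FALSE)
    data.frame(win_start = s0, win_end = s0 + window_bp, n_sites = K,
               n_dml = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Mean |statistic| as a function of distance to the TSS
#'
#' Per-distance means of absolute test statistics with a Gaussian-kernel
#' smoothed curve evaluated at the same distances.
#'
#' @param tss_dist signed distances (sites to nearest TSS).
#' @param stat per-site test statistics (finite; absolute value is taken).
#' @param bandwidth kernel bandwidth in bp (default 200).
#' @return Data frame `distance`, `mean_stat`, `smoothed`, sorted by
#'   distance.
#' @export
distance_stat_profile <- function(tss_dist, stat, bandwidth = 200) {
  ok <- !is.na(tss_dist) & is.finite(stat)
  d <- tss_dist[ok]; a <- abs(stat[ok])
  agg <- stats::aggregate(a, by = list(distance = d), FUN = mean)
  names(agg)[2] <- "mean_stat"
  agg <- agg[order(agg$distance), ]
  sm <- stats::ksmooth(agg$distance, agg$mean_stat, kernel = "normal",
                       bandwidth = bandwidth, x.points = agg$distance)
  agg$smoothed <- sm$y
  rownames(agg) <- NULL
  agg
}

#' Mean methylation in nested windows around TSSs
#'
#' For each sample and each nested extent `w` (upstream window `[-w, 0)`,
#' downstream window `[0, w)` in strand-oriented coordinates), computes the
#' unweighted mean of per-site methylation levels of the CpGs falling in
#' any TSS's window. A CpG near several TSSs contributes to each of their
#' windows. Returns both the per-TSS matrices (samples x TSS, for
#' window-wise PCA) and the sample x window summary matrix.
#'
#' @param table a (coverage-filtered) [meth_table()].
#' @param model a [genome_model()].
#' @param extents nested window extents in bp (default 600..4800 by 600).
#' @return Object of class `tss_window_matrix`: list with `summary`
#'   (samples x windows; window names like `"-2400"`, `"+600"`; `NA` where
#'   a window holds no covered CpG), `per_window` (named list of samples x
#'   TSS matrices) and `extents`.
#' @export
nested_window_methylation <- function(table, model,
                                      extents = seq(600, 4800, by = 600)) {
  tx <- model$transcripts
  sites <- table$sites
  wmax <- max(extents)
  # (site, TSS) pairs within the largest extent, with signed distance
  pair_site <- integer(0); pair_tss <- integer(0); pair_d <- numeric(0)
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    ti <- which(tx$chrom == ch)
    if (!length(ti) || !length(si)) next
    pos <- sites$pos[si]
    for (j in ti) {
      lo <- findInterval(tx$tss[j] - wmax - 0.5, pos) + 1L
      hi <- findInterval(tx$tss[j] + wmax + 0.5, pos)
      if (hi < lo) next
      k <- lo:hi
      d <- pos[k] - tx$tss[j]
      if (tx$strand[j] == "-") d <- -d
      pair_site <- c(pair_site, si[k])
      pair_tss <- c(pair_tss, rep.int(j, length(k)))
      pair_d <- c(pair_d, d)
    }
  }
  lev <- table$m / table$t               # NaN where t == 0
  lev[table$t == 0] <- NA
  nsamp <- nrow(table$samples)
  win_names <- c(paste0("-", rev(extents)), paste0("+", extents))
  summary_mat <- matrix(NA_real_, nrow = nsamp, ncol = length(win_names),
                        dimnames = list(table$samples$sample_id, win_names))
  per_window <- stats::setNames(vector("list", length(win_names)), win_names)
  for (w in extents) {
    for (side in c("-", "+")) {
      sel <- if (side == "-") pair_d >= -w & pair_d < 0
             else pair_d >= 0 & pair_d < w
      nm <- paste0(side, w)
      if (!any(sel)) next
      ps <- pair_site[sel]; pt <- pair_tss[sel]
      grp <- match(pt, sort(unique(pt)))
      L <- lev[ps, , drop = FALSE]
      sums <- rowsum(ifelse(is.na(L), 0, L), grp)
      cnts <- rowsum((!is.na(L)) * 1, grp)
      tssmean <- sums / cnts             # TSS x sample, NaN where no cover
      tssmean[cnts == 0] <- NA
      mat <- t(tssmean)                  # samples x TSS
      rownames(mat) <- table$samples$sample_id
      colnames(mat) <- tx$transcript_id[sort(unique(pt))]
      per_window[[nm]] <- mat
      summary_mat[, nm] <- rowMeans(mat, na.rm = TRUE)
    }
  }
  structure(list(summary = summary_mat, per_window = per_window,
                 extents = extents),
            class = "tss_window_matrix")
}

#' @export
print.tss_window_matrix <- function(x, ...) {
  cat("tss_window_matrix:", nrow(x$summary), "samples x",
      ncol(x$summary), "nested windows\n")
  invisible(x)
}

#' PCA-based group segregation test
#'
#' Centred, unscaled PCA of a samples x features matrix; the first
#' principal component's scores are compared between the two groups with a
#' Welch t-test and an exact two-sided Mann-Whitney U test, and complete
#' separation (disjoint group ranges on PC1) is flagged.
#'
#' @param x numeric matrix, samples in rows; columns containing missing
#'   values are dropped.
#' @param groups two-level label per sample (>= 2 samples per group).
#' @return List: `scores` (PC1 per sample), `var_explained`, `t_p`,
#'   `mwu_p`, `separated`.
#' @export
pca_group_segregation <- function(x, groups) {
  x <- as.matrix(x)
  keep <- colSums(is.na(x)) == 0
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) stop("no complete columns for PCA")
  if (all(apply(x, 2, stats::sd) == 0)) stop("constant matrix: PCA undefined")
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2 || min(table(groups)) < 2)
    stop("need two groups with >= 2 samples each")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  s1 <- pc$x[, 1]
  g1 <- s1[groups == lv[1]]; g2 <- s1[groups == lv[2]]
  t_p <- stats::t.test(g1, g2)$p.value
  mwu_p <- stats::wilcox.test(g1, g2, exact = TRUE)$p.value
  separated <- max(g1) < min(g2) || max(g2) < min(g1)
  list(scores = s1,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
       t_p = t_p, mwu_p = mwu_p, separated = separated)
}

#' Window-wise TSS methylation PCA with segregation tests
#'
#' Runs [pca_group_segregation()] on the per-TSS matrix of every nested
#' window (TSS columns with missing entries dropped per window).
#'
#' @param windows a `tss_window_matrix` from [nested_window_methylation()].
#' @param groups two-level label per sample.
#' @return Data frame: `window`, `n_tss`, `var_explained`, `t_p`, `mwu_p`,
#'   `separated`; the PC1 score vectors are attached as
#'   `attr(, "scores")`.
#' @export
tss_window_pca <- function(windows, groups) {
  rows <- list(); scores <- list()
  for (nm in names(windows$per_window)) {
    mat <- windows$per_window[[nm]]
    if (is.null(mat)) next
    res <- tryCatch(pca_group_segregation(mat, groups), error = function(e) NULL)
    if (is.null(res)) next
    rows[[nm]] <- data.frame(window = nm,
                             n_tss = sum(colSums(is.na(mat)) == 0),
                             var_explained = res$var_explained,
                             t_p = res$t_p, mwu_p = res$mwu_p,
                             separated = res$separated,
                             stringsAsFactors = FALSE)
    scores[[nm]] <- res$scores
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  out
}

#' Nearest-gene assignment for regions
#'
#' Assigns each region (e.g. a DMR or a DML) the closest gene within
#' `max_dist` bp, distance 0 when overlapping; equidistant ties resolve to
#' the gene with the smaller start coordinate.
#'
#' @param regions data frame `chrom`, `start`, `end` (0-based half-open).
#' @param model a [genome_model()] (its transcripts are the genes).
#' @param max_dist maximum assignment distance (default 40000).
#' @return Data frame: the regions plus `gene_id` (NA when nothing is close
#'   enough) and `distance`.
#' @export
nearest_gene_assignment <- function(regions, model, max_dist = 40000) {
  genes <- model$transcripts
  q <- .gr_from_df(regions, model$chrom_sizes)
  s <- .gr_from_df(genes, model$chrom_sizes)
  hits <- GenomicRanges::distanceToNearest(q, s, select = "all",
                                           ignore.strand = TRUE)
  gene_id <- rep(NA_character_, nrow(regions))
  distance <- rep(NA_real_, nrow(regions))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    dd <- S4Vectors::mcols(hits)$distance
    for (i in unique(qh)) {
      j <- which(qh == i)
      j <- j[order(dd[j], genes$start[sh[j]])]
      if (dd[j[1]] <= max_dist) {
        gene_id[i] <- genes$gene_id[sh[j[1]]]
        distance[i] <- dd[j[1]]
      }
    }
  }
  cbind(regions, data.frame(gene_id = gene_id, distance = distance,
                            stringsAsFactors = FALSE))
}

#' Association between promoter methylation and gene expression
#'
#' Spearman correlation across genes between mean promoter methylation and
#' mean log2 expression, with a permutation p-value.
#'
#' @param promoter_meth named numeric vector, mean promoter methylation per
#'   gene.
#' @param mean_expr named numeric vector, mean log2 expression per gene.
#' @param n_perm permutations for the p-value (default 999).
#' @param seed integer seed.
#' @return List: `rho`, `p`, `n_genes`, `degenerate` (TRUE with `rho = 0`
#'   and `p = NA` when either input is constant).
#' @export
promoter_meth_expr_association <- function(promoter_meth, mean_expr,
                                           n_perm = 999, seed = 1) {
  common <- intersect(names(promoter_meth), names(mean_expr))
  if (length(common) < 3) stop("need at least 3 matched genes")
  x <- promoter_meth[common]; y <- mean_expr[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = 0, p = NA_real_, n_genes = length(common),
                degenerate = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(seed)
  null <- replicate(n_perm, stats::cor(x, sample(y), method = "spearman"))
  p <- (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p = p, n_genes = length(common), degenerate = FALSE)
}
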