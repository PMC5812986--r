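#' Filter CpG sites by minimum coverage in every sample
#'
#' Retains sites whose total read count is at least `min_cov` in all
#' samples, preserving order. This is the site set used for the f-statistic
#' track and the methylation PCAs; the beta-binomial site test instead uses
#' every sample with nonzero coverage.
#'
#' @param table a [meth_table()].
#' @param min_cov minimum reads required in every sample (default 10).
#' @return A filtered [meth_table()] (possibly with zero sites, with a
#'   warning).
#' @export
filter_by_coverage <- function(table, min_cov = 10) {
  keep <- rowSums(table$t >= min_cov) == ncol(table$t)
  if (!any(keep)) warning("no sites pass the coverage filter")
  out <- table
  out$sites <- table$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$m <- table$m[keep, , drop = FALSE]
  out$t <- table$t[keep, , drop = FALSE]
  out
}

.F_CAP <- 1e8   # 1/epsilon cap for zero within-group variance

#' One-way ANOVA f-statistic for a single CpG
#'
#' Ratio of between-group to within-group mean squares of per-sample
#' methylation proportions. When the within-group variance is exactly zero
#' and the group means differ, the statistic is capped at `1/eps`; such
#' capped values are flagged and excluded from track means.
#'
#' @param beta_by_group list of numeric vectors of per-sample methylation
#'   proportions, one vector per group (each of length >= 2).
#' @param eps epsilon of the capping policy (default 1e-8).
#' @return Numeric f >= 0 with attribute `capped` (logical).
#' @export
site_fstat <- function(beta_by_group, eps = 1e-8) {
  x <- unlist(beta_by_group)
  if (any(x < 0 | x > 1)) stop("methylation proportions must lie in [0, 1]")
  if (any(lengths(beta_by_group) < 2)) stop("need >= 2 samples per group")
  g <- rep(seq_along(beta_by_group), lengths(beta_by_group))
  gm <- tapply(x, g, mean)
  n <- lengths(beta_by_group)
  grand <- mean(x)
  msb <- sum(n * (gm - grand)^2) / (length(n) - 1)
  msw <- sum((x - gm[g])^2) / (length(x) - length(n))
  if (msw <= 0) {
    if (msb <= 0) return(structure(0, capped = FALSE))
    return(structure(1 / eps, capped = TRUE))
  }
  f <- msb / msw
  structure(min(f, 1 / eps), capped = f > 1 / eps)
}

#' f-statistic track over coverage-filtered CpGs
#'
#' Applies the all-sample coverage filter, computes the two-group one-way
#' ANOVA f-statistic of methylation proportions at every retained CpG, and
#' records the genome-wide mean of the finite (uncapped) f values that the
#' running-sum DMR score normalises against.
#'
#' @param table a [meth_table()].
#' @param min_cov coverage filter passed to [filter_by_coverage()].
#' @param eps capping epsilon, see [site_fstat()].
#' @return Object of class `fstat_track`: list with `sites` (data frame
#'   `chrom`, `pos`, `f`, `capped`) and `mean_f` (mean of uncapped f).
#' @export
compute_fstat_track <- function(table, min_cov = 10, eps = 1e-8) {
  tbl <- filter_by_coverage(table, min_cov)
  if (nrow(tbl$sites) == 0)
    return(structure(list(sites = cbind(tbl$sites, f = numeric(0),
                                        capped = logical(0)),
                          mean_f = NA_real_, min_cov = min_cov),
                     class = "fstat_track"))
  p <- tbl$m / tbl$t
  g <- tbl$samples$group
  lv <- unique(g)
  i1 <- which(g == lv[1]); i2 <- which(g == lv[2])
  if (length(i1) < 2 || length(i2) < 2) stop("need >= 2 samples per group")
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2
  m1 <- rowMeans(p[, i1, drop = FALSE]); m2 <- rowMeans(p[, i2, drop = FALSE])
  grand <- (n1 * m1 + n2 * m2) / n
  msb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2   # df = 1 for two groups
  ssw <- rowSums((p[, i1, drop = FALSE] - m1)^2) +
    rowSums((p[, i2, drop = FALSE] - m2)^2)
  msw <- ssw / (n - 2)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  capped <- !is.finite(f) | f > 1 / eps
  f <- pmin(f, 1 / eps)
  mean_f <- mean(f[!capped])
  structure(list(sites = cbind(tbl$sites, f = f, capped = capped),
                 mean_f = mean_f, min_cov = min_cov),
            class = "fstat_track")
}

#' @export
print.fstat_track <- function(x, ...) {
  cat("fstat_track:", nrow(x$sites), "CpGs, mean f =",
      format(x$mean_f, digits = 4), "\n")
  invisible(x)
}

#' Shrink per-site dispersion estimates toward their genome-wide centre
#'
#' Linear shrinkage `w * phi_hat + (1 - w) * phi_bar` where the weight
#' `w = total_cov / (total_cov + prior_cov)` grows with the site's total
#' coverage and `phi_bar` is the trimmed mean of the finite raw estimates.
#' Negative moment estimates are clamped to zero; missing estimates get
#' `phi_bar`.
#'
#' @param phi_hat numeric vector of per-site method-of-moments dispersion
#'   estimates (may contain NA for inestimable sites).
#' @param total_cov per-site total read counts across all samples; when
#'   omitted, a constant weight of 0.5 is used.
#' @param prior_cov coverage at which the raw estimate and the centre get
#'   equal weight (default 1000 reads).
#' @param trim trimming fraction for the centre (default 0.1).
#' @return Numeric vector of shrunken dispersions, in `[0, 1)`.
#' @export
shrink_dispersion <- function(phi_hat, total_cov = NULL, prior_cov = 1000,
                              trim = 0.1) {
  ok <- is.finite(phi_hat)
  phi_bar <- if (any(ok)) max(0, mean(phi_hat[ok], trim = trim)) else 0
  ph <- pmax(phi_hat, 0)
  w <- if (is.null(total_cov)) rep(0.5, length(phi_hat))
       else total_cov / (total_cov + prior_cov)
  out <- w * ph + (1 - w) * phi_bar
  out[!ok] <- phi_bar
  pmin(pmax(out, 0), 1 - 1e-6)
}

#' Beta-binomial Wald test for per-CpG differential methylation
#'
#' For every CpG, group methylation proportions are estimated as pooled
#' counts (samples with zero depth are ignored) and compared with a Wald
#' statistic whose variance follows the beta-binomial law
#' `t * mu * (1 - mu) * (1 + (t - 1) * phi) / t^2`, summed over samples and
#' using the pooled two-group mean in `mu * (1 - mu)` so the statistic is
#' defined at every site. Dispersions are per-site moment estimates
#' shrunken with [shrink_dispersion()]. Two-sided normal p-values and
#' Benjamini-Hochberg q-values are returned; sites with zero total coverage
#' in either group are flagged `skipped` and excluded from the FDR.
#'
#' @param table a [meth_table()].
#' @param prior_cov,trim passed to [shrink_dispersion()].
#' @return Data frame with `chrom`, `pos`, `mu1`, `mu2` (control and
#'   treatment proportions, in the order of the group levels), `diff`
#'   (`mu2 - mu1`), `phi_shrunk`, `stat`, `p`, `q`, `skipped`.
#' @export
dml_test <- function(table, prior_cov = 1000, trim = 0.1) {
  g <- table$samples$group
  lv <- unique(g)
  i1 <- which(g == lv[1]); i2 <- which(g == lv[2])
  m <- table$m; t <- table$t
  T1 <- rowSums(t[, i1, drop = FALSE]); T2 <- rowSums(t[, i2, drop = FALSE])
  M1 <- rowSums(m[, i1, drop = FALSE]); M2 <- rowSums(m[, i2, drop = FALSE])
  skipped <- T1 == 0 | T2 == 0
  mu1 <- ifelse(T1 > 0, M1 / T1, NA_real_)
  mu2 <- ifelse(T2 > 0, M2 / T2, NA_real_)
  mu0 <- (M1 + M2) / pmax(T1 + T2, 1)

  # moment estimate of phi from the spread of per-sample proportions
  p <- m / t                       # NaN where t == 0
  pos_cov <- t > 0
  nz1 <- rowSums(pos_cov[, i1, drop = FALSE])
  nz2 <- rowSums(pos_cov[, i2, drop = FALSE])
  pm1 <- rowSums(p[, i1, drop = FALSE], na.rm = TRUE) / pmax(nz1, 1)
  pm2 <- rowSums(p[, i2, drop = FALSE], na.rm = TRUE) / pmax(nz2, 1)
  dev1 <- (p[, i1, drop = FALSE] - pm1)^2
  dev2 <- (p[, i2, drop = FALSE] - pm2)^2
  ss <- rowSums(dev1, na.rm = TRUE) + rowSums(dev2, na.rm = TRUE)
  df <- nz1 + nz2 - 2
  s2 <- ifelse(df >= 1, ss / pmax(df, 1), NA_real_)
  inv_t <- ifelse(pos_cov, 1 / t, 0)
  a_bar <- rowSums(inv_t) / pmax(nz1 + nz2, 1)
  denom <- mu0 * (1 - mu0)
  phi_hat <- ifelse(denom > 0 & !is.na(s2) & a_bar < 1,
                    (s2 / denom - a_bar) / (1 - a_bar), NA_real_)
  phi <- shrink_dispersion(phi_hat, total_cov = T1 + T2,
                           prior_cov = prior_cov, trim = trim)

  bb_var <- function(idx, Tg) {
    tg <- t[, idx, drop = FALSE]
    denom * (Tg + phi * rowSums(tg * (tg - 1))) / pmax(Tg, 1)^2
  }
  v <- bb_var(i1, T1) + bb_var(i2, T2)
  diffm <- mu2 - mu1
  stat <- ifelse(v > 0, diffm / sqrt(v), 0)
  stat[!is.na(diffm) & diffm == 0] <- 0
  pval <- 2 * stats::pnorm(-abs(stat))
  pval[skipped] <- NA_real_
  stat[skipped] <- NA_real_
  q <- rep(NA_real_, length(pval))
  q[!skipped] <- bh_fdr(pval[!skipped])
  data.frame(chrom = table$sites$chrom, pos = table$sites$pos,
             mu1 = mu1, mu2 = mu2, diff = diffm, phi_shrunk = phi,
             stat = stat, p = pval, q = q, skipped = skipped,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Step-up adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genome-wide methylation level histogram
#'
#' Pools counts across samples at each site and bins the resulting mean
#' methylation levels. Also reports the fraction of sites above a high
#' threshold and below a low threshold, the standard summary of the bimodal
#' vertebrate methylation landscape.
#'
#' @param table a (typically coverage-filtered) [meth_table()].
#' @param breaks bin boundaries on `[0, 1]`.
#' @param high,low thresholds for the high/low summary fractions
#'   (strict inequalities).
#' @return List with `levels` (per-site pooled level), `bin_fractions`
#'   (named, sums to 1), `fraction_high`, `fraction_low`.
#' @export
methylation_histogram <- function(table, breaks = seq(0, 1, by = 0.1),
                                  high = 0.8, low = 0.1) {
  Tt <- rowSums(table$t)
  lev <- rowSums(table$m)[Tt > 0] / Tt[Tt > 0]
  h <- hist(lev, breaks = breaks, plot = FALSE, include.lowest = TRUE,
            right = FALSE)
  fr <- h$counts / length(lev)
  names(fr) <- paste0("[", utils::head(breaks, -1), ",", breaks[-1], ")")
  list(levels = lev, bin_fractions = fr,
       fraction_high = mean(lev > high), fraction_low = mean(lev < low))
}
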