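# Small configurations and independent oracles shared across tests.

small_cfg <- function(seed = 1, ...) {
  cfg <- sim_config(n_chroms = 2L, chrom_length = 2e6, n_transcripts = 50L,
                    n_islands = 40L, n_cpg = 3000L, n_genes = 400L,
                    n_true_dml = 20L, n_true_deg = 40L, seed = seed)
  override <- list(...)
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  validate_sim_config(cfg)
  cfg
}

# hand-built methylation table
toy_meth <- function(m, t, pos = seq_len(nrow(m)) * 10L,
                     chrom = rep("chr1", nrow(m)),
                     groups = rep(c("control", "low1C"), each = ncol(m) / 2)) {
  meth_table(chrom, pos, m, t,
             sample_ids = paste0("s", seq_len(ncol(m))), groups = groups)
}

# hand-built f-statistic track (bypasses counts entirely)
toy_track <- function(chrom, pos, f, mean_f = mean(f[f < 1e8])) {
  structure(list(sites = data.frame(chrom = chrom, pos = as.integer(pos),
                                    f = f, capped = f >= 1e8,
                                    stringsAsFactors = FALSE),
                 mean_f = mean_f, min_cov = 10),
            class = "fstat_track")
}

# O(n^2) direct maximization oracle for the running-sum score: the score at
# CpG i is the best clipped window sum ending at i, where each term is the
# log-ratio minus the penalty times the gap to the previous CpG (no gap term
# at the chromosome's first CpG).
score_oracle <- function(chrom, pos, f, mean_f, penalty) {
  lr <- ifelse(f <= 0, -1e9, log2(f / mean_f))
  s <- numeric(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    d <- pos[idx]
    contrib <- lr[idx]
    contrib[-1] <- contrib[-1] - penalty * diff(d)
    for (i in seq_along(idx)) {
      best <- -Inf
      for (j in 1:i) best <- max(best, sum(contrib[j:i]))
      s[idx[i]] <- max(0, best)
    }
  }
  s
}

# independent region finder applied to a score vector
dmr_oracle <- function(chrom, pos, s) {
  out <- NULL
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos_c <- pos[idx]; s_c <- s[idx]
    r <- rle(s_c > 0)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- starts[k]:ends[k]
      pk <- run[which.max(s_c[run])]
      out <- rbind(out, data.frame(chrom = ch, start_pos = pos_c[starts[k]],
                                   peak_pos = pos_c[pk],
                                   score = max(s_c[run]),
                                   n_cpgs = pk - starts[k] + 1L,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

random_track <- function(n, seed, zero_frac = 0.1) {
  set.seed(seed)
  pos <- sort(sample.int(5000, n))
  f <- stats::rexp(n, rate = 0.5)
  f[stats::runif(n) < zero_frac] <- 0
  mean_f <- mean(f[f > 0 & f < 1e8])
  toy_track(rep("chr1", n), pos, f, mean_f)
}

# exhaustive hypergeometric upper tail from binomial coefficients
phyper_upper_oracle <- function(k, M, N, K) {
  xs <- k:min(K, M)
  sum(choose(M, xs) * choose(N - M, K - xs)) / choose(N, K)
}

# two-sided Fisher p by enumerating all tables with the observed margins
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  lo <- max(0, c1 - (N - r1)); hi <- min(r1, c1)
  pr <- vapply(lo:hi, function(x) dhyper(x, r1, N - r1, c1), numeric(1))
  p0 <- dhyper(a, r1, N - r1, c1)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

# step-up BH recursion written directly from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}
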