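.NEG_CLAMP <- -1e9   # log-ratio stand-in for f = 0 (forces a score reset)

#' Running-sum DMR score track
#'
#' Traverses each chromosome left to right and computes, at the i-th CpG,
#' `s_i = max(0, s_{i-1} + log2(f_i / mean_f) - penalty * (d_i - d_{i-1}))`,
#' where `d_i` is the genomic position. At the first CpG of every chromosome
#' the gap term is dropped (`d_{i-1}` is undefined), so
#' `s_1 = max(0, log2(f_1 / mean_f))`. Sites with `f = 0` contribute a
#' log-ratio clamped at a large negative value, which resets the score;
#' capped-infinite f values enter with their capped value.
#'
#' @param track an `fstat_track` from [compute_fstat_track()].
#' @param penalty per-bp separation penalty (default 0.02).
#' @return Object of class `score_track`: data frame `chrom`, `pos`, `f`,
#'   `lr` (log-ratio), `s` plus attributes `mean_f` and `penalty`.
#' @export
compute_score_track <- function(track, penalty = 0.02) {
  st <- track$sites
  if (nrow(st) == 0) stop("empty f-statistic track")
  if (!is.finite(track$mean_f) || track$mean_f <= 0)
    stop("mean_f must be positive")
  if (any(unlist(tapply(st$pos, st$chrom, function(x) diff(x) <= 0))))
    stop("positions must be strictly increasing within chromosomes")
  lr <- ifelse(st$f <= 0, .NEG_CLAMP, log2(st$f / track$mean_f))
  s <- numeric(nrow(st))
  for (ch in unique(st$chrom)) {
    idx <- which(st$chrom == ch)
    d <- st$pos[idx]
    si <- numeric(length(idx))
    si[1] <- max(0, lr[idx[1]])
    if (length(idx) > 1) {
      for (i in 2:length(idx)) {
        si[i] <- max(0, si[i - 1] + lr[idx[i]] - penalty * (d[i] - d[i - 1]))
      }
    }
    s[idx] <- si
  }
  out <- data.frame(chrom = st$chrom, pos = st$pos, f = st$f, lr = lr, s = s,
                    stringsAsFactors = FALSE)
  attr(out, "mean_f") <- track$mean_f
  attr(out, "penalty") <- penalty
  class(out) <- c("score_track", "data.frame")
  out
}

#' Call differentially methylated regions from a score track
#'
#' A region is emitted every time the running score returns to zero after
#' having been positive (with a flush at each chromosome end). The region
#' spans its first positive-score CpG through the CpG attaining the maximal
#' score; its score is that maximum. The last positive-score CpG of the run
#' (the decaying tail) is reported in `tail_pos` for inspection.
#'
#' @param score a `score_track` from [compute_score_track()].
#' @return Data frame with `chrom`, `start_pos`, `peak_pos`, `tail_pos`,
#'   `score`, `n_cpgs` (CpGs from start through peak inclusive).
#' @export
call_dmrs <- function(score) {
  res <- list()
  for (ch in unique(score$chrom)) {
    idx <- which(score$chrom == ch)
    s <- score$s[idx]; pos <- score$pos[idx]
    run_start <- NA_integer_; best <- -Inf; best_i <- NA_integer_
    flush <- function(last_pos_i) {
      res[[length(res) + 1L]] <<- data.frame(
        chrom = ch, start_pos = pos[run_start], peak_pos = pos[best_i],
        tail_pos = pos[last_pos_i], score = best,
        n_cpgs = best_i - run_start + 1L, stringsAsFactors = FALSE)
    }
    for (i in seq_along(s)) {
      if (s[i] > 0) {
        if (is.na(run_start)) { run_start <- i; best <- -Inf }
        if (s[i] > best) { best <- s[i]; best_i <- i }
      } else if (!is.na(run_start)) {
        flush(i - 1L)
        run_start <- NA_integer_
      }
    }
    if (!is.na(run_start)) flush(length(s))
  }
  if (!length(res))
    return(data.frame(chrom = character(0), start_pos = integer(0),
                      peak_pos = integer(0), tail_pos = integer(0),
                      score = numeric(0), n_cpgs = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full DMR pipeline from a methylation table
#'
#' Convenience wrapper: coverage filter, f-statistic track, running-sum
#' score and region calls.
#'
#' @param table a [meth_table()].
#' @param min_cov coverage filter.
#' @param penalty per-bp separation penalty.
#' @return List with `track`, `score` and `dmrs`.
#' @export
find_dmrs <- function(table, min_cov = 10, penalty = 0.02) {
  track <- compute_fstat_track(table, min_cov = min_cov)
  score <- compute_score_track(track, penalty = penalty)
  list(track = track, score = score, dmrs = call_dmrs(score))
}
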