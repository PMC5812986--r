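#' Per-CpG methylation count table
#'
#' Container for RRBS-style per-CpG counts: an ordered set of CpG sites and,
#' for every sample, the number of methylated reads and the total read depth
#' at each site. Samples carry a two-level group label (e.g. `control` vs
#' `low1C`).
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 0-based CpG positions, strictly increasing
#'   within each chromosome.
#' @param m numeric matrix of methylated read counts, sites in rows and
#'   samples in columns.
#' @param t numeric matrix of total read counts, same shape as `m`.
#' @param sample_ids character vector of sample names (column order of `m`).
#' @param groups character/factor vector assigning each sample to one of two
#'   groups.
#'
#' @return An object of class `meth_table` with elements `sites` (data frame
#'   with `chrom`, `pos`), `m`, `t` and `samples` (data frame with
#'   `sample_id`, `group`).
#' @export
meth_table <- function(chrom, pos, m, t, sample_ids, groups) {
  m <- as.matrix(m)
  t <- as.matrix(t)
  stopifnot(length(chrom) == length(pos),
            nrow(m) == length(pos), identical(dim(m), dim(t)),
            ncol(m) == length(sample_ids),
            length(groups) == length(sample_ids))
  if (any(m < 0) || any(t < 0) || any(m > t))
    stop("counts must satisfy 0 <= m <= t")
  groups <- as.character(groups)
  if (length(unique(groups)) != 2L)
    stop("exactly two sample groups are required")
  if (min(table(groups)) < 1L)
    stop("each group needs at least one sample")
  ord <- order(chrom, pos)
  if (!identical(ord, seq_along(pos))) {
    chrom <- chrom[ord]; pos <- pos[ord]
    m <- m[ord, , drop = FALSE]; t <- t[ord, , drop = FALSE]
  }
  if (any(unlist(tapply(pos, chrom, function(x) diff(x) <= 0))))
    stop("CpG positions must be strictly increasing within chromosomes")
  colnames(m) <- colnames(t) <- sample_ids
  structure(
    list(sites = data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                            stringsAsFactors = FALSE),
         m = m, t = t,
         samples = data.frame(sample_id = sample_ids, group = groups,
                              stringsAsFactors = FALSE)),
    class = "meth_table")
}

#' @export
print.meth_table <- function(x, ...) {
  cat("meth_table:", nrow(x$sites), "CpG sites x", nrow(x$samples), "samples\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                                 table(x$samples$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of CpG sites in a methylation table
#' @param table a `meth_table`.
#' @return integer site count.
#' @export
n_sites <- function(table) nrow(table$sites)

#' Gene-by-sample expression table
#'
#' FPKM-like nonnegative abundances for a two-group design.
#'
#' @param abundance numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param sample_ids character vector of sample names.
#' @param groups two-level group label per sample.
#' @return An object of class `expr_table` with `abundance` and `samples`.
#' @export
expr_table <- function(abundance, sample_ids = colnames(abundance), groups) {
  abundance <- as.matrix(abundance)
  stopifnot(!is.null(rownames(abundance)),
            ncol(abundance) == length(sample_ids),
            length(groups) == length(sample_ids))
  if (any(abundance < 0)) stop("abundances must be nonnegative")
  groups <- as.character(groups)
  if (length(unique(groups)) != 2L)
    stop("exactly two sample groups are required")
  if (min(table(groups)) < 2L)
    stop("each group needs at least two samples")
  colnames(abundance) <- sample_ids
  structure(list(abundance = abundance,
                 samples = data.frame(sample_id = sample_ids, group = groups,
                                      stringsAsFactors = FALSE)),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat("expr_table:", nrow(x$abundance), "genes x", nrow(x$samples), "samples\n")
  invisible(x)
}

#' Genome model
#'
#' Flat-file style genome annotation: chromosome sizes, transcripts with
#' exons and strand-aware TSSs, CpG islands and the ordered catalogue of CpG
#' sites. All coordinates are 0-based half-open.
#'
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param transcripts data frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`.
#' @param exons data frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`.
#' @param cpg_islands data frame with `chrom`, `start`, `end`.
#' @param cpg_sites data frame with `chrom`, `pos`, sorted and unique within
#'   chromosome.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chrom_sizes, transcripts, exons, cpg_islands, cpg_sites) {
  stopifnot(!is.null(names(chrom_sizes)))
  check_bounds <- function(df) {
    bad <- df$start < 0 | df$end > chrom_sizes[df$chrom] | df$start >= df$end
    if (any(bad)) stop("intervals outside chromosome bounds")
  }
  check_bounds(transcripts); check_bounds(exons); check_bounds(cpg_islands)
  # exons must lie within their transcript
  tx <- transcripts[match(exons$transcript_id, transcripts$transcript_id), ]
  if (any(exons$start < tx$start | exons$end > tx$end))
    stop("exons must lie within their transcript")
  with_tss <- ifelse(transcripts$strand == "+", transcripts$start, transcripts$end)
  if (any(with_tss != transcripts$tss))
    stop("TSS must equal transcript start (+) or end (-)")
  ord <- order(cpg_sites$chrom, cpg_sites$pos)
  cpg_sites <- cpg_sites[ord, , drop = FALSE]
  rownames(cpg_sites) <- NULL
  if (any(unlist(tapply(cpg_sites$pos, cpg_sites$chrom, function(x) diff(x) <= 0))))
    stop("CpG positions must be strictly increasing within chromosomes")
  structure(list(chrom_sizes = chrom_sizes, transcripts = transcripts,
                 exons = exons, cpg_islands = cpg_islands,
                 cpg_sites = cpg_sites),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_sizes), "chromosomes,",
      nrow(x$transcripts), "transcripts,", nrow(x$cpg_islands), "CpG islands,",
      nrow(x$cpg_sites), "CpG sites\n")
  invisible(x)
}
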