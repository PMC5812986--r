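#' Write a methylation table as bedGraph-like TSV
#'
#' Columns: `chrom`, `start` (0-based), `end`, then interleaved
#' `m_<sample>` / `t_<sample>` count pairs.
#'
#' @param table a [meth_table()].
#' @param path output file.
#' @export
write_methylation_tsv <- function(table, path) {
  out <- data.frame(chrom = table$sites$chrom, start = table$sites$pos,
                    end = table$sites$pos + 1L)
  for (i in seq_len(nrow(table$samples))) {
    out[[paste0("m_", table$samples$sample_id[i])]] <- table$m[, i]
    out[[paste0("t_", table$samples$sample_id[i])]] <- table$t[, i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation table written by [write_methylation_tsv()]
#'
#' @param path TSV path.
#' @param samples data frame `sample_id`, `group` (a sample sheet).
#' @return A [meth_table()].
#' @export
read_methylation_tsv <- function(path, samples) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[paste0("m_", samples$sample_id)])
  t <- as.matrix(df[paste0("t_", samples$sample_id)])
  meth_table(df$chrom, df$start, m, t, samples$sample_id, samples$group)
}

#' Write / read a sample sheet
#'
#' @param samples data frame `sample_id`, `group`.
#' @param path TSV path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read an expression table (gene x sample TSV)
#'
#' @param table an [expr_table()].
#' @param path TSV path.
#' @export
write_expression_tsv <- function(table, path) {
  df <- data.frame(gene_id = rownames(table$abundance), table$abundance,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param samples sample sheet data frame (`sample_id`, `group`).
#' @export
read_expression_tsv <- function(path, samples) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ab <- as.matrix(df[samples$sample_id])
  rownames(ab) <- df$gene_id
  expr_table(ab, samples$sample_id, samples$group)
}

#' Write genome annotation as BED files
#'
#' Emits `transcripts.bed` (BED6), `exons.bed` (BED6), `islands.bed` (BED3)
#' and `tss.bed` (single-bp BED6) into a directory.
#'
#' @param model a [genome_model()].
#' @param dir output directory (created if missing).
#' @export
write_annotation_bed <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tx <- model$transcripts
  wb <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  wb(data.frame(tx$chrom, tx$start, tx$end, tx$transcript_id, 0, tx$strand),
     "transcripts.bed")
  ex <- model$exons
  wb(data.frame(ex$chrom, ex$start, ex$end, ex$transcript_id, 0, "."),
     "exons.bed")
  isl <- model$cpg_islands
  wb(data.frame(isl$chrom, isl$start, isl$end), "islands.bed")
  wb(data.frame(tx$chrom, tx$tss, tx$tss + 1L, tx$transcript_id, 0, tx$strand),
     "tss.bed")
  invisible(dir)
}

#' Write called DMRs as BED6 plus a detailed TSV
#'
#' @param dmrs data frame from [call_dmrs()].
#' @param path BED output path; a `.tsv` with all columns is written next
#'   to it.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  lo <- pmin(dmrs$start_pos, dmrs$peak_pos)
  hi <- pmax(dmrs$start_pos, dmrs$peak_pos) + 1L
  bed <- data.frame(dmrs$chrom, lo, hi,
                    sprintf("dmr_%d", seq_len(nrow(dmrs))),
                    round(dmrs$score, 4), ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(dmrs, paste0(sub("\\.bed$", "", path), ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a permutation summary as JSON
#'
#' Records the observed count, per-assignment counts with composition
#' class, the null mean and the empirical FDR.
#'
#' @param summary a `permutation_summary`.
#' @param path JSON output path.
#' @param seed optional seed to log alongside the results.
#' @export
write_permutation_json <- function(summary, path, seed = NULL) {
  obj <- list(observed = summary$observed,
              threshold_kind = summary$threshold_kind,
              threshold = summary$threshold,
              mean_null = summary$mean_null,
              empirical_fdr = summary$empirical_fdr,
              counts = summary$counts)
  if (!is.null(seed)) obj$seed <- seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
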