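#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' structure of a two-group parental-diet liver study: a 6 vs 6 RRBS design
#' and a 4 vs 4 expression design, a strongly bimodal CpG methylation
#' landscape (about 80% of sites essentially fully methylated and about 6%
#' essentially unmethylated), a methylation dip with elevated read coverage
#' around TSSs and CpG islands, differential methylation planted near
#' promoters, and a predominantly down-regulated planted gene module
#' (68% of planted genes down in the treatment group).
#'
#' @param n_chroms,chrom_length number and length (bp) of chromosomes.
#' @param n_transcripts transcripts to place (one gene per transcript).
#' @param n_islands,island_tss_frac,island_width_range CpG islands: count,
#'   fraction centred on a randomly chosen TSS, and width range in bp.
#' @param n_cpg total CpG sites; `frac_cpg_in_islands` of them are placed
#'   inside islands (RRBS-like enrichment).
#' @param n_samples_per_group RRBS samples per group.
#' @param coverage_mean,coverage_size negative-binomial read-depth mean and
#'   size; the mean is multiplied by `island_coverage_boost` inside islands.
#' @param bimodal_mixture list with `fraction_high`, `fraction_low` and
#'   Beta shape pairs `shape_high`, `shape_low`, `shape_mid` for the latent
#'   methylation mixture. The default latent high weight (0.86) is set
#'   above the targeted realized share of highly methylated sites (~0.80)
#'   because the TSS dip subsequently demethylates the promoter-proximal
#'   part of the genome; with the default annotation this yields about 80%
#'   of sites above 0.8 and 6% below 0.1 methylation.
#' @param tss_dip_bp,tss_dip_factor latent methylation within `tss_dip_bp`
#'   of a TSS is multiplied by `tss_dip_factor` (TSS methylation dip).
#' @param n_true_dml,delta_beta planted differentially methylated CpGs and
#'   their group difference in methylation proportion.
#' @param dispersion beta-binomial dispersion (intra-sample correlation phi).
#' @param tss_shift_delta,tss_shift_range optional group-wide methylation
#'   shift (proportion) applied to CpGs whose strand-oriented distance to a
#'   TSS falls in `[-range[2], -range[1]]` (upstream); 0 disables it.
#' @param n_genes,n_expr_per_group,expr_meanlog,expr_sdlog,expr_cv expression
#'   generator: gene count, samples per group, log-normal baseline
#'   parameters, and per-sample coefficient of variation.
#' @param n_true_deg,deg_log2fc,fraction_deg_down planted differentially
#'   expressed genes, their absolute log2 fold change and the fraction that
#'   are down-regulated in the treatment group.
#' @param seed integer master seed; each generator stage draws from its own
#'   sub-stream derived from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 25e6, n_transcripts = 300L,
                       n_islands = 200L, island_tss_frac = 0.7,
                       island_width_range = c(300, 1500),
                       n_cpg = 20000L, frac_cpg_in_islands = 0.15,
                       n_samples_per_group = 6L,
                       coverage_mean = 30, coverage_size = 8,
                       island_coverage_boost = 3,
                       bimodal_mixture = list(fraction_high = 0.86,
                                              fraction_low = 0.06,
                                              shape_high = c(54, 6),
                                              shape_low = c(1, 40),
                                              shape_mid = c(2, 2)),
                       tss_dip_bp = 200, tss_dip_factor = 0.25,
                       n_true_dml = 100L, delta_beta = 0.3,
                       dispersion = 0.03,
                       tss_shift_delta = 0, tss_shift_range = c(1600, 4800),
                       n_genes = 2000L, n_expr_per_group = 4L,
                       expr_meanlog = 2, expr_sdlog = 1.5, expr_cv = 0.2,
                       n_true_deg = 100L, deg_log2fc = 2,
                       fraction_deg_down = 0.68,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$bimodal_mixture$fraction_high, cfg$bimodal_mixture$fraction_low,
          cfg$island_tss_frac, cfg$frac_cpg_in_islands, cfg$fraction_deg_down)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (sum(cfg$bimodal_mixture$fraction_high, cfg$bimodal_mixture$fraction_low) > 1)
    stop("mixture fractions must sum to at most 1")
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be positive")
  if (cfg$delta_beta < 0 || cfg$delta_beta > 0.96)
    stop("delta_beta must keep group means inside [0, 1]")
  if (cfg$dispersion < 0 || cfg$dispersion >= 1)
    stop("dispersion must lie in [0, 1)")
  if (cfg$n_samples_per_group < 1 || cfg$n_expr_per_group < 2)
    stop("too few samples per group")
  invisible(cfg)
}

# sub-stream seeds so stages are decoupled but governed by one master seed
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 7L + stage * 104729L) %% .Machine$integer.max
}

#' Simulate a genome annotation
#'
#' Places transcripts (with exons), CpG islands and CpG sites on a small
#' multi-chromosome genome. CpG density is elevated inside islands and a
#' configurable fraction of islands is centred on TSSs, which reproduces the
#' association between CpG islands, promoters and RRBS coverage.
#'
#' @param config a [sim_config()].
#' @return A [genome_model()].
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  if (config$n_chroms < 1L || config$n_transcripts < 1L)
    stop("need at least one chromosome and one transcript")
  set.seed(.stage_seed(config$seed, 1L))
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- stats::setNames(rep(as.integer(config$chrom_length),
                                     config$n_chroms), chroms)

  # transcripts: uniform placement, 2-20 kb, random strand
  tx_chrom <- sample(chroms, config$n_transcripts, replace = TRUE,
                     prob = chrom_sizes / sum(chrom_sizes))
  tx_len <- round(stats::runif(config$n_transcripts, 2000, 20000))
  tx_start <- vapply(seq_len(config$n_transcripts), function(i) {
    round(stats::runif(1, 10000, chrom_sizes[tx_chrom[i]] - tx_len[i] - 10000))
  }, numeric(1))
  tx_end <- tx_start + tx_len
  tx_strand <- sample(c("+", "-"), config$n_transcripts, replace = TRUE)
  transcripts <- data.frame(
    transcript_id = sprintf("tx_%04d", seq_len(config$n_transcripts)),
    gene_id = sprintf("gene_%04d", seq_len(config$n_transcripts)),
    chrom = tx_chrom, start = as.integer(tx_start), end = as.integer(tx_end),
    strand = tx_strand,
    tss = as.integer(ifelse(tx_strand == "+", tx_start, tx_end)),
    stringsAsFactors = FALSE)

  # exons: 1-5 per transcript, alternating exon/intron cut points,
  # first exon starts at the transcript start and last ends at its end
  exon_list <- lapply(seq_len(nrow(transcripts)), function(i) {
    k <- sample(1:5, 1)
    s <- transcripts$start[i]; e <- transcripts$end[i]
    if (k == 1L || e - s < 4 * k)
      return(data.frame(transcript_id = transcripts$transcript_id[i],
                        chrom = transcripts$chrom[i], start = s, end = e,
                        stringsAsFactors = FALSE))
    cuts <- sort(sample(seq(s + 1, e - 1), 2 * (k - 1)))
    starts <- c(s, cuts[seq(2, length(cuts), by = 2)])
    ends <- c(cuts[seq(1, length(cuts), by = 2)], e)
    data.frame(transcript_id = transcripts$transcript_id[i],
               chrom = transcripts$chrom[i],
               start = as.integer(starts), end = as.integer(ends),
               stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, exon_list)

  # CpG islands: a fraction centred on TSSs, the rest uniform
  widths <- round(stats::runif(config$n_islands, config$island_width_range[1],
                               config$island_width_range[2]))
  on_tss <- stats::runif(config$n_islands) < config$island_tss_frac
  centre <- numeric(config$n_islands)
  isl_chrom <- character(config$n_islands)
  for (i in seq_len(config$n_islands)) {
    if (on_tss[i]) {
      j <- sample.int(nrow(transcripts), 1)
      centre[i] <- transcripts$tss[j]; isl_chrom[i] <- transcripts$chrom[j]
    } else {
      isl_chrom[i] <- sample(chroms, 1, prob = chrom_sizes / sum(chrom_sizes))
      centre[i] <- round(stats::runif(1, widths[i], chrom_sizes[isl_chrom[i]] - widths[i]))
    }
  }
  cpg_islands <- data.frame(
    chrom = isl_chrom,
    start = as.integer(pmax(0, centre - widths %/% 2)),
    end = as.integer(pmin(chrom_sizes[isl_chrom], centre + widths %/% 2)),
    stringsAsFactors = FALSE)

  # CpG sites: background uniform + island-enriched
  n_isl_sites <- round(config$n_cpg * config$frac_cpg_in_islands)
  n_bg_sites <- config$n_cpg - n_isl_sites
  bg_chrom <- sample(chroms, n_bg_sites, replace = TRUE,
                     prob = chrom_sizes / sum(chrom_sizes))
  bg_pos <- floor(stats::runif(n_bg_sites, 0, chrom_sizes[bg_chrom]))
  isl_idx <- sample.int(nrow(cpg_islands), n_isl_sites, replace = TRUE,
                        prob = cpg_islands$end - cpg_islands$start)
  isl_pos <- floor(stats::runif(n_isl_sites, cpg_islands$start[isl_idx],
                                cpg_islands$end[isl_idx]))
  sites <- data.frame(chrom = c(bg_chrom, cpg_islands$chrom[isl_idx]),
                      pos = as.integer(c(bg_pos, isl_pos)),
                      stringsAsFactors = FALSE)
  sites <- unique(sites)
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL

  genome_model(chrom_sizes, transcripts, exons, cpg_islands, sites)
}

# strand-oriented signed distance from each site to its nearest TSS
# (negative = upstream of the TSS); internal, shared with genome_context
.signed_tss_distance <- function(sites, transcripts) {
  d <- rep(NA_real_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    ti <- which(transcripts$chrom == ch)
    if (!length(ti)) next
    ord <- order(transcripts$tss[ti], transcripts$start[ti])
    tp <- transcripts$tss[ti][ord]
    tstrand <- transcripts$strand[ti][ord]
    pos <- sites$pos[si]
    left <- findInterval(pos, tp)
    right <- pmin(left + 1L, length(tp))
    left <- pmax(left, 1L)
    dl <- abs(pos - tp[left]); dr <- abs(pos - tp[right])
    use_left <- dl <= dr        # tie-break toward the smaller TSS position
    k <- ifelse(use_left, left, right)
    signed <- pos - tp[k]
    signed[tstrand[k] == "-"] <- -signed[tstrand[k] == "-"]
    d[si] <- signed
  }
  d
}

.draw_latent_levels <- function(n, mix) {
  cls <- sample(c("high", "low", "mid"), n, replace = TRUE,
                prob = c(mix$fraction_high, mix$fraction_low,
                         1 - mix$fraction_high - mix$fraction_low))
  pi <- numeric(n)
  pi[cls == "high"] <- stats::rbeta(sum(cls == "high"),
                                    mix$shape_high[1], mix$shape_high[2])
  pi[cls == "low"] <- stats::rbeta(sum(cls == "low"),
                                   mix$shape_low[1], mix$shape_low[2])
  pi[cls == "mid"] <- stats::rbeta(sum(cls == "mid"),
                                   mix$shape_mid[1], mix$shape_mid[2])
  pi
}

#' Simulate an RRBS methylome with planted differential methylation
#'
#' Latent per-CpG methylation is drawn from a bimodal Beta mixture,
#' multiplicatively suppressed near TSSs, and observed through
#' beta-binomially dispersed counts with negative-binomial coverage boosted
#' inside CpG islands. Exactly `n_true_dml` CpGs located upstream of TSSs
#' (promoter-proximal) carry a group difference of `delta_beta`; half of the
#' planted sites gain and half lose methylation in the treatment group.
#' Optionally, a coherent group shift of `tss_shift_delta` is applied to all
#' CpGs in the configured upstream distance band (used to emulate a
#' promoter-wide methylation response).
#'
#' @param model a [genome_model()] from [simulate_annotation()].
#' @param config a [sim_config()].
#' @return A list with `table` (a [meth_table()], groups `control`/`low1C`),
#'   and `truth` (data frame of planted sites: `chrom`, `pos`, `direction`,
#'   `pi_control`, `pi_low1C`). The number of sites whose latent level had to
#'   be redrawn to accommodate `delta_beta` is recorded in
#'   `attr(truth, "n_resampled")`.
#' @export
simulate_methylome <- function(model, config) {
  validate_sim_config(config)
  set.seed(.stage_seed(config$seed, 2L))
  sites <- model$cpg_sites
  ns <- nrow(sites)
  npg <- config$n_samples_per_group
  sample_ids <- c(sprintf("ctrl_%d", seq_len(npg)),
                  sprintf("low1C_%d", seq_len(npg)))
  groups <- rep(c("control", "low1C"), each = npg)

  pi0 <- .draw_latent_levels(ns, config$bimodal_mixture)

  # TSS methylation dip
  tssd <- .signed_tss_distance(sites, model$transcripts)
  near <- !is.na(tssd) & abs(tssd) <= config$tss_dip_bp
  pi0[near] <- pi0[near] * config$tss_dip_factor

  pi_ctrl <- pi_trt <- pi0

  # optional coherent upstream shift in the treatment group
  if (config$tss_shift_delta != 0) {
    zone <- !is.na(tssd) & tssd <= -config$tss_shift_range[1] &
      tssd >= -config$tss_shift_range[2]
    pi_trt[zone] <- pmin(0.99, pmax(0.01, pi_trt[zone] + config$tss_shift_delta))
  }

  # planted DMLs near promoters (upstream of a TSS, within 5 kb)
  truth <- data.frame(chrom = character(0), pos = integer(0),
                      direction = integer(0), pi_control = numeric(0),
                      pi_low1C = numeric(0), stringsAsFactors = FALSE)
  n_resampled <- 0L
  if (config$n_true_dml > 0) {
    pool <- which(!is.na(tssd) & tssd < 0 & tssd >= -5000)
    if (length(pool) < config$n_true_dml)
      pool <- union(pool, sample(setdiff(seq_len(ns), pool),
                                 config$n_true_dml - length(pool)))
    dml_idx <- sample(pool, config$n_true_dml)
    dir <- rep(c(1L, -1L), length.out = config$n_true_dml)
    dir <- sample(dir)
    p1 <- pi_ctrl[dml_idx]
    bad <- (dir > 0 & p1 + config$delta_beta > 0.98) &
      (p1 - config$delta_beta < 0.02)
    # flip direction where only one side fits
    flip <- (dir > 0 & p1 + config$delta_beta > 0.98 & p1 - config$delta_beta >= 0.02)
    dir[flip] <- -1L
    flip2 <- (dir < 0 & p1 - config$delta_beta < 0.02 & p1 + config$delta_beta <= 0.98)
    dir[flip2] <- 1L
    # neither side fits: resample the latent level (logged)
    bad <- (dir > 0 & p1 + config$delta_beta > 0.98) |
      (dir < 0 & p1 - config$delta_beta < 0.02)
    n_resampled <- sum(bad)
    if (n_resampled > 0) {
      lo <- ifelse(dir[bad] > 0, 0.02, 0.02 + config$delta_beta)
      hi <- ifelse(dir[bad] > 0, 0.98 - config$delta_beta, 0.98)
      p1[bad] <- stats::runif(n_resampled, lo, hi)
      pi_ctrl[dml_idx[bad]] <- p1[bad]
    }
    pi_trt[dml_idx] <- p1 + dir * config$delta_beta
    truth <- data.frame(chrom = sites$chrom[dml_idx], pos = sites$pos[dml_idx],
                        direction = dir, pi_control = p1,
                        pi_low1C = pi_trt[dml_idx], stringsAsFactors = FALSE)
    truth <- truth[order(truth$chrom, truth$pos), ]
    rownames(truth) <- NULL
  }
  attr(truth, "n_resampled") <- n_resampled

  # coverage: negative binomial, boosted inside islands
  in_island <- .in_intervals(sites, model$cpg_islands)
  mu_cov <- config$coverage_mean * ifelse(in_island, config$island_coverage_boost, 1)
  nsamp <- 2L * npg
  t <- matrix(stats::rnbinom(ns * nsamp, size = config$coverage_size,
                             mu = rep(mu_cov, nsamp)), nrow = ns)

  # beta-binomial counts with intra-sample correlation phi
  phi <- config$dispersion
  pim <- cbind(matrix(rep(pi_ctrl, npg), ncol = npg),
               matrix(rep(pi_trt, npg), ncol = npg))
  if (phi > 0) {
    a <- pim * (1 - phi) / phi
    b <- (1 - pim) * (1 - phi) / phi
    p_rep <- matrix(stats::rbeta(ns * nsamp, a, b), nrow = ns)
    p_rep[pim == 0] <- 0; p_rep[pim == 1] <- 1
  } else p_rep <- pim
  m <- matrix(stats::rbinom(ns * nsamp, size = t, prob = p_rep), nrow = ns)

  tbl <- meth_table(sites$chrom, sites$pos, m, t, sample_ids, groups)
  list(table = tbl, truth = truth)
}

# logical: is each site inside any interval (0-based half-open)?
.in_intervals <- function(sites, intervals) {
  out <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (!nrow(iv)) next
    for (j in seq_len(nrow(iv)))
      out[si] <- out[si] | (sites$pos[si] >= iv$start[j] & sites$pos[si] < iv$end[j])
  }
  out
}

#' Simulate a gene expression matrix with planted DEGs
#'
#' Log-normal baseline abundances observed with multiplicative log-normal
#' noise; `n_true_deg` genes carry a signed log2 fold change in the
#' treatment group, with `fraction_deg_down` of them down-regulated.
#'
#' @param model a [genome_model()] (gene identifiers are reused from it when
#'   enough transcripts are available).
#' @param config a [sim_config()].
#' @return List with `table` (an [expr_table()], groups `control`/`low1C`)
#'   and `truth` (data frame `gene_id`, `log2fc` signed).
#' @export
simulate_expression <- function(model, config) {
  validate_sim_config(config)
  if (config$n_true_deg > config$n_genes)
    stop("n_true_deg exceeds the number of genes")
  set.seed(.stage_seed(config$seed, 3L))
  ng <- config$n_genes
  gene_ids <- if (nrow(model$transcripts) >= ng)
    model$transcripts$gene_id[seq_len(ng)]
  else sprintf("gene_%05d", seq_len(ng))
  npg <- config$n_expr_per_group
  sample_ids <- c(sprintf("ctrl_%d", seq_len(npg)),
                  sprintf("low1C_%d", seq_len(npg)))
  groups <- rep(c("control", "low1C"), each = npg)

  base <- stats::rlnorm(ng, meanlog = config$expr_meanlog,
                        sdlog = config$expr_sdlog)
  sd_log2 <- config$expr_cv / log(2)    # CV on natural scale -> log2 sd
  ab <- base * 2^matrix(stats::rnorm(ng * 2 * npg, sd = sd_log2), nrow = ng)

  truth <- data.frame(gene_id = character(0), log2fc = numeric(0),
                      stringsAsFactors = FALSE)
  if (config$n_true_deg > 0) {
    deg <- sample.int(ng, config$n_true_deg)
    down <- stats::runif(config$n_true_deg) < config$fraction_deg_down
    fc <- ifelse(down, -config$deg_log2fc, config$deg_log2fc)
    ab[deg, groups == "low1C"] <- ab[deg, groups == "low1C"] * 2^fc
    truth <- data.frame(gene_id = gene_ids[deg], log2fc = fc,
                        stringsAsFactors = FALSE)
  }
  rownames(ab) <- gene_ids
  list(table = expr_table(ab, sample_ids, groups), truth = truth)
}
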