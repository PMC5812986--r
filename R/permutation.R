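.composition_class <- function(labels, true_groups) {
  lv <- unique(true_groups)
  n1 <- sum(true_groups == lv[1])
  same_partition <- all(labels == true_groups) ||
    (sum(labels == lv[1]) == n1 &&
       all((labels == lv[1]) == (true_groups == lv[2])))
  if (same_partition) return("true")
  k <- sum(labels == lv[1] & true_groups == lv[1])
  paste0(max(k, n1 - k), "+", min(k, n1 - k))
}

.new_assignments <- function(labels_mat, true_groups, type) {
  comp <- apply(labels_mat, 1, .composition_class, true_groups = true_groups)
  is_true <- apply(labels_mat, 1, function(x) all(x == true_groups))
  structure(list(labels = labels_mat, composition = comp, is_true = is_true,
                 true_groups = true_groups, type = type),
            class = "label_assignments")
}

#' @export
print.label_assignments <- function(x, ...) {
  cat("label_assignments (", x$type, "): ", nrow(x$labels),
      " assignments over ", ncol(x$labels), " samples\n", sep = "")
  print(table(x$composition))
  invisible(x)
}

#' Enumerate all labelled two-group assignments
#'
#' Produces every distinct way of assigning the samples to the two group
#' labels while preserving the group sizes, in a deterministic order. Each
#' assignment carries a composition class: `"true"` when the induced
#' partition equals the true one (two labelled assignments for equal group
#' sizes), otherwise `"k+j"` giving how many samples of the majority true
#' group fall together.
#'
#' @param true_groups character vector of true group labels, one per sample
#'   (two levels).
#' @return A `label_assignments` object with elements `labels` (matrix of
#'   assignments x samples), `composition`, `is_true`.
#' @export
enumerate_group_assignments <- function(true_groups) {
  true_groups <- as.character(true_groups)
  lv <- unique(true_groups)
  if (length(lv) != 2) stop("exactly two groups required")
  n <- length(true_groups)
  n1 <- sum(true_groups == lv[1])
  sets <- utils::combn(n, n1)
  labels <- matrix(lv[2], nrow = ncol(sets), ncol = n)
  for (i in seq_len(ncol(sets))) labels[i, sets[, i]] <- lv[1]
  colnames(labels) <- names(true_groups)
  .new_assignments(labels, true_groups, "exhaustive")
}

#' Random group-label permutations
#'
#' Draws `n` label permutations with `sample()`, i.e. uniformly over the
#' labelled assignment space, sampling with replacement (repeats, and even
#' the true assignment, may occur; see [permutation_discovery_counts()] for
#' how the true assignment is handled downstream).
#'
#' @param true_groups character vector of true labels, one per sample.
#' @param n number of permutations (default 100).
#' @param seed integer seed.
#' @return A `label_assignments` object.
#' @export
random_assignments <- function(true_groups, n = 100, seed = 1) {
  true_groups <- as.character(true_groups)
  if (length(unique(true_groups)) != 2) stop("exactly two groups required")
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  labels <- t(vapply(seq_len(n), function(i) sample(true_groups),
                     character(length(true_groups))))
  colnames(labels) <- names(true_groups)
  .new_assignments(labels, true_groups, "random")
}

#' Discovery counts under group-label permutation
#'
#' Re-runs an injected per-feature testing procedure under every label
#' assignment and counts the features passing a p- or q-value threshold.
#' The same engine serves the expression and the methylation tests: the
#' procedure receives the data object and a label vector and must return
#' per-feature p-values.
#'
#' @param data opaque data object handed to `test_fun`.
#' @param test_fun `function(data, labels) -> numeric p-values` (NAs are
#'   dropped from counting and from the q-value computation).
#' @param assignments a `label_assignments` object; the observed count is
#'   always computed under the true labels.
#' @param threshold_kind count features with `p` or BH `q` below
#'   `threshold`.
#' @param threshold significance cutoff (default 0.05).
#' @param include_true_in_null whether assignments flagged `is_true` (or in
#'   composition class `"true"`) contribute to the null summary. Defaults to
#'   `TRUE` for random permutation sets (a drawn permutation is a draw) and
#'   `FALSE` for exhaustive enumerations.
#' @return Object of class `permutation_summary`: list with `observed`,
#'   `counts` (data frame: composition, is_true, count), `mean_null`,
#'   `empirical_fdr`, `threshold_kind`, `threshold`.
#' @export
permutation_discovery_counts <- function(data, test_fun, assignments,
                                         threshold_kind = c("q", "p"),
                                         threshold = 0.05,
                                         include_true_in_null = NULL) {
  threshold_kind <- match.arg(threshold_kind)
  if (is.null(include_true_in_null))
    include_true_in_null <- identical(assignments$type, "random")
  count_one <- function(labels) {
    p <- test_fun(data, labels)
    if (!is.numeric(p)) stop("test_fun must return numeric p-values")
    p <- p[!is.na(p)]
    x <- if (threshold_kind == "q") bh_fdr(p) else p
    sum(x < threshold)
  }
  observed <- count_one(assignments$true_groups)
  counts <- vapply(seq_len(nrow(assignments$labels)), function(i) {
    tryCatch(count_one(assignments$labels[i, ]),
             error = function(e) stop("test failed under permutation ", i,
                                      ": ", conditionMessage(e)))
  }, numeric(1))
  null_mask <- if (include_true_in_null) rep(TRUE, length(counts))
               else assignments$composition != "true"
  null_counts <- counts[null_mask]
  structure(list(observed = observed,
                 counts = data.frame(composition = assignments$composition,
                                     is_true = assignments$is_true,
                                     count = counts,
                                     stringsAsFactors = FALSE),
                 mean_null = mean(null_counts),
                 empirical_fdr = empirical_fdr(observed, null_counts),
                 threshold_kind = threshold_kind, threshold = threshold),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat("permutation_summary: observed =", x$observed,
      "(", x$threshold_kind, "<", x$threshold, ")\n")
  cat("  mean null =", format(x$mean_null, digits = 4),
      " empirical FDR =", format(x$empirical_fdr, digits = 4), "\n")
  invisible(x)
}

#' Empirical (permutation) false discovery rate
#'
#' Ratio of the mean discovery count over relabelled null datasets to the
#' observed discovery count under the true labels.
#'
#' @param observed observed discovery count (>= 0).
#' @param null_counts vector of discovery counts under null relabellings.
#' @return `mean(null_counts) / observed`; `NA` when `observed` is 0 (the
#'   ratio is undefined).
#' @export
empirical_fdr <- function(observed, null_counts) {
  if (length(null_counts) == 0) stop("null_counts must be non-empty")
  if (observed < 0) stop("observed must be >= 0")
  if (observed == 0) return(NA_real_)
  mean(null_counts) / observed
}
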