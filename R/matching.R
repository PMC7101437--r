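#' Genes usable for cross-panel correlation
#'
#' Keeps genes whose mean TPM strictly exceeds `min_mean_tpm` in the GB
#' panel AND in the noGB panel; lowly-expressed genes carry mostly
#' sampling noise and dilute the rank correlation.
#'
#' @param tpm_GB,tpm_noGB Genes x samples TPM matrices sharing a gene
#'   universe (same row names, any order).
#' @param min_mean_tpm Strict lower bound on the panel mean TPM,
#'   default 0.5.
#' @return Character vector of retained gene ids.
#' @export
correlation_gene_filter <- function(tpm_GB, tpm_noGB, min_mean_tpm = 0.5) {
  if (!setequal(rownames(tpm_GB), rownames(tpm_noGB))) {
    stop("GB and noGB matrices must share the same gene universe")
  }
  tpm_noGB <- tpm_noGB[rownames(tpm_GB), , drop = FALSE]
  keep <- rowMeans(tpm_GB) > min_mean_tpm &
    rowMeans(tpm_noGB) > min_mean_tpm
  genes <- rownames(tpm_GB)[keep]
  if (!length(genes)) {
    stop("no gene passes the mean-TPM filter in both panels; ",
         "consider lowering min_mean_tpm below ", min_mean_tpm)
  }
  genes
}

#' Cross-panel Spearman correlation matrix
#'
#' Spearman rank correlation (average ranks for ties) of raw counts on
#' a filtered gene set, computed for every noGB sample (rows) against
#' every GB sample (columns). Spearman is preferred over Pearson for
#' its insensitivity to the strong outliers typical of expression
#' counts.
#'
#' @param counts_noGB,counts_GB Genes x samples count matrices.
#' @param genes Gene ids to correlate on (>= 3 required), e.g. from
#'   [correlation_gene_filter()].
#' @return A list of class `correlation_result` with `raw` (the
#'   correlation matrix), `column_means` and `scaled` (filled by
#'   [scale_correlation_matrix()]), `row_labels`, `column_labels`,
#'   `gene_set`.
#' @export
spearman_matrix <- function(counts_noGB, counts_GB, genes) {
  genes <- as.character(genes)
  if (length(genes) < 3) stop("need at least 3 genes for rank correlation")
  miss <- setdiff(genes, intersect(rownames(counts_noGB), rownames(counts_GB)))
  if (length(miss)) {
    stop("genes absent from a panel: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  x <- counts_noGB[genes, , drop = FALSE]
  y <- counts_GB[genes, , drop = FALSE]
  const_x <- apply(x, 2, function(v) length(unique(v)) == 1)
  const_y <- apply(y, 2, function(v) length(unique(v)) == 1)
  if (any(const_x) || any(const_y)) {
    stop("constant count vector(s), correlation undefined: ",
         paste(c(colnames(x)[const_x], colnames(y)[const_y]), collapse = ", "))
  }
  raw <- cor(x, y, method = "spearman")
  structure(
    list(raw = raw, column_means = NULL, scaled = NULL,
         row_labels = colnames(x), column_labels = colnames(y),
         gene_set = genes),
    class = "correlation_result"
  )
}

#' Scale a raw correlation matrix into matching scores
#'
#' The scaled score corrects for columns (GB samples) that correlate
#' globally more or less strongly than others: each raw value is first
#' divided by the mean of its column, then each row is divided by its
#' own maximum, so exactly one entry per row (noGB sample) equals one —
#' the row's best-matching GB sample.
#'
#' @param raw Raw correlation matrix (rows noGB, columns GB), or a
#'   `correlation_result` from [spearman_matrix()].
#' @return A matrix of scaled scores (row maxima exactly 1), or the
#'   input `correlation_result` with `scaled` and `column_means`
#'   filled.
#' @examples
#' scale_correlation_matrix(rbind(c(0.90, 0.80), c(0.70, 0.95)))
#' @export
scale_correlation_matrix <- function(raw) {
  if (inherits(raw, "correlation_result")) {
    raw$column_means <- colMeans(raw$raw)
    raw$scaled <- scale_correlation_matrix(raw$raw)
    return(raw)
  }
  raw <- as.matrix(raw)
  if (!all(is.finite(raw))) stop("raw correlation matrix must be finite")
  col_means <- colMeans(raw)
  if (any(col_means <= 0)) {
    stop("non-positive column mean(s); score undefined for ",
         "anti-correlated panels")
  }
  a <- sweep(raw, 2, col_means, "/")
  row_max <- apply(a, 1, max)
  a / row_max
}

#' Assign each noGB sample to its best-scoring GB sample
#'
#' Each row (noGB sample) of the scaled matrix is assigned to the
#' column at which its score equals the row maximum (one by
#' construction). Assignments need not be one-to-one: two rows may pick
#' the same column, which is exactly how mismatches surface. Ties break
#' deterministically to the lowest column index with a warning.
#'
#' @param scaled Scaled score matrix from [scale_correlation_matrix()]
#'   (or a `correlation_result` with `scaled` filled).
#' @param truth Optional ground-truth pairing (`gb_sample`,
#'   `nogb_sample` columns) to score against.
#' @return A `match_report` list: `assignments` data.frame
#'   (`nogb_sample`, `gb_assigned`, plus `gb_true` and `correct` when
#'   truth is given), `excluded_outliers`, `rounds`, `n_pairs`,
#'   `n_correct`, `accuracy` (over `n_pairs`), and
#'   `accuracy_post_exclusion`.
#' @export
assign_pairs <- function(scaled, truth = NULL) {
  if (inherits(scaled, "correlation_result")) {
    if (is.null(scaled$scaled)) scaled <- scale_correlation_matrix(scaled)
    scaled <- scaled$scaled
  }
  scaled <- as.matrix(scaled)
  assigned <- vapply(seq_len(nrow(scaled)), function(i) {
    row <- scaled[i, ]
    hits <- which(row == max(row))
    if (length(hits) > 1) {
      warning("tied maximal scores for row '", rownames(scaled)[i],
              "'; assigning lowest column index")
    }
    hits[1L]
  }, integer(1))
  assignments <- data.frame(
    nogb_sample = rownames(scaled),
    gb_assigned = colnames(scaled)[assigned],
    stringsAsFactors = FALSE
  )
  report <- list(
    assignments = assignments,
    excluded_outliers = list(),
    rounds = 1L,
    n_pairs = nrow(scaled),
    n_correct = NA_integer_,
    accuracy = NA_real_,
    accuracy_post_exclusion = NA_real_
  )
  class(report) <- "match_report"
  if (!is.null(truth)) report <- score_match_report(report, truth)
  report
}

#' @keywords internal
#' @noRd
score_match_report <- function(report, truth, n_pairs_original = NULL) {
  truth <- as.data.frame(truth)
  idx <- match(report$assignments$nogb_sample, truth$nogb_sample)
  report$assignments$gb_true <- truth$gb_sample[idx]
  report$assignments$correct <-
    report$assignments$gb_assigned == report$assignments$gb_true
  report$n_correct <- sum(report$assignments$correct, na.rm = TRUE)
  if (is.null(n_pairs_original)) n_pairs_original <- nrow(truth)
  report$n_pairs <- n_pairs_original
  report$accuracy <- report$n_correct / n_pairs_original
  report$accuracy_post_exclusion <-
    report$n_correct / nrow(report$assignments)
  report
}

#' @export
print.match_report <- function(x, ...) {
  cat("match_report:", nrow(x$assignments), "assignments over",
      x$n_pairs, "pairs,", x$rounds, "round(s)\n")
  if (!is.na(x$accuracy)) {
    cat(sprintf("  accuracy %.3f (%d/%d); post-exclusion %.3f\n",
                x$accuracy, x$n_correct, x$n_pairs,
                x$accuracy_post_exclusion))
  }
  n_excl <- length(unlist(x$excluded_outliers))
  if (n_excl) cat("  excluded outliers:",
                  paste(unlist(x$excluded_outliers), collapse = ", "), "\n")
  invisible(x)
}

#' Flag samples that correlate far less with the opposite panel
#'
#' For each sample, its mean raw correlation against all samples of the
#' opposite panel is computed; within each panel, samples whose robust
#' z-score (median/MAD) falls below `z_threshold` are flagged. A zero
#' MAD falls back to the mean/sd z-score with a warning.
#'
#' @param raw Raw correlation matrix (rows noGB, columns GB) or a
#'   `correlation_result`.
#' @param z_threshold Robust z-score cutoff, default -2.5.
#' @return Character vector of flagged sample ids (from either panel).
#' @export
detect_outliers <- function(raw, z_threshold = -2.5) {
  if (inherits(raw, "correlation_result")) raw <- raw$raw
  raw <- as.matrix(raw)
  if (nrow(raw) < 3 || ncol(raw) < 3) {
    stop("outlier detection needs at least 3 samples per panel")
  }
  robust_z <- function(x) {
    s <- mad(x)
    if (s == 0) {
      if (sd(x) == 0) return(rep(0, length(x)))
      warning("zero MAD; falling back to mean/sd z-score")
      return((x - mean(x)) / sd(x))
    }
    (x - median(x)) / s
  }
  row_means <- rowMeans(raw)
  col_means <- colMeans(raw)
  flagged <- c(
    names(row_means)[robust_z(row_means) < z_threshold],
    names(col_means)[robust_z(col_means) < z_threshold]
  )
  flagged
}

#' Match GB to noGB samples with outlier exclusion and re-matching
#'
#' The full matching procedure: compute TPM, keep genes passing the
#' cross-panel mean-TPM filter, build the raw Spearman matrix on raw
#' counts of those genes, flag outlier samples, exclude the flagged
#' samples together with their true partners (whole pairs are
#' excluded), recompute the raw and scaled matrices on the survivors,
#' and assign each remaining noGB sample to its best-scoring GB sample.
#' With `max_rounds = 1` no exclusion is applied (detection is still
#' reported). Headline accuracy counts excluded pairs as failures, i.e.
#' uses the original pair count as denominator; the post-exclusion rate
#' is reported alongside.
#'
#' @param counts_noGB,counts_GB Genes x samples count matrices of the
#'   two panels.
#' @param genes A [gene_table()] covering both panels.
#' @param truth Ground-truth pairing (`gb_sample`, `nogb_sample`).
#' @param max_rounds Maximum matching rounds; round `k < max_rounds`
#'   may exclude outlier pairs, the final round assigns. Default 2.
#' @param min_mean_tpm Gene filter threshold, see
#'   [correlation_gene_filter()].
#' @param outlier_z Outlier cutoff, see [detect_outliers()].
#' @param use_tpm Correlate TPM instead of raw counts (sensitivity
#'   analysis); default `FALSE`, raw counts.
#' @return A `match_report` (see [assign_pairs()]) with per-round
#'   `excluded_outliers` and `rounds` filled in.
#' @export
iterative_matching <- function(counts_noGB, counts_GB, genes, truth,
                               max_rounds = 2L, min_mean_tpm = 0.5,
                               outlier_z = -2.5, use_tpm = FALSE) {
  counts_noGB <- validate_count_matrix(counts_noGB)
  counts_GB <- validate_count_matrix(counts_GB)
  if (max_rounds < 1L) stop("max_rounds must be >= 1")
  tpm_noGB <- compute_tpm(counts_noGB, genes)
  tpm_GB <- compute_tpm(counts_GB, genes)
  gene_set <- correlation_gene_filter(tpm_GB, tpm_noGB, min_mean_tpm)
  mat_noGB <- if (use_tpm) tpm_noGB else counts_noGB
  mat_GB <- if (use_tpm) tpm_GB else counts_GB

  truth <- as.data.frame(truth)
  n_pairs_original <- nrow(truth)
  excluded <- list()

  for (round in seq_len(max_rounds)) {
    cr <- spearman_matrix(mat_noGB, mat_GB, gene_set)
    can_detect <- nrow(cr$raw) >= 3 && ncol(cr$raw) >= 3
    flagged <- if (can_detect) detect_outliers(cr$raw, outlier_z) else character(0)
    last_round <- round == max_rounds || !length(flagged)
    if (last_round) {
      cr <- scale_correlation_matrix(cr)
      report <- assign_pairs(cr$scaled)
      report$excluded_outliers <- excluded
      if (round == max_rounds && length(flagged) && max_rounds > 1L) {
        # outliers surfaced on the final round stay in, but are reported
        report$excluded_outliers[[paste0("round", round, "_detected_only")]] <-
          flagged
      }
      if (max_rounds == 1L && length(flagged)) {
        report$excluded_outliers[["round1_detected_only"]] <- flagged
      }
      report$rounds <- round
      report <- score_match_report(report, truth, n_pairs_original)
      return(report)
    }
    # drop flagged samples and their true partners: whole pairs go
    bad_pairs <- truth$gb_sample %in% flagged | truth$nogb_sample %in% flagged
    drop_ids <- c(truth$gb_sample[bad_pairs], truth$nogb_sample[bad_pairs])
    excluded[[paste0("round", round)]] <- flagged
    mat_noGB <- mat_noGB[, !(colnames(mat_noGB) %in% drop_ids), drop = FALSE]
    mat_GB <- mat_GB[, !(colnames(mat_GB) %in% drop_ids), drop = FALSE]
    truth_remaining <- truth[!bad_pairs, , drop = FALSE]
    if (!nrow(truth_remaining) || !ncol(mat_noGB) || !ncol(mat_GB)) {
      stop("all samples excluded as outliers; nothing left to match")
    }
    truth <- truth_remaining
  }
}
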