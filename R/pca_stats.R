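#' Genes eligible for PCA
#'
#' Keeps genes whose TPM has mean >= `min_tpm` AND median >= `min_tpm`
#' across the selected samples (inclusive thresholds).
#'
#' @param tpm Genes x samples TPM matrix.
#' @param min_tpm Inclusive threshold on both mean and median, default 1.
#' @return Character vector of retained gene ids.
#' @export
pca_gene_filter <- function(tpm, min_tpm = 1.0) {
  if (ncol(tpm) < 1) stop("need at least one sample")
  keep <- rowMeans(tpm) >= min_tpm &
    apply(tpm, 1, median) >= min_tpm
  genes <- rownames(tpm)[keep]
  if (!length(genes)) stop("no gene passes the mean/median TPM filter")
  genes
}

#' PCA on scaled TPM
#'
#' Principal component analysis of samples on z-scored TPM: each gene
#' is centered and scaled to unit variance across samples before
#' decomposition, so highly expressed genes do not dominate. Globin
#' genes are excluded beforehand by default, since their blocked vs
#' unblocked abundance difference is the known, uninteresting signal.
#'
#' @param tpm Genes x samples TPM matrix.
#' @param genes Gene ids to use; defaults to [pca_gene_filter()] on
#'   `tpm`.
#' @param gene_table Optional [gene_table()] supplying globin flags.
#' @param exclude_globin Drop globin-flagged genes first? Default
#'   `TRUE` (requires `gene_table`).
#' @return A list of class `pca_result`: `scores` (samples x PCs),
#'   `variance_explained` (proportion per PC, non-increasing),
#'   `loadings` (genes x PCs, unit-norm columns), `genes_used`.
#' @export
run_pca <- function(tpm, genes = NULL, gene_table = NULL,
                    exclude_globin = TRUE) {
  if (ncol(tpm) < 2) stop("PCA needs at least 2 samples")
  if (is.null(genes)) genes <- pca_gene_filter(tpm)
  genes <- as.character(genes)
  if (exclude_globin && !is.null(gene_table)) {
    genes <- setdiff(genes, gene_table$gene_id[gene_table$is_globin])
  }
  if (length(genes) < 2) stop("PCA needs at least 2 genes after filtering")
  x <- t(tpm[genes, , drop = FALSE])
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s) before PCA")
    x <- x[, v > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 genes with non-zero variance")
  }
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  structure(
    list(
      scores = fit$x,
      variance_explained = fit$sdev^2 / sum(fit$sdev^2),
      loadings = fit$rotation,
      genes_used = colnames(x)
    ),
    class = "pca_result"
  )
}

#' Top genes by absolute loading on one principal component
#'
#' Ranks genes by the absolute value of their loading on the chosen
#' component, descending; ties break deterministically by gene id.
#'
#' @param result A `pca_result` from [run_pca()].
#' @param pc Component index.
#' @param k Number of genes to return, default 100. When `k` exceeds
#'   the available genes, all are returned with a warning.
#' @return Character vector of gene ids, best first.
#' @export
top_loading_genes <- function(result, pc = 1L, k = 100L) {
  stopifnot(inherits(result, "pca_result"))
  if (pc < 1 || pc > ncol(result$loadings)) {
    stop("pc out of range (1..", ncol(result$loadings), ")")
  }
  ids <- rownames(result$loadings)
  if (k > length(ids)) {
    warning("k exceeds available genes; returning all ", length(ids))
    k <- length(ids)
  }
  if (k == 0) return(character(0))
  load <- abs(result$loadings[, pc])
  ids[order(-load, ids)][seq_len(k)]
}

#' Upper-tail hypergeometric probability of shared terms
#'
#' Probability of observing at least `n_shared` shared terms between a
#' query list of `n_query_terms` terms and a background hit list of
#' `n_background_hits` terms, both drawn from a universe of
#' `n_universe` queryable terms. Exact summation of the hypergeometric
#' probability mass in log space.
#'
#' @param n_universe Total queryable terms.
#' @param n_background_hits Terms hit by the background list.
#' @param n_query_terms Terms hit by the query list (the draw size).
#' @param n_shared Observed shared terms.
#' @return `P(X >= n_shared)`.
#' @examples
#' shared_term_hypergeom(6784, 345, 34, 14)
#' @export
shared_term_hypergeom <- function(n_universe, n_background_hits,
                                  n_query_terms, n_shared) {
  counts <- c(n_universe, n_background_hits, n_query_terms, n_shared)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("all arguments must be non-negative integers")
  }
  if (n_background_hits > n_universe || n_query_terms > n_universe) {
    stop("hit and query counts cannot exceed the universe")
  }
  if (n_shared > min(n_background_hits, n_query_terms)) {
    stop("n_shared cannot exceed min(n_background_hits, n_query_terms)")
  }
  k_min <- max(0, n_background_hits + n_query_terms - n_universe)
  if (n_shared <= k_min) return(1)
  ks <- n_shared:min(n_background_hits, n_query_terms)
  logp <- lchoose(n_background_hits, ks) +
    lchoose(n_universe - n_background_hits, n_query_terms - ks) -
    lchoose(n_universe, n_query_terms)
  m <- max(logp)
  exp(m) * sum(exp(logp - m))
}
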