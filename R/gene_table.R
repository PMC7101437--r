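#' Build a per-gene annotation table
#'
#' A gene table carries the per-gene information needed for TPM
#' normalization and globin accounting: a unique identifier, an
#' effective length in bases, and a globin flag. For 3'-tag protocols
#' (e.g. QuantSeq) where one fragment is produced per transcript,
#' length normalization is conceptually unnecessary; setting all
#' lengths to 1 makes TPM coincide with counts-per-million.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param length Positive integer vector of gene lengths in bases
#'   (recycled if length 1). Default 1.
#' @param is_globin Logical vector flagging globin genes. Defaults to
#'   membership in [default_globin_genes].
#' @return A `data.frame` of class `gene_table` with columns
#'   `gene_id`, `length`, `is_globin`.
#' @examples
#' gene_table(c("HBB", "HBA2", "GAPDH"), length = c(1606, 835, 1310))
#' @export
gene_table <- function(gene_id, length = 1L,
                       is_globin = gene_id %in% default_globin_genes) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicated gene ids: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  length <- rep_len(as.numeric(length), length.out = base::length(gene_id))
  if (any(!is.finite(length)) || any(length < 1)) {
    stop("gene lengths must be finite and >= 1")
  }
  is_globin <- rep_len(as.logical(is_globin), length.out = base::length(gene_id))
  if (anyNA(is_globin)) stop("is_globin must not contain NA")
  structure(
    data.frame(gene_id = gene_id, length = length, is_globin = is_globin,
               stringsAsFactors = FALSE),
    class = c("gene_table", "data.frame")
  )
}

#' @keywords internal
#' @noRd
validate_gene_table <- function(genes) {
  if (!is.data.frame(genes) ||
      !all(c("gene_id", "length", "is_globin") %in% names(genes))) {
    stop("`genes` must be a gene_table (gene_id, length, is_globin)")
  }
  genes
}

#' Validate a genes-by-samples count matrix
#'
#' Checks that `counts` is a non-negative, integer-valued numeric matrix
#' with gene row names and sample column names.
#'
#' @param counts Matrix-like object, genes in rows, samples in columns.
#' @return The validated matrix (invisibly coerced to `matrix`).
#' @keywords internal
#' @noRd
validate_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids in count matrix")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids in count matrix")
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric and free of NA")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integer-valued")
  counts
}
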