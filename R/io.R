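#' Read a genes-by-samples count matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Values must be non-negative integers; duplicated gene ids are
#' rejected.
#'
#' @param path Path to a tab-separated file.
#' @return Integer-valued genes x samples matrix.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count matrix needs a gene column and >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated gene id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop("non-numeric counts in column(s): ",
         paste(names(df)[-1][bad], collapse = ", "))
  }
  rownames(m) <- ids
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer or negative count at gene '", ids[bad[1, 1]],
         "', sample '", colnames(m)[bad[1, 2]], "'")
  }
  storage.mode(m) <- "integer"
  validate_count_matrix(m)
}

#' Write a count matrix as TSV
#'
#' @param counts Genes x samples matrix.
#' @param path Output path; first column `gene_id`, one column per
#'   sample.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write tabular package objects
#'
#' TSV readers/writers for the gene table, sample sheet and
#' ground-truth pairing. Sample sheets must carry `sample_id`,
#' `isolate_id`, `protocol` (one of `GB`, `noGB`), `run`, `machine`,
#' `lane`; pairings carry `gb_sample`, `nogb_sample` and optionally
#' `isolate_id`.
#'
#' @param path File path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  gene_table(df$gene_id, length = df$length, is_globin = df$is_globin)
}

#' @rdname table_io
#' @param genes A [gene_table()].
#' @export
write_gene_table <- function(genes, path) {
  write.table(as.data.frame(genes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "isolate_id", "protocol", "run", "machine", "lane")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$protocol %in% c("GB", "noGB"))) {
    stop("protocol must be 'GB' or 'noGB'")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids")
  df
}

#' @rdname table_io
#' @param sheet Sample sheet `data.frame`.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_pairing <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gb_sample", "nogb_sample"), names(df))
  if (length(miss)) stop("pairing missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gb_sample) || anyDuplicated(df$nogb_sample)) {
    stop("pairing must be a bijection between GB and noGB samples")
  }
  df
}

#' @rdname table_io
#' @param pairing Pairing `data.frame`.
#' @export
write_pairing <- function(pairing, path) {
  write.table(pairing, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
#' @noRd
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

#' Write a configuration object as YAML or JSON
#'
#' Format follows the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param config A `simulation_config` or `pipeline_config` (any
#'   list-like configuration).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  plain <- strip_classes(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(plain, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported config extension (use .yaml, .yml or .json)")
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension (use .yaml, .yml or .json)")
  }
}
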