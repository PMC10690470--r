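#' Construct a count dataset
#'
#' Bundles a gene-by-sample integer count matrix with its per-sample
#' annotation table. Columns of `counts` and rows of `samples` are joined
#' on sample id and reordered to match; the join is independent of input
#' order.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data frame with a `sample` column plus annotations
#'   (treatment, time_h, genotype, replicate as applicable).
#' @return object of class `count_dataset` with elements `counts` and
#'   `samples`.
#' @export
count_dataset <- function(counts, samples) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts)))
    stop2("'counts' must be a matrix with gene rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop2("'counts' must contain non-negative integers")
  if (anyDuplicated(rownames(counts))) stop2("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stop2("duplicate sample ids in counts")
  validate_sample_table(samples, "sample")
  missing_in_counts <- setdiff(samples$sample, colnames(counts))
  if (length(missing_in_counts))
    stop2("metadata sample(s) missing from counts: ",
          paste(missing_in_counts, collapse = ", "))
  missing_in_meta <- setdiff(colnames(counts), samples$sample)
  if (length(missing_in_meta))
    stop2("count column(s) missing from metadata: ",
          paste(missing_in_meta, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("annotations:", paste(setdiff(names(x$samples), "sample"),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header line; the first column holds gene ids, the remaining
#' columns one sample each, integer counts.
#'
#' @param path file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop2("count table needs a gene id column plus samples")
  gene <- df[[1L]]
  if (anyDuplicated(gene)) stop2("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(m != round(m)) || any(m < 0))
    stop2("counts in ", path, " must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- gene
  m
}

#' Read a sample metadata table from TSV
#'
#' @param path file path to a tab-delimited table with header; must contain
#'   a `sample` column.
#' @return data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample" %in% names(df))
    stop2("metadata ", path, " lacks a 'sample' column")
  if (anyDuplicated(df$sample)) stop2("duplicate sample ids in ", path)
  df
}

#' Read counts and metadata and join them into a count dataset
#'
#' @param counts_path,metadata_path TSV paths (see [read_counts()],
#'   [read_metadata()]).
#' @return a `count_dataset`.
#' @export
read_count_dataset <- function(counts_path, metadata_path) {
  count_dataset(read_counts(counts_path), read_metadata(metadata_path))
}

#' Write a count dataset as counts + metadata TSV
#'
#' @param dataset a `count_dataset`.
#' @param counts_path,metadata_path output file paths.
#' @return invisibly, the dataset.
#' @export
write_count_dataset <- function(dataset, counts_path, metadata_path) {
  stopifnot(inherits(dataset, "count_dataset"))
  df <- data.frame(gene = rownames(dataset$counts), dataset$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$samples, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Read a gene-set collection in GMT format
#'
#' One term per line: term id, description, then one member gene per
#' tab-separated field. Lines with fewer than three fields are malformed;
#' empty terms are rejected.
#'
#' @param path GMT file path.
#' @return object of class `gene_set_collection`: a named list of unique
#'   member character vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop2("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop2("malformed GMT line(s) (fewer than 3 fields): ",
          paste(bad, collapse = ", "))
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop2("duplicate term ids in ", path)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- which(lengths(sets) == 0L)
  if (length(empty))
    stop2("empty term(s) in GMT: ", paste(ids[empty], collapse = ", "))
  gene_set_collection(stats::setNames(sets, ids),
                      stats::setNames(desc, ids))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of member gene ids.
#' @param descriptions optional named character vector of term
#'   descriptions.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop2("'sets' must be a named list of member vectors")
  if (any(lengths(sets) == 0L)) stop2("empty gene sets are not allowed")
  sets <- lapply(sets, unique)
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions[names(sets)],
            class = c("gene_set_collection", "list"))
}

#' Write a GMT file
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(id) {
    paste(c(id, desc[[id]], collection[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(collection)
}
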