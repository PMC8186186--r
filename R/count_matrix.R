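#' Construct a count matrix object
#'
#' The central data container of the package: a cells x genes matrix of raw
#' (unnormalized) transcript counts together with gene and cell identifiers
#' and, optionally, a per-cell batch label. All downstream stages (likelihood
#' evaluation, autoencoder training, the integration pipeline) operate on this
#' orientation; readers normalize on-disk orientation to it.
#'
#' @param values numeric matrix, cells in rows, genes in columns. Entries must
#'   be non-negative and integral (raw counts; the count likelihoods are not
#'   valid on normalized data).
#' @param gene_ids character vector of unique gene identifiers, one per column.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param batch_labels optional vector of per-cell batch/sample labels
#'   (coerced to character), length equal to the number of cells.
#' @return an object of class `count_matrix` with fields `values`, `gene_ids`,
#'   `cell_ids`, `batch_labels`.
#' @export
count_matrix <- function(values, gene_ids, cell_ids, batch_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("count values must be finite")
  if (any(values < 0)) stop("count values must be non-negative")
  if (any(abs(values - round(values)) > 1e-8)) {
    stop("count values must be integral raw counts; normalized input is not supported")
  }
  values <- round(values)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(values)) {
    stop(sprintf("gene_ids length (%d) does not match number of genes (%d)",
                 length(gene_ids), ncol(values)))
  }
  if (length(cell_ids) != nrow(values)) {
    stop(sprintf("cell_ids length (%d) does not match number of cells (%d)",
                 length(cell_ids), nrow(values)))
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (!is.null(batch_labels)) {
    batch_labels <- as.character(batch_labels)
    if (length(batch_labels) != nrow(values)) {
      stop("batch_labels must have exactly one label per cell")
    }
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 batch_labels = batch_labels),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$batch_labels)) {
    tb <- table(x$batch_labels)
    cat(sprintf("batches: %s\n",
                paste(sprintf("%s (%d)", names(tb), tb), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Construct a latent matrix object
#'
#' Holds the low-dimensional embedding produced by [encode()]: one row per
#' cell, `L` latent dimensions, with cell identifiers aligned to the source
#' count matrix.
#'
#' @param values numeric matrix, cells x latent dimensions; finite entries.
#' @param cell_ids character vector of unique cell identifiers.
#' @return an object of class `latent_matrix`.
#' @export
latent_matrix <- function(values, cell_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L || ncol(values) == 0L) stop("latent matrix must be non-empty")
  if (any(!is.finite(values))) stop("latent values must be finite")
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(values)) stop("one cell id per latent row required")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  rownames(values) <- cell_ids
  colnames(values) <- paste0("z", seq_len(ncol(values)) - 1L)
  structure(list(values = values, cell_ids = cell_ids), class = "latent_matrix")
}

#' @export
print.latent_matrix <- function(x, ...) {
  cat(sprintf("latent_matrix: %d cells x %d dimensions\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Load a count matrix from disk
#'
#' Reads a raw count matrix from one of the standard single-cell exchange
#' formats and returns it in cells x genes orientation.
#'
#' For `format = "mtx_dir"`, `path` is a directory holding a Matrix Market
#' triplet file (`matrix.mtx`) plus `genes.tsv` (or `features.tsv`) and
#' `barcodes.tsv`, as written by 10x-style tools; the matrix on disk is genes
#' x cells and is transposed on read. For `csv`/`tsv`, the file must carry a
#' header row and row names; by default rows are cells, set
#' `genes_as_rows = TRUE` if rows are genes.
#'
#' @param path file (csv/tsv) or directory (mtx_dir).
#' @param format one of `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @param genes_as_rows for csv/tsv: `TRUE` when the on-disk orientation is
#'   genes x cells.
#' @return a [count_matrix()].
#' @export
load_counts <- function(path, format = c("mtx_dir", "csv", "tsv"),
                        genes_as_rows = FALSE) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stop("mtx_dir path does not exist: ", path)
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("missing matrix.mtx in ", path)
    genes_f <- file.path(path, "genes.tsv")
    if (!file.exists(genes_f)) genes_f <- file.path(path, "features.tsv")
    if (!file.exists(genes_f)) stop("missing genes.tsv/features.tsv in ", path)
    barcodes_f <- file.path(path, "barcodes.tsv")
    if (!file.exists(barcodes_f)) stop("missing barcodes.tsv in ", path)
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- utils::read.delim(genes_f, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    barcodes <- utils::read.delim(barcodes_f, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m)) {
      stop(sprintf("gene file has %d ids but matrix has %d rows",
                   length(genes), nrow(m)))
    }
    if (length(barcodes) != ncol(m)) {
      stop(sprintf("barcode file has %d ids but matrix has %d columns",
                   length(barcodes), ncol(m)))
    }
    # on-disk convention is genes x cells
    return(count_matrix(t(m), gene_ids = genes, cell_ids = barcodes))
  }
  if (!file.exists(path)) stop("file does not exist: ", path)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (genes_as_rows) {
    count_matrix(t(m), gene_ids = rownames(m), cell_ids = colnames(m))
  } else {
    count_matrix(m, gene_ids = colnames(m), cell_ids = rownames(m))
  }
}

#' Write a count matrix as a Matrix Market triplet directory
#'
#' Writes `matrix.mtx` (genes x cells, the on-disk convention), `genes.tsv`,
#' `barcodes.tsv`, and, when batch labels are present, `batches.tsv`.
#'
#' @param counts a [count_matrix()].
#' @param path directory to create/write into.
#' @export
save_counts_mtx <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(counts$values), sparse = TRUE),
                  file.path(path, "matrix.mtx"))
  writeLines(counts$gene_ids, file.path(path, "genes.tsv"))
  writeLines(counts$cell_ids, file.path(path, "barcodes.tsv"))
  if (!is.null(counts$batch_labels)) {
    writeLines(counts$batch_labels, file.path(path, "batches.tsv"))
  }
  invisible(path)
}

#' Merge per-sample count matrices into one multi-batch matrix
#'
#' Stacks cells from several samples and restricts genes to the intersection
#' of the samples' gene sets (genes not measured in every sample are dropped
#' rather than zero-imputed). `batch_labels` of the result records the sample
#' of origin; cell ids that collide across samples are disambiguated by
#' suffixing `-<sample_name>`.
#'
#' @param samples list of [count_matrix()] objects (at least 2).
#' @param sample_names character vector naming each sample; used as the batch
#'   labels of the merged matrix.
#' @return a merged [count_matrix()] with `batch_labels` set.
#' @export
merge_samples <- function(samples, sample_names) {
  if (length(samples) < 2L) stop("need at least 2 samples to merge")
  if (length(sample_names) != length(samples)) {
    stop("one sample name per sample required")
  }
  if (anyDuplicated(sample_names)) stop("sample_names must be unique")
  stopifnot(all(vapply(samples, inherits, logical(1), "count_matrix")))
  genes <- Reduce(intersect, lapply(samples, `[[`, "gene_ids"))
  if (length(genes) == 0L) stop("empty gene intersection across samples")
  all_cells <- unlist(lapply(samples, `[[`, "cell_ids"))
  dup <- anyDuplicated(all_cells) > 0L
  blocks <- vector("list", length(samples))
  ids <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    blocks[[i]] <- s$values[, genes, drop = FALSE]
    ids[[i]] <- if (dup) paste0(s$cell_ids, "-", sample_names[i]) else s$cell_ids
  }
  values <- do.call(rbind, blocks)
  batch <- rep(sample_names, vapply(samples, function(s) nrow(s$values),
                                    integer(1)))
  count_matrix(values, gene_ids = genes, cell_ids = unlist(ids),
               batch_labels = batch)
}

#' Save a latent matrix as CSV
#'
#' First column `cell_id`, then one column per latent dimension named
#' `z0..z{L-1}`. Round-trips through [load_latent()] up to float formatting.
#'
#' @param latent a [latent_matrix()].
#' @param path output CSV path.
#' @export
save_latent <- function(latent, path) {
  stopifnot(inherits(latent, "latent_matrix"))
  df <- data.frame(cell_id = latent$cell_ids, latent$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a latent matrix written by [save_latent()]
#' @param path CSV path.
#' @return a [latent_matrix()].
#' @export
load_latent <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  latent_matrix(as.matrix(df[, -1, drop = FALSE]), cell_ids = df[[1]])
}

#' Save cluster labels as CSV
#' @param labels integer or character label vector.
#' @param cell_ids matching cell identifiers.
#' @param path output CSV path.
#' @export
save_labels <- function(labels, cell_ids, path) {
  if (length(labels) != length(cell_ids)) stop("one label per cell required")
  utils::write.csv(data.frame(cell_id = cell_ids, label = labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a metric report as JSON
#' @param metrics named list or vector of numeric metric values.
#' @param path output JSON path.
#' @export
save_metrics <- function(metrics, path) {
  jsonlite::write_json(as.list(metrics), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
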