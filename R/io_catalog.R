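#' @importFrom methods as is new
#' @importFrom Matrix readMM writeMM sparseMatrix colSums rowSums t
#' @importFrom utils read.delim write.table combn
NULL

GENE_CLASSES <- c("V1R", "V2R_ABDE", "V2R_C1", "V2R_C2", "H2Mv",
                  "marker", "mito", "hemoglobin", "ER", "other")

RECEPTOR_FAMILIES <- c("V1R", "V2R_ABDE", "V2R_C1", "V2R_C2", "H2Mv")

#' Construct a validated count matrix
#'
#' Wraps a genes x cells matrix of raw counts together with its gene and
#' barcode identifiers, checking the invariants every downstream stage
#' relies on: unique identifiers, matching dimensions, and non-negative
#' integral entries.
#'
#' @param counts Matrix (dense or `Matrix::dgCMatrix`), genes in rows,
#'   cells in columns.
#' @param genes Character vector of unique gene identifiers (row names).
#' @param barcodes Character vector of unique cell barcodes (column names).
#' @return A `dgCMatrix` with dimnames set.
#' @export
vr_counts <- function(counts, genes = rownames(counts),
                      barcodes = colnames(counts)) {
  if (is.null(genes) || is.null(barcodes))
    stop("gene and barcode identifiers are required")
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(genes) || ncol(counts) != length(barcodes))
    stop("format error: matrix dimensions (", nrow(counts), " x ",
         ncol(counts), ") do not match identifier lists (",
         length(genes), " genes, ", length(barcodes), " barcodes)")
  if (anyDuplicated(genes)) stop("validation error: duplicate gene IDs")
  if (anyDuplicated(barcodes)) stop("validation error: duplicate barcodes")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("validation error: counts must be non-negative integers")
  dimnames(counts) <- list(as.character(genes), as.character(barcodes))
  counts
}

# counts and normalized matrices are plain dgCMatrix; kept as a seam in
# case a richer container is adopted later
unclass_matrix <- function(m) m

#' Load a count matrix
#'
#' Reads either a CellRanger-style MatrixMarket triplet (`matrix.mtx` +
#' `features.tsv`/`genes.tsv` + `barcodes.tsv`, optionally gzipped) or a
#' dense TSV with gene rows and cell columns.
#'
#' @param path Directory containing the triplet (for `format = "mtx_triplet"`)
#'   or the TSV file itself (for `format = "dense_tsv"`).
#' @param format One of `"mtx_triplet"`, `"dense_tsv"`.
#' @return A [vr_counts] matrix, gene order preserved from the features file.
#' @export
load_counts <- function(path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx <- find_triplet_file(path, c("matrix.mtx", "matrix.mtx.gz"))
    fts <- find_triplet_file(path, c("features.tsv", "features.tsv.gz",
                                     "genes.tsv", "genes.tsv.gz"))
    bcs <- find_triplet_file(path, c("barcodes.tsv", "barcodes.tsv.gz"))
    m <- Matrix::readMM(mtx)
    features <- read.delim(fts, header = FALSE, stringsAsFactors = FALSE)
    if (!ncol(features) %in% 2:3 && ncol(features) != 1)
      stop("format error: features file must have 1-3 columns")
    barcodes <- read.delim(bcs, header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != nrow(features))
      stop("format error: matrix has ", nrow(m), " rows but features file ",
           "lists ", nrow(features), " genes")
    if (ncol(m) != length(barcodes))
      stop("format error: matrix has ", ncol(m), " columns but barcodes ",
           "file lists ", length(barcodes), " cells")
    vr_counts(m, genes = features[[1]], barcodes = barcodes)
  } else {
    df <- read.delim(path, header = TRUE, row.names = 1, check.names = FALSE)
    vr_counts(as.matrix(df), genes = rownames(df), barcodes = colnames(df))
  }
}

find_triplet_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("format error: none of ", paste(candidates, collapse = ", "),
       " found in ", dir)
}

#' Write a count matrix as a CellRanger-style MTX triplet
#'
#' @param counts A [vr_counts] matrix.
#' @param dir Output directory (created if absent).
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(unclass_matrix(counts), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Load a gene catalog
#'
#' The catalog maps each gene to a receptor family / functional class and
#' optional subfamily. Recognised classes: V1R, V2R_ABDE, V2R_C1, V2R_C2,
#' H2Mv, marker, mito, hemoglobin, ER, other. In the default mouse
#' vocabulary family-C1 is the single gene Vmn2r1 and family-C2 is
#' Vmn2r2-Vmn2r7.
#'
#' @param path TSV with columns `gene_id`, `class`, `subfamily` (and
#'   optionally `display_name`).
#' @return Data frame classed `vr_catalog`.
#' @export
load_gene_catalog <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  gene_catalog(df)
}

#' Construct a gene catalog from a data frame
#'
#' @param df Data frame with columns `gene_id`, `class`, optional
#'   `subfamily` and `display_name`.
#' @return Validated data frame classed `vr_catalog`.
#' @export
gene_catalog <- function(df) {
  req <- c("gene_id", "class")
  if (!all(req %in% names(df)))
    stop("validation error: catalog needs columns ",
         paste(req, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("validation error: duplicate gene_id in catalog: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  bad <- setdiff(unique(df$class), GENE_CLASSES)
  if (length(bad))
    stop("validation error: unknown gene class(es): ",
         paste(bad, collapse = ", "))
  if (is.null(df$subfamily)) df$subfamily <- ""
  if (is.null(df$display_name)) df$display_name <- df$gene_id
  df <- df[, c("gene_id", "class", "subfamily", "display_name")]
  rownames(df) <- NULL
  class(df) <- c("vr_catalog", "data.frame")
  df
}

#' Genes of a catalog class
#'
#' @param catalog A `vr_catalog`.
#' @param class One or more class names.
#' @return Character vector of gene IDs.
#' @export
catalog_genes <- function(catalog, class) {
  catalog$gene_id[catalog$class %in% class]
}

#' Load an externally supplied cell-label table
#'
#' @param path TSV with columns `barcode`, `label`.
#' @return Data frame with columns barcode/label, one row per barcode.
#' @export
load_labels <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("barcode", "label") %in% names(df)))
    stop("validation error: label table needs columns barcode, label")
  if (anyDuplicated(df$barcode))
    stop("validation error: duplicate barcodes in label table")
  df[, c("barcode", "label")]
}

#' Write a result table as TSV
#'
#' All pipeline result tables are written as tab-separated UTF-8 with a
#' header row; [read_table_tsv] reproduces them exactly.
#'
#' @param table Data frame.
#' @param path Output file.
#' @export
write_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a TSV result table
#'
#' @param path File written by [write_table].
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
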