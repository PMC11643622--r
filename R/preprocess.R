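#' Per-cell quality-control metrics
#'
#' Computes, for every barcode: the number of detected genes (count > 0),
#' total counts, the percentage of counts coming from mitochondrial-class
#' genes, and whether any hemoglobin-class gene has a nonzero count
#' (red-blood-cell contamination flag).
#'
#' @param counts A [vr_counts] matrix.
#' @param catalog A `vr_catalog`; the mito and hemoglobin classes may be
#'   empty, in which case pct_mito is 0 and hbb_positive is FALSE.
#' @return Data frame with columns barcode, n_genes, total_counts,
#'   pct_mito, hbb_positive.
#' @export
compute_qc <- function(counts, catalog) {
  m <- unclass_matrix(counts)
  total <- Matrix::colSums(m)
  n_genes <- Matrix::colSums(m > 0)
  mito <- intersect(catalog_genes(catalog, "mito"), rownames(m))
  hbb <- intersect(catalog_genes(catalog, "hemoglobin"), rownames(m))
  pct_mito <- if (length(mito)) {
    ifelse(total > 0, 100 * Matrix::colSums(m[mito, , drop = FALSE]) / total, 0)
  } else rep(0, ncol(m))
  hbb_positive <- if (length(hbb)) {
    Matrix::colSums(m[hbb, , drop = FALSE] > 0) > 0
  } else rep(FALSE, ncol(m))
  data.frame(barcode = colnames(m),
             n_genes = as.integer(n_genes),
             total_counts = as.numeric(total),
             pct_mito = as.numeric(pct_mito),
             hbb_positive = as.logical(hbb_positive),
             stringsAsFactors = FALSE)
}

#' Filter cells on QC metrics
#'
#' Retains cells detecting between `min_genes` and `max_genes` genes
#' (closed interval), optionally drops hemoglobin-positive cells, and
#' drops cells above a mitochondrial-percentage cutoff. The
#' mitochondrial rule is a per-cell stand-in for removing a
#' mitochondria-enriched cluster; see the methods vignette.
#'
#' @param counts A [vr_counts] matrix.
#' @param qc QC table from [compute_qc] on the same matrix.
#' @param min_genes,max_genes Inclusive detected-gene bounds (defaults
#'   200 and 7000).
#' @param drop_hbb Drop cells with any hemoglobin-class count.
#' @param max_pct_mito Maximum mitochondrial percentage retained.
#' @return Filtered [vr_counts]; cell order preserved. If every cell is
#'   removed a warning is raised and an empty matrix returned.
#' @export
filter_cells <- function(counts, qc, min_genes = 200, max_genes = 7000,
                         drop_hbb = TRUE, max_pct_mito = 20) {
  stopifnot(identical(qc$barcode, colnames(counts)))
  keep <- qc$n_genes >= min_genes & qc$n_genes <= max_genes &
    qc$pct_mito <= max_pct_mito
  if (drop_hbb) keep <- keep & !qc$hbb_positive
  if (!any(keep)) warning("all cells removed by QC filters")
  out <- unclass_matrix(counts)[, keep, drop = FALSE]
  vr_counts(out, genes = rownames(counts), barcodes = colnames(counts)[keep])
}

#' Log-normalize a count matrix
#'
#' Per-cell library-size normalization to a fixed total followed by a
#' log(1 + x) transform: value(g, c) = ln(1 + scale * count(g, c) /
#' total(c)). Zero counts map to exactly zero, so sparsity is preserved.
#'
#' @param counts A [vr_counts] matrix; every cell must have a positive
#'   total count.
#' @param scale Scale factor (default 10000).
#' @return Sparse genes x cells matrix (`dgCMatrix`) of normalized
#'   expression.
#' @export
lognormalize <- function(counts, scale = 10000) {
  m <- unclass_matrix(counts)
  total <- Matrix::colSums(m)
  if (any(total == 0))
    stop("zero-total cell(s): ",
         paste(colnames(m)[total == 0], collapse = ", "))
  norm <- m
  # dgCMatrix stores column-major nonzeros; rescale in place
  ptr <- diff(norm@p)
  norm@x <- log1p(scale * norm@x / rep.int(total, ptr))
  norm
}

default_marker_roles <- function() {
  list(Gnao1 = "Gnao1", Gnai2 = "Gnai2", Gap43 = "Gap43",
       progenitor = c("Ascl1", "Neurod1"))
}

#' Marker-based cell-type classification
#'
#' Assigns each cell one of mature_Gnao1, mature_Gnai2, immature_Gnao1,
#' immature_Gnai2, progenitor, ambiguous or other from marker expression,
#' unless an external label table is supplied, which is returned verbatim.
#'
#' Rules (applied on normalized expression with cutoff `marker_cut`):
#' cells above the cutoff for both Gnao1 and Gnai2 are `ambiguous`;
#' otherwise Gap43-high cells are immature of the dominant G-protein
#' type; Gap43-low cells above a G-protein cutoff are mature; remaining
#' cells with Ascl1 or Neurod1 above the cutoff are `progenitor`; all
#' else `other`.
#'
#' @param norm A `vr_norm` matrix.
#' @param catalog A `vr_catalog` (marker genes must be class `marker`).
#' @param labels Optional external label table (columns barcode, label);
#'   returned unchanged when supplied.
#' @param marker_cut Normalized-expression cutoff (default 1.0).
#' @param roles Role map: list with entries Gnao1, Gnai2, Gap43,
#'   progenitor naming the marker gene(s) for each role.
#' @return Data frame with columns barcode, label.
#' @export
classify_cells <- function(norm, catalog, labels = NULL, marker_cut = 1.0,
                           roles = default_marker_roles()) {
  if (!is.null(labels)) {
    if (!all(c("barcode", "label") %in% names(labels)))
      stop("validation error: label table needs columns barcode, label")
    return(labels)
  }
  needed <- unlist(roles)
  missing <- setdiff(needed, rownames(norm))
  if (length(missing))
    stop("configuration error: marker gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  val <- function(genes) {
    v <- unclass_matrix(norm)[genes, , drop = FALSE]
    apply(as.matrix(v), 2, max)  # role met if any of its genes is high
  }
  gnao1 <- val(roles$Gnao1)
  gnai2 <- val(roles$Gnai2)
  gap43 <- val(roles$Gap43)
  prog <- val(roles$progenitor)
  lab <- rep("other", ncol(norm))
  lab[prog > marker_cut] <- "progenitor"
  mature <- gap43 <= marker_cut
  lab[mature & gnao1 > marker_cut] <- "mature_Gnao1"
  lab[mature & gnai2 > marker_cut] <- "mature_Gnai2"
  lab[!mature & gnao1 > marker_cut] <- "immature_Gnao1"
  lab[!mature & gnai2 > marker_cut] <- "immature_Gnai2"
  lab[gnao1 > marker_cut & gnai2 > marker_cut] <- "ambiguous"
  data.frame(barcode = colnames(norm), label = lab, stringsAsFactors = FALSE)
}
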