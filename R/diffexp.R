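# Two-sided Wilcoxon rank-sum p-value.
# Normal approximation with tie correction and continuity correction;
# exact enumeration of all group assignments (ties allowed) when both
# groups have <= `exact_max` observations.
ranksum_p <- function(a, b, exact_max = 10) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na <= exact_max && nb <= exact_max) {
    # exact permutation distribution of U under the null
    idx <- utils::combn(n, na)
    us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    return(mean(abs(us - mu) >= abs(u - mu) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- na * nb / 12 *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)  # all values tied
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)  # continuity-corrected
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two cell groups on
#' normalized expression, with Bonferroni correction over all tested
#' genes. Genes detected in fewer than `min_pct` of cells in both groups
#' are left untested. The fold change is computed on de-logged
#' normalized means: log2FC = log2((mean(expm1 A) + pseudocount) /
#' (mean(expm1 B) + pseudocount)).
#'
#' @param norm A `vr_norm` matrix.
#' @param cells_A,cells_B Disjoint barcode vectors, each with >= 3 cells.
#' @param pseudocount Added to the de-logged means (default 1).
#' @param min_pct Minimum detection fraction in either group for a gene
#'   to enter the test family (default 0.01).
#' @param lfc_cut,alpha Significance criteria recorded in the
#'   `significant` flag: |log2FC| > lfc_cut and p_adj < alpha.
#' @return Data frame classed `vr_de`: gene, log2FC (A over B), p_value,
#'   p_adj, pct_expressed_A, pct_expressed_B, significant.
#' @export
wilcoxon_de <- function(norm, cells_A, cells_B, pseudocount = 1,
                        min_pct = 0.01, lfc_cut = 1, alpha = 1e-6) {
  if (length(intersect(cells_A, cells_B)))
    stop("groups overlap: ",
         paste(utils::head(intersect(cells_A, cells_B), 3), collapse = ", "))
  if (length(cells_A) < 3 || length(cells_B) < 3)
    stop("each group needs >= 3 cells")
  ma <- as.matrix(unclass_matrix(norm)[, cells_A, drop = FALSE])
  mb <- as.matrix(unclass_matrix(norm)[, cells_B, drop = FALSE])
  pct_a <- rowMeans(ma > 0)
  pct_b <- rowMeans(mb > 0)
  tested <- which(pct_a >= min_pct | pct_b >= min_pct)
  lfc <- log2((rowMeans(expm1(ma[tested, , drop = FALSE])) + pseudocount) /
              (rowMeans(expm1(mb[tested, , drop = FALSE])) + pseudocount))
  p <- vapply(tested, function(g) ranksum_p(ma[g, ], mb[g, ]), 0)
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  out <- data.frame(gene = rownames(norm)[tested],
                    log2FC = unname(lfc),
                    p_value = p, p_adj = p_adj,
                    pct_expressed_A = unname(pct_a[tested]),
                    pct_expressed_B = unname(pct_b[tested]),
                    stringsAsFactors = FALSE)
  out$significant <- abs(out$log2FC) > lfc_cut & out$p_adj < alpha
  rownames(out) <- NULL
  class(out) <- c("vr_de", "data.frame")
  out
}

#' Filter a DE table on the significance criteria
#'
#' Retains genes with |log2FC| > `lfc_cut` and adjusted p below `alpha`,
#' and labels each by the enriched group (positive log2FC = group A).
#'
#' @param de A `vr_de` table.
#' @param lfc_cut Absolute log2 fold-change cutoff (default 1).
#' @param alpha Adjusted-p cutoff (default 1e-6).
#' @return Subset of `de` with an added `enriched_in` column
#'   (`"A"`/`"B"`).
#' @export
filter_significant <- function(de, lfc_cut = 1, alpha = 1e-6) {
  out <- de[abs(de$log2FC) > lfc_cut & de$p_adj < alpha, , drop = FALSE]
  out$enriched_in <- ifelse(out$log2FC > 0, "A", "B")
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set's overlap with a
#' query list against a gene universe: p = P(overlap >= observed) when
#' drawing |query| genes without replacement from the universe. Gene
#' sets are intersected with the universe before testing.
#'
#' @param query_genes Query gene list (must be a subset of the universe).
#' @param gene_sets Named list of gene-ID vectors.
#' @param universe Background gene universe.
#' @return Data frame sorted by p: set, overlap, set_size, query_size,
#'   universe_size, p_value.
#' @export
hypergeom_ora <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(intersect(query_genes, universe))
  if (length(setdiff(query_genes, universe)))
    warning("query genes outside the universe were dropped")
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(intersect(gene_sets[[nm]], universe))
    ov <- length(intersect(set, query))
    p <- stats::phyper(ov - 1, length(set),
                       length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(set),
               query_size = length(query),
               universe_size = length(universe), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene IDs,
#' tab-separated.
#'
#' @param path GMT file.
#' @return Named list of gene-ID vectors.
#' @export
read_gmt <- function(path) {
  lapply(fgsea::gmtPathways(path), unique)
}
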