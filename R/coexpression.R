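# catalog class -> call-table family tag
CLASS_TO_TAG <- c(V1R = "V1R", V2R_ABDE = "ABD", V2R_C1 = "C1",
                  V2R_C2 = "C2", H2Mv = "H2Mv")
# family tag -> threshold family
TAG_TO_THRESHOLD <- c(V1R = "V1R", ABD = "V2R", C1 = "V2R", C2 = "V2R",
                      H2Mv = "H2Mv")

# scope name -> family tags it covers ("C" pools C1 and C2)
resolve_scope <- function(scope) {
  map <- list(V1R = "V1R", ABD = "ABD", C = c("C1", "C2"), C1 = "C1",
              C2 = "C2", H2Mv = "H2Mv")
  bad <- setdiff(scope, names(map))
  if (length(bad)) stop("unknown family scope: ", paste(bad, collapse = ", "))
  unique(unlist(map[scope]))
}

#' Call expressed receptors per cell
#'
#' A receptor or H2-Mv gene is called expressed in a cell only if its
#' normalized expression value strictly exceeds the threshold of its
#' family ("surpasses", so a value exactly at the threshold is not
#' called). Cells with no calls are retained with empty sets.
#'
#' @param norm A `vr_norm` matrix.
#' @param catalog A `vr_catalog`.
#' @param thresholds A `vr_thresholds` table from [family_thresholds].
#' @param cells Barcodes to analyze (default: all).
#' @return Object of class `vr_calls`: list with `cells` (all analyzed
#'   barcodes) and `calls`, a long data frame (barcode, gene, family,
#'   value) of threshold-exceeding receptor genes.
#' @export
call_receptors <- function(norm, catalog, thresholds,
                           cells = colnames(norm)) {
  rec <- catalog[catalog$class %in% names(CLASS_TO_TAG), , drop = FALSE]
  genes <- intersect(rec$gene_id, rownames(norm))
  rec <- rec[rec$gene_id %in% genes, , drop = FALSE]
  tag <- CLASS_TO_TAG[rec$class]
  thr_of_fam <- stats::setNames(thresholds$threshold, thresholds$family)
  thr <- thr_of_fam[TAG_TO_THRESHOLD[tag]]
  if (anyNA(thr))
    stop("missing threshold for family ",
         paste(unique(TAG_TO_THRESHOLD[tag][is.na(thr)]), collapse = ", "))
  sub <- as(unclass_matrix(norm)[rec$gene_id, cells, drop = FALSE],
            "TsparseMatrix")
  keep <- sub@x > thr[sub@i + 1L]
  calls <- data.frame(
    barcode = cells[sub@j[keep] + 1L],
    gene = rec$gene_id[sub@i[keep] + 1L],
    family = unname(tag[sub@i[keep] + 1L]),
    value = sub@x[keep],
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$barcode, calls$family, calls$gene), ]
  rownames(calls) <- NULL
  structure(list(cells = cells, calls = calls), class = "vr_calls")
}

#' @export
print.vr_calls <- function(x, ...) {
  cat("vr_calls: ", length(x$cells), " cells, ", nrow(x$calls),
      " receptor calls (", length(unique(x$calls$barcode)),
      " cells with >= 1 call)\n", sep = "")
  invisible(x)
}

# per-cell called gene sets within a scope, as a named list (all analyzed
# cells present; empty character for cells with no call)
called_sets <- function(calls, scope) {
  tags <- resolve_scope(scope)
  df <- calls$calls
  out <- stats::setNames(vector("list", length(calls$cells)), calls$cells)
  out[] <- list(character(0))
  if (is.null(df)) return(out)
  df <- df[df$family %in% tags, , drop = FALSE]
  if (!nrow(df)) return(out)
  sets <- split(paste0(df$family, ":", df$gene), df$barcode)
  out[names(sets)] <- lapply(sets, sort)
  out
}

#' Per-cell receptor-count histogram
#'
#' Number of cells expressing k = 0, 1, 2, ... called genes of the given
#' family scope. Cells calling no receptor are part of the histogram at
#' k = 0; the histogram totals the number of analyzed cells.
#'
#' @param calls A `vr_calls` object.
#' @param family_scope Scope name(s): any of `"V1R"`, `"ABD"`, `"C"`
#'   (C1 and C2 pooled), `"C1"`, `"C2"`, `"H2Mv"`.
#' @return Data frame with columns k, n_cells.
#' @export
count_per_cell <- function(calls, family_scope) {
  k <- lengths(called_sets(calls, family_scope))
  tab <- table(factor(k, levels = 0:max(k)))
  data.frame(k = as.integer(names(tab)), n_cells = as.integer(tab))
}

#' Enumerate combinatorial co-expression patterns
#'
#' Counts, over cells, each distinct combination of called genes within
#' the scope (cross-family scopes concatenate the per-family call sets;
#' combination identity includes the family tag). Combinations seen in
#' fewer than `min_cells` cells are dropped — the frequency-based
#' doublet filter: a chimeric droplet produces a spurious combination
#' once, so requiring recurrence (default 2 cells) removes it.
#'
#' @param calls A `vr_calls` object.
#' @param family_scope Scope name(s), e.g. `c("ABD", "C", "H2Mv")`.
#' @param min_cells Minimum cell frequency retained (default 2).
#' @param count_mode `"exact"` counts each cell's exact called set only;
#'   `"subsets"` additionally credits every nonempty subset of it.
#' @return Data frame classed `vr_patterns` with columns scope,
#'   combination (`+`-joined sorted `family:gene` tags), n_cells, sorted
#'   by n_cells descending then lexicographically.
#' @export
enumerate_patterns <- function(calls, family_scope, min_cells = 2,
                               count_mode = c("exact", "subsets")) {
  count_mode <- match.arg(count_mode)
  sets <- called_sets(calls, family_scope)
  sets <- sets[lengths(sets) > 0]
  combos <- if (count_mode == "exact") {
    vapply(sets, paste, "", collapse = "+")
  } else {
    unlist(lapply(sets, function(s) {
      unlist(lapply(seq_along(s), function(m)
        apply(utils::combn(s, m, simplify = TRUE), 2, paste, collapse = "+")))
    }), use.names = FALSE)
  }
  tab <- table(combos)
  out <- data.frame(scope = rep(paste(family_scope, collapse = ","),
                                length(tab)),
                    combination = names(tab),
                    n_cells = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$n_cells >= min_cells, , drop = FALSE]
  if (nrow(out)) out <- out[order(-out$n_cells, out$combination), ]
  rownames(out) <- NULL
  class(out) <- c("vr_patterns", "data.frame")
  out
}

#' Receptor dosage analysis
#'
#' For each cell, sums the normalized expression of its called genes in
#' the scope and groups cells by k (number of called members). If the
#' summed expression scales proportionally with k while a control gene
#' (Gnao1 or Gnai2) stays flat across k, multi-receptor cells are real
#' co-expression rather than doublets.
#'
#' @param norm A `vr_norm` matrix.
#' @param calls A `vr_calls` object.
#' @param family_scope Scope name(s).
#' @param control_gene Gene whose expression should not depend on k.
#' @return List with `per_cell` (barcode, k, total_expression, control)
#'   and `summary` (per k: n_cells, median/q1/q3 of the summed family
#'   expression and of the control gene).
#' @export
dosage_analysis <- function(norm, calls, family_scope, control_gene) {
  if (!control_gene %in% rownames(norm))
    stop("configuration error: control gene ", control_gene,
         " absent from matrix")
  sets <- called_sets(calls, family_scope)
  df <- calls$calls[calls$calls$family %in% resolve_scope(family_scope), ]
  tot <- vapply(split(df$value, df$barcode), sum, 0)
  per_cell <- data.frame(
    barcode = calls$cells,
    k = unname(lengths(sets)),
    total_expression = unname(ifelse(is.na(tot[calls$cells]), 0,
                                     tot[calls$cells])),
    control = as.numeric(unclass_matrix(norm)[control_gene, calls$cells]),
    stringsAsFactors = FALSE)
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  summary <- do.call(rbind, lapply(split(per_cell, per_cell$k), function(g) {
    qt <- q(g$total_expression); qc <- q(g$control)
    data.frame(k = g$k[1], n_cells = nrow(g),
               total_q1 = qt[1], total_median = qt[2], total_q3 = qt[3],
               control_q1 = qc[1], control_median = qc[2],
               control_q3 = qc[3])
  }))
  summary <- summary[order(summary$k), ]
  rownames(summary) <- NULL
  list(per_cell = per_cell, summary = summary)
}

#' Classify mature Gnao1 cells by family-C and H2-Mv calls
#'
#' The broad division of mature basal neurons: `C1` (Vmn2r1-calling, no
#' family-C2 call), `C2_H2Mv_pos` / `C2_H2Mv_neg` (family-C2 callers
#' with / without an H2-Mv call), `C_none` (no family-C call), and
#' `mixed` for the rare cells calling both C1 and C2 (reported
#' separately). Also reports the fraction of H2-Mv-negative cells among
#' family-C callers.
#'
#' @param calls A `vr_calls` object restricted to mature Gnao1 cells.
#' @return List with `per_cell` (barcode, class), `summary` (class,
#'   n_cells, fraction) and `frac_H2Mv_negative_among_C`.
#' @export
classify_gnao1_subsets <- function(calls) {
  has <- function(tag) lengths(called_sets(calls, tag)) > 0
  c1 <- has("C1"); c2 <- has("C2"); h2 <- has("H2Mv")
  cls <- rep("C_none", length(calls$cells))
  cls[c1 & !c2] <- "C1"
  cls[c2 & !c1 & h2] <- "C2_H2Mv_pos"
  cls[c2 & !c1 & !h2] <- "C2_H2Mv_neg"
  cls[c1 & c2] <- "mixed"
  per_cell <- data.frame(barcode = calls$cells, class = cls,
                         stringsAsFactors = FALSE)
  tab <- table(factor(cls, levels = c("C1", "C2_H2Mv_pos", "C2_H2Mv_neg",
                                      "mixed", "C_none")))
  summary <- data.frame(class = names(tab), n_cells = as.integer(tab),
                        fraction = as.integer(tab) / length(cls))
  anyC <- c1 | c2
  frac <- if (any(anyC)) sum(anyC & !h2) / sum(anyC) else NA_real_
  list(per_cell = per_cell, summary = summary,
       frac_H2Mv_negative_among_C = frac)
}
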