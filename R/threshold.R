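#' Pool normalized expression values of a receptor family
#'
#' Extracts, for every (cell, family-gene) pair in the requested cell
#' subset, the normalized expression value, and pools them into one
#' vector. Exact zeros are excluded: the near-zero peak of the bimodal
#' distribution is carried by ambient low positive values, and the
#' zero point mass would otherwise dominate the density estimate
#' without moving the between-peak valley.
#'
#' @param norm A `vr_norm` matrix.
#' @param catalog A `vr_catalog`.
#' @param family Catalog class name (e.g. `"V1R"`, `"V2R_C2"`) or a
#'   vector of classes pooled together.
#' @param cells Barcodes to pool over (default: all columns).
#' @return Numeric vector of nonzero normalized values.
#' @export
pool_family_values <- function(norm, catalog, family, cells = colnames(norm)) {
  if (!length(cells)) stop("cell subset is empty")
  genes <- intersect(catalog_genes(catalog, family), rownames(norm))
  if (!length(genes))
    stop("no genes of family ", paste(family, collapse = "+"),
         " present in matrix")
  sub <- unclass_matrix(norm)[genes, cells, drop = FALSE]
  x <- as(sub, "CsparseMatrix")@x
  x[x > 0]
}

#' Detect a bimodal expression threshold
#'
#' Fits a Gaussian kernel density estimate (Sheather-Jones bandwidth,
#' 512-point grid) to pooled nonzero normalized expression values,
#' locates the two highest-density modes separated by at least
#' `min_separation`, and returns the position of the density minimum
#' between them — the valley that operationalizes "the start of the
#' second peak" of a bimodal expression distribution. If no two
#' qualifying modes exist the configured default is returned with
#' `fallback_used = TRUE` and a warning.
#'
#' @param values Nonzero pooled values from [pool_family_values].
#' @param default Fallback threshold when the distribution is not
#'   bimodal (and the value used when thresholds are pinned).
#' @param min_separation Minimum distance between the two modes.
#' @return List with threshold, mode locations, bandwidth, n_values,
#'   modes_found, fallback_used.
#' @export
detect_threshold <- function(values, default, min_separation = 0.2) {
  if (!length(values)) stop("no values supplied")
  fallback <- list(threshold = default, modes = numeric(0),
                   kde_bandwidth = NA_real_, n_values = length(values),
                   modes_found = 0L, fallback_used = TRUE)
  if (length(unique(values)) < 3) {
    warning("too few distinct values; using default threshold ", default)
    return(fallback)
  }
  # Sheather-Jones bandwidth: Silverman's rule assumes roughly unimodal
  # data and oversmooths the sharp ambient component of a well-separated
  # bimodal mixture, dragging the valley toward the wide component;
  # fall back to Silverman when the SJ equation has no solution.
  bw <- tryCatch(stats::bw.SJ(values), error = function(e)
    stats::bw.nrd0(values))
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = 512,
                      from = min(values), to = max(values))
  fallback$kde_bandwidth <- d$bw
  # interior local maxima of the density grid
  y <- d$y
  is_max <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  # include grid endpoints as candidate modes (half-peaks at the range edge)
  is_max[1] <- y[1] > y[2]
  is_max[length(y)] <- y[length(y)] > y[length(y) - 1]
  mx <- which(is_max)
  fallback$modes_found <- length(mx)
  if (length(mx) < 2) {
    warning("distribution not bimodal; using default threshold ", default)
    return(fallback)
  }
  # the two highest modes at least min_separation apart
  mx <- mx[order(y[mx], decreasing = TRUE)]
  pick <- NULL
  for (i in seq_along(mx)[-1]) {
    if (abs(d$x[mx[i]] - d$x[mx[1]]) >= min_separation) {
      pick <- sort(c(mx[1], mx[i]))
      break
    }
  }
  if (is.null(pick)) {
    warning("no two modes separated by >= ", min_separation,
            "; using default threshold ", default)
    return(fallback)
  }
  valley <- seq(pick[1], pick[2])[which.min(y[pick[1]:pick[2]])]
  list(threshold = d$x[valley], modes = d$x[pick],
       kde_bandwidth = d$bw, n_values = length(values),
       modes_found = length(which(is_max)), fallback_used = FALSE)
}

default_fixed_thresholds <- function() {
  c(V1R = 2.5, V2R = 1.25, H2Mv = 1.25)
}

# the three thresholded families and the catalog classes they pool
threshold_family_classes <- function() {
  list(V1R = "V1R", V2R = c("V2R_ABDE", "V2R_C1", "V2R_C2"), H2Mv = "H2Mv")
}

#' Derive per-family receptor-calling thresholds
#'
#' One threshold per receptor family (V1R, V2R, H2-Mv), pooled over all
#' family genes. In `"auto"` mode the threshold is detected from the
#' bimodal distribution via [detect_threshold], falling back to the
#' fixed value; in `"fixed"` mode the pinned values are used directly
#' (defaults 2.5 for V1R, 1.25 for V2R and H2-Mv).
#'
#' @param norm A `vr_norm` matrix.
#' @param catalog A `vr_catalog`.
#' @param cells Cell subset to pool; default all cells. May be a named
#'   list (V1R/V2R/H2Mv) with one subset per family — e.g. the mature
#'   neurons of the relevant type.
#' @param mode `"auto"` or `"fixed"`.
#' @param fixed Named fallback/pinned thresholds.
#' @param min_separation Passed to [detect_threshold].
#' @return Data frame classed `vr_thresholds` with one row per family:
#'   family, threshold, fallback_used, n_values, kde_bandwidth.
#' @export
family_thresholds <- function(norm, catalog, cells = colnames(norm),
                              mode = c("auto", "fixed"),
                              fixed = default_fixed_thresholds(),
                              min_separation = 0.2) {
  mode <- match.arg(mode)
  fams <- threshold_family_classes()
  rows <- lapply(names(fams), function(f) {
    genes <- intersect(catalog_genes(catalog, fams[[f]]), rownames(norm))
    if (!length(genes)) return(NULL)
    if (mode == "fixed") {
      return(data.frame(family = f, threshold = unname(fixed[f]),
                        fallback_used = FALSE, n_values = NA_integer_,
                        kde_bandwidth = NA_real_))
    }
    cells_f <- if (is.list(cells)) cells[[f]] else cells
    vals <- pool_family_values(norm, catalog, fams[[f]], cells_f)
    det <- detect_threshold(vals, default = unname(fixed[f]),
                            min_separation = min_separation)
    data.frame(family = f, threshold = det$threshold,
               fallback_used = det$fallback_used,
               n_values = det$n_values, kde_bandwidth = det$kde_bandwidth)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vr_thresholds", "data.frame")
  out
}
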