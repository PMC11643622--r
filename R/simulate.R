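# run expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Default simulation configuration
#'
#' Describes the synthetic vomeronasal population the generator emits: a
#' mixed pool of progenitor, immature and mature (Gnao1 / Gnai2)
#' neurons plus non-neuronal cells; a receptor panel at loosely mouse
#' scale (150 V1R, 70 family-ABD V2R, Vmn2r1 + Vmn2r2-Vmn2r7 family-C,
#' 6 H2-Mv); negative-binomial counts with lognormal library sizes;
#' per-gene ambient contamination producing the near-zero peak of the
#' bimodal receptor distribution; planted co-expression rules (single
#' V1R with rare recurring pairs; one ABD + C1 xor a 2-6-member C2 set;
#' 1-4 H2-Mv members coupled to family-C); ER-gene upregulation in
#' Gnao1 cells; doublet, RBC-contamination and low-quality-cell rates.
#'
#' @param ... Overrides for any default field.
#' @return Named list of simulation parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_cells = c(mature_Gnao1 = 1500, mature_Gnai2 = 1500,
                immature_Gnao1 = 600, immature_Gnai2 = 600,
                progenitor = 400, other = 400),
    n_V1R = 150, n_ABD = 70, n_C2 = 6, n_H2Mv = 6,
    n_background = 1000, n_ER = 50,
    on_mean = 100, ambient_mean = 0.02, marker_mean = 40,
    mito_mean = 60, hbb_mean = 20, er_base_mean = 2,
    bg_shape = 0.8, bg_scale = 15,
    dispersion = 0.1, lib_logmean = 0, lib_logsd = 0.3,
    p_V1R_pair = 0.05, n_planted_V1R_pairs = 5,
    p_C1_vs_C2 = 0.4, C2_members_range = c(2, 6),
    H2Mv_range = c(1, 4), p_H2Mv_given_C2 = 0.65,
    p_H2Mv_given_C1 = 0.1, p_C1C2_mix = 0.02,
    er_log2fc = 2,
    doublet_rate = 0.01, hbb_rate = 0.01, low_quality_rate = 0.02,
    seed = 1L)
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  pr <- unlist(cfg[c("p_V1R_pair", "p_C1_vs_C2", "p_H2Mv_given_C2",
                     "p_H2Mv_given_C1", "p_C1C2_mix", "doublet_rate",
                     "hbb_rate", "low_quality_rate")])
  if (any(pr < 0 | pr > 1)) stop("validation error: probabilities in [0,1]")
  if (cfg$C2_members_range[1] > cfg$C2_members_range[2] ||
      cfg$H2Mv_range[1] > cfg$H2Mv_range[2])
    stop("validation error: ranges must be ordered")
  if (cfg$C2_members_range[2] > cfg$n_C2)
    stop("validation error: C2_members_range exceeds panel size")
  cfg
}

# the default mouse-style gene catalog implied by a config
sim_catalog <- function(cfg) {
  abd_sub <- rep(c("A", "B", "D"), length.out = cfg$n_ABD)
  er_real <- c("Creld2", "Dnajc3", "Pdia6", "Sdf2l1")
  er_ids <- c(er_real[seq_len(min(4, cfg$n_ER))],
              if (cfg$n_ER > 4) paste0("Ergene", 5:cfg$n_ER))
  df <- rbind(
    data.frame(gene_id = paste0("Vmn1r", seq_len(cfg$n_V1R)),
               class = "V1R", subfamily = ""),
    data.frame(gene_id = paste0("Vmn2r", seq_len(cfg$n_ABD) + 7),
               class = "V2R_ABDE", subfamily = abd_sub),
    data.frame(gene_id = "Vmn2r1", class = "V2R_C1", subfamily = "C1"),
    data.frame(gene_id = paste0("Vmn2r", 1 + seq_len(cfg$n_C2)),
               class = "V2R_C2", subfamily = "C2"),
    data.frame(gene_id = paste0("H2-M", seq_len(cfg$n_H2Mv)),
               class = "H2Mv", subfamily = ""),
    data.frame(gene_id = c("Gnao1", "Gnai2", "Gap43", "Omp", "Ascl1",
                           "Neurod1"),
               class = "marker", subfamily = ""),
    data.frame(gene_id = c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2",
                           "mt-Cytb"),
               class = "mito", subfamily = ""),
    data.frame(gene_id = "Hbb-bs", class = "hemoglobin", subfamily = ""),
    data.frame(gene_id = er_ids, class = "ER", subfamily = ""),
    data.frame(gene_id = sprintf("Bg%04d", seq_len(cfg$n_background)),
               class = "other", subfamily = ""))
  gene_catalog(df)
}

# draw the planted receptor set for one cell, as "TAG:gene" strings
draw_receptors <- function(type, cfg, v1r, abd, c2, h2mv, pair_pool) {
  if (type == "mature_Gnai2") {
    g <- if (stats::runif(1) < cfg$p_V1R_pair) {
      pair_pool[[sample.int(length(pair_pool), 1)]]
    } else sample(v1r, 1)
    return(paste0("V1R:", sort(g)))
  }
  if (type == "mature_Gnao1") {
    set <- paste0("ABD:", sample(abd, 1))
    if (stats::runif(1) < cfg$p_C1_vs_C2) {
      set <- c(set, "C1:Vmn2r1")
      if (stats::runif(1) < cfg$p_C1C2_mix)  # rare C1+C2 co-expressors
        set <- c(set, paste0("C2:", c2[length(c2)]))
      p_h2 <- cfg$p_H2Mv_given_C1
    } else {
      k <- sample(cfg$C2_members_range[1]:cfg$C2_members_range[2], 1)
      set <- c(set, paste0("C2:", sample(c2, k)))
      p_h2 <- cfg$p_H2Mv_given_C2
    }
    if (stats::runif(1) < p_h2) {
      m <- sample(cfg$H2Mv_range[1]:cfg$H2Mv_range[2], 1)
      set <- c(set, paste0("H2Mv:", sample(h2mv, m)))
    }
    return(sort(set))
  }
  character(0)  # immature / progenitor / non-neuronal: no receptors
}

#' Generate a synthetic VNO single-cell dataset with planted truth
#'
#' Draws a count matrix, catalog, label table and ground truth under
#' the model described in [sim_config]. Same config and seed give
#' bit-identical output. When `doublet_rate > 0`, doublets are injected
#' via [inject_doublets]; a doublet of two same-type cells keeps that
#' type's label (as a clustering would see it), mixed doublets are
#' labelled `doublet`.
#'
#' @param cfg Configuration from [sim_config].
#' @return List with `counts` ([vr_counts]), `catalog`, `labels`
#'   (barcode/label), and `truth`: cells (barcode, type, doublet,
#'   constituents, hbb_planted, low_quality), receptor_sets (named list
#'   of `TAG:gene` vectors), de (per ER gene planted log2FC,
#'   mature_Gnao1 over mature_Gnai2).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    catalog <- sim_catalog(cfg)
    genes <- catalog$gene_id
    types <- rep(names(cfg$n_cells), cfg$n_cells)
    n <- length(types)
    barcodes <- sprintf("cell_%05d", seq_len(n))
    v1r <- catalog_genes(catalog, "V1R")
    abd <- catalog_genes(catalog, "V2R_ABDE")
    c2 <- catalog_genes(catalog, "V2R_C2")
    h2mv <- catalog_genes(catalog, "H2Mv")
    er <- catalog_genes(catalog, "ER")
    bg <- catalog_genes(catalog, "other")
    mito <- catalog_genes(catalog, "mito")
    # recurring V1R pairs planted at the configured rate
    pair_pool <- lapply(seq_len(cfg$n_planted_V1R_pairs), function(i)
      sample(v1r, 2))
    sets <- lapply(types, draw_receptors, cfg = cfg, v1r = v1r, abd = abd,
                   c2 = c2, h2mv = h2mv, pair_pool = pair_pool)
    names(sets) <- barcodes

    mu <- matrix(cfg$ambient_mean, nrow = length(genes), ncol = n,
                 dimnames = list(genes, NULL))
    mu[bg, ] <- stats::rgamma(length(bg), shape = cfg$bg_shape,
                              scale = cfg$bg_scale)  # recycled per column
    mu[mito, ] <- cfg$mito_mean
    mu["Hbb-bs", ] <- 0  # RBC contamination is cell-specific, not ambient
    mu["Omp", types %in% c("mature_Gnao1", "mature_Gnai2")] <- cfg$marker_mean
    mu["Gnao1", types %in% c("mature_Gnao1", "immature_Gnao1")] <- cfg$marker_mean
    mu["Gnai2", types %in% c("mature_Gnai2", "immature_Gnai2")] <- cfg$marker_mean
    mu["Gap43", types %in% c("immature_Gnao1", "immature_Gnai2")] <- cfg$marker_mean
    mu[c("Ascl1", "Neurod1"), types == "progenitor"] <- cfg$marker_mean
    mu[er, ] <- cfg$er_base_mean
    gnao1_cells <- types %in% c("mature_Gnao1", "immature_Gnao1")
    mu[er, gnao1_cells] <- cfg$er_base_mean * 2^cfg$er_log2fc
    for (i in seq_len(n)) {
      s <- sets[[i]]
      if (length(s)) mu[sub("^[^:]+:", "", s), i] <- cfg$on_mean
    }
    hbb_planted <- stats::runif(n) < cfg$hbb_rate
    mu["Hbb-bs", hbb_planted] <- cfg$hbb_mean
    low_quality <- stats::runif(n) < cfg$low_quality_rate
    mu[, low_quality] <- mu[, low_quality] * 0.005
    lib <- stats::rlnorm(n, cfg$lib_logmean, cfg$lib_logsd)
    mu <- sweep(mu, 2, lib, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$dispersion),
                     nrow = nrow(mu), dimnames = list(genes, barcodes))
    counts <- vr_counts(counts, genes = genes, barcodes = barcodes)

    truth_cells <- data.frame(barcode = barcodes, type = types,
                              doublet = FALSE, constituents = "",
                              hbb_planted = hbb_planted,
                              low_quality = low_quality,
                              stringsAsFactors = FALSE)
    de <- data.frame(gene = er, log2fc = cfg$er_log2fc,
                     stringsAsFactors = FALSE)
    out <- list(counts = counts, catalog = catalog,
                labels = data.frame(barcode = barcodes, type = types,
                                    stringsAsFactors = FALSE),
                truth = list(cells = truth_cells, receptor_sets = sets,
                             de = de))
    names(out$labels)[2] <- "label"
    if (cfg$doublet_rate > 0)
      out <- inject_doublets(out, cfg$doublet_rate,
                             seed = cfg$seed + 1000003L)
    out
  })
}

#' Inject doublets into a simulated dataset
#'
#' Replaces `floor(rate * n)` pairs of distinct cells with their summed
#' count profiles, mimicking droplets that captured two cells. The
#' constituents are removed and the doublet barcodes, constituent
#' records and union receptor sets are added to the ground truth.
#'
#' @param sim Output of [generate_dataset] (pre-doublet).
#' @param rate Doublet rate in `[0, 0.5)`.
#' @param seed RNG seed for pair selection.
#' @return The dataset list with doublets spliced in.
#' @export
inject_doublets <- function(sim, rate, seed = 1L) {
  if (rate < 0 || rate >= 0.5) stop("doublet rate must be in [0, 0.5)")
  m <- unclass_matrix(sim$counts)
  n <- ncol(m)
  if (n == 0) stop("empty matrix")
  k <- floor(rate * n)
  if (k == 0) return(sim)
  with_seed(seed, {
    pick <- sample.int(n, 2 * k)
    a <- pick[seq_len(k)]; b <- pick[k + seq_len(k)]
    dbl <- m[, a, drop = FALSE] + m[, b, drop = FALSE]
    dbl_bc <- sprintf("doublet_%04d", seq_len(k))
    colnames(dbl) <- dbl_bc
    keep <- setdiff(seq_len(n), pick)
    counts <- vr_counts(cbind(m[, keep, drop = FALSE], dbl),
                        genes = rownames(m),
                        barcodes = c(colnames(m)[keep], dbl_bc))
    tc <- sim$truth$cells
    ta <- tc$type[a]; tb <- tc$type[b]
    dbl_rows <- data.frame(barcode = dbl_bc,
                           type = ifelse(ta == tb, ta, "doublet"),
                           doublet = TRUE,
                           constituents = paste(tc$barcode[a], tc$barcode[b],
                                                sep = "+"),
                           hbb_planted = tc$hbb_planted[a] | tc$hbb_planted[b],
                           low_quality = FALSE,
                           stringsAsFactors = FALSE)
    sets <- sim$truth$receptor_sets
    dbl_sets <- lapply(seq_len(k), function(i)
      sort(union(sets[[a[i]]], sets[[b[i]]])))
    names(dbl_sets) <- dbl_bc
    sim$truth$cells <- rbind(tc[keep, ], dbl_rows)
    sim$truth$receptor_sets <- c(sets[keep], dbl_sets)
    sim$counts <- counts
    sim$labels <- data.frame(barcode = sim$truth$cells$barcode,
                             label = sim$truth$cells$type,
                             stringsAsFactors = FALSE)
    sim
  })
}

#' Planted co-expression pattern list implied by the ground truth
#'
#' The distinct true receptor combinations (within a scope) carried by
#' at least `min_cells` non-doublet cells — the reference list that
#' [enumerate_patterns] should recover.
#'
#' @param truth Ground-truth element of a generated dataset.
#' @param family_scope Scope name(s) as in [enumerate_patterns].
#' @param min_cells Minimum planted frequency.
#' @param cells Restrict to these barcodes (default: all non-doublet).
#' @return Data frame with columns combination, n_cells.
#' @export
truth_patterns <- function(truth, family_scope, min_cells = 2,
                           cells = NULL) {
  tags <- resolve_scope(family_scope)
  tc <- truth$cells
  if (is.null(cells)) cells <- tc$barcode[!tc$doublet]
  sets <- truth$receptor_sets[cells]
  combos <- vapply(sets, function(s) {
    s <- s[sub(":.*$", "", s) %in% tags]
    paste(sort(s), collapse = "+")
  }, "")
  combos <- combos[nzchar(combos)]
  tab <- table(combos)
  out <- data.frame(combination = names(tab), n_cells = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$n_cells >= min_cells, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample a two-component Gaussian expression mixture
#'
#' The idealized bimodal normalized-expression distribution: an ambient
#' component near zero and a true-expression component, used to
#' exercise threshold detection against a known analytic valley.
#'
#' @param n Number of values.
#' @param seed RNG seed.
#' @param w Weight of the ambient component.
#' @param m1,s1 Ambient component mean and sd.
#' @param m2,s2 Expression component mean and sd.
#' @return Numeric vector of length `n`.
#' @export
simulate_bimodal_values <- function(n, seed = 1L, w = 0.7, m1 = 0.1,
                                    s1 = 0.05, m2 = 3.0, s2 = 0.5) {
  with_seed(seed, {
    z <- stats::runif(n) < w
    stats::rnorm(n, mean = ifelse(z, m1, m2), sd = ifelse(z, s1, s2))
  })
}

#' Analytic valley of the two-component Gaussian mixture
#'
#' Numerical argmin of the mixture density between the two component
#' means, on a fine grid — the target the detector should find.
#'
#' @inheritParams simulate_bimodal_values
#' @param grid_n Grid resolution.
#' @return Valley location.
#' @export
mixture_valley <- function(w = 0.7, m1 = 0.1, s1 = 0.05, m2 = 3.0,
                           s2 = 0.5, grid_n = 20001) {
  x <- seq(m1, m2, length.out = grid_n)
  dens <- w * stats::dnorm(x, m1, s1) + (1 - w) * stats::dnorm(x, m2, s2)
  x[which.min(dens)]
}

#' Simulate a two-group DE calibration matrix
#'
#' Null genes share a gamma-drawn mean across groups; `n_de` planted
#' genes (half up, half down) differ by `2^log2fc` in group A. Used to
#' measure false-positive control and recall of the Wilcoxon criteria.
#'
#' @param n_null,n_de Numbers of null and planted genes.
#' @param log2fc Planted absolute log2 fold change.
#' @param cells_per_group Cells in each group.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param seed RNG seed.
#' @return List with `norm` (a `vr_norm`), `groups` (list A/B of
#'   barcodes) and `truth` (gene, planted log2fc).
#' @export
simulate_de_matrix <- function(n_null = 1000, n_de = 50, log2fc = 2,
                               cells_per_group = 200, dispersion = 0.1,
                               seed = 1L) {
  with_seed(seed, {
    g <- n_null + n_de
    genes <- c(sprintf("null%04d", seq_len(n_null)),
               sprintf("de%03d", seq_len(n_de)))
    base <- stats::rgamma(g, shape = 2, scale = 2)
    fc <- c(rep(0, n_null),
            rep(c(log2fc, -log2fc), length.out = n_de))
    mu_a <- base * 2^fc
    mu_b <- base
    n <- 2 * cells_per_group
    lib <- stats::rlnorm(n, 0, 0.2)
    mu <- cbind(matrix(mu_a, g, cells_per_group),
                matrix(mu_b, g, cells_per_group))
    mu <- sweep(mu, 2, lib, "*")
    bcs <- sprintf("c%04d", seq_len(n))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion),
                     nrow = g, dimnames = list(genes, bcs))
    counts <- vr_counts(counts)
    keep <- Matrix::colSums(unclass_matrix(counts)) > 0
    counts <- vr_counts(unclass_matrix(counts)[, keep, drop = FALSE])
    list(norm = lognormalize(counts),
         groups = list(A = bcs[seq_len(cells_per_group)][
                         keep[seq_len(cells_per_group)]],
                       B = bcs[cells_per_group + seq_len(cells_per_group)][
                         keep[cells_per_group + seq_len(cells_per_group)]]),
         truth = data.frame(gene = genes, log2fc = fc,
                            stringsAsFactors = FALSE))
  })
}

#' Generate synthetic apical-basal intensity profiles
#'
#' Emits ROI intensity tables with planted channel trends along the
#' apical (0) to basal (1) axis: a rising sigmoid for the Gnao1 channel,
#' a co-rising sigmoid for the ER channel, and a flat Omp channel, plus
#' Gaussian noise and a per-section affine intensity distortion that
#' min-max normalization must remove.
#'
#' @param n_sections Number of ROIs (default 20).
#' @param n_points Samples per ROI.
#' @param noise_sd Gaussian noise sd on the unit-scale signal.
#' @param seed RNG seed.
#' @return List of raw (unnormalized) `vr_profile` objects.
#' @export
generate_axis_profiles <- function(n_sections = 20, n_points = 120,
                                   noise_sd = 0.05, seed = 1L) {
  with_seed(seed, {
    trend <- list(
      Gnao1 = function(x) stats::plogis((x - 0.6) * 12),
      ER = function(x) stats::plogis((x - 0.55) * 10),
      Omp = function(x) rep(0.8, length(x)))
    lapply(seq_len(n_sections), function(i) {
      pos <- sort(stats::runif(n_points)) * stats::runif(1, 200, 400)
      x01 <- (pos - min(pos)) / (max(pos) - min(pos))
      ch <- lapply(trend, function(f) {
        gain <- stats::runif(1, 50, 200)  # arbitrary imaging units
        offset <- stats::runif(1, 5, 30)
        offset + gain * pmax(f(x01) + stats::rnorm(n_points, 0, noise_sd), 0)
      })
      axis_profile(sprintf("section_%02d", i), pos, ch)
    })
  })
}
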