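#' Default pipeline configuration
#'
#' Every default matches the published analysis where one exists: QC
#' gene bounds 200-7000, scale factor 10000, pinned thresholds 2.5
#' (V1R) / 1.25 (V2R, H2-Mv), pattern frequency filter 2 cells, DE
#' criteria |log2FC| > 1 and Bonferroni-adjusted p < 1e-6, ORA p
#' cutoff 0.05.
#'
#' @param ... Overrides, named as in the returned list (nested lists
#'   are replaced wholesale).
#' @return Nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    qc = list(min_genes = 200, max_genes = 7000, drop_hbb = TRUE,
              max_pct_mito = 20),
    norm = list(scale = 10000),
    markers = list(cut = 1.0),
    thresholds = list(mode = "auto",
                      fixed = default_fixed_thresholds(),
                      min_separation = 0.2),
    patterns = list(min_cells = 2,
                    scopes = list("V1R", "C", "ABD", "H2Mv",
                                  c("ABD", "C", "H2Mv"))),
    dosage = list(scopes = c("C", "ABD", "H2Mv"), control_gene = "Gnao1"),
    de = list(group_a = "mature_Gnao1", group_b = "mature_Gnai2",
              lfc_cut = 1, alpha = 1e-6, min_pct = 0.01),
    ora = list(p_cut = 0.05),
    profile = list(span = 0.5),
    seed = 1L)
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) stop("unknown pipeline_config field(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(override)) {
    if (is.list(cfg[[nm]]) && is.list(override[[nm]])) {
      cfg[[nm]][names(override[[nm]])] <- override[[nm]]
    } else cfg[[nm]] <- override[[nm]]
  }
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults of
#' [pipeline_config]; absent keys keep their defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(pipeline_config, user)
}

run_stage <- function(name, log, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  msg <- sprintf("[%s] %s (%.1fs)", name,
                 if (is.data.frame(out)) paste0(nrow(out), " rows") else "ok",
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
  message(msg)
  assign("lines", c(get("lines", envir = log), msg), envir = log)
  out
}

#' Run the full analysis pipeline
#'
#' Executes QC -> cell filtering -> log-normalization -> cell-type
#' classification (or external label pass-through) -> family threshold
#' derivation -> receptor calling -> pattern enumeration -> dosage
#' analysis -> Gnao1 subtype classification -> differential expression
#' -> over-representation (if gene sets given) -> axis profiling (if
#' profiles given), writing one TSV per stage plus a run manifest to
#' `out_dir`. Identical inputs and config give identical outputs.
#'
#' Thresholds are derived on the mature cells of the relevant type
#' (V1R on mature Gnai2 cells, V2R and H2-Mv on mature Gnao1 cells)
#' and receptor calling is restricted to mature neurons.
#'
#' @param counts A [vr_counts] matrix or a path loadable by
#'   [load_counts] (directory = MTX triplet, file = dense TSV).
#' @param catalog A `vr_catalog` or TSV path.
#' @param config List from [pipeline_config].
#' @param labels Optional external label table (data frame or TSV
#'   path); when supplied, marker classification is skipped.
#' @param gene_sets Optional named list of gene sets or GMT path.
#' @param profiles Optional list of `vr_profile` or TSV path.
#' @param out_dir Output directory; `NULL` skips writing.
#' @return List with qc, norm, labels, thresholds, calls, patterns,
#'   histograms, dosage, subtypes, de, de_significant, ora, profile
#'   results.
#' @export
run_pipeline <- function(counts, catalog, config = pipeline_config(),
                         labels = NULL, gene_sets = NULL, profiles = NULL,
                         out_dir = NULL) {
  log <- new.env(); assign("lines", character(0), envir = log)
  if (is.character(counts))
    counts <- if (dir.exists(counts)) load_counts(counts, "mtx_triplet")
              else load_counts(counts, "dense_tsv")
  if (is.character(catalog)) catalog <- load_gene_catalog(catalog)
  if (is.character(labels)) labels <- load_labels(labels)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  if (is.character(profiles)) profiles <- read_profiles(profiles)

  qc <- run_stage("qc", log, compute_qc(counts, catalog))
  filtered <- run_stage("filter", log, filter_cells(
    counts, qc, min_genes = config$qc$min_genes,
    max_genes = config$qc$max_genes, drop_hbb = config$qc$drop_hbb,
    max_pct_mito = config$qc$max_pct_mito))
  norm <- run_stage("normalize", log,
                    lognormalize(filtered, scale = config$norm$scale))
  lab <- run_stage("classify", log, {
    l <- classify_cells(norm, catalog, labels = labels,
                        marker_cut = config$markers$cut)
    l[l$barcode %in% colnames(norm), , drop = FALSE]
  })
  of_type <- function(types) lab$barcode[lab$label %in% types]
  mature <- of_type(c("mature_Gnao1", "mature_Gnai2"))
  thr_cells <- list(V1R = of_type("mature_Gnai2"),
                    V2R = of_type("mature_Gnao1"),
                    H2Mv = of_type("mature_Gnao1"))
  thr_cells <- lapply(thr_cells, function(x) if (length(x)) x else mature)
  thresholds <- run_stage("thresholds", log, family_thresholds(
    norm, catalog, cells = thr_cells, mode = config$thresholds$mode,
    fixed = config$thresholds$fixed,
    min_separation = config$thresholds$min_separation))
  calls <- run_stage("call", log,
                     call_receptors(norm, catalog, thresholds,
                                    cells = mature))
  patterns <- run_stage("patterns", log, do.call(rbind, lapply(
    config$patterns$scopes, function(sc)
      enumerate_patterns(calls, sc,
                         min_cells = config$patterns$min_cells))))
  histograms <- run_stage("histograms", log, do.call(rbind, lapply(
    config$patterns$scopes, function(sc)
      cbind(scope = paste(sc, collapse = ","), count_per_cell(calls, sc)))))
  dosage <- run_stage("dosage", log, {
    res <- lapply(config$dosage$scopes, function(sc)
      cbind(scope = sc,
            dosage_analysis(norm, calls, sc,
                            control_gene = config$dosage$control_gene)$summary))
    do.call(rbind, res)
  })
  gnao1 <- of_type(config$de$group_a)
  subtypes <- run_stage("subtypes", log, {
    if (length(gnao1)) classify_gnao1_subsets(
      call_receptors(norm, catalog, thresholds, cells = gnao1))
    else NULL
  })
  de <- run_stage("de", log, {
    a <- of_type(config$de$group_a); b <- of_type(config$de$group_b)
    if (length(a) >= 3 && length(b) >= 3)
      wilcoxon_de(norm, a, b, min_pct = config$de$min_pct,
                  lfc_cut = config$de$lfc_cut, alpha = config$de$alpha)
    else NULL
  })
  de_sig <- if (!is.null(de))
    filter_significant(de, config$de$lfc_cut, config$de$alpha) else NULL
  ora <- run_stage("ora", log, {
    if (!is.null(gene_sets) && !is.null(de_sig)) {
      query <- de_sig$gene[de_sig$enriched_in == "A" &
                             de_sig$log2FC > config$de$lfc_cut]
      hypergeom_ora(query, gene_sets, universe = de$gene)
    } else NULL
  })
  profile_res <- run_stage("profile", log, {
    if (!is.null(profiles)) {
      npro <- lapply(profiles, normalize_profile)
      chans <- unique(unlist(lapply(npro, function(p) names(p$channels))))
      fits <- lapply(chans, function(ch)
        cbind(channel = ch,
              fit_trendline(npro, ch, span = config$profile$span)))
      do.call(rbind, fits)
    } else NULL
  })

  res <- list(qc = qc, filtered = filtered, norm = norm, labels = lab,
              thresholds = thresholds, calls = calls, patterns = patterns,
              histograms = histograms, dosage = dosage,
              subtypes = subtypes, de = de, de_significant = de_sig,
              ora = ora, profile = profile_res)
  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir, log)
  res
}

write_pipeline_outputs <- function(res, config, out_dir, log) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) if (!is.null(x)) write_table(x, file.path(out_dir, f))
  w(res$qc, "qc.tsv")
  w(res$labels, "labels.tsv")
  w(as.data.frame(res$thresholds), "thresholds.tsv")
  w(res$calls$calls, "calls.tsv")
  w(res$patterns, "patterns.tsv")
  w(res$histograms, "histograms.tsv")
  w(res$dosage, "dosage.tsv")
  if (!is.null(res$subtypes)) {
    w(res$subtypes$per_cell, "subtypes.tsv")
    w(res$subtypes$summary, "subtype_summary.tsv")
  }
  w(res$de, "de.tsv")
  w(res$de_significant, "de_significant.tsv")
  w(res$ora, "ora.tsv")
  w(res$profile, "profile_trendlines.tsv")
  manifest <- c(
    sprintf("vrcall %s", as.character(utils::packageVersion("vrcall"))),
    sprintf("R %s", R.version.string),
    sprintf("seed %s", config$seed),
    "config:",
    strsplit(yaml::as.yaml(config), "\n")[[1]],
    "stages:",
    get("lines", envir = log))
  writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  invisible(out_dir)
}
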