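fixed_thr <- function() {
  structure(data.frame(family = c("V1R", "V2R", "H2Mv"),
                       threshold = c(2.5, 1.25, 1.25),
                       fallback_used = FALSE),
            class = c("vr_thresholds", "data.frame"))
}

test_that("calling uses strict exceedance of the family threshold", {
  m <- matrix(c(1.30, 1.25, 2.5, 2.51), nrow = 4,
              dimnames = list(c("Vmn2r2", "Vmn2r3", "Vmn1r1", "Vmn1r2"),
                              "c1"))
  norm <- as(m, "CsparseMatrix")
  cat <- gene_catalog(data.frame(
    gene_id = rownames(m),
    class = c("V2R_C2", "V2R_C2", "V1R", "V1R"), subfamily = ""))
  calls <- call_receptors(norm, cat, fixed_thr())
  # 1.30 > 1.25 called; 1.25 == 1.25 not called; same at the V1R cutoff
  expect_setequal(calls$calls$gene, c("Vmn1r2", "Vmn2r2"))
  # cells with no calls are retained
  expect_identical(calls$cells, "c1")
})

test_that("calls on simulated data match planted truth with high accuracy", {
  sim <- small_sim()
  nl <- sim_norm_labels(sim)
  mature <- nl$labels$barcode[nl$labels$label %in%
                                c("mature_Gnao1", "mature_Gnai2")]
  calls <- call_receptors(nl$norm, sim$catalog, fixed_thr(), cells = mature)
  sets <- vrcall:::called_sets(calls, c("V1R", "ABD", "C", "H2Mv"))
  truth <- sim$truth$receptor_sets[mature]
  tp <- sum(mapply(function(a, b) length(intersect(a, b)), sets, truth))
  prec <- tp / sum(lengths(sets))
  rec <- tp / sum(lengths(truth))
  expect_gte(prec, 0.98)
  expect_gte(rec, 0.98)
})

test_that("per-cell receptor-count histogram matches hand counts", {
  calls <- calls_from_sets(list(
    a = c("C2:Vmn2r2", "C2:Vmn2r3"), b = character(0),
    c = c("C2:Vmn2r2", "C2:Vmn2r4"), d = "C1:Vmn2r1"))
  h <- count_per_cell(calls, "C")
  expect_identical(h$k, 0:2)
  expect_identical(h$n_cells, c(1L, 1L, 2L))
  expect_equal(sum(h$n_cells), length(calls$cells))
  h0 <- count_per_cell(calls_from_sets(list(a = character(0),
                                            b = character(0))), "C")
  expect_identical(h0, data.frame(k = 0L, n_cells = 2L))
})

test_that("pattern enumeration counts exact sets and applies min_cells", {
  calls <- calls_from_sets(list(
    c1 = c("ABD:A", "ABD:B"), c2 = c("ABD:A", "ABD:B"),
    c3 = c("ABD:A", "ABD:B"), c4 = c("ABD:C", "ABD:D")))
  p2 <- enumerate_patterns(calls, "ABD", min_cells = 2)
  expect_identical(p2$combination, "ABD:A+ABD:B")
  expect_identical(p2$n_cells, 3L)
  p1 <- enumerate_patterns(calls, "ABD", min_cells = 1)
  expect_true("ABD:C+ABD:D" %in% p1$combination)
  expect_identical(p1$n_cells, c(3L, 1L))
})

test_that("pattern table equals brute-force enumeration on small matrices", {
  sim <- small_sim(seed = 23L)
  nl <- sim_norm_labels(sim)
  mature <- head(nl$labels$barcode[nl$labels$label %in%
                                     c("mature_Gnao1", "mature_Gnai2")], 20)
  calls <- call_receptors(nl$norm, sim$catalog, fixed_thr(), cells = mature)
  for (scope in list("C", "V1R", c("ABD", "C", "H2Mv"))) {
    pat <- enumerate_patterns(calls, scope, min_cells = 1)
    # oracle: loop over cells, build each set label naively from the
    # long call table, tally with a named vector
    tags <- vrcall:::resolve_scope(scope)
    tally <- character(0)
    for (bc in mature) {
      rows <- calls$calls[calls$calls$barcode == bc &
                            calls$calls$family %in% tags, ]
      if (!nrow(rows)) next
      key <- paste(sort(paste0(rows$family, ":", rows$gene)),
                   collapse = "+")
      tally <- c(tally, key)
    }
    oracle <- table(tally)
    got <- setNames(pat$n_cells, pat$combination)
    expect_setequal(as.character(names(got)),
                    as.character(names(oracle)))
    if (length(oracle))
      expect_identical(unname(got[names(oracle)]),
                       as.integer(oracle))
  }
})

test_that("pattern counts are cell-order invariant and sum to calling cells", {
  sim <- small_sim(seed = 5L)
  nl <- sim_norm_labels(sim)
  mature <- nl$labels$barcode[nl$labels$label %in%
                                c("mature_Gnao1", "mature_Gnai2")]
  calls <- call_receptors(nl$norm, sim$catalog, fixed_thr(), cells = mature)
  calls_rev <- call_receptors(nl$norm, sim$catalog, fixed_thr(),
                              cells = rev(mature))
  p <- enumerate_patterns(calls, "C", min_cells = 1)
  p_rev <- enumerate_patterns(calls_rev, "C", min_cells = 1)
  expect_identical(p, p_rev)
  n_calling <- sum(lengths(vrcall:::called_sets(calls, "C")) > 0)
  expect_equal(sum(p$n_cells), n_calling)
})

test_that("raising a threshold never grows any call set", {
  sim <- small_sim(seed = 31L)
  nl <- sim_norm_labels(sim)
  thr_hi <- fixed_thr()
  thr_hi$threshold <- thr_hi$threshold + 1
  lo <- call_receptors(nl$norm, sim$catalog, fixed_thr())
  hi <- call_receptors(nl$norm, sim$catalog, thr_hi)
  slo <- vrcall:::called_sets(lo, c("V1R", "ABD", "C", "H2Mv"))
  shi <- vrcall:::called_sets(hi, c("V1R", "ABD", "C", "H2Mv"))
  expect_true(all(mapply(function(h, l) all(h %in% l), shi, slo)))
})

test_that("dosage analysis sums called values and groups by k", {
  m <- matrix(c(1.5, 2.0, 0.5, 3.0,
                1.5, 0.0, 0.5, 3.0), nrow = 4,
              dimnames = list(c("Vmn2r2", "Vmn2r3", "Vmn2r4", "Gnao1"),
                              c("c1", "c2")))
  norm <- as(m, "CsparseMatrix")
  cat <- gene_catalog(data.frame(
    gene_id = rownames(m),
    class = c("V2R_C2", "V2R_C2", "V2R_C2", "marker"), subfamily = ""))
  calls <- call_receptors(norm, cat, fixed_thr())
  d <- dosage_analysis(norm, calls, "C", "Gnao1")
  # c1 calls 1.5 and 2.0 (0.5 below threshold) -> k=2, total 3.5
  expect_equal(d$per_cell$k, c(2L, 1L))
  expect_equal(d$per_cell$total_expression, c(3.5, 1.5))
  expect_equal(d$per_cell$control, c(3, 3))
  expect_error(dosage_analysis(norm, calls, "C", "Omp"),
               "configuration error")
})

test_that("summed expression scales with k while the control stays flat", {
  sim <- small_sim(seed = 41L)
  nl <- sim_norm_labels(sim)
  gnao1 <- nl$labels$barcode[nl$labels$label == "mature_Gnao1"]
  calls <- call_receptors(nl$norm, sim$catalog, fixed_thr(), cells = gnao1)
  d <- dosage_analysis(nl$norm, calls, "C", "Gnao1")$summary
  med <- setNames(d$total_median, d$k)
  expect_gt(med["2"] / med["1"], 1.6)
  expect_lt(med["2"] / med["1"], 2.4)
  ctrl <- setNames(d$control_median, d$k)
  ratios <- ctrl[c("2", "3", "4")] / ctrl["1"]
  expect_true(all(ratios > 0.9 & ratios < 1.1))
})

test_that("Gnao1 subsets classify by family-C and H2-Mv calls", {
  calls <- calls_from_sets(list(
    a = "C1:Vmn2r1",
    b = c("C2:Vmn2r2", "C2:Vmn2r3", "H2Mv:H2-M1"),
    c = c("C2:Vmn2r2", "C2:Vmn2r4"),
    d = "ABD:Vmn2r8",
    e = c("C1:Vmn2r1", "C2:Vmn2r7")))
  st <- classify_gnao1_subsets(calls)
  expect_identical(
    st$per_cell$class,
    c("C1", "C2_H2Mv_pos", "C2_H2Mv_neg", "C_none", "mixed"))
  # H2-Mv-negative among the 4 family-C callers: a, c, e
  expect_equal(st$frac_H2Mv_negative_among_C, 3 / 4)
  expect_equal(sum(st$summary$n_cells), length(calls$cells))
})

test_that("planted H2-Mv-negative fraction is recovered on sim data", {
  sim <- small_sim(seed = 13L)
  nl <- sim_norm_labels(sim)
  gnao1 <- nl$labels$barcode[nl$labels$label == "mature_Gnao1"]
  calls <- call_receptors(nl$norm, sim$catalog, fixed_thr(), cells = gnao1)
  st <- classify_gnao1_subsets(calls)
  truth_sets <- sim$truth$receptor_sets[gnao1]
  planted_neg <- mean(vapply(truth_sets, function(s)
    !any(grepl("^H2Mv:", s)), TRUE))
  expect_lt(abs(st$frac_H2Mv_negative_among_C - planted_neg), 0.03)
})
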