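# independent exact-permutation oracle: two-sided rank-sum p by
# enumerating every assignment of the pooled values to group A
perm_ranksum_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  mu <- na * (n - na) / 2
  obs <- abs(sum(r[seq_len(na)]) - na * (na + 1) / 2 - mu)
  idx <- combn(n, na)
  stat <- apply(idx, 2, function(i) sum(r[i])) - na * (na + 1) / 2
  mean(abs(stat - mu) >= obs - 1e-9)
}

de_fixture <- function(values, groups) {
  # one-gene matrix plus a filler gene so min_pct filtering keeps shape
  m <- rbind(g = values, filler = 1)
  colnames(m) <- sprintf("c%02d", seq_along(values))
  list(norm = as(m, "CsparseMatrix"),
       a = colnames(m)[groups == "A"], b = colnames(m)[groups == "B"])
}

test_that("identical group distributions give log2FC 0 and p 1", {
  v <- rep(c(1, 2, 3), 4)
  fx <- de_fixture(v, rep(c("A", "B"), each = 6))
  # same multiset in both groups
  de <- wilcoxon_de(fx$norm, fx$a, fx$b)
  g <- de[de$gene == "g", ]
  expect_equal(g$log2FC, 0)
  expect_equal(g$p_value, 1)
})

test_that("exact branch equals the brute-force permutation oracle", {
  a_vals <- c(5.1, 5.0, 5.2, 4.9, 5.05)
  b_vals <- c(0, 0, 0.1, 0, 0.05)
  fx <- de_fixture(c(a_vals, b_vals), rep(c("A", "B"), each = 5))
  de <- wilcoxon_de(fx$norm, fx$a, fx$b)
  expect_equal(de$p_value[de$gene == "g"],
               perm_ranksum_p(a_vals, b_vals))
  # and with heavy ties
  a2 <- c(1, 1, 2, 2, 3); b2 <- c(1, 2, 2, 3, 3)
  fx2 <- de_fixture(c(a2, b2), rep(c("A", "B"), each = 5))
  de2 <- wilcoxon_de(fx2$norm, fx2$a, fx2$b)
  expect_equal(de2$p_value[de2$gene == "g"], perm_ranksum_p(a2, b2))
})

test_that("normal branch agrees with stats::wilcox.test on large groups", {
  set.seed(71)
  a <- rpois(60, 5); b <- rpois(55, 7)
  fx <- de_fixture(c(a, b), rep(c("A", "B"), c(60, 55)))
  de <- wilcoxon_de(fx$norm, fx$a, fx$b)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                      correct = TRUE)$p.value)
  expect_equal(de$p_value[de$gene == "g"], ref, tolerance = 1e-8)
})

test_that("exact and normal branches agree within 10% for groups of 8-10", {
  set.seed(5)
  checked <- 0
  for (i in 1:20) {
    na <- sample(8:10, 1); nb <- sample(8:10, 1)
    a <- rnorm(na); b <- rnorm(nb)
    p_exact <- vrcall:::ranksum_p(a, b, exact_max = 10)
    p_norm <- vrcall:::ranksum_p(a, b, exact_max = 0)
    if (p_exact < 0.05) next  # the approximation claim is for the bulk
    checked <- checked + 1
    expect_lt(abs(p_norm - p_exact) / p_exact, 0.10)
  }
  expect_gte(checked, 10)
})

test_that("group swap negates log2FC and keeps p", {
  set.seed(8)
  v <- rpois(40, 4)
  fx <- de_fixture(v, rep(c("A", "B"), each = 20))
  d1 <- wilcoxon_de(fx$norm, fx$a, fx$b)
  d2 <- wilcoxon_de(fx$norm, fx$b, fx$a)
  expect_equal(d1$log2FC, -d2$log2FC)
  expect_equal(d1$p_value, d2$p_value)
})

test_that("Bonferroni is raw p times family size, capped at 1", {
  sim <- simulate_de_matrix(n_null = 50, n_de = 5, cells_per_group = 30,
                            seed = 2)
  de <- wilcoxon_de(sim$norm, sim$groups$A, sim$groups$B)
  expect_equal(de$p_adj, pmin(1, de$p_value * nrow(de)))
  expect_true(all(de$p_adj >= de$p_value))
})

test_that("group validation rejects overlap and tiny groups", {
  fx <- de_fixture(rnorm(10), rep(c("A", "B"), each = 5))
  expect_error(wilcoxon_de(fx$norm, fx$a, c(fx$a[1], fx$b)), "overlap")
  expect_error(wilcoxon_de(fx$norm, fx$a[1:2], fx$b), ">= 3 cells")
})

test_that("significance filter applies both criteria and splits by sign", {
  de <- structure(data.frame(
    gene = c("up", "weak_fc", "weak_p", "down"),
    log2FC = c(1.5, 0.9, 2.0, -1.5),
    p_value = c(1e-10, 1e-14, 1e-3, 1e-9),
    p_adj = c(1e-8, 1e-12, 1e-3, 1e-7),
    pct_expressed_A = 1, pct_expressed_B = 1,
    significant = NA), class = c("vr_de", "data.frame"))
  sig <- filter_significant(de, lfc_cut = 1, alpha = 1e-6)
  expect_identical(sig$gene, c("up", "down"))
  expect_identical(sig$enriched_in, c("A", "B"))
  expect_identical(nrow(filter_significant(de[0, ])), 0L)
})

test_that("planted DE genes are recovered with no null false positives", {
  sim <- simulate_de_matrix(n_null = 300, n_de = 20, log2fc = 2,
                            cells_per_group = 100, seed = 6)
  de <- wilcoxon_de(sim$norm, sim$groups$A, sim$groups$B)
  sig <- filter_significant(de)
  planted <- sim$truth$gene[sim$truth$log2fc != 0]
  expect_length(setdiff(sig$gene, planted), 0)
  expect_gte(mean(planted %in% sig$gene), 0.9)
  # signs match the planted direction
  up <- sim$truth$gene[sim$truth$log2fc > 0]
  expect_true(all(sig$enriched_in[sig$gene %in% up] == "A"))
})

test_that("hypergeometric p equals the combinatorial tail sum", {
  # universe 100, set 10, query 10, overlap 5
  universe <- sprintf("u%03d", 1:100)
  set <- universe[1:10]
  query <- c(universe[1:5], universe[51:55])
  res <- hypergeom_ora(query, list(s = set), universe)
  oracle <- sum(vapply(5:10, function(j)
    choose(10, j) * choose(90, 10 - j), 0)) / choose(100, 10)
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  expect_equal(res$overlap, 5L)
})

test_that("ORA handles degenerate overlaps and validates inputs", {
  universe <- sprintf("u%02d", 1:20)
  res0 <- hypergeom_ora(universe[11:15], list(s = universe[1:5]), universe)
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p_value, 1)
  resall <- hypergeom_ora(universe, list(s = universe), universe)
  expect_equal(resall$overlap, 20L)
  expect_equal(resall$p_value, 1)
  expect_error(hypergeom_ora("a", list(s = "a"), character(0)),
               "empty universe")
  # sets are intersected with the universe before testing
  res <- hypergeom_ora(universe[1:3], list(s = c(universe[1:3], "alien")),
                       universe)
  expect_equal(res$set_size, 3L)
})

test_that("GMT round trip through read_gmt", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), f)
  sets <- read_gmt(f)
  expect_identical(sets, list(setA = c("g1", "g2", "g3"),
                              setB = c("g2", "g4")))
})
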