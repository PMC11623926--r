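test_that("wilcoxon AUC equals brute-force pair counting", {
  expect_equal(wilcoxonAuc(c(5, 6, 7), c(1, 2, 3))$auc, 1)
  expect_equal(wilcoxonAuc(rep(2, 4), rep(2, 5))$auc, 0.5)
  expect_error(wilcoxonAuc(numeric(0), 1:3), "non-empty")
  set.seed(17)
  for (i in 1:100) {
    n1 <- sample(2:9, 1); n2 <- sample(2:9, 1)
    # integer values force midrank ties
    x <- sample(0:6, n1, TRUE); y <- sample(0:6, n2, TRUE)
    got <- wilcoxonAuc(x, y)
    expect_identical(got$auc, bruteAuc(x, y))
    # complementarity under group swap
    expect_identical(got$auc + wilcoxonAuc(y, x)$auc, 1)
  }
})

test_that("wilcoxon p-values agree with the reference rank-sum test", {
  set.seed(18)
  # exact branch: small n, no ties
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:10, 1)); y <- stats::rnorm(sample(3:10, 1))
    got <- wilcoxonAuc(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$u, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # normal-approximation branch: large n with ties
  for (i in 1:10) {
    x <- sample(0:20, 60, TRUE); y <- sample(0:20, 80, TRUE)
    got <- wilcoxonAuc(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("gene ranking recovers a planted effect-size ordering", {
  set.seed(19)
  nGenes <- 100; nCells <- 500
  mult <- exp(seq(log(1 / 3), log(3), length.out = nGenes))
  base <- 2
  counts <- cbind(
    matrix(stats::rnbinom(nGenes * nCells, mu = base * mult, size = 2),
           nGenes, nCells),
    matrix(stats::rnbinom(nGenes * nCells, mu = base, size = 2),
           nGenes, nCells))
  rownames(counts) <- sprintf("g%03d", seq_len(nGenes))
  meta <- data.frame(
    cluster = "myeloid",
    sample = rep(c("A1", "B1"), each = nCells),
    group = rep(c("high_burden", "negative"), each = nCells))
  rg <- suppressMessages(rankGenes(list(counts = counts, metadata = meta),
                                   "myeloid", "high_burden", "negative"))
  rho <- stats::cor(rg$rank_score,
                    mult[match(rg$gene, rownames(counts))],
                    method = "spearman")
  expect_gte(rho, 0.9)
  # strongest planted up-regulation ranks at the top
  expect_true(rownames(counts)[nGenes] %in% head(rg$gene, 5))
})

test_that("undetected genes are dropped and missing groups are skipped", {
  counts <- matrix(5, 3, 20, dimnames = list(c("gA", "gB", "gC"), NULL))
  counts["gB", ] <- 0
  meta <- data.frame(cluster = "m", sample = "s",
                     group = rep(c("high_burden", "negative"), 10))
  rg <- suppressMessages(rankGenes(list(counts = counts, metadata = meta),
                                   "m", "high_burden", "negative"))
  expect_false("gB" %in% rg$gene)
  expect_warning(
    out <- rankGenes(list(counts = counts, metadata = meta),
                     "m", "high_burden", "missing_group"),
    "skipped")
  expect_null(out)
})

test_that("the enrichment score matches a hand-computed running sum", {
  stats <- c(g01 = 0.45, g02 = 0.40, g03 = 0.35, g04 = 0.30, g05 = 0.25,
             g06 = 0.20, g07 = 0.10, g08 = 0.05, g09 = -0.05, g10 = -0.15,
             g11 = -0.25, g12 = -0.35)
  set4 <- c("g02", "g04", "g05", "g10")
  # spreadsheet-style walk: in-set steps +|score|/1.10, out-of-set -1/8
  sumW <- 0.40 + 0.30 + 0.25 + 0.15
  want <- cumsum(c(-1 / 8, 0.40 / sumW, -1 / 8, 0.30 / sumW, 0.25 / sumW,
                   -1 / 8, -1 / 8, -1 / 8, -1 / 8, 0.15 / sumW,
                   -1 / 8, -1 / 8))
  got <- gseaEs(stats, set4, minSetSize = 4)
  expect_equal(got$running_sum, want, tolerance = 1e-12)
  expect_equal(got$es, max(want), tolerance = 1e-12)
  expect_identical(got$leading_edge, c("g02", "g04", "g05"))
  expect_equal(got$n_overlap, 4L)
})

test_that("extreme set placements give extreme or null scores", {
  n <- 200
  stats <- sort(stats::rnorm(n, sd = 0.2), decreasing = TRUE)
  names(stats) <- sprintf("g%03d", seq_len(n))
  top <- gseaEs(stats, names(stats)[1:10])
  expect_gt(top$es, 0.85)
  expect_lte(abs(top$es), 1)
  # a set spread uniformly through the list stays near zero
  unif <- gseaEs(stats, names(stats)[seq(5, n, by = 20)])
  expect_lt(abs(unif$es), 0.35)
  expect_true(length(top$leading_edge) > 0)
})

test_that("enrichment scores agree with the reference preranked statistic", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  for (i in 1:25) {
    n <- sample(50:300, 1)
    stats <- sort(stats::rnorm(n), decreasing = TRUE)
    names(stats) <- sprintf("g%04d", seq_len(n))
    k <- sample(5:20, 1)
    pos <- sort(sample.int(n, k))
    got <- gseaEs(stats, names(stats)[pos])
    ref <- fgsea::calcGseaStat(stats, pos, gseaParam = 1)
    expect_equal(got$es, ref, tolerance = 1e-10)
    # the fast in-set-positions path equals the full running sum
    expect_equal(CHIPburden:::.gseaEsFast(stats, pos), got$es,
                 tolerance = 1e-12)
  }
})

test_that("group swap flips rank scores and negates every set's score", {
  set.seed(24)
  n <- 150
  stats <- sort(stats::rnorm(n), decreasing = TRUE)
  names(stats) <- sprintf("g%03d", seq_len(n))
  swapped <- sort(-stats, decreasing = TRUE)
  for (i in 1:10) {
    set <- sample(names(stats), sample(6:25, 1))
    es1 <- gseaEs(stats, set)$es
    es2 <- gseaEs(swapped, set)$es
    expect_equal(es2, -es1, tolerance = 1e-12)
  }
})

test_that("small overlaps are skipped with a recorded reason", {
  stats <- sort(stats::rnorm(50), decreasing = TRUE)
  names(stats) <- sprintf("g%02d", 1:50)
  expect_warning(out <- gseaEs(stats, c("g01", "g02", "zzz")), "overlap")
  expect_null(out)
  res <- gseaPermutation(stats, list(small = c("g01", "g02"),
                                     ok = names(stats)[1:10]),
                         nPerm = 100, seed = 1)
  expect_identical(res$flag[res$pathway == "small"],
                   "skipped_small_overlap")
  expect_true(is.na(res$padj[res$pathway == "small"]))
  expect_false(is.na(res$padj[res$pathway == "ok"]))
})

test_that("permutation GSEA is reproducible and BH-adjusts across sets", {
  set.seed(25)
  n <- 300
  stats <- sort(stats::rnorm(n), decreasing = TRUE)
  names(stats) <- sprintf("g%03d", seq_len(n))
  sets <- c(list(top = names(stats)[1:15]),
            lapply(1:5, function(i) sample(names(stats), 20)))
  names(sets)[2:6] <- paste0("rand", 1:5)
  a <- gseaPermutation(stats, sets, nPerm = 500, seed = 7)
  b <- gseaPermutation(stats, sets, nPerm = 500, seed = 7)
  expect_identical(a, b)
  expect_equal(a$padj, bhAdjust(a$p_perm))
  expect_true(all(a$padj >= a$p_perm))
  expect_lt(a$padj[a$pathway == "top"], 0.05)
  expect_gt(a$nes[a$pathway == "top"], 1)
  # leading edge stays within the set
  le <- strsplit(a$leading_edge[a$pathway == "top"], ";")[[1]]
  expect_true(all(le %in% sets$top))
})
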