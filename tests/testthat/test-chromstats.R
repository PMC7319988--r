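test_that("directionality scores span [-1, 1] with the expected values", {
  tr <- make_tracks(list(
    a = data.frame(chrom = "c", pos = c(100L, 110L, 120L, 130L),
                   strand = c("+", "+", "-", "-"),
                   count = c(20L, 10L, 5L, 5L))))
  tss <- tibble::tibble(chrom = "c", pos = 110L, strand = "+")
  # S_sense = 30 units, S_anti = 10 (counts share the same library total)
  expect_equal(directionality_score(tr, tss), 0.5)
  expect_equal(directionality_score(tr, dplyr::mutate(tss, strand = "-")),
               -0.5)
  only_sense <- make_tracks(list(
    a = data.frame(chrom = "c", pos = c(100L, 120L), strand = "+",
                   count = c(4L, 6L))))
  expect_equal(directionality_score(only_sense, tss), 1)
  eq <- make_tracks(list(
    a = data.frame(chrom = "c", pos = c(100L, 120L), strand = c("+", "-"),
                   count = c(5L, 5L))))
  expect_equal(directionality_score(eq, tss), 0)
  far <- tibble::tibble(chrom = "c", pos = 10000L, strand = "+")
  expect_true(is.na(directionality_score(tr, far)))
  expect_error(directionality_score(tr, tss, window = 0), "> 0")
})

test_that("methylation windows are coverage-weighted and scale-invariant", {
  meth <- tibble::tibble(
    chrom = "c", pos = c(90L, 120L, 400L), strand = "+",
    context = c("CG", "CG", "CG"),
    meth = c(3L, 7L, 10L), total = c(10L, 10L, 10L))
  tss <- tibble::tibble(chrom = "c", pos = 100L)
  expect_equal(methylation_level(meth, tss, 101L, "CG"), 0.5)
  # no cytosines of the context in the window -> missing
  expect_true(is.na(methylation_level(meth, tss, 101L, "CHH")))
  expect_error(methylation_level(meth, tss, 100L), "odd")
  # invariant under uniform scaling of (meth, total)
  scaled <- dplyr::mutate(meth, meth = meth * 7L, total = total * 7L)
  expect_equal(methylation_level(scaled, tss, 101L, "CG"), 0.5)
})

test_that("the low-CHG subset rule isolates the intended loci", {
  # planted: locus 1 low CHG (5%), locus 2 high CHG (60%)
  meth <- tibble::tibble(
    chrom = "c", pos = c(1000L, 1010L, 5000L, 5010L), strand = "+",
    context = "CHG", meth = c(1L, 0L, 6L, 6L), total = c(10L, 10L, 10L, 10L))
  loci <- tibble::tibble(chrom = "c", pos = c(1000L, 5000L))
  lvl <- methylation_level(meth, loci, 101L, "CHG")
  low <- loci[!is.na(lvl) & lvl < 0.10, ]
  expect_equal(low$pos, 1000L)
})

test_that("the paired t-test matches the closed form", {
  res <- paired_diff_test(c(1, 2, 3), c(2, 3, 5))
  expect_equal(res$t, -4)
  expect_equal(res$p, 2 * pt(-4, df = 2), tolerance = 1e-12)
  deg <- paired_diff_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))

  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    d <- x - y
    t_direct <- mean(d) / (sd(d) / sqrt(length(d)))
    p_direct <- 2 * pt(-abs(t_direct), df = length(d) - 1)
    res <- paired_diff_test(x, y)
    expect_equal(res$t, t_direct, tolerance = 1e-12)
    expect_equal(res$p, p_direct, tolerance = 1e-12)
  }
})

test_that("the rank-sum test is exact for small samples", {
  rs <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(unname(rs$U), 0)
  expect_equal(rs$p, 1 / 3, tolerance = 1e-12)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")

  # E[U] = n1 n2 / 2 under exchangeability
  set.seed(3)
  us <- replicate(300, {
    z <- rnorm(12)
    rank_sum_test(z[1:6], z[7:12])$U
  })
  expect_equal(mean(us), 18, tolerance = 2)

  # exact and approximate p agree reasonably at n = 10 vs 10
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10, 0.3)
    p_exact <- rank_sum_test(x, y)$p
    p_approx <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("Fisher tests match the hypergeometric enumeration oracle", {
  f <- fisher_2x2(3, 1, 1, 3)
  expect_equal(f$p, 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_2x2(0, 5, 0, 7)$p, 1)
  expect_error(fisher_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("TE-family enrichment uses the upper-tail hypergeometric", {
  tes <- tibble::tibble(
    te_id = sprintf("te%02d", 1:10), chrom = "c",
    start = seq(0L, 9000L, by = 1000L),
    end = seq(0L, 9000L, by = 1000L) + 500L,
    family = c(rep("LTR/Gypsy", 4), rep("LINE", 6)),
    superfamily = c(rep("LTR", 4), rep("LINE", 6)))
  ann <- genome_annotation(
    tibble::tibble(gene_id = character(), chrom = character(),
                   strand = character(), start = integer(), end = integer(),
                   tss = integer()),
    tibble::tibble(gene_id = character(), type = character(),
                   chrom = character(), strand = character(),
                   start = integer(), end = integer()),
    tes)
  # EPICATs inside all 4 Gypsy TEs plus 1 LINE: n = 5, k(Gypsy) = 4
  ep <- tibble::tibble(chrom = "c",
                       dominant_pos = c(100L, 1100L, 2100L, 3100L, 4100L))
  enr <- te_epicat_enrichment(ep, ann)
  gyp <- enr[enr$family == "LTR/Gypsy", ]
  expect_equal(gyp[, c("K", "k", "n", "N")],
               tibble::tibble(K = 4L, k = 4L, n = 5L, N = 10L))
  expect_equal(gyp$p, 6 / 252, tolerance = 1e-12)
  # k = 0 has upper-tail p = 1
  none <- te_epicat_enrichment(tibble::tibble(chrom = "c",
                                              dominant_pos = 999999L), ann)
  expect_true(all(none$p == 1))
})

test_that("neighbor impact honors the radius and suppression flag", {
  annotated <- tibble::tibble(
    cluster_id = c("ep", "n_near", "n_far", "n_edge"),
    chrom = "c",
    strand = "+",
    dominant_pos = c(10000L, 12999L, 13001L, 7001L),
    feature_class = c("INTERGENIC", "PROMOTER", "PROMOTER", "UTR5"),
    annotated = c("NON_ANNOTATED", rep("ANNOTATED", 3)))
  samples <- tibble::tibble(sample_id = c("wt_1", "wt_2", "m_1", "m_2"),
                            genotype = c("wt", "wt", "mut", "mut"))
  expr <- tidyr::expand_grid(cluster_id = annotated$cluster_id,
                             sample_id = samples$sample_id)
  expr$tpm <- 5
  expr$tpm[expr$cluster_id == "ep" & grepl("wt", expr$sample_id)] <- 0
  # n_near is silenced in the mutant
  expr$tpm[expr$cluster_id == "n_near" & grepl("m_", expr$sample_id)] <- 0
  calls <- tibble::tibble(cluster_id = "ep", genotype = "mut",
                          epicat = TRUE)
  out <- neighbor_impact(calls, annotated, expr, samples, radius = 3000L)
  expect_setequal(out$neighbors$neighbor_cluster_id, c("n_near", "n_edge"))
  expect_true(out$neighbors$suppressed[
    out$neighbors$neighbor_cluster_id == "n_near"])
  expect_false(out$neighbors$suppressed[
    out$neighbors$neighbor_cluster_id == "n_edge"])
  expect_equal(out$neighbors$distance[
    out$neighbors$neighbor_cluster_id == "n_near"], 2999L)

  # an EPICAT with no qualifying neighbor is absent from the table
  lonely <- tibble::tibble(cluster_id = "ep2", genotype = "mut",
                           epicat = TRUE)
  ann2 <- dplyr::bind_rows(annotated,
                           tibble::tibble(cluster_id = "ep2", chrom = "c2",
                                          strand = "+",
                                          dominant_pos = 500L,
                                          feature_class = "INTERGENIC",
                                          annotated = "NON_ANNOTATED"))
  expr2 <- dplyr::bind_rows(
    expr, tidyr::expand_grid(cluster_id = "ep2",
                             sample_id = samples$sample_id,
                             tpm = 0))
  out2 <- neighbor_impact(lonely, ann2, expr2, samples, radius = 3000L)
  expect_equal(nrow(out2$neighbors), 0)
})

test_that("random small instances match the enumeration oracles", {
  set.seed(606)
  for (i in 1:25) {
    tb <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tb) == 0) tb[1, 1] <- 1
    got <- fisher_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(got$p, fisher_oracle(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-9)
  }
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:100, n1); y <- sample(setdiff(1:100, x), n2)
    got <- rank_sum_test(x, y)
    ora <- mw_oracle(x, y)
    expect_equal(unname(got$U), ora$U)
    expect_equal(got$p, ora$p, tolerance = 1e-9)
  }
  for (i in 1:25) {
    N <- sample(5:40, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 hyper_tail_oracle(k, K, n, N), tolerance = 1e-9)
  }
})
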