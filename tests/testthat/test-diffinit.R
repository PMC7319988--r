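test_that("size factors recover scaling and match direct recomputation", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
  sf <- size_factors(m)
  expect_equal(sf[2] / sf[1], 2, ignore_attr = TRUE)
  ident <- matrix(rep(c(5, 9, 13), 3), ncol = 3)
  expect_equal(unname(size_factors(ident)), rep(1, 3))

  set.seed(404)
  m <- matrix(rnbinom(200, mu = 40, size = 5), ncol = 4)
  sf <- size_factors(m)
  # independent median-of-ratios recomputation, loop form
  pos <- which(apply(m, 1, function(r) all(r > 0)))
  ref <- sapply(pos, function(r) prod(m[r, ])^(1 / ncol(m)))
  sf2 <- sapply(seq_len(ncol(m)), function(j) median(m[pos, j] / ref))
  expect_equal(unname(sf), unname(sf2), tolerance = 1e-10)

  zeros <- matrix(c(0, 5, 3, 0), ncol = 2)
  expect_warning(size_factors(zeros), "library-total")
})

test_that("the NB Wald test behaves at the null and at strong signal", {
  null <- nb_diff_test(c(10, 10, 10, 10), c("wt", "wt", "m", "m"))
  expect_equal(null$log2fc, 0)
  expect_equal(null$p, 1, tolerance = 1e-12)

  strong <- nb_diff_test(c(0, 0, 200, 180), c("wt", "wt", "m", "m"),
                         dispersion = 0.1)
  expect_lt(strong$p, 1e-6)
  expect_gt(strong$log2fc, 5)

  # likelihood-ratio oracle on the same NB model agrees it is extreme
  ll <- function(cnt, mu, disp) sum(dnbinom(cnt, mu = mu, size = 1 / disp,
                                            log = TRUE))
  cnt <- c(0, 0, 200, 180); grp <- c(1, 1, 2, 2)
  mu0 <- mean(cnt)
  l0 <- ll(cnt, mu0, 0.1)
  l1 <- ll(cnt[1:2], max(mean(cnt[1:2]), 1e-8), 0.1) +
    ll(cnt[3:4], mean(cnt[3:4]), 0.1)
  p_lr <- pchisq(2 * (l1 - l0), df = 1, lower.tail = FALSE)
  expect_lt(p_lr, 1e-6)

  allz <- nb_diff_test(c(0, 0, 0, 0), c("wt", "wt", "m", "m"))
  expect_equal(allz$p, 1)
  expect_equal(allz$log2fc, 0)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # padj >= p always
  set.seed(8)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("EPICAT calling applies all three gates", {
  annotated <- tibble::tibble(
    cluster_id = c("c1", "c2", "c3", "c4"),
    annotated = c("NON_ANNOTATED", "ANNOTATED", "NON_ANNOTATED",
                  "NON_ANNOTATED"))
  de <- tibble::tibble(
    cluster_id = c("c1", "c2", "c3", "c4"),
    genotype = "mut",
    log2fc = c(5, 5, 5, 5),
    p = 0.001, padj = c(0.05, 0.05, 0.05, 0.5))
  samples <- tibble::tibble(sample_id = c("wt_1", "wt_2", "m_1", "m_2"),
                            genotype = c("wt", "wt", "mut", "mut"))
  expr <- tidyr::expand_grid(cluster_id = annotated$cluster_id,
                             sample_id = samples$sample_id)
  expr$tpm <- 0
  expr$tpm[expr$sample_id %in% c("m_1", "m_2")] <- 4
  expr$tpm[expr$cluster_id == "c3" & expr$sample_id == "wt_1"] <- 0.5

  calls <- call_epicats(annotated, de, expr, samples)
  expect_equal(sort(calls$cluster_id), c("c1", "c3", "c4"))  # only NON_ANNOTATED
  expect_true(calls$epicat[calls$cluster_id == "c1"])
  # c2 ANNOTATED: excluded; c3 expressed in a WT replicate: not de novo
  expect_false(calls$epicat[calls$cluster_id == "c3"])
  expect_false(calls$de_novo[calls$cluster_id == "c3"])
  # c4 not significant
  expect_false(calls$epicat[calls$cluster_id == "c4"])
  expect_true(calls$de_novo[calls$cluster_id == "c4"])

  # gates are individually switchable
  no_sig <- call_epicats(annotated, de, expr, samples,
                         require_significant = FALSE)
  expect_true(no_sig$epicat[no_sig$cluster_id == "c4"])

  # raising detect_tpm is monotone: calls can only be added
  relaxed <- call_epicats(annotated, de, expr, samples, detect_tpm = 1)
  expect_true(all(calls$cluster_id[calls$epicat] %in%
                    relaxed$cluster_id[relaxed$epicat]))
})

test_that("the convergence matrix counts shared EPICATs symmetrically", {
  calls <- tibble::tibble(
    cluster_id = c("1", "2", "3", "2", "3", "4"),
    genotype = c("A", "A", "A", "B", "B", "B"))
  m <- convergence_matrix(calls)
  expect_equal(m["A", "B"], 2L)
  expect_equal(diag(m), c(A = 3L, B = 3L))

  dis <- convergence_matrix(tibble::tibble(
    cluster_id = c("1", "2"), genotype = c("A", "B")))
  expect_equal(dis["A", "B"], 0L)

  set.seed(55)
  for (i in 1:100) {
    calls <- tibble::tibble(
      cluster_id = as.character(sample(1:20, 12, replace = TRUE)),
      genotype = sample(c("A", "B", "C"), 12, replace = TRUE))
    calls <- dplyr::distinct(calls)
    m <- convergence_matrix(calls)
    expect_identical(m, t(m))
  }
})

test_that("differential initiation tidiers summarize the fit", {
  res <- small_sim_result()
  td <- tidy(res$de)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("cluster_id", "genotype", "log2fc", "p", "padj") %in%
                    names(td)))
  expect_true(all(td$padj >= td$p, na.rm = TRUE))
  gl <- glance(res$de)
  expect_equal(sort(unique(gl$genotype)), sort(unique(td$genotype)))
  expect_true(all(gl$n_significant <= gl$n_tested))
  # EPICAT calls are a subset of NON-ANNOTATED clusters
  non_ann <- res$annotated$cluster_id[res$annotated$annotated ==
                                        "NON_ANNOTATED"]
  expect_true(all(res$epicats$cluster_id %in% non_ann))
})
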