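test_that("cluster pruning applies stability, length and singleton rules", {
  # singleton pruning around the keep-above threshold
  cand1 <- paraclu(50L, 0.2)
  expect_equal(nrow(select_clusters(cand1, 50L, 0.2)), 0)
  cand2 <- paraclu(50L, 0.4)
  kept <- select_clusters(cand2, 50L, 0.4)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$dominant_pos, 50L)

  # spans longer than max_length are discarded, not trimmed
  pos <- c(0L, 150L); tpm <- c(5, 5)
  cand <- paraclu(pos, tpm)
  wide <- select_clusters(cand, pos, tpm, max_length = 100L,
                          remove_singletons = FALSE)
  expect_true(all(wide$end - wide$start <= 100))
  expect_false(any(wide$n_sites == 2))

  # dominant CTSS is the argmax site
  pos <- c(10L, 11L, 12L); tpm <- c(10, 20, 5)
  out <- select_clusters(paraclu(pos, tpm), pos, tpm, min_stability = 1)
  expect_true(11L %in% out$dominant_pos)
})

test_that("dominant-site ties break toward the midpoint then lower coordinate", {
  pos <- c(0L, 10L, 11L, 30L); tpm <- c(5, 5, 5, 5)
  d <- epicat:::dominant_site(pos, tpm)
  # midpoint is 15; nearest tied sites are 11
  expect_equal(pos[d], 11L)
  pos2 <- c(0L, 10L, 20L); tpm2 <- c(5, 5, 5)
  expect_equal(pos2[epicat:::dominant_site(pos2, tpm2)], 10L)
  pos3 <- c(0L, 9L, 11L, 20L); tpm3 <- c(1, 5, 5, 1)
  expect_equal(pos3[epicat:::dominant_site(pos3, tpm3)], 9L)
})

test_that("interquantile width follows the cumulative-signal definition", {
  pm <- iq_width(42L, 10)
  expect_equal(pm$width, 1L)
  expect_equal(pm$shape_class, "NP")

  unif <- iq_width(0:99, rep(1, 100))
  expect_equal(unif$width, 81L)
  expect_equal(unif$shape_class, "WP")

  two <- iq_width(c(0L, 5L), c(1, 1))
  expect_equal(two$width, 6L)

  # invariant under uniform scaling of tpm
  set.seed(5)
  pos <- sort(sample(0:200, 15)); tpm <- runif(15, 0.1, 9)
  expect_equal(iq_width(pos, tpm)$width, iq_width(pos, tpm * 1000)$width)
})

test_that("retained clusters are disjoint within sample and strand", {
  set.seed(77)
  tr <- make_tracks(list(
    a = data.frame(chrom = "c", pos = sort(sample(1:3000, 120)),
                   strand = "+", count = sample(1:60, 120, replace = TRUE)),
    b = data.frame(chrom = "c", pos = sort(sample(1:3000, 120)),
                   strand = "+", count = sample(1:60, 120, replace = TRUE))))
  tc <- cluster_tags(tr, nr_pass = 1L, min_stability = 1)
  by_grp <- split(tc, paste(tc$sample_id, tc$chrom, tc$strand))
  for (g in by_grp) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) {
      expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }
  }
})

test_that("consensus aggregation merges within the distance cutoff", {
  tc <- dplyr::bind_rows(
    tibble::tibble(sample_id = "A", chrom = "c", strand = "+", start = 100L,
                   end = 120L, n_sites = 2L, total_tpm = 5,
                   dominant_pos = 110L, dominant_tpm = 3, min_density = 1,
                   max_density = 10, stability = 10, iq_width = 5L,
                   shape_class = "NP",
                   sites = list(tibble::tibble(pos = c(105L, 110L),
                                               tpm = c(2, 3)))),
    tibble::tibble(sample_id = "B", chrom = "c", strand = "+", start = 180L,
                   end = 200L, n_sites = 1L, total_tpm = 4,
                   dominant_pos = 190L, dominant_tpm = 4, min_density = 1,
                   max_density = 10, stability = 10, iq_width = 1L,
                   shape_class = "NP",
                   sites = list(tibble::tibble(pos = 190L, tpm = 4))))
  one <- aggregate_consensus(tc, max_dist = 100L, tpm_threshold = 0.3)
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 100L)
  expect_equal(one$end, 200L)
  expect_equal(one$dominant_pos, 190L)  # pooled argmax

  two <- aggregate_consensus(tc, max_dist = 50L, tpm_threshold = 0.3)
  expect_equal(nrow(two), 2)

  # low-signal consensus removed
  weak <- dplyr::mutate(tc, total_tpm = 0.2,
                        sites = lapply(sites, function(s)
                          dplyr::mutate(s, tpm = tpm / 100)))
  expect_equal(nrow(aggregate_consensus(weak, tpm_threshold = 0.3)), 0)
})

test_that("consensus aggregation is invariant to sample input order", {
  set.seed(13)
  mk <- function(sid, offset) {
    pos <- sort(sample(1:2000, 40)) + offset
    tr <- data.frame(chrom = "c", pos = pos, strand = "+",
                     count = sample(5:50, 40, replace = TRUE))
    tr
  }
  tr <- make_tracks(list(a = mk("a", 0L), b = mk("b", 3L), c = mk("c", 7L)))
  tc <- cluster_tags(tr, nr_pass = 1L, min_stability = 1)
  fwd <- aggregate_consensus(tc)
  rev <- aggregate_consensus(tc[rev(seq_len(nrow(tc))), ])
  expect_equal(fwd$start, rev$start)
  expect_equal(fwd$end, rev$end)
  expect_equal(fwd$dominant_pos, rev$dominant_pos)
})

test_that("quantification sums all CTSSs inside spans, filtered or not", {
  cons <- tibble::tibble(cluster_id = "cc_00001", chrom = "c", strand = "+",
                         start = 100L, end = 120L, dominant_pos = 105L,
                         dominant_tpm_pooled = 1, n_samples = 1L)
  tr <- make_tracks(list(
    a = data.frame(chrom = "c", pos = c(105L, 110L, 500L), strand = "+",
                   count = c(5L, 3L, 2L)),
    b = data.frame(chrom = "c", pos = 500L, strand = "+", count = 9L)))
  q <- quantify_consensus(cons, tr)
  expect_equal(nrow(q), 2)
  expect_equal(q$count[q$sample_id == "a"], 8L)
  expect_equal(q$count[q$sample_id == "b"], 0L)
  # conservation bound: per-sample sum over consensus <= library total
  lt <- library_totals(tr)
  agg <- tapply(q$count, q$sample_id, sum)
  expect_true(all(agg <= lt$library_total[match(names(agg), lt$sample_id)]))
  # opposite-strand signal is not counted
  trm <- make_tracks(list(
    a = data.frame(chrom = "c", pos = 105L, strand = "-", count = 5L)))
  expect_equal(quantify_consensus(cons, trm)$count, 0L)
})
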