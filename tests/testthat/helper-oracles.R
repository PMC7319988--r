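# Independent oracles and shared fixtures, built in code.

# Brute-force density-stability clustering oracle. For every segment the
# dissolve density is the minimum over ALL proper subsegments sharing an
# endpoint of (sum(S) - sum(R)) / (span(S) - span(R)); the candidate
# family is generated by sweeping the density upward from 0: a segment's
# interval runs from the density at which its parent dissolves to the
# density at which it dissolves itself (empty intervals are dropped).
paraclu_oracle <- function(pos, tpm) {
  sum_seg <- function(i, j) sum(tpm[i:j])
  dissolve <- function(i, j) {
    if (i == j) return(list(d = Inf, split = NA))
    best <- Inf; split <- NA
    sS <- sum_seg(i, j); eS <- pos[j] - pos[i] + 1
    for (k in i:(j - 1)) {
      r1 <- (sS - sum_seg(k + 1, j)) / (eS - (pos[j] - pos[k + 1] + 1))
      if (r1 < best) { best <- r1; split <- k }
      r2 <- (sS - sum_seg(i, k)) / (eS - (pos[k] - pos[i] + 1))
      if (r2 < best) { best <- r2; split <- k }
    }
    list(d = best, split = split)
  }
  out <- NULL
  rec <- function(i, j, dmin) {
    dd <- dissolve(i, j)
    if (dd$d > dmin) {
      out <<- rbind(out, data.frame(first = i, last = j,
                                    min_density = dmin,
                                    max_density = dd$d))
    }
    if (i == j) return()
    d2 <- max(dd$d, dmin)
    rec(i, dd$split, d2)
    rec(dd$split + 1, j, d2)
  }
  rec(1, length(pos), 0)
  out[order(out$first, -out$last), , drop = FALSE]
}

expect_paraclu_matches_oracle <- function(pos, tpm, tol = 1e-9) {
  a <- as.data.frame(paraclu(pos, tpm))
  b <- paraclu_oracle(pos, tpm)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$first, b$first)
  expect_equal(a$last, b$last)
  same_num <- function(x, y) abs(x - y) < tol | x == y
  expect_true(all(same_num(a$min_density, b$min_density)))
  expect_true(all(same_num(a$max_density, b$max_density)))
  invisible(a)
}

# exact two-sided Mann-Whitney by enumeration of all group assignments
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(p, 1))
}

# two-sided Fisher p by enumerating tables with fixed margins
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  lo <- max(0, k - nn); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by direct summation of the pmf
hyper_tail_oracle <- function(k, K, n, N) {
  xs <- k:min(K, n)
  if (k <= max(0, n - (N - K))) return(1)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# small hand-built annotation used across annotation/EPICAT tests:
# chrA, one + gene, one - gene, one TE, on 50 kb
toy_annotation <- function() {
  genes <- tibble::tibble(
    gene_id = c("gP", "gM"),
    chrom = "chrA",
    strand = c("+", "-"),
    start = c(5000L, 20000L), end = c(7000L, 22000L),
    tss = c(5000L, 21999L))
  features <- tibble::tibble(
    gene_id = c("gP", "gP", "gP", "gP", "gM", "gM", "gM"),
    type = c("utr5", "exon", "exon", "utr3", "utr5", "exon", "utr3"),
    chrom = "chrA",
    strand = c(rep("+", 4), rep("-", 3)),
    start = c(5000L, 5000L, 6000L, 6800L, 21800L, 20000L, 20000L),
    end = c(5200L, 5800L, 7000L, 7000L, 22000L, 22000L, 20150L))
  tes <- tibble::tibble(
    te_id = "te1", chrom = "chrA", start = 30000L, end = 31000L,
    family = "LTR/Gypsy", superfamily = "LTR")
  genome_annotation(genes, features, tes)
}

# normalized multi-sample track from a compact description:
# list of per-sample data frames with chrom/pos/strand/count
make_tracks <- function(per_sample, genotypes = NULL) {
  ids <- names(per_sample)
  out <- dplyr::bind_rows(lapply(ids, function(sid) {
    df <- tibble::as_tibble(per_sample[[sid]])
    df$sample_id <- sid
    df$genotype <- if (is.null(genotypes)) NA_character_ else genotypes[[sid]]
    df$replicate <- 1L
    df[, c("sample_id", "genotype", "replicate", "chrom", "pos", "strand",
           "count")]
  }))
  tpm_normalize(out)
}

# shared small synthetic study, computed once per test run
small_sim_env <- new.env()
small_sim <- function() {
  if (is.null(small_sim_env$sim)) {
    cfg <- sim_config(n_chroms = 1L, chrom_length = 300000L, n_genes = 90L,
                      n_tes = 40L, n_regular_tss = 80L, n_cryptic_tss = 16L,
                      seed = 11L)
    small_sim_env$cfg <- cfg
    small_sim_env$sim <- simulate_study(cfg)
  }
  list(cfg = small_sim_env$cfg, sim = small_sim_env$sim)
}

small_sim_result <- function() {
  if (is.null(small_sim_env$res)) {
    ss <- small_sim()
    small_sim_env$res <- epicat_pipeline(ss$sim$tracks, ss$sim$annotation,
                                         ss$sim$samples)
  }
  small_sim_env$res
}
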