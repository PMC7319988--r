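#' Transcription directionality around a TSS
#'
#' `D = (S_sense - S_anti) / (S_sense + S_anti)` where the two terms sum
#' TPM on the TSS strand and the opposite strand within `pos +/- window`.
#' `D = 1` means fully unidirectional sense transcription; missing (NA)
#' when both sums are 0.
#'
#' @param tracks Normalized CTSS tibble (pooled over the samples given).
#' @param tss Tibble with `chrom`, `pos`, `strand` (one row per TSS).
#' @param window Half-window in bp (default 100; must be > 0).
#' @return Numeric vector of directionality scores, one per TSS row.
#' @export
directionality_score <- function(tracks, tss, window = 100L) {
  assert_that(window > 0, "window must be > 0")
  vapply(seq_len(nrow(tss)), function(i) {
    near <- tracks$chrom == tss$chrom[i] &
      abs(tracks$pos - tss$pos[i]) <= window
    s_sense <- sum(tracks$tpm[near & tracks$strand == tss$strand[i]])
    s_anti <- sum(tracks$tpm[near & tracks$strand != tss$strand[i]])
    if (s_sense + s_anti == 0) return(NA_real_)
    (s_sense - s_anti) / (s_sense + s_anti)
  }, numeric(1))
}

#' Read a cytosine methylation table
#'
#' TAB-separated text: `chrom pos strand context meth total`, 0-based
#' positions, contexts CG/CHG/CHH.
#'
#' @param path File path.
#' @return Methylation tibble.
#' @export
read_methylation <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "pos", "strand", "context",
                                 "meth", "total"),
                   colClasses = c("character", "integer", "character",
                                  "character", "integer", "integer"))
  df <- as_tibble(df)
  assert_that(all(df$context %in% c("CG", "CHG", "CHH")),
              "context must be CG/CHG/CHH")
  assert_that(all(df$meth >= 0 & df$total >= df$meth),
              "need total >= meth >= 0")
  df
}

#' Coverage-weighted methylation level in a window around a TSS
#'
#' Sums methylated and total reads over the cytosines of the requested
#' context within the odd-width window centered on each dominant CTSS
#' (101 bp by default: `pos - 50 .. pos + 50`); level = meth / total,
#' missing when no covered cytosine lies in the window. Cytosines on both
#' strands contribute.
#'
#' @param methyl Methylation tibble (see [read_methylation()]).
#' @param tss Tibble with `chrom`, `pos`.
#' @param window Odd window width in bp (default 101).
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`, or `"all"`.
#' @return Numeric vector of levels in `[0, 1]` (NA when uncovered).
#' @export
methylation_level <- function(methyl, tss, window = 101L, context = "CG") {
  assert_that(window %% 2 == 1, "window must be odd so the TSS is the center base")
  half <- (window - 1L) %/% 2L
  if (context != "all") {
    methyl <- filter(methyl, .data$context == !!context)
  }
  vapply(seq_len(nrow(tss)), function(i) {
    sel <- methyl$chrom == tss$chrom[i] &
      methyl$pos >= tss$pos[i] - half & methyl$pos <= tss$pos[i] + half
    if (!any(sel)) return(NA_real_)
    sum(methyl$meth[sel]) / sum(methyl$total[sel])
  }, numeric(1))
}

#' Paired two-sided Student t-test
#'
#' @param x,y Equal-length numeric vectors (paired observations).
#' @return List with `t`, `p`, `df`, `degenerate` (TRUE when all paired
#'   differences are identical, in which case `t`/`p` are NA).
#' @export
paired_diff_test <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(length(x) >= 2, "need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1,
                degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact p for small samples (both groups <= 10, no ties), normal
#' approximation with tie correction otherwise.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `U` (statistic for `x`) and `p`.
#' @export
rank_sum_test <- function(x, y) {
  assert_that(length(x) > 0 && length(y) > 0, "both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 10 && length(y) <= 10 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p by summing hypergeometric probabilities no larger than that of
#' the observed table.
#'
#' @param a,b,c,d Cell counts (row-wise).
#' @return List with `odds_ratio` (conditional MLE) and `p`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  assert_that(all(cells >= 0), "cell counts must be non-negative")
  assert_that(sum(cells) > 0, "at least one positive margin required")
  ft <- fisher.test(matrix(cells, nrow = 2, byrow = TRUE))
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' TE-family enrichment among EPICAT-harboring TEs
#'
#' A TE harbors an EPICAT when an EPICAT's dominant CTSS lies within the
#' TE span. For each family the upper-tail hypergeometric p-value
#' `P(X >= k)` is computed with `N` = all TEs, `K` = TEs of the family,
#' `n` = EPICAT-harboring TEs, `k` = those of the family. Families with
#' fewer than `low_power_below` genome copies are flagged.
#'
#' @param epicats Tibble of EPICAT positions: `chrom`, `dominant_pos`.
#' @param annotation `genome_annotation` (TE table with `family`).
#' @param low_power_below Copy-number flag threshold (default 5).
#' @return Tibble per family: `family`, `K`, `k`, `n`, `N`, `p`,
#'   `low_power`.
#' @export
te_epicat_enrichment <- function(epicats, annotation, low_power_below = 5L) {
  tes <- annotation$tes
  harboring <- vapply(seq_len(nrow(tes)), function(i) {
    any(epicats$chrom == tes$chrom[i] &
          epicats$dominant_pos >= tes$start[i] &
          epicats$dominant_pos < tes$end[i])
  }, logical(1))
  N <- nrow(tes)
  n <- sum(harboring)
  tes %>%
    mutate(harboring = harboring) %>%
    group_by(.data$family) %>%
    summarise(K = n(), k = sum(.data$harboring), .groups = "drop") %>%
    mutate(n = n, N = N,
           p = phyper(.data$k - 1, .data$K, N - .data$K, n,
                      lower.tail = FALSE),
           low_power = .data$K < low_power_below) %>%
    arrange(.data$p)
}

#' Impact of EPICAT activation on neighboring regular TSSs
#'
#' Neighbors are wild-type-active consensus clusters (mean WT TPM at
#' least `detect_tpm`) classified PROMOTER or UTR5 whose dominant CTSS
#' lies within `radius` bp of an EPICAT's dominant CTSS. Per genotype a
#' paired two-sided t-test compares the neighbors' WT and mutant mean
#' TPM, and a neighbor is flagged `suppressed` when its expression is 0
#' in every replicate of the mutant.
#'
#' @param calls EPICAT call tibble (rows with `epicat = TRUE` used).
#' @param annotated Annotated consensus tibble (`cluster_id`, `chrom`,
#'   `dominant_pos`, `feature_class`).
#' @param expr Long expression tibble (`cluster_id`, `sample_id`, `tpm`).
#' @param samples Sample metadata (`sample_id`, `genotype`).
#' @param wt Wild-type genotype label.
#' @param radius Neighborhood radius in bp (default 3000).
#' @param detect_tpm WT activity threshold (default 0.1 mean TPM).
#' @return List with `neighbors` (tibble: `epicat_id`, `genotype`,
#'   `neighbor_cluster_id`, `distance`, `wt_tpm`, `mut_tpm`,
#'   `suppressed`) and `tests` (per-genotype paired-t summary).
#' @export
neighbor_impact <- function(calls, annotated, expr, samples, wt = "wt",
                            radius = 3000L, detect_tpm = 0.1) {
  if ("epicat" %in% names(calls)) calls <- filter(calls, .data$epicat)
  mean_tpm <- expr %>%
    left_join(distinct(samples, .data$sample_id, .data$genotype),
              by = "sample_id") %>%
    group_by(.data$cluster_id, .data$genotype) %>%
    summarise(mean_tpm = mean(.data$tpm), all_zero = all(.data$tpm == 0),
              .groups = "drop")
  wt_active <- mean_tpm %>%
    filter(.data$genotype == wt, .data$mean_tpm >= detect_tpm) %>%
    pull(.data$cluster_id)
  cand <- annotated %>%
    filter(.data$feature_class %in% c("PROMOTER", "UTR5"),
           .data$cluster_id %in% wt_active)
  ep_pos <- calls %>%
    left_join(select(annotated, "cluster_id", "chrom", "dominant_pos"),
              by = "cluster_id")
  neighbors <- purrr::map_dfr(seq_len(nrow(ep_pos)), function(i) {
    sel <- cand$chrom == ep_pos$chrom[i] &
      abs(cand$dominant_pos - ep_pos$dominant_pos[i]) <= radius &
      cand$cluster_id != ep_pos$cluster_id[i]
    if (!any(sel)) return(NULL)
    tibble(epicat_id = ep_pos$cluster_id[i], genotype = ep_pos$genotype[i],
           neighbor_cluster_id = cand$cluster_id[sel],
           distance = abs(cand$dominant_pos[sel] -
                            ep_pos$dominant_pos[i]))
  })
  if (is.null(neighbors) || nrow(neighbors) == 0) {
    return(list(neighbors = tibble(epicat_id = character(),
                                   genotype = character(),
                                   neighbor_cluster_id = character(),
                                   distance = integer(), wt_tpm = numeric(),
                                   mut_tpm = numeric(),
                                   suppressed = logical()),
                tests = tibble(genotype = character(), n = integer(),
                               t = numeric(), p = numeric())))
  }
  neighbors <- neighbors %>%
    left_join(mean_tpm %>% filter(.data$genotype == wt) %>%
                select("cluster_id", wt_tpm = "mean_tpm"),
              by = c(neighbor_cluster_id = "cluster_id")) %>%
    left_join(mean_tpm %>%
                select("cluster_id", "genotype", mut_tpm = "mean_tpm",
                       mut_all_zero = "all_zero"),
              by = c(neighbor_cluster_id = "cluster_id", "genotype")) %>%
    mutate(suppressed = .data$mut_all_zero) %>%
    select(-"mut_all_zero")
  tests <- neighbors %>%
    distinct(.data$genotype, .data$neighbor_cluster_id, .keep_all = TRUE) %>%
    group_by(.data$genotype) %>%
    summarise(n = n(),
              t = if (n() >= 2 && sd(.data$wt_tpm - .data$mut_tpm) > 0)
                paired_diff_test(.data$wt_tpm, .data$mut_tpm)$t else NA_real_,
              p = if (n() >= 2 && sd(.data$wt_tpm - .data$mut_tpm) > 0)
                paired_diff_test(.data$wt_tpm, .data$mut_tpm)$p else NA_real_,
              .groups = "drop")
  list(neighbors = neighbors, tests = tests)
}
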