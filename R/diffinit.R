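#' Median-of-ratios size factors
#'
#' Classic median-of-ratios normalization: the reference is the geometric
#' mean of each cluster's counts over clusters positive in every sample;
#' a sample's size factor is the median of its count-to-reference ratios.
#' If no cluster is positive in all samples the function falls back to
#' library-total ratios (scaled to geometric mean 1) with a warning.
#'
#' @param counts Integer matrix, clusters x samples.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warn("no cluster with positive counts in all samples; falling back to library-total size factors")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
    return(sf)
  }
  lref <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(cnt) {
    median(exp(log(cnt) - lref))
  })
  sf
}

#' Moderated per-cluster NB dispersion estimates
#'
#' Method-of-moments dispersion on normalized counts per cluster,
#' estimated within groups and shrunk toward the trimmed mean of the
#' per-cluster estimates (weights: residual degrees of freedom vs
#' `prior_df`).
#'
#' @param counts Clusters x samples count matrix.
#' @param sf Size factors (length `ncol(counts)`).
#' @param groups Factor/character group labels per sample.
#' @param prior_df Prior degrees of freedom for shrinkage (default 10).
#' @param trim Trim fraction for the pooled dispersion (default 0.2).
#' @param min_disp Dispersion floor (default 1e-8).
#' @return Numeric vector of per-cluster dispersions.
#' @export
estimate_dispersions <- function(counts, sf, groups, prior_df = 10,
                                 trim = 0.2, min_disp = 1e-8) {
  counts <- as.matrix(counts)
  z <- sweep(counts, 2, sf, "/")
  groups <- as.character(groups)
  glev <- unique(groups)
  inv_s <- mean(1 / sf)
  raw <- vapply(seq_len(nrow(z)), function(r) {
    ss <- 0; df <- 0; mu_all <- mean(z[r, ])
    for (g in glev) {
      zz <- z[r, groups == g]
      if (length(zz) >= 2) {
        ss <- ss + sum((zz - mean(zz))^2)
        df <- df + length(zz) - 1
      }
    }
    if (df == 0 || mu_all <= 0) return(NA_real_)
    s2 <- ss / df
    max((s2 - mu_all * inv_s) / mu_all^2, min_disp)
  }, numeric(1))
  informative <- !is.na(raw) & rowMeans(z) >= 1
  disp_pool <- if (any(informative)) {
    mean(raw[informative], trim = trim)
  } else 0.1
  df_res <- length(groups) - length(glev)
  shrunk <- (df_res * ifelse(is.na(raw), disp_pool, raw) +
               prior_df * disp_pool) / (df_res + prior_df)
  pmax(shrunk, min_disp)
}

#' Negative-binomial Wald test for one cluster
#'
#' Two-group comparison of a cluster's raw counts on the NB model with a
#' supplied dispersion. Group means are estimated from size-factor
#' normalized counts (with a small pseudo-mean `pseudo` stabilizing the
#' log at zero counts); the Wald statistic compares the log2 fold change
#' against its delta-method standard error, two-sided normal p.
#'
#' @param counts Integer vector of raw counts for one cluster.
#' @param groups Two-level group labels aligned with `counts`; the first
#'   level of `ref` is the reference (wild type).
#' @param sf Size factors aligned with `counts`.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param ref Reference group label; defaults to the first label.
#' @param pseudo Pseudo-mean added to each group mean (default 0.5
#'   normalized counts).
#' @return One-row tibble: `base_mean_ref`, `base_mean_alt`, `log2fc`,
#'   `se`, `stat`, `p`.
#' @export
nb_diff_test <- function(counts, groups, sf = rep(1, length(counts)),
                         dispersion = 0.1, ref = NULL, pseudo = 0.5) {
  groups <- as.character(groups)
  glev <- unique(groups)
  assert_that(length(glev) == 2, "nb_diff_test needs exactly two groups")
  ref <- ref %||% glev[1]
  alt <- setdiff(glev, ref)
  if (all(counts == 0)) {
    return(tibble(base_mean_ref = 0, base_mean_alt = 0, log2fc = 0,
                  se = NA_real_, stat = 0, p = 1))
  }
  z <- counts / sf
  grp_stats <- function(g) {
    idx <- which(groups == g)
    mu <- mean(z[idx]) + pseudo
    # Var(K_j / s_j) = mu_g / s_j + dispersion * mu_g^2 under the NB model
    v <- sum(mu / sf[idx] + dispersion * mu^2) / length(idx)^2
    list(mu = mu, se_log2 = sqrt(v) / (mu * log(2)))
  }
  a <- grp_stats(ref); b <- grp_stats(alt)
  lfc <- log2(b$mu) - log2(a$mu)
  se <- sqrt(a$se_log2^2 + b$se_log2^2)
  stat <- lfc / se
  tibble(base_mean_ref = a$mu - pseudo, base_mean_alt = b$mu - pseudo,
         log2fc = lfc, se = se, stat = stat,
         p = 2 * pnorm(-abs(stat)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (capped at 1, monotone).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential initiation across mutant genotypes
#'
#' Tests every consensus cluster for differential initiation in each
#' mutant genotype against wild type, one independent two-group NB Wald
#' test per genotype, using raw counts, median-of-ratios size factors and
#' moderated dispersions; BH correction is applied within genotype.
#'
#' @param expr Long expression tibble from [quantify_consensus()]
#'   (`cluster_id`, `sample_id`, `count`).
#' @param samples Sample metadata tibble: `sample_id`, `genotype`.
#' @param wt Wild-type genotype label (default `"wt"`).
#' @param prior_df,trim Dispersion moderation parameters.
#' @return An `epicat_de` object: tibble of `cluster_id`, `genotype`,
#'   `base_mean_wt`, `base_mean_mut`, `log2fc`, `se`, `stat`, `p`,
#'   `padj`, with the per-genotype size factors in
#'   `attr(x, "size_factors")`.
#' @export
diff_initiation <- function(expr, samples, wt = "wt", prior_df = 10,
                            trim = 0.2) {
  samples <- distinct(samples, .data$sample_id, .data$genotype)
  muts <- setdiff(unique(samples$genotype), wt)
  assert_that(length(muts) >= 1, "need at least one non-wild-type genotype")
  wide <- expr %>%
    select("cluster_id", "sample_id", "count") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$cluster_id

  sf_list <- list()
  out <- purrr::map_dfr(muts, function(m) {
    ids <- samples$sample_id[samples$genotype %in% c(wt, m)]
    sub <- mat[, ids, drop = FALSE]
    grp <- samples$genotype[match(ids, samples$sample_id)]
    sf <- size_factors(sub)
    sf_list[[m]] <<- sf
    disp <- estimate_dispersions(sub, sf, grp, prior_df = prior_df,
                                 trim = trim)
    res <- purrr::map_dfr(seq_len(nrow(sub)), function(r) {
      nb_diff_test(sub[r, ], grp, sf, disp[r], ref = wt)
    })
    res %>%
      mutate(cluster_id = rownames(sub), genotype = m,
             dispersion = disp, padj = bh_adjust(.data$p)) %>%
      rename(base_mean_wt = "base_mean_ref", base_mean_mut = "base_mean_alt") %>%
      select("cluster_id", "genotype", "base_mean_wt", "base_mean_mut",
             "log2fc", "se", "stat", "dispersion", "p", "padj")
  })
  structure(out, class = c("epicat_de", class(out)),
            size_factors = sf_list, wt = wt)
}

#' @export
tidy.epicat_de <- function(x, ...) {
  as_tibble(unclass_de(x))
}

#' @export
glance.epicat_de <- function(x, alpha = 0.1, ...) {
  tbl <- unclass_de(x)
  tbl %>%
    group_by(.data$genotype) %>%
    summarise(n_tested = n(),
              n_significant = sum(.data$padj <= alpha, na.rm = TRUE),
              n_up = sum(.data$padj <= alpha & .data$log2fc > 0, na.rm = TRUE),
              .groups = "drop") %>%
    mutate(alpha = alpha)
}

unclass_de <- function(x) {
  class(x) <- setdiff(class(x), "epicat_de")
  attr(x, "size_factors") <- NULL
  attr(x, "wt") <- NULL
  x
}

#' Generic tidiers
#'
#' `tidy()` returns the per-cluster test table; `glance()` a one-row-per-
#' genotype summary.
#'
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Call EPICATs (epigenetically induced consensus tag clusters)
#'
#' A consensus cluster is an EPICAT in a mutant genotype iff
#' (i) it is NON-ANNOTATED, (ii) it is significantly up-regulated in that
#' genotype (`padj <= alpha` and `log2fc > 0`), and (iii) it is activated
#' de novo: TPM below `detect_tpm` in every wild-type replicate. Gates
#' (ii) and (iii) can be switched off individually.
#'
#' @param annotated Annotated consensus tibble (needs `cluster_id`,
#'   `annotated`).
#' @param de An `epicat_de` object or its tidy tibble.
#' @param expr Long expression tibble with `cluster_id`, `sample_id`,
#'   `tpm`.
#' @param samples Sample metadata (`sample_id`, `genotype`).
#' @param wt Wild-type genotype label.
#' @param detect_tpm Wild-type detection threshold (default 0.1 TPM).
#' @param alpha Significance cutoff on `padj` (default 0.1).
#' @param require_significant,require_de_novo Toggle gates (ii)/(iii).
#' @return Tibble of calls: `cluster_id`, `genotype`, `wt_max_tpm`,
#'   `non_annotated`, `de_novo`, `significant`, `epicat` (all flags), with
#'   one row per (NON-ANNOTATED cluster, genotype) tested.
#' @export
call_epicats <- function(annotated, de, expr, samples, wt = "wt",
                         detect_tpm = 0.1, alpha = 0.1,
                         require_significant = TRUE,
                         require_de_novo = TRUE) {
  de_tbl <- if (inherits(de, "epicat_de")) unclass_de(de) else as_tibble(de)
  wt_ids <- samples$sample_id[samples$genotype == wt]
  wt_tpm <- expr %>%
    filter(.data$sample_id %in% wt_ids) %>%
    group_by(.data$cluster_id) %>%
    summarise(wt_max_tpm = max(.data$tpm), .groups = "drop")
  missing_de <- setdiff(annotated$cluster_id, unique(de_tbl$cluster_id))
  if (length(missing_de) > 0) {
    warn(sprintf("%d clusters lack differential-initiation results and are skipped",
                 length(missing_de)))
  }
  de_tbl %>%
    dplyr::inner_join(select(annotated, "cluster_id", "annotated"),
                      by = "cluster_id") %>%
    left_join(wt_tpm, by = "cluster_id") %>%
    mutate(wt_max_tpm = tidyr::replace_na(.data$wt_max_tpm, 0),
           non_annotated = .data$annotated == "NON_ANNOTATED",
           significant = !is.na(.data$padj) & .data$padj <= alpha &
             .data$log2fc > 0,
           de_novo = .data$wt_max_tpm < detect_tpm,
           epicat = .data$non_annotated &
             (!require_significant | .data$significant) &
             (!require_de_novo | .data$de_novo)) %>%
    filter(.data$non_annotated) %>%
    select("cluster_id", "genotype", "wt_max_tpm", "non_annotated",
           "de_novo", "significant", "epicat")
}

#' Mutant-convergence matrix of EPICAT calls
#'
#' Cell `(i, j)` holds the number of EPICATs shared by the two genotypes;
#' the diagonal holds per-genotype totals. The matrix is symmetric.
#'
#' @param calls EPICAT call tibble from [call_epicats()] (rows with
#'   `epicat = TRUE` are used), or any tibble with `cluster_id`,
#'   `genotype`.
#' @return Symmetric integer matrix, genotypes x genotypes.
#' @export
convergence_matrix <- function(calls) {
  if ("epicat" %in% names(calls)) calls <- filter(calls, .data$epicat)
  sets <- split(calls$cluster_id, calls$genotype)
  gts <- names(sets)
  m <- matrix(0L, length(gts), length(gts), dimnames = list(gts, gts))
  for (i in seq_along(gts)) {
    for (j in seq_along(gts)) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  m
}
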