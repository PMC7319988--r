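#' Density-stability (paraclu-style) clustering of one site list
#'
#' Given CTSS sites on a single chromosome and strand, returns all
#' candidate segments that are maximal-scoring segments of
#' `score(segment, d) = sum(tpm) - d * span` for some density `d >= 0`,
#' where `span = last_pos - first_pos + 1`. Each candidate carries the
#' infimum (`min_density`) and supremum (`max_density`) of the density
#' interval over which it is maximal; candidates form a laminar (nested)
#' family, computed by the weakest-prefix/weakest-suffix recursion.
#' Segments whose density interval is empty (ties) are not reported.
#' A lone site gets `min_density = 0`, `max_density = Inf` by convention.
#'
#' @param pos Integer vector of 0-based site positions, strictly increasing.
#' @param tpm Numeric vector of per-site TPM, all > 0.
#' @return Tibble with `first`, `last` (site indexes), `start`, `end`
#'   (0-based half-open span), `n_sites`, `total_tpm`, `min_density`,
#'   `max_density`, `stability`.
#' @export
paraclu <- function(pos, tpm) {
  n <- length(pos)
  assert_that(length(tpm) == n, "pos and tpm must have equal length")
  if (n == 0) {
    return(tibble(first = integer(), last = integer(), start = integer(),
                  end = integer(), n_sites = integer(), total_tpm = numeric(),
                  min_density = numeric(), max_density = numeric(),
                  stability = numeric()))
  }
  assert_that(all(tpm > 0), "all site tpm values must be > 0")
  assert_that(n == 1 || all(diff(pos) > 0),
              "site positions must be strictly increasing")

  cum <- c(0, cumsum(tpm))
  seg_sum <- function(i, j) cum[j + 1] - cum[i]

  res_first <- integer(0); res_last <- integer(0)
  res_min <- numeric(0); res_max <- numeric(0)

  # explicit stack: frames (i, j, min_density inherited from the split that
  # created this segment)
  stack <- list(list(i = 1L, j = n, d = 0))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- fr$i; j <- fr$j
    if (i == j) {
      res_first <- c(res_first, i); res_last <- c(res_last, j)
      res_min <- c(res_min, fr$d); res_max <- c(res_max, Inf)
      next
    }
    k <- i:(j - 1L)
    pref <- (cum[k + 1L] - cum[i]) / (pos[k + 1L] - pos[i])
    suff <- (cum[j + 1L] - cum[k + 1L]) / (pos[j] - pos[k])
    split_d <- pmin(pref, suff)
    b <- k[which.min(split_d)]
    break_density <- min(split_d)
    if (break_density > fr$d) {
      res_first <- c(res_first, i); res_last <- c(res_last, j)
      res_min <- c(res_min, fr$d); res_max <- c(res_max, break_density)
    }
    child_d <- max(break_density, fr$d)
    stack[[length(stack) + 1L]] <- list(i = i, j = b, d = child_d)
    stack[[length(stack) + 1L]] <- list(i = b + 1L, j = j, d = child_d)
  }

  tibble(
    first = res_first, last = res_last,
    start = pos[res_first], end = pos[res_last] + 1L,
    n_sites = res_last - res_first + 1L,
    total_tpm = seg_sum(res_first, res_last),
    min_density = res_min, max_density = res_max,
    stability = ifelse(res_min > 0, res_max / res_min, Inf)
  ) %>% arrange(.data$first, dplyr::desc(.data$last))
}

#' Dominant CTSS of a site list
#'
#' Highest-TPM site; ties are broken toward the site nearest the midpoint
#' of the covered span, then toward the lower coordinate.
#'
#' @param pos,tpm Site positions and TPM values.
#' @return Index into `pos` of the dominant site.
#' @keywords internal
dominant_site <- function(pos, tpm) {
  best <- which(tpm == max(tpm))
  if (length(best) > 1) {
    mid <- (pos[1] + pos[length(pos)]) / 2
    d <- abs(pos[best] - mid)
    best <- best[d == min(d)]
    best <- best[which.min(pos[best])]
  }
  best
}

#' Interquantile width and shape class of a tag cluster
#'
#' Width between the first site where the cumulative TPM reaches
#' `q_low * total` and the first site where it reaches `q_up * total`
#' (inclusive of both bases). Shape classes follow narrow-peak (NP),
#' broad-with-peak (BP) and weak-peak (WP) promoter categories:
#' NP if width <= `np_max`, BP if <= `bp_max`, else WP.
#'
#' @param pos,tpm Site positions (sorted) and TPM values of one cluster.
#' @param q_low,q_up Lower/upper cumulative quantiles (defaults 0.1, 0.9).
#' @param np_max,bp_max Shape-class width cutoffs in bp (defaults 10, 40).
#' @return List with `width` (integer bp) and `shape_class`.
#' @export
iq_width <- function(pos, tpm, q_low = 0.1, q_up = 0.9,
                     np_max = 10L, bp_max = 40L) {
  total <- sum(tpm)
  cum <- cumsum(tpm)
  lo <- pos[which(cum >= q_low * total)[1]]
  hi <- pos[which(cum >= q_up * total)[1]]
  width <- as.integer(hi - lo + 1L)
  shape <- if (width <= np_max) "NP" else if (width <= bp_max) "BP" else "WP"
  list(width = width, shape_class = shape)
}

#' Per-sample tag clustering of filtered CTSSs
#'
#' Runs [paraclu()] on every (sample, chrom, strand) site list restricted
#' to positions passing the expression filter, then prunes candidates:
#' keep stability >= `min_stability` and span <= `max_length` bp; among
#' nested survivors keep the outermost; drop single-site clusters unless
#' their TPM exceeds `keep_singletons_above`. Defaults follow the standard
#' CAGE tag-clustering parameterization (minStability 2, maxLength 100,
#' removeSingletons with keepSingletonAbove 0.3 TPM).
#'
#' @param tracks Normalized CTSS tibble (all samples).
#' @param pass Tibble of passing positions from [ctss_pass_filter()]; if
#'   `NULL`, computed with `tpm_threshold`/`nr_pass`.
#' @param tpm_threshold,nr_pass Expression filter parameters (0.1, 2).
#' @param min_stability Minimum density stability (default 2).
#' @param max_length Maximum cluster span in bp (default 100); longer
#'   candidates are discarded, not trimmed.
#' @param remove_singletons Drop single-site clusters (default TRUE).
#' @param keep_singletons_above TPM above which singletons are kept
#'   despite `remove_singletons` (default 0.3).
#' @param q_low,q_up,np_max,bp_max Passed to [iq_width()].
#' @return Tibble of tag clusters: `sample_id`, `chrom`, `strand`,
#'   `start`, `end`, `n_sites`, `total_tpm`, `dominant_pos`,
#'   `dominant_tpm`, `min_density`, `max_density`, `stability`,
#'   `iq_width`, `shape_class`, and a `sites` list-column of
#'   `(pos, tpm)` tibbles.
#' @export
cluster_tags <- function(tracks, pass = NULL, tpm_threshold = 0.1,
                         nr_pass = 2L, min_stability = 2, max_length = 100L,
                         remove_singletons = TRUE,
                         keep_singletons_above = 0.3,
                         q_low = 0.1, q_up = 0.9,
                         np_max = 10L, bp_max = 40L) {
  if (is.null(pass)) {
    pass <- ctss_pass_filter(tracks, tpm_threshold, nr_pass)
  }
  input <- tracks %>%
    dplyr::semi_join(pass, by = c("chrom", "pos", "strand")) %>%
    arrange(.data$sample_id, .data$chrom, .data$strand, .data$pos)
  if (nrow(input) == 0) {
    return(empty_tagcluster_tbl())
  }
  input %>%
    group_by(.data$sample_id, .data$chrom, .data$strand) %>%
    dplyr::group_modify(function(df, key) {
      cand <- paraclu(df$pos, df$tpm)
      select_clusters(cand, df$pos, df$tpm,
                      min_stability = min_stability, max_length = max_length,
                      remove_singletons = remove_singletons,
                      keep_singletons_above = keep_singletons_above,
                      q_low = q_low, q_up = q_up,
                      np_max = np_max, bp_max = bp_max)
    }) %>%
    ungroup()
}

empty_tagcluster_tbl <- function() {
  tibble(sample_id = character(), chrom = character(), strand = character(),
         start = integer(), end = integer(), n_sites = integer(),
         total_tpm = numeric(), dominant_pos = integer(),
         dominant_tpm = numeric(), min_density = numeric(),
         max_density = numeric(), stability = numeric(),
         iq_width = integer(), shape_class = character(),
         sites = list())
}

#' Prune paraclu candidates into retained tag clusters
#'
#' @param candidates Candidate tibble from [paraclu()].
#' @param pos,tpm The site vectors the candidates index into.
#' @inheritParams cluster_tags
#' @return Tibble of retained clusters (without sample metadata columns).
#' @export
select_clusters <- function(candidates, pos, tpm, min_stability = 2,
                            max_length = 100L, remove_singletons = TRUE,
                            keep_singletons_above = 0.3,
                            q_low = 0.1, q_up = 0.9,
                            np_max = 10L, bp_max = 40L) {
  keep <- candidates %>%
    filter(.data$stability >= min_stability,
           .data$end - .data$start <= max_length)
  if (remove_singletons) {
    keep <- keep %>%
      filter(.data$n_sites > 1 | .data$total_tpm > keep_singletons_above)
  }
  if (nrow(keep) == 0) {
    out <- empty_tagcluster_tbl()
    return(select(out, -"sample_id", -"chrom", -"strand"))
  }
  # outermost among nested survivors: candidates are laminar, so after
  # sorting by start asc / end desc, a cluster is nested iff it lies within
  # the running maximum end of previously accepted clusters
  keep <- keep %>% arrange(.data$first, dplyr::desc(.data$last))
  sel <- logical(nrow(keep))
  max_last <- -1L
  for (r in seq_len(nrow(keep))) {
    if (keep$first[r] > max_last) {
      sel[r] <- TRUE
      max_last <- keep$last[r]
    }
  }
  keep <- keep[sel, , drop = FALSE]
  nk <- nrow(keep)
  dom_pos <- integer(nk); dom_tpm <- numeric(nk)
  widths <- integer(nk); shapes <- character(nk)
  sites <- vector("list", nk)
  for (r in seq_len(nk)) {
    p <- pos[keep$first[r]:keep$last[r]]
    w <- tpm[keep$first[r]:keep$last[r]]
    dom <- dominant_site(p, w)
    iq <- iq_width(p, w, q_low, q_up, np_max, bp_max)
    dom_pos[r] <- p[dom]; dom_tpm[r] <- w[dom]
    widths[r] <- iq$width; shapes[r] <- iq$shape_class
    sites[[r]] <- tibble(pos = p, tpm = w)
  }
  tibble(start = keep$start, end = keep$end, n_sites = keep$n_sites,
         total_tpm = keep$total_tpm,
         dominant_pos = dom_pos, dominant_tpm = dom_tpm,
         min_density = keep$min_density, max_density = keep$max_density,
         stability = keep$stability,
         iq_width = widths, shape_class = shapes,
         sites = sites)
}

#' Merge per-sample tag clusters into consensus clusters
#'
#' Same-chromosome, same-strand tag clusters from any samples whose spans
#' are separated by a gap of at most `max_dist` bp are merged transitively;
#' the consensus span is the union extent (no quantile trimming). A
#' consensus cluster is kept only if its within-span filtered-signal TPM is
#' at least `tpm_threshold` in at least one sample (signal below the
#' clustering threshold is excluded from this decision). The consensus
#' dominant CTSS is the position with the highest TPM pooled across all
#' samples (ties toward the lower coordinate).
#'
#' @param tag_clusters Tibble from [cluster_tags()].
#' @param max_dist Maximum merge gap in bp (default 100).
#' @param tpm_threshold Minimum per-sample pooled TPM (default 0.3).
#' @return Tibble of consensus clusters: `cluster_id`, `chrom`, `strand`,
#'   `start`, `end`, `dominant_pos`, `dominant_tpm_pooled`, `n_samples`.
#' @export
aggregate_consensus <- function(tag_clusters, max_dist = 100L,
                                tpm_threshold = 0.3) {
  if (nrow(tag_clusters) == 0) {
    return(tibble(cluster_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  dominant_pos = integer(), dominant_tpm_pooled = numeric(),
                  n_samples = integer()))
  }
  merged <- tag_clusters %>%
    group_by(.data$chrom, .data$strand) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(group = cumsum(
      .data$start > dplyr::lag(cummax(as.numeric(.data$end)), default = -Inf) + max_dist
    )) %>%
    ungroup()

  cons <- merged %>%
    group_by(.data$chrom, .data$strand, .data$group) %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      n_samples = dplyr::n_distinct(.data$sample_id),
      site_tbl = list({
        reps <- vapply(.data$sites, nrow, integer(1))
        dplyr::bind_cols(sample_id = rep(.data$sample_id, reps),
                         bind_rows(.data$sites))
      }),
      .groups = "drop"
    )

  per_sample_ok <- vapply(cons$site_tbl, function(st) {
    any(tapply(st$tpm, st$sample_id, sum) >= tpm_threshold)
  }, logical(1))
  cons <- cons[per_sample_ok, , drop = FALSE]
  if (nrow(cons) == 0) {
    return(tibble(cluster_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  dominant_pos = integer(), dominant_tpm_pooled = numeric(),
                  n_samples = integer()))
  }

  dom <- purrr::map(cons$site_tbl, function(st) {
    pooled <- tapply(st$tpm, st$pos, sum)
    pos <- as.integer(names(pooled))
    i <- which(pooled == max(pooled))
    i <- i[which.min(pos[i])]
    list(pos = pos[i], tpm = unname(pooled[i]))
  })
  cons %>%
    mutate(dominant_pos = vapply(dom, function(d) d$pos, integer(1)),
           dominant_tpm_pooled = vapply(dom, function(d) d$tpm, numeric(1))) %>%
    arrange(.data$chrom, .data$start, .data$strand) %>%
    mutate(cluster_id = sprintf("cc_%05d", row_number())) %>%
    select("cluster_id", "chrom", "strand", "start", "end",
           "dominant_pos", "dominant_tpm_pooled", "n_samples")
}

#' Quantify consensus clusters across all samples
#'
#' Per sample, the raw count (and TPM) of a consensus cluster is the sum
#' over all same-strand CTSSs inside its span, including CTSSs that failed
#' the clustering expression filter.
#'
#' @param consensus Tibble from [aggregate_consensus()].
#' @param tracks Normalized CTSS tibble (all samples).
#' @return Long tibble: `cluster_id`, `sample_id`, `count`, `tpm` (complete
#'   grid; absent signal gives 0).
#' @export
quantify_consensus <- function(consensus, tracks) {
  samples <- sort(unique(tracks$sample_id))
  if (nrow(consensus) == 0) {
    return(tibble(cluster_id = character(), sample_id = character(),
                  count = integer(), tpm = numeric()))
  }
  key <- paste(consensus$chrom, consensus$strand)
  tkey <- paste(tracks$chrom, tracks$strand)
  hits <- purrr::map_dfr(unique(key), function(k) {
    ci <- which(key == k)
    ti <- which(tkey == k)
    if (length(ti) == 0) return(NULL)
    q <- IRanges::IRanges(start = consensus$start[ci] + 1L,
                          end = consensus$end[ci])
    s <- IRanges::IRanges(start = tracks$pos[ti] + 1L, width = 1L)
    ov <- IRanges::findOverlaps(s, q)
    if (length(ov) == 0) return(NULL)
    tibble(cluster_id = consensus$cluster_id[ci][S4Vectors::subjectHits(ov)],
           sample_id = tracks$sample_id[ti][S4Vectors::queryHits(ov)],
           count = tracks$count[ti][S4Vectors::queryHits(ov)],
           tpm = tracks$tpm[ti][S4Vectors::queryHits(ov)])
  })
  grid <- tidyr::expand_grid(cluster_id = consensus$cluster_id,
                             sample_id = samples)
  if (is.null(hits) || nrow(hits) == 0) {
    return(mutate(grid, count = 0L, tpm = 0))
  }
  hits %>%
    group_by(.data$cluster_id, .data$sample_id) %>%
    summarise(count = sum(.data$count), tpm = sum(.data$tpm),
              .groups = "drop") %>%
    dplyr::right_join(grid, by = c("cluster_id", "sample_id")) %>%
    mutate(count = as.integer(tidyr::replace_na(.data$count, 0L)),
           tpm = tidyr::replace_na(.data$tpm, 0)) %>%
    arrange(.data$cluster_id, .data$sample_id)
}
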