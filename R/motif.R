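#' Construct a motif model (PWM)
#'
#' @param matrix_probs 4 x W numeric matrix of per-position base
#'   probabilities, rows named A, C, G, T; columns must each sum to 1.
#' @param background Background base frequencies (named, sums to 1);
#'   default uniform.
#' @param id Motif identifier.
#' @return A `motif_model` list with the log-odds matrix precomputed.
#' @export
motif_model <- function(matrix_probs, background = c(A = 0.25, C = 0.25,
                                                     G = 0.25, T = 0.25),
                        id = "motif") {
  matrix_probs <- as.matrix(matrix_probs)
  stopifnot(nrow(matrix_probs) == 4)
  rownames(matrix_probs) <- c("A", "C", "G", "T")
  assert_that(all(abs(colSums(matrix_probs) - 1) < 1e-9),
              "each PWM column must sum to 1")
  background <- background[c("A", "C", "G", "T")]
  assert_that(abs(sum(background) - 1) < 1e-9, "background must sum to 1")
  pseudo <- 1e-6
  lod <- log2((matrix_probs + pseudo) / (1 + 4 * pseudo)) -
    log2(as.numeric(background))
  structure(list(id = id, probs = matrix_probs, background = background,
                 lod = lod, width = ncol(matrix_probs)),
            class = "motif_model")
}

#' Read a simple probability-matrix motif file
#'
#' Plain text: one line per motif position with four whitespace-separated
#' probabilities in A C G T order (the positional-frequency block used by
#' minimal MEME-style files).
#'
#' @param path File path.
#' @param ... Passed to [motif_model()].
#' @return A `motif_model`.
#' @export
read_motif <- function(path, ...) {
  m <- as.matrix(read.table(path))
  motif_model(t(m), ...)
}

#' Exact null distribution of PWM scores
#'
#' Dynamic programming over the motif columns: the score distribution of
#' a random word under the 0-order background is built by convolving the
#' per-column log-odds score distributions. States are keyed on exact
#' partial sums, so the state count is bounded by 4^width; suitable for
#' the short core-promoter motifs (width <= ~10) this package targets.
#'
#' @param motif A `motif_model`.
#' @return Tibble with `score` (sorted decreasing) and `p`
#'   (`P(S >= score)` under the background).
#' @export
pwm_score_distribution <- function(motif) {
  dist <- c(`0` = 1)
  for (j in seq_len(motif$width)) {
    sc <- motif$lod[, j]
    pr <- as.numeric(motif$background)
    new_scores <- outer(as.numeric(names(dist)), sc, "+")
    new_probs <- outer(as.numeric(dist), pr, "*")
    key <- sprintf("%.17g", new_scores)
    dist <- tapply(as.numeric(new_probs), key, sum)
  }
  tb <- tibble(score = as.numeric(names(dist)), p_mass = as.numeric(dist)) %>%
    arrange(dplyr::desc(.data$score)) %>%
    mutate(p = cumsum(.data$p_mass)) %>%
    select("score", "p")
  tb
}

#' Scan sequences with a PWM and exact p-values
#'
#' Log-odds scoring of every position on both strands; the exact
#' score-distribution p-value (`P(S >= s)` under the 0-order background)
#' is attached per hit and instances with `p <= p_threshold` are
#' reported. Ambiguous bases contribute a neutral (zero) log-odds score.
#' Instance midpoints are `start + floor(width / 2)` in 0-based genomic
#' coordinates, independent of strand.
#'
#' @param seqs Named character vector or `Biostrings::DNAStringSet`.
#' @param motif A `motif_model`.
#' @param p_threshold Report instances with p at or below this value
#'   (default 1e-4).
#' @return Tibble: `seqname`, `start` (0-based), `strand`, `midpoint`,
#'   `score`, `p`.
#' @export
pwm_scan <- function(seqs, motif, p_threshold = 1e-4) {
  if (inherits(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  w <- motif$width
  null_dist <- pwm_score_distribution(motif)
  p_of <- function(s) {
    # smallest index with score <= s + eps gives the tail p
    idx <- findInterval(-(s - 1e-6), -null_dist$score)
    ifelse(idx < 1, 0, null_dist$p[pmin(idx, nrow(null_dist))])
  }
  score_threshold <- {
    ok <- null_dist$score[null_dist$p <= p_threshold]
    if (length(ok) == 0) Inf else min(ok)
  }
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  rc <- motif$lod[4:1, w:1, drop = FALSE]  # reverse complement log-odds
  purrr::map_dfr(names(seqs) %||% as.character(seq_along(seqs)),
                 function(nm) {
    s <- toupper(seqs[[nm]])
    L <- nchar(s)
    if (L < w) return(NULL)
    codes <- base_idx[strsplit(s, "", fixed = TRUE)[[1]]]
    n_pos <- L - w + 1L
    fwd <- numeric(n_pos); rev <- numeric(n_pos)
    for (j in seq_len(w)) {
      cj <- codes[j:(j + n_pos - 1L)]
      sc_f <- motif$lod[, j][cj]
      sc_r <- rc[, j][cj]
      sc_f[is.na(sc_f)] <- 0  # ambiguous base: neutral
      sc_r[is.na(sc_r)] <- 0
      fwd <- fwd + unname(sc_f)
      rev <- rev + unname(sc_r)
    }
    hits_f <- which(fwd >= score_threshold - 1e-6)
    hits_r <- which(rev >= score_threshold - 1e-6)
    bind_rows(
      if (length(hits_f)) tibble(seqname = nm, start = hits_f - 1L,
                                 strand = "+", score = fwd[hits_f]),
      if (length(hits_r)) tibble(seqname = nm, start = hits_r - 1L,
                                 strand = "-", score = rev[hits_r])
    )
  }) -> hits
  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble(seqname = character(), start = integer(),
                  strand = character(), midpoint = integer(),
                  score = numeric(), p = numeric()))
  }
  hits %>%
    mutate(midpoint = .data$start + w %/% 2L, p = p_of(.data$score)) %>%
    filter(.data$p <= p_threshold) %>%
    select("seqname", "start", "strand", "midpoint", "score", "p") %>%
    arrange(.data$seqname, .data$start, .data$strand)
}

#' Positional profile of motif instances around TSSs
#'
#' Signed, strand-oriented offsets (upstream negative) between motif
#' instance midpoints and dominant CTSSs, binned per nt in
#' `[-flank, +flank]`. The peak offset is the argmax after moving-average
#' smoothing (window 3 nt); a peak is flagged only if the smoothed maximum
#' exceeds mean + 3 sd of the smoothed profile.
#'
#' @param instances Tibble from [pwm_scan()] (`seqname`, `midpoint`).
#' @param tss Tibble with `chrom`, `pos` (dominant CTSS), `strand`.
#' @param flank Window half-width in nt (default 200).
#' @return A `motif_profile` object: tibble of `offset`, `count`,
#'   `smoothed`, with attributes `peak_offset` (NA when flat/empty) and
#'   `has_peak`.
#' @export
motif_positional_profile <- function(instances, tss, flank = 200L) {
  offsets <- integer(0)
  if (nrow(instances) > 0 && nrow(tss) > 0) {
    offsets <- purrr::map(seq_len(nrow(tss)), function(i) {
      mid <- instances$midpoint[instances$seqname == tss$chrom[i]]
      if (length(mid) == 0) return(integer(0))
      off <- if (tss$strand[i] == "+") mid - tss$pos[i] else tss$pos[i] - mid
      off[abs(off) <= flank]
    }) %>% unlist()
  }
  grid <- seq(-flank, flank)
  counts <- tabulate(match(offsets, grid), nbins = length(grid))
  smoothed <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  smoothed[is.na(smoothed)] <- counts[is.na(smoothed)]
  prof <- tibble(offset = grid, count = counts, smoothed = smoothed)
  if (sum(counts) == 0) {
    peak <- NA_integer_; has_peak <- FALSE
  } else {
    # ties on the smoothed maximum resolve by raw count, then centrality
    cand <- which(smoothed == max(smoothed))
    cand <- cand[order(-counts[cand], abs(grid[cand]))][1]
    peak <- grid[cand]
    has_peak <- max(smoothed) > mean(smoothed) + 3 * sd(smoothed)
    if (!has_peak) peak <- NA_integer_
  }
  structure(prof, class = c("motif_profile", class(prof)),
            peak_offset = peak, has_peak = has_peak,
            n_pairs = sum(counts))
}
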