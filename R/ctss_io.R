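#' Read a per-base CTSS count track
#'
#' Reads a TAB-separated 4-column text file (`chrom`, `pos`, `strand`,
#' `count`) holding the per-base 5'-end tag counts of one CAGE library.
#' Positions are 0-based in the native dialect; files exported from BED6
#' (1 entry per base, `start` column as position) use the same 0-based
#' convention, while `one_based = TRUE` converts 1-based positions on input.
#'
#' @param path Path to the CTSS text file.
#' @param sample_id Sample identifier stored in the `sample_id` column.
#' @param genotype Genotype label (e.g. `"wt"`, `"met1"`).
#' @param replicate Replicate number (integer >= 1).
#' @param one_based If `TRUE`, input positions are 1-based and are shifted
#'   to the internal 0-based convention.
#' @return A CTSS track tibble with columns `sample_id`, `genotype`,
#'   `replicate`, `chrom`, `pos`, `strand`, `count` and attribute-free
#'   sparse representation (zero-count bases are absent). Use
#'   [tpm_normalize()] to add the `tpm` column.
#' @export
read_ctss <- function(path, sample_id, genotype = NA_character_,
                      replicate = 1L, one_based = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(
      sample_id = character(), genotype = character(), replicate = integer(),
      chrom = character(), pos = integer(), strand = character(),
      count = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 4L)
  if (length(bad) > 0) {
    abort(sprintf("malformed CTSS line %d in '%s': expected 4 TAB-separated fields, got %d",
                  bad[1], path, nf[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  count <- suppressWarnings(as.integer(m[, 4]))
  bad <- which(is.na(pos) | is.na(count))
  if (length(bad) > 0) {
    abort(sprintf("malformed CTSS line %d in '%s': non-integer pos or count", bad[1], path))
  }
  track <- tibble(
    sample_id = as.character(sample_id),
    genotype = as.character(genotype),
    replicate = as.integer(replicate),
    chrom = m[, 1],
    pos = if (one_based) pos - 1L else pos,
    strand = m[, 3],
    count = count
  )
  validate_ctss(track)
  track
}

#' Write a CTSS track to the 4-column text dialect
#'
#' Inverse of [read_ctss()]: writes `chrom`, `pos` (0-based), `strand`,
#' `count` as TAB-separated text, one sample per file.
#'
#' @param track A CTSS track tibble (one sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ctss <- function(track, path) {
  stopifnot(length(unique(track$sample_id)) <= 1)
  out <- track %>%
    arrange(.data$chrom, .data$pos, .data$strand) %>%
    select("chrom", "pos", "strand", "count")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate the CTSS track contract
#'
#' Checks strand levels, strictly positive integer counts and absence of
#' duplicate `(sample_id, chrom, pos, strand)` keys.
#'
#' @param track A CTSS track tibble (one or several samples stacked).
#' @return The track, invisibly, if valid; otherwise an error.
#' @export
validate_ctss <- function(track) {
  assert_that(all(track$strand %in% c("+", "-")),
              "CTSS strand must be '+' or '-'")
  assert_that(all(track$count >= 1L),
              "CTSS counts must be strictly positive integers (sparse representation)")
  assert_that(all(track$pos >= 0L), "CTSS positions must be >= 0 (0-based)")
  key <- paste(track$sample_id, track$chrom, track$pos, track$strand)
  if (anyDuplicated(key)) {
    abort("duplicate (sample, chrom, pos, strand) CTSS keys")
  }
  invisible(track)
}

#' Normalize CTSS counts to tags per million (TPM)
#'
#' Adds a `tpm` column: `count / library_total * 1e6`, computed per sample.
#' The per-sample TPM values of a non-empty track sum to `1e6`.
#'
#' @param tracks CTSS tibble for one or more samples (stacked rows).
#' @return The same tibble with a `tpm` column.
#' @export
tpm_normalize <- function(tracks) {
  if (nrow(tracks) == 0) {
    return(mutate(tracks, tpm = numeric(0)))
  }
  totals <- tracks %>%
    group_by(.data$sample_id) %>%
    summarise(library_total = sum(.data$count), .groups = "drop")
  if (any(totals$library_total == 0)) {
    abort("empty library: cannot TPM-normalize a track with library_total = 0")
  }
  tracks %>%
    left_join(totals, by = "sample_id") %>%
    mutate(tpm = .data$count / .data$library_total * 1e6) %>%
    select(-"library_total")
}

#' Per-sample library totals
#'
#' @param tracks CTSS tibble.
#' @return Tibble with `sample_id` and `library_total`.
#' @export
library_totals <- function(tracks) {
  tracks %>%
    group_by(.data$sample_id) %>%
    summarise(library_total = sum(.data$count), .groups = "drop")
}

#' Select CTSS positions passing the expression filter
#'
#' A position enters the clustering input if its TPM is at least
#' `tpm_threshold` in at least `nr_pass` of the supplied samples
#' (defaults 0.1 TPM in >= 2 samples). Positions failing the filter are
#' excluded from clustering but are still counted when consensus clusters
#' are quantified.
#'
#' @param tracks Normalized CTSS tibble (all samples of the clustering run).
#' @param tpm_threshold Minimum TPM (default 0.1).
#' @param nr_pass Minimum number of samples meeting the threshold (default 2).
#' @return Tibble of passing positions: `chrom`, `pos`, `strand`.
#' @export
ctss_pass_filter <- function(tracks, tpm_threshold = 0.1, nr_pass = 2L) {
  assert_that(tpm_threshold >= 0, "tpm_threshold must be >= 0")
  assert_that(nr_pass >= 1, "nr_pass must be >= 1")
  n_samples <- length(unique(tracks$sample_id))
  if (nr_pass > n_samples) {
    abort(sprintf("nr_pass (%d) exceeds the number of samples (%d)",
                  nr_pass, n_samples))
  }
  assert_that("tpm" %in% names(tracks), "tracks must be TPM-normalized first")
  tracks %>%
    filter(.data$tpm >= tpm_threshold) %>%
    group_by(.data$chrom, .data$pos, .data$strand) %>%
    summarise(n_pass = dplyr::n_distinct(.data$sample_id), .groups = "drop") %>%
    filter(.data$n_pass >= nr_pass) %>%
    select("chrom", "pos", "strand")
}

#' Pearson correlation between two replicate CTSS tracks
#'
#' Computed on `log(tpm + 1)` over the union of positions of the two
#' samples; a position absent from one sample contributes TPM 0 there.
#' A quality-control metric for replicate agreement.
#'
#' @param a,b Normalized single-sample CTSS tibbles.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
replicate_correlation <- function(a, b) {
  assert_that(all(c("tpm") %in% names(a)) && all(c("tpm") %in% names(b)),
              "both tracks must be TPM-normalized")
  u <- dplyr::full_join(
    select(a, "chrom", "pos", "strand", tpm_a = "tpm"),
    select(b, "chrom", "pos", "strand", tpm_b = "tpm"),
    by = c("chrom", "pos", "strand")
  ) %>%
    mutate(tpm_a = tidyr::replace_na(.data$tpm_a, 0),
           tpm_b = tidyr::replace_na(.data$tpm_b, 0))
  if (nrow(u) < 2) {
    abort("fewer than 2 union positions: correlation undefined")
  }
  cor(log(u$tpm_a + 1), log(u$tpm_b + 1), method = "pearson")
}
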