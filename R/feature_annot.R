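#' Feature classes, in precedence order
#'
#' The genomic feature classes a consensus cluster can be assigned to,
#' ordered by the precedence used for classification:
#' PROMOTER > UTR5 > UTR3 > INTRON > EXON > ANTISENSE > TE > INTERGENIC.
#'
#' @export
feature_classes <- function() {
  c("PROMOTER", "UTR5", "UTR3", "INTRON", "EXON", "ANTISENSE", "TE",
    "INTERGENIC")
}

#' Assemble a genome annotation object
#'
#' @param genes Tibble: `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open gene span), `tss` (0-based position of the
#'   annotated TSS base).
#' @param features Tibble of sub-gene intervals: `gene_id`, `type`
#'   (`"exon"`, `"utr5"`, `"utr3"`), `chrom`, `strand`, `start`, `end`.
#' @param tes Tibble: `te_id`, `chrom`, `start`, `end`, `family`,
#'   `superfamily`.
#' @return A validated `genome_annotation` list.
#' @export
genome_annotation <- function(genes, features, tes) {
  genes <- as_tibble(genes); features <- as_tibble(features)
  tes <- as_tibble(tes)
  assert_that(all(features$type %in% c("exon", "utr5", "utr3")),
              "feature type must be exon/utr5/utr3")
  chk <- features %>%
    left_join(select(genes, "gene_id", gstart = "start", gend = "end"),
              by = "gene_id")
  if (any(is.na(chk$gstart)) ||
      any(chk$start < chk$gstart | chk$end > chk$gend)) {
    abort("gene sub-features must lie within their gene span")
  }
  structure(list(genes = genes, features = features, tes = tes),
            class = "genome_annotation")
}

#' Read a genome annotation from GFF3 (and an optional TE file)
#'
#' Parses `gene`, `exon`, `five_prime_UTR` and `three_prime_UTR` features
#' from a GFF3 file; `transposable_element` features (or a separate TE
#' GFF3/BED) supply TE spans with a `family` attribute. GFF3 1-based
#' closed coordinates are converted to the internal 0-based half-open
#' convention at this boundary; the annotated TSS of a gene is its
#' 5'-most base (strand-aware).
#'
#' @param path GFF3 file with gene models.
#' @param te_path Optional GFF3/BED file with TE spans; if `NULL`, TE
#'   features are taken from `path`.
#' @return A `genome_annotation` object.
#' @export
read_annotation_gff3 <- function(path, te_path = NULL) {
  gr <- rtracklayer::import(path)
  df <- as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  genes <- df %>%
    filter(.data$type == "gene") %>%
    mutate(gene_id = as.character(.data$ID),
           chrom = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           start0 = .data$start - 1L, end0 = .data$end,
           tss = ifelse(.data$strand == "+", .data$start - 1L, .data$end - 1L)) %>%
    select("gene_id", "chrom", "strand", start = "start0", end = "end0", "tss")
  feat <- df %>%
    filter(.data$type %in% c("exon", "five_prime_UTR", "three_prime_UTR")) %>%
    mutate(gene_id = as.character(.data$Parent),
           type = c(exon = "exon", five_prime_UTR = "utr5",
                    three_prime_UTR = "utr3")[.data$type],
           chrom = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           start0 = .data$start - 1L, end0 = .data$end) %>%
    select("gene_id", "type", "chrom", "strand",
           start = "start0", end = "end0")
  te_src <- if (is.null(te_path)) df else {
    as_tibble(as.data.frame(rtracklayer::import(te_path))) %>%
      mutate(type = as.character(.data$type %||% "transposable_element"))
  }
  tes <- te_src %>%
    filter(.data$type == "transposable_element") %>%
    mutate(te_id = as.character(.data$ID),
           chrom = as.character(.data$seqnames),
           start0 = .data$start - 1L, end0 = .data$end,
           family = as.character(.data$family),
           superfamily = sub("/.*$", "", as.character(.data$family))) %>%
    select("te_id", "chrom", start = "start0", end = "end0",
           "family", "superfamily")
  genome_annotation(genes, feat, tes)
}

#' Build the searchable feature index
#'
#' Derives strand-aware 1-kb promoters upstream of each annotated TSS,
#' introns as gene span minus exons, and stacks all feature intervals
#' with their precedence rank. The promoter of a plus-strand gene with
#' TSS at `t` is `[t - promoter_len, t)`; for a minus-strand gene it is
#' `[t + 1, t + 1 + promoter_len)` (0-based half-open).
#'
#' @param annotation A `genome_annotation` object.
#' @param promoter_len Promoter length in bp (default 1000).
#' @return Tibble of intervals: `chrom`, `strand` (`"*"` for TE),
#'   `start`, `end`, `class`, `priority`, `id`.
#' @export
build_feature_index <- function(annotation, promoter_len = 1000L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  promoters <- g %>%
    mutate(p_start = ifelse(.data$strand == "+",
                            pmax(.data$tss - promoter_len, 0L), .data$tss + 1L),
           p_end = ifelse(.data$strand == "+",
                          .data$tss, .data$tss + 1L + promoter_len)) %>%
    mutate(class = "PROMOTER", id = .data$gene_id) %>%
    select("chrom", "strand", start = "p_start", end = "p_end",
           "class", "id")

  fmap <- c(utr5 = "UTR5", utr3 = "UTR3", exon = "EXON")
  sub <- annotation$features %>%
    mutate(class = fmap[.data$type], id = .data$gene_id) %>%
    select("chrom", "strand", "start", "end", "class", "id")

  introns <- purrr::map_dfr(split(annotation$features %>%
                                    filter(.data$type == "exon"),
                                  annotation$features$gene_id[
                                    annotation$features$type == "exon"]),
                            function(ex) {
    gi <- g[g$gene_id == ex$gene_id[1], ]
    gene_rng <- IRanges::IRanges(gi$start + 1L, gi$end)
    ex_rng <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    intr <- IRanges::setdiff(gene_rng, ex_rng)
    if (length(intr) == 0) return(NULL)
    tibble(chrom = gi$chrom, strand = gi$strand,
           start = IRanges::start(intr) - 1L, end = IRanges::end(intr),
           class = "INTRON", id = gi$gene_id)
  })

  antisense <- g %>%
    mutate(strand = ifelse(.data$strand == "+", "-", "+"),
           class = "ANTISENSE", id = .data$gene_id) %>%
    select("chrom", "strand", "start", "end", "class", "id")

  te <- annotation$tes %>%
    mutate(strand = "*", class = "TE", id = .data$te_id) %>%
    select("chrom", "strand", "start", "end", "class", "id")

  bind_rows(promoters, sub, introns, antisense, te) %>%
    mutate(priority = match(.data$class, feature_classes())) %>%
    arrange(.data$priority, .data$chrom, .data$start)
}

#' Classify consensus clusters by genomic feature
#'
#' Tests the dominant CTSS base of each cluster against the feature
#' intervals in strict precedence order (PROMOTER > UTR5 > UTR3 > INTRON >
#' EXON > ANTISENSE > TE > INTERGENIC); the first hit wins. Sense features
#' require the cluster's strand; ANTISENSE means within a gene on the
#' opposite strand; TE ignores strand; no hit gives INTERGENIC. Spans play
#' no role: only the dominant CTSS is tested.
#'
#' @param clusters Tibble with `cluster_id`, `chrom`, `strand`,
#'   `dominant_pos`.
#' @param index Feature index from [build_feature_index()].
#' @return `clusters` with added `feature_class` and `feature_id`.
#' @export
classify_feature <- function(clusters, index) {
  n <- nrow(clusters)
  cls <- rep(NA_character_, n)
  fid <- rep(NA_character_, n)
  strand_ok <- function(iv_strand, cl_strand) {
    iv_strand == "*" | iv_strand == cl_strand
  }
  for (k in feature_classes()[feature_classes() != "INTERGENIC"]) {
    todo <- which(is.na(cls))
    if (length(todo) == 0) break
    iv <- index %>% filter(.data$class == k)
    if (nrow(iv) == 0) next
    for (ch in unique(clusters$chrom[todo])) {
      ci <- todo[clusters$chrom[todo] == ch]
      ii <- which(iv$chrom == ch)
      if (length(ii) == 0) next
      q <- IRanges::IRanges(clusters$dominant_pos[ci] + 1L, width = 1L)
      s <- IRanges::IRanges(iv$start[ii] + 1L, iv$end[ii])
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov) == 0) next
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      ok <- strand_ok(iv$strand[ii][sh], clusters$strand[ci][qh])
      qh <- qh[ok]; sh <- sh[ok]
      if (length(qh) == 0) next
      firsts <- !duplicated(qh)
      cls[ci[qh[firsts]]] <- k
      fid[ci[qh[firsts]]] <- iv$id[ii][sh[firsts]]
    }
  }
  cls[is.na(cls)] <- "INTERGENIC"
  clusters %>% mutate(feature_class = cls, feature_id = fid)
}

#' Assign ANNOTATED / NON-ANNOTATED status
#'
#' A cluster is ANNOTATED if the unsigned distance from its dominant CTSS
#' to the nearest annotated TSS in the same orientation is strictly less
#' than `radius` nt (default 180); otherwise NON-ANNOTATED. Chromosome/
#' strand combinations without annotated TSSs give infinite distance.
#'
#' @param clusters Tibble with `cluster_id`, `chrom`, `strand`,
#'   `dominant_pos`.
#' @param annotation A `genome_annotation` object.
#' @param radius Distance cutoff in nt (default 180; strict `<`).
#' @return `clusters` with added `tss_distance` and `annotated`
#'   (`"ANNOTATED"` / `"NON_ANNOTATED"`).
#' @export
annotated_status <- function(clusters, annotation, radius = 180L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  dist <- purrr::map_dbl(seq_len(nrow(clusters)), function(i) {
    cand <- g$tss[g$chrom == clusters$chrom[i] &
                    g$strand == clusters$strand[i]]
    if (length(cand) == 0) return(Inf)
    min(abs(cand - clusters$dominant_pos[i]))
  })
  clusters %>%
    mutate(tss_distance = dist,
           annotated = ifelse(dist < radius, "ANNOTATED", "NON_ANNOTATED"))
}

#' Annotate consensus clusters (class + annotated status)
#'
#' Convenience wrapper running [classify_feature()] and
#' [annotated_status()] on a consensus table.
#'
#' @inheritParams classify_feature
#' @inheritParams annotated_status
#' @param promoter_len Promoter length passed to [build_feature_index()].
#' @return Annotated consensus tibble.
#' @export
annotate_consensus <- function(clusters, annotation, promoter_len = 1000L,
                               radius = 180L) {
  index <- build_feature_index(annotation, promoter_len)
  clusters %>%
    classify_feature(index) %>%
    annotated_status(annotation, radius)
}
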