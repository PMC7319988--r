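#' Run the full cryptic-TSS discovery pipeline
#'
#' CTSS expression filter, per-sample tag clustering, consensus
#' aggregation, quantification, feature annotation, per-mutant
#' differential-initiation testing and EPICAT calling, in one call.
#'
#' @param tracks Normalized CTSS tibble (all samples).
#' @param annotation A `genome_annotation`.
#' @param samples Sample metadata tibble (`sample_id`, `genotype`).
#' @param wt Wild-type genotype label (default `"wt"`).
#' @param tpm_threshold,nr_pass CTSS filter (0.1 TPM, 2 samples).
#' @param min_stability,max_length,remove_singletons,keep_singletons_above
#'   Tag-cluster pruning parameters.
#' @param max_dist,agg_tpm_threshold Consensus aggregation parameters
#'   (100 bp, 0.3 TPM).
#' @param promoter_len,radius Annotation parameters (1 kb promoters,
#'   180 nt annotated-TSS radius).
#' @param detect_tpm,alpha EPICAT calling parameters (0.1 TPM, padj 0.1).
#' @return An `epicat_result` list: `tag_clusters`, `consensus`, `expr`,
#'   `annotated`, `de`, `calls`, `epicats`, `convergence`.
#' @export
epicat_pipeline <- function(tracks, annotation, samples, wt = "wt",
                            tpm_threshold = 0.1, nr_pass = 2L,
                            min_stability = 2, max_length = 100L,
                            remove_singletons = TRUE,
                            keep_singletons_above = 0.3,
                            max_dist = 100L, agg_tpm_threshold = 0.3,
                            promoter_len = 1000L, radius = 180L,
                            detect_tpm = 0.1, alpha = 0.1) {
  tc <- cluster_tags(tracks, tpm_threshold = tpm_threshold,
                     nr_pass = nr_pass, min_stability = min_stability,
                     max_length = max_length,
                     remove_singletons = remove_singletons,
                     keep_singletons_above = keep_singletons_above)
  cons <- aggregate_consensus(tc, max_dist = max_dist,
                              tpm_threshold = agg_tpm_threshold)
  expr <- quantify_consensus(cons, tracks)
  ann <- annotate_consensus(cons, annotation, promoter_len = promoter_len,
                            radius = radius)
  de <- diff_initiation(expr, samples, wt = wt)
  calls <- call_epicats(ann, de, expr, samples, wt = wt,
                        detect_tpm = detect_tpm, alpha = alpha)
  epicats <- filter(calls, .data$epicat)
  structure(list(tag_clusters = tc, consensus = cons, expr = expr,
                 annotated = ann, de = de, calls = calls,
                 epicats = epicats,
                 convergence = convergence_matrix(epicats)),
            class = "epicat_result")
}

#' @export
print.epicat_result <- function(x, ...) {
  cat("Cryptic-TSS discovery result\n")
  cat(sprintf("  tag clusters:       %d\n", nrow(x$tag_clusters)))
  cat(sprintf("  consensus clusters: %d\n", nrow(x$consensus)))
  cat(sprintf("  EPICAT calls:       %d (%d unique clusters)\n",
              nrow(x$epicats), length(unique(x$epicats$cluster_id))))
  gts <- sort(unique(x$epicats$genotype))
  for (g in gts) {
    cat(sprintf("    %-10s %d\n", g, sum(x$epicats$genotype == g)))
  }
  invisible(x)
}

#' Write pipeline results as TAB-separated text
#'
#' Deterministic plain-text export: consensus clusters (BED-like, with
#' the dominant CTSS as thickStart/thickEnd), the expression matrix,
#' the differential-initiation table, EPICAT calls and the convergence
#' matrix.
#'
#' @param result An `epicat_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name, ...) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, ...)
  }
  bed <- result$annotated %>%
    mutate(score = round(.data$dominant_tpm_pooled, 3),
           thick_start = .data$dominant_pos,
           thick_end = .data$dominant_pos + 1L) %>%
    select("chrom", "start", "end", name = "cluster_id", "score",
           "strand", "thick_start", "thick_end", "feature_class",
           "annotated", "tss_distance")
  w(bed, "consensus_clusters.tsv")
  w(result$expr, "expression.tsv")
  w(tidy(result$de), "differential_initiation.tsv")
  w(result$calls, "epicat_calls.tsv")
  conv <- as.data.frame(result$convergence)
  conv <- cbind(genotype = rownames(result$convergence), conv)
  w(conv, "convergence_matrix.tsv")
  invisible(dir)
}
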