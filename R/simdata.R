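#' Configuration for the synthetic CAGE study generator
#'
#' Defines the study conditions emulated by [simulate_reference()] and
#' [simulate_tracks()]: a compact multi-chromosome genome carrying genes
#' with promoters and UTR/exon structure, transposable elements from a
#' family mix, regular TSSs at gene promoters and cryptic TSSs planted
#' inside TEs and intergenic space, activated only in mutant genotypes.
#' Cluster mean expression is log-normal in TPM; replicate counts are
#' negative-binomial; a TATA box is planted upstream of every planted
#' dominant CTSS.
#'
#' @param n_chroms,chrom_length Genome shape (default 2 x 500 kb).
#' @param n_genes,n_tes Feature counts (300 genes, 200 TEs).
#' @param te_family_mix Named sampling weights over TE families.
#' @param n_regular_tss Regular (wild-type-active) TSSs, at gene
#'   promoters (default 250; must be <= `n_genes`).
#' @param n_cryptic_tss Cryptic TSSs, silent in wild type (default 60).
#' @param fraction_cryptic_in_te Fraction of cryptic TSSs hosted by TEs
#'   (default 0.65, deterministic rounding).
#' @param tata_offset,tata_jitter TATA-box midpoint offset upstream of the
#'   dominant CTSS in nt (default -36 +/- 1).
#' @param narrow_fraction,narrow_fraction_cryptic Fraction of narrow-shape
#'   TSSs among regular / cryptic TSSs.
#' @param narrow_geom_p Two-sided geometric decay parameter of the narrow
#'   per-base kernel (default 0.5, ~1-3 bp spread).
#' @param broad_sd Standard deviation (bp) of the discretized-normal broad
#'   kernel (default 10, so the single-tag support of a deeply sampled
#'   broad cluster stays within the 100-bp cluster-length cap).
#' @param genotypes Mutant genotype labels (wild type `"wt"` is implicit).
#' @param replicates Replicates per genotype (default 2).
#' @param mean_tpm_meanlog,mean_tpm_sdlog Log-normal parameters of the
#'   relative cluster mean expression (defaults `log(30)`, 0.5); drawn
#'   means are rescaled so wild-type-active clusters sum to 1e6 TPM,
#'   which makes realized library totals match the configured library
#'   size.
#' @param nb_dispersion NB dispersion of replicate counts (default 0.1).
#' @param background_rate_per_mb Poisson rate of background singleton tags
#'   per Mb per library (default 50).
#' @param library_size_range Uniform range of library sizes (tags).
#' @param meth_wt_level Wild-type methylation level at TE cytosines
#'   (CG/CHG; CHH is scaled down, default 0.8).
#' @param meth_loss_fraction Fractional methylation loss in a mutant at
#'   TEs/windows hosting cryptic TSSs it activates (default 0.8).
#' @param seed Mandatory RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 500000L,
                       n_genes = 300L, n_tes = 200L,
                       te_family_mix = c("LTR/Gypsy" = 0.30,
                                         "LTR/Copia" = 0.25,
                                         "DNA/En-Spm" = 0.15,
                                         "LINE" = 0.12, "SINE" = 0.08,
                                         "RC/Helitron" = 0.10),
                       n_regular_tss = 250L, n_cryptic_tss = 60L,
                       fraction_cryptic_in_te = 0.65,
                       tata_offset = -36L, tata_jitter = 1L,
                       narrow_fraction = 0.7,
                       narrow_fraction_cryptic = 0.85,
                       narrow_geom_p = 0.5, broad_sd = 10,
                       genotypes = c("ddm1", "met1"), replicates = 2L,
                       mean_tpm_meanlog = log(30), mean_tpm_sdlog = 0.5,
                       nb_dispersion = 0.1,
                       background_rate_per_mb = 50,
                       library_size_range = c(8e5, 1.2e6),
                       meth_wt_level = 0.8, meth_loss_fraction = 0.8,
                       seed) {
  if (missing(seed)) abort("sim_config requires an explicit seed")
  assert_that(n_regular_tss <= n_genes,
              "n_regular_tss cannot exceed n_genes")
  assert_that(all(c(n_chroms, chrom_length, n_genes, n_tes, n_regular_tss,
                    n_cryptic_tss, replicates) >= 0),
              "all counts must be >= 0")
  assert_that(tata_offset < 0, "tata_offset is upstream (negative)")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' The TATA-box word planted by the generator
#'
#' An 8-nt TATA-box consensus word; [tata_motif()] returns a near
#' point-mass PWM on it whose exact best-score p-value (4^-8 under the
#' uniform background) clears the usual 1e-4 instance threshold.
#'
#' @return Character scalar / a `motif_model`.
#' @export
tata_word <- function() "TATAAATA"

#' @rdname tata_word
#' @export
tata_motif <- function() {
  b <- strsplit(tata_word(), "")[[1]]
  m <- matrix(0.01, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(b, rownames(m)), seq_along(b))] <- 0.97
  motif_model(m, id = "TATA")
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# deterministic per-chrom allocation of a total count, largest-remainder
split_count <- function(total, weights) {
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate the reference: genome, annotation and ground truth
#'
#' Lays out genes (promoter + UTR/exon/intron body), TEs and intergenic
#' cryptic-TSS slots along random-sequence chromosomes, plants a TATA box
#' upstream of every planted dominant CTSS, and records the ground truth.
#' Fully deterministic under `config$seed`.
#'
#' @param config A `sim_config`.
#' @return List with `genome` (named character vector of sequences),
#'   `annotation` (a `genome_annotation`) and `truth` (registry tibble:
#'   `tss_id`, `kind`, `chrom`, `strand`, `dominant_pos`, `shape`,
#'   `host`, `host_id`, `te_family`, `active_genotypes` comma-separated,
#'   `mean_tpm`).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_cry_te <- as.integer(round(config$fraction_cryptic_in_te *
                                 config$n_cryptic_tss))
  n_cry_ig <- config$n_cryptic_tss - n_cry_te

  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  w <- rep(1, config$n_chroms)
  genes_per <- split_count(config$n_genes, w)
  tes_per <- split_count(config$n_tes, w)
  slots_per <- split_count(n_cry_ig, w)

  seqs <- list()
  genes <- list(); feats <- list(); tes <- list(); islots <- list()
  gene_i <- 0L; te_i <- 0L
  for (ci in seq_len(config$n_chroms)) {
    L <- config$chrom_length
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    items <- sample(c(rep("gene", genes_per[ci]), rep("te", tes_per[ci]),
                      rep("islot", slots_per[ci])))
    cursor <- 1500L
    for (it in items) {
      cursor <- cursor + sample(100:250, 1)
      if (it == "gene") {
        gene_i <- gene_i + 1L
        strand <- sample(c("+", "-"), 1)
        utr5_len <- sample(60:120, 1)
        n_ex <- sample(1:2, 1)
        ex_len <- sample(150:300, n_ex, replace = TRUE)
        in_len <- if (n_ex > 1) sample(80:150, n_ex - 1, replace = TRUE) else integer(0)
        utr3_len <- sample(80:140, 1)
        body_len <- utr5_len + sum(ex_len) + sum(in_len) + utr3_len
        extent <- body_len + 1000L
        if (cursor + extent > L - 1500L) {
          abort("requested features exceed genome capacity")
        }
        b_start <- if (strand == "+") cursor + 1000L else cursor
        b_end <- b_start + body_len
        tss <- if (strand == "+") b_start else b_end - 1L
        gid <- sprintf("gene_%04d", gene_i)
        # genomic layout 5'->3' (flip for minus strand)
        pieces <- c(utr5 = utr5_len)
        for (k in seq_len(n_ex)) {
          pieces <- c(pieces, setNames(ex_len[k], paste0("cds", k)))
          if (k < n_ex) pieces <- c(pieces, setNames(in_len[k], paste0("int", k)))
        }
        pieces <- c(pieces, utr3 = utr3_len)
        if (strand == "-") pieces <- rev(pieces)
        offs <- cumsum(c(0, pieces))
        pstart <- b_start + offs[-length(offs)]
        pend <- b_start + offs[-1]
        nm <- names(pieces)
        # exon records cover UTRs + CDS so introns derive correctly
        is_intr <- startsWith(nm, "int")
        runs <- rle(!is_intr)
        idx_end <- cumsum(runs$lengths)
        idx_start <- idx_end - runs$lengths + 1
        frow <- list()
        for (rr in seq_along(runs$values)) {
          if (!runs$values[rr]) next
          frow[[length(frow) + 1]] <- tibble(
            gene_id = gid, type = "exon", chrom = chroms[ci],
            strand = strand, start = pstart[idx_start[rr]],
            end = pend[idx_end[rr]])
        }
        frow[[length(frow) + 1]] <- tibble(
          gene_id = gid, type = "utr5", chrom = chroms[ci], strand = strand,
          start = pstart[nm == "utr5"], end = pend[nm == "utr5"])
        frow[[length(frow) + 1]] <- tibble(
          gene_id = gid, type = "utr3", chrom = chroms[ci], strand = strand,
          start = pstart[nm == "utr3"], end = pend[nm == "utr3"])
        feats[[length(feats) + 1]] <- bind_rows(frow)
        genes[[length(genes) + 1]] <- tibble(
          gene_id = gid, chrom = chroms[ci], strand = strand,
          start = b_start, end = b_end, tss = tss)
        cursor <- cursor + extent
      } else if (it == "te") {
        te_i <- te_i + 1L
        len <- sample(300:1200, 1)
        if (cursor + len > L - 1500L) {
          abort("requested features exceed genome capacity")
        }
        fam <- sample(names(config$te_family_mix), 1,
                      prob = config$te_family_mix)
        tes[[length(tes) + 1]] <- tibble(
          te_id = sprintf("te_%04d", te_i), chrom = chroms[ci],
          start = cursor, end = cursor + len, family = fam,
          superfamily = sub("/.*$", "", fam))
        cursor <- cursor + len
      } else {
        if (cursor + 600L > L - 1500L) {
          abort("requested features exceed genome capacity")
        }
        islots[[length(islots) + 1]] <- tibble(
          chrom = chroms[ci], pos = cursor + 300L)
        cursor <- cursor + 600L
      }
    }
    seqs[[chroms[ci]]] <- base
  }
  genes <- bind_rows(genes); feats <- bind_rows(feats)
  tes <- bind_rows(tes)
  islots <- bind_rows(c(list(tibble(chrom = character(), pos = integer())),
                        islots))

  # regular TSSs: planted in the promoters of a sample of genes
  reg_genes <- genes[sort(sample(nrow(genes), config$n_regular_tss)), ]
  reg <- reg_genes %>%
    mutate(up = sample(0:60, n(), replace = TRUE),
           dominant_pos = ifelse(.data$strand == "+",
                                 .data$tss - .data$up, .data$tss + .data$up),
           tss_id = sprintf("reg_%04d", row_number()),
           kind = "regular", host = "promoter", host_id = .data$gene_id,
           te_family = NA_character_) %>%
    select("tss_id", "kind", "chrom", "strand", "dominant_pos",
           "host", "host_id", "te_family")

  # cryptic TSSs: hosts are TEs (>= 400 bp) and dedicated intergenic slots
  hosts_te <- tes %>% filter(.data$end - .data$start >= 400L)
  assert_that(nrow(hosts_te) >= n_cry_te,
              "not enough TEs >= 400 bp to host cryptic TSSs")
  hosts_te <- hosts_te[sort(sample(nrow(hosts_te), n_cry_te)), ]
  cry_te <- hosts_te %>%
    mutate(dominant_pos = .data$start + 150L +
             vapply(.data$end - .data$start - 300L,
                    function(w) sample(w, 1L), integer(1)),
           strand = sample(c("+", "-"), n(), replace = TRUE),
           kind = "cryptic", host = "te", host_id = .data$te_id,
           te_family = .data$family) %>%
    select("kind", "chrom", "strand", "dominant_pos", "host", "host_id",
           "te_family")
  assert_that(nrow(islots) >= n_cry_ig,
              "not enough intergenic slots for cryptic TSSs")
  cry_ig <- islots[seq_len(n_cry_ig), ] %>%
    mutate(strand = sample(c("+", "-"), n(), replace = TRUE),
           kind = "cryptic", host = "intergenic", host_id = NA_character_,
           te_family = NA_character_) %>%
    rename(dominant_pos = "pos") %>%
    select("kind", "chrom", "strand", "dominant_pos", "host", "host_id",
           "te_family")
  cry <- bind_rows(cry_te, cry_ig) %>%
    mutate(tss_id = sprintf("cry_%04d", row_number())) %>%
    select("tss_id", dplyr::everything())

  truth <- bind_rows(reg, cry) %>%
    mutate(
      shape = ifelse(
        runif(n()) < ifelse(.data$kind == "cryptic",
                            config$narrow_fraction_cryptic,
                            config$narrow_fraction),
        "narrow", "broad"),
      mean_tpm = rlnorm(n(), config$mean_tpm_meanlog, config$mean_tpm_sdlog),
      # rescale so wild-type-active clusters sum to 1e6 TPM: realized
      # library totals then match the configured library size and one tag
      # corresponds to roughly one TPM, as in a real CAGE library
      mean_tpm = .data$mean_tpm * 1e6 /
        max(sum(.data$mean_tpm[.data$kind == "regular"]),
            sum(.data$mean_tpm)),
      active_genotypes = ifelse(
        .data$kind == "regular",
        paste(c("wt", config$genotypes), collapse = ","),
        vapply(seq_len(n()), function(i) {
          k <- sample(seq_along(config$genotypes), 1)
          paste(sort(sample(config$genotypes, k)), collapse = ",")
        }, character(1))))

  # plant a TATA-box word upstream of every planted dominant CTSS
  tata <- strsplit(tata_word(), "")[[1]]
  tata_rc <- strsplit(revcomp_chr(tata_word()), "")[[1]]
  w <- length(tata)
  for (i in seq_len(nrow(truth))) {
    off <- config$tata_offset +
      sample(seq(-config$tata_jitter, config$tata_jitter), 1)
    mid <- if (truth$strand[i] == "+") truth$dominant_pos[i] + off
           else truth$dominant_pos[i] - off
    word <- if (truth$strand[i] == "+") tata else tata_rc
    # 0-based word start so that the instance midpoint = start + floor(w/2)
    s0 <- mid - w %/% 2L
    seqs[[truth$chrom[i]]][(s0 + 1L):(s0 + w)] <- word
  }

  genome <- vapply(seqs, paste, character(1), collapse = "")
  list(genome = genome,
       annotation = genome_annotation(genes, feats, tes),
       truth = truth %>%
         select("tss_id", "kind", "chrom", "strand", "dominant_pos",
                "shape", "host", "host_id", "te_family",
                "active_genotypes", "mean_tpm"))
}

#' Simulate CTSS tracks and methylation tables
#'
#' For every sample (wild type plus each mutant genotype, `replicates`
#' libraries each) and every TSS active in that genotype, the cluster
#' total count is negative-binomial with mean `mean_tpm * libsize / 1e6`
#' and the configured dispersion; tags are placed around the dominant
#' CTSS by a two-sided geometric kernel (narrow) or a discretized normal
#' kernel (broad). Background singleton tags are Poisson over the genome.
#' Methylation tables carry every TE cytosine plus cytosines within
#' 75 bp of cryptic TSSs, at the wild-type level in wild type and reduced
#' by `meth_loss_fraction` in a mutant at TEs/windows whose cryptic TSSs
#' it activates. Deterministic under `config$seed`.
#'
#' @param ref Output of [simulate_reference()].
#' @param config The same `sim_config`.
#' @return List with `tracks` (normalized CTSS tibble, all samples),
#'   `samples` (metadata tibble), `methylation` (tibble with `genotype`,
#'   `chrom`, `pos`, `strand`, `context`, `meth`, `total`).
#' @export
simulate_tracks <- function(ref, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  truth <- ref$truth
  active_sets <- strsplit(truth$active_genotypes, ",", fixed = TRUE)
  genotypes <- c("wt", config$genotypes)
  chrom_len <- nchar(ref$genome)

  rows <- list()
  samples <- list()
  for (g in genotypes) {
    for (r in seq_len(config$replicates)) {
      sid <- sprintf("%s_%d", g, r)
      samples[[length(samples) + 1]] <- tibble(
        sample_id = sid, genotype = g, replicate = r)
      lib <- runif(1, config$library_size_range[1],
                   config$library_size_range[2])
      act <- which(vapply(active_sets, function(s) g %in% s, logical(1)))
      pos_all <- integer(0); strand_all <- character(0)
      chrom_all <- character(0)
      for (i in act) {
        mu <- truth$mean_tpm[i] * lib / 1e6
        total <- rnbinom(1, mu = mu, size = 1 / config$nb_dispersion)
        if (total == 0) next
        off <- if (truth$shape[i] == "narrow") {
          rgeom(total, config$narrow_geom_p) *
            sample(c(-1L, 1L), total, replace = TRUE)
        } else {
          as.integer(round(rnorm(total, 0, config$broad_sd)))
        }
        p <- truth$dominant_pos[i] + off
        p <- pmin(pmax(p, 0L), chrom_len[truth$chrom[i]] - 1L)
        pos_all <- c(pos_all, p)
        strand_all <- c(strand_all, rep(truth$strand[i], total))
        chrom_all <- c(chrom_all, rep(truth$chrom[i], total))
      }
      n_bg <- rpois(1, config$background_rate_per_mb *
                      sum(chrom_len) / 1e6)
      if (n_bg > 0) {
        bg_chrom <- sample(names(chrom_len), n_bg, replace = TRUE,
                           prob = chrom_len)
        bg_pos <- vapply(bg_chrom, function(ch) sample(chrom_len[[ch]], 1L) - 1L,
                         integer(1))
        pos_all <- c(pos_all, bg_pos)
        strand_all <- c(strand_all, sample(c("+", "-"), n_bg, replace = TRUE))
        chrom_all <- c(chrom_all, bg_chrom)
      }
      tr <- tibble(chrom = chrom_all, pos = as.integer(pos_all),
                   strand = strand_all) %>%
        dplyr::count(.data$chrom, .data$pos, .data$strand, name = "count") %>%
        mutate(sample_id = sid, genotype = g, replicate = r) %>%
        select("sample_id", "genotype", "replicate", "chrom", "pos",
               "strand", "count")
      rows[[length(rows) + 1]] <- tr
    }
  }
  tracks <- bind_rows(rows) %>%
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$strand)
  validate_ctss(tracks)
  tracks <- tpm_normalize(tracks)

  methylation <- simulate_methylation(ref, config, genotypes)

  list(tracks = tracks,
       samples = bind_rows(samples),
       methylation = methylation)
}

# cytosine records over TE spans and cryptic windows, with genotype-
# dependent methylation loss at activated cryptic TSS loci
simulate_methylation <- function(ref, config, genotypes) {
  truth <- ref$truth
  tes <- ref$annotation$tes
  half <- 75L
  windows <- bind_rows(
    tes %>% select("chrom", "start", "end") %>%
      mutate(key = tes$te_id),
    truth %>% filter(.data$kind == "cryptic") %>%
      mutate(start = pmax(.data$dominant_pos - half, 0L),
             end = .data$dominant_pos + half + 1L, key = .data$tss_id) %>%
      select("chrom", "start", "end", "key")
  )
  cry <- truth %>% filter(.data$kind == "cryptic")
  lost_keys <- function(g) {
    act <- cry[vapply(strsplit(cry$active_genotypes, ",", fixed = TRUE),
                      function(s) g %in% s, logical(1)), ]
    c(act$tss_id, act$host_id[!is.na(act$host_id)])
  }

  base_by_chrom <- lapply(ref$genome, function(s) strsplit(s, "")[[1]])
  recs <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    ch <- windows$chrom[i]
    b <- base_by_chrom[[ch]]
    idx <- (windows$start[i] + 1L):min(windows$end[i], length(b))
    bases <- b[idx]
    keep <- bases %in% c("C", "G")
    if (!any(keep)) return(NULL)
    idx <- idx[keep]; bases <- bases[keep]
    ctx <- vapply(seq_along(idx), function(k) {
      j <- idx[k]
      if (bases[k] == "C") {
        nxt1 <- if (j + 1 <= length(b)) b[j + 1] else "N"
        nxt2 <- if (j + 2 <= length(b)) b[j + 2] else "N"
        if (nxt1 == "G") "CG" else if (nxt2 == "G") "CHG" else "CHH"
      } else {
        pr1 <- if (j - 1 >= 1) b[j - 1] else "N"
        pr2 <- if (j - 2 >= 1) b[j - 2] else "N"
        if (pr1 == "C") "CG" else if (pr2 == "C") "CHG" else "CHH"
      }
    }, character(1))
    tibble(chrom = ch, pos = idx - 1L,
           strand = ifelse(bases == "C", "+", "-"),
           context = ctx, key = windows$key[i])
  }) %>% distinct(.data$chrom, .data$pos, .data$strand,
                  .keep_all = TRUE)

  level0 <- c(CG = config$meth_wt_level, CHG = config$meth_wt_level * 0.9,
              CHH = config$meth_wt_level * 0.2)
  purrr::map_dfr(genotypes, function(g) {
    lost <- if (g == "wt") character(0) else lost_keys(g)
    lvl <- level0[recs$context] *
      ifelse(recs$key %in% lost, 1 - config$meth_loss_fraction, 1)
    total <- rpois(nrow(recs), 17) + 3L
    meth <- rbinom(nrow(recs), total, lvl)
    tibble(genotype = g, chrom = recs$chrom, pos = recs$pos,
           strand = recs$strand, context = recs$context,
           meth = meth, total = total)
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper: [simulate_reference()] then [simulate_tracks()].
#'
#' @param config A `sim_config`.
#' @return List: `genome`, `annotation`, `truth`, `tracks`, `samples`,
#'   `methylation`.
#' @export
simulate_study <- function(config) {
  ref <- simulate_reference(config)
  tr <- simulate_tracks(ref, config)
  c(ref, tr)
}
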