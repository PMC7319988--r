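---
title: "Discovering epigenetically suppressed cryptic TSSs from CAGE data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering epigenetically suppressed cryptic TSSs from CAGE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicat)
library(dplyr)
```

## The problem

Cap analysis of gene expression (CAGE) sequences the 5' ends of capped
transcripts and, after alignment, yields per-base counts of transcription
start signal: CTSSs (CAGE transcription start sites at single-base
resolution, strand-specific). In plants, repressive chromatin — DNA
methylation in CG/CHG/CHH contexts, H3K9me2 and related marks — silences
not only transposable elements (TEs) but also a hidden layer of *cryptic*
promoters. When the maintenance machinery is compromised (e.g. in
*met1*, *ddm1*, *suvh456* or RNA-directed DNA methylation mutants of
*Arabidopsis thaliana*), transcription initiates de novo from loci that
are silent in wild-type plants. This package implements a complete,
reusable pipeline for detecting such loci — EPICATs, *epigenetically
induced consensus tag clusters* — from multi-genotype, multi-replicate
CTSS tracks, together with the downstream statistics used to
characterize them, and a seeded synthetic-data generator that provides a
full ground-truth test bed.

## From tags to TSSs

**Normalization and filtering.** Raw per-base counts are converted to
tags per million (TPM) by each library's total. A position enters the
clustering input only if its TPM is at least `tpm_threshold` (default
0.1) in at least `nr_pass` samples (default 2); positions failing the
filter are excluded from cluster *formation* but still counted during
quantification. The filter is applied across all supplied tracks; if a
per-genotype run is preferred, the functions accept any subset of
samples.

**Density-stability clustering.** Within one sample, chromosome and
strand, CTSSs are grouped by the paraclu principle: for a density
penalty $d \ge 0$, a segment $S$ of consecutive sites scores
$\mathrm{score}(S, d) = \sum_{i \in S} \mathrm{tpm}_i - d \cdot
\mathrm{span}(S)$ with $\mathrm{span} = \mathrm{last} - \mathrm{first} +
1$ bp. As $d$ sweeps upward, the optimal segmentation refines through a
nested (laminar) family of candidates; each candidate carries the
density interval $[d_{\min}, d_{\max}]$ on which it is part of the
segmentation, where $d_{\min}$ is the density at which its parent
dissolves and $d_{\max}$ the density at which it dissolves itself. The
implementation uses the weakest-prefix/weakest-suffix recursion; the
test suite verifies it, including the interval endpoints, against a
brute-force oracle that enumerates all endpoint-sharing subsegments and
checks the partition property at sampled densities. Conventions: a lone
site has $d_{\min} = 0$, $d_{\max} = \infty$; candidates with an empty
density interval (ties) are dropped; dominant-CTSS ties break toward the
site nearest the cluster midpoint, then the lower coordinate.

**Pruning.** Retained tag clusters need stability
$d_{\max}/d_{\min} \ge 2$ and span $\le 100$ bp; longer candidates are
discarded rather than trimmed, since the clustering contract specifies a
hard cap and trimming would manufacture spans the recursion never
produced. Single-site clusters are removed unless their signal exceeds
0.3 TPM. Among nested survivors the outermost is kept, which together
with laminarity guarantees disjoint clusters per sample and strand.

**Shape.** The interquantile width is the distance between the first
site where cumulative signal reaches 10% of the cluster total and the
first site where it reaches 90% (inclusive). Clusters are classed NP
(narrow peak, width <= 10 bp), BP (broad with peak, <= 40 bp) or WP
(weak peak) — the cutoffs are configuration, defaulting to values that
separate the generator's narrow and broad kernels cleanly; empirical
calibration against external shape catalogs is out of scope.

**Consensus.** Tag clusters from all samples on the same strand are
merged transitively whenever the gap between spans is at most 100 bp;
the consensus span is the union extent (no quantile trimming, matching
an aggregation run with both trim quantiles unset). A consensus cluster
is kept when its within-span filtered signal reaches 0.3 TPM in at
least one sample, and its dominant CTSS is the argmax of pooled per-base
TPM. Expression is then quantified per sample as the sum of *all* raw
counts inside the span — including positions that failed the expression
filter — because testing uses raw counts.

## Annotation

Promoters are the 1-kb regions upstream of annotated gene TSSs,
strand-aware. Each consensus cluster is classified by the location of
its dominant CTSS alone, against feature intervals in strict precedence:

PROMOTER > 5'UTR > 3'UTR > INTRON > EXON > ANTISENSE > TE > INTERGENIC.

Sense features require matching strand; ANTISENSE means inside a gene on
the opposite strand; TE hits ignore strand. Independently, a cluster is
ANNOTATED when the unsigned distance from its dominant CTSS to the
nearest annotated TSS *in the same orientation* is strictly below 180
nt, NON-ANNOTATED otherwise. The distance is unsigned (upstream and
downstream both count) because only distance and orientation enter the
rule; a flag can restrict it if a signed variant is wanted.

## Differential initiation and EPICAT calling

Raw consensus counts are tested per mutant genotype against wild type
with a self-contained negative-binomial Wald test:

* size factors by median-of-ratios (geometric-mean reference over
  clusters positive in every sample; library-total fallback with a
  warning);
* per-cluster method-of-moments dispersion on normalized counts, shrunk
  toward the trimmed-mean dispersion across clusters with prior weight
  `prior_df = 10` — with two replicates per group the prior dominates,
  which is intended;
* group means with a pseudo-mean of 0.5 normalized counts stabilizing
  the log at zero counts; the Wald statistic divides the log2 fold
  change by its delta-method standard error, two-sided normal p;
* Benjamini–Hochberg correction within genotype, decision rule
  padj <= 0.1.

The test's type-I error at nominal 0.05 is checked by simulation (2 vs
2, dispersion 0.1, 2000 clusters) and its FDR control on a 10%-signal
mixture; both run in the test suite. A cluster is called an EPICAT in a
genotype iff it is (i) NON-ANNOTATED, (ii) significantly up-regulated
there (padj <= 0.1 and log2FC > 0), and (iii) activated de novo — TPM
below 0.1 in every wild-type replicate. The de novo threshold
operationalizes "exclusively expressed in the mutant"; it is
configurable, and gates (ii) and (iii) can be disabled individually
since the literature does not fix whether significance is required in
addition to wild-type absence. The convergence matrix counts EPICATs
shared between mutants.

## Downstream statistics

* **Motifs.** PWM scanning scores every position on both strands with
  log-odds against a 0-order background; p-values are exact, from the
  dynamic-programming convolution of per-column score distributions
  (states are exact partial sums, so the approach suits core-promoter
  motifs up to ~10 columns). Instances at p <= 1e-4 are summarized as a
  strand-oriented positional profile around dominant CTSSs (upstream
  negative), smoothed with a 3-nt moving average; a peak is reported
  only above mean + 3 sd of the smoothed profile. Ambiguous bases score
  zero log-odds rather than failing.
* **Directionality.** $D = (S_\mathrm{sense} - S_\mathrm{anti}) /
  (S_\mathrm{sense} + S_\mathrm{anti})$ over ±100 bp of the dominant
  CTSS (window configurable; the appropriate half-width is not settled,
  so it is exposed); undefined when both strands are silent.
* **Methylation.** Coverage-weighted levels over cytosines of one
  context in an odd window (101 bp default) centered on the dominant
  CTSS; missing when no covered cytosine. Paired two-sided t-tests
  compare levels across genotypes; the low-CHG subset rule (< 10% CHG in
  the window) reproduces the filter used for intragenic cryptic TSSs.
* **TE enrichment.** A TE harbors an EPICAT when the EPICAT's dominant
  CTSS falls in its span; per-family upper-tail hypergeometric
  p-values, with families under 5 genome copies flagged low-power.
* **Neighbors.** Wild-type-active PROMOTER/5'UTR clusters within 3 kb of
  an EPICAT are paired across genotypes; per-genotype paired t-tests on
  mean TPM (per-cluster means across replicates — replicate-level
  pairing is not used since the pairing unit is the locus), and a
  `suppressed` flag when mutant expression is exactly 0 in all
  replicates.
* Mann–Whitney tests are exact for groups of up to 10 without ties,
  normal-approximated with tie correction otherwise; Fisher's exact test
  and BH correction use the standard library routines, cross-checked in
  the test suite against enumeration oracles.

## The synthetic study

`sim_config(seed = ...)` defines the default study: 2 chromosomes x
500 kb, 300 genes (1-kb promoters; UTR/exon/intron bodies), 200 TEs
drawn from a family mix dominated by LTR/Gypsy and LTR/Copia, 250
regular TSSs planted in gene promoters, and 60 cryptic TSSs — 65%
inside TEs, the rest intergenic — each active in one or two of two
mutant genotypes and silent in wild type. Two replicates per genotype.

Generative details and the reasoning behind them:

* Cluster mean expression is log-normal (meanlog `log(30)`, sdlog 0.5)
  *relatively*; means are rescaled so wild-type-active clusters sum to
  1e6 TPM. Realized library totals then land in the configured library
  range (0.8–1.2 M tags) and one tag corresponds to roughly one TPM, so
  the pipeline's TPM thresholds act at the intended scale. Because the
  toy genome concentrates a whole library into ~300 loci, per-cluster
  TPM is high; tag-cluster tails can therefore survive as singleton
  clusters (1 tag ≈ 1 TPM > 0.3), which the consensus-aggregation stage
  absorbs — a useful reminder that consensus clusters, not per-sample
  tag clusters, are the analysis unit.
* Replicate counts are NB with dispersion 0.1; per-base placement uses a
  two-sided geometric kernel (p = 0.5, ~1–3 bp spread) for narrow TSSs
  and a discretized normal (sd 10 bp) for broad ones. The broad sd is
  chosen so that the single-tag support of a deeply sampled broad
  cluster stays inside the 100-bp cluster-length cap; a wider kernel at
  this coverage shatters into singletons by construction.
* An 8-nt TATA-box word (`TATAAATA`) is planted with its midpoint 36 ± 1
  nt upstream of every planted dominant CTSS, strand-aware; 8 columns
  are needed for an exact PWM p-value below 1e-4 (a 6-mer point mass
  bottoms out at 4^-6 ≈ 2.4e-4).
* Background noise: Poisson singleton tags at 50 per Mb per library.
* Methylation: cytosine records (contexts read from the simulated
  sequence) across TE spans and 151-bp windows around cryptic TSSs; CG
  and CHG at level 0.8 (CHH scaled to 0.16) in wild type, reduced by
  80% in a mutant at exactly the TEs/windows whose cryptic TSSs it
  activates — coupling methylation loss to activation so the
  methylation-window statistics have planted signal.
* Geometry guarantees: genes reserve their promoter on the TSS side;
  TEs and intergenic slots sit between gene units, so every cryptic TSS
  is > 1 kb from any annotated TSS (hence NON-ANNOTATED) and planted
  TSSs are mutually separated beyond the 100-bp merge distance.
* Everything is deterministic under the seed: two runs produce
  byte-identical tables.

What the generator does *not* emulate: realistic sequence composition
(GC skew, codon structure, repeat libraries), read-level artifacts
(mapping ambiguity, the CAGE first-base G bias), biological variation
beyond NB noise, partial methylation loss gradients, and genome-scale
TSS counts. Passing the recovery tests therefore demonstrates that the
pipeline's logic is correct under its stated model, not that the
thresholds are optimal for any particular real organism.

## Problem sizes and numerical choices

The bundled validation runs at desk scale by design: the recovery study
uses the default 1-Mb genome and 6 libraries; clustering oracles use
500 random instances of up to 12 sites; calibration uses 2000 simulated
clusters; motif recovery uses 200 planted TSSs on a 450-kb chromosome.
Exact-test oracles enumerate assignments or tables directly. Degenerate
inputs are defined rather than left to chance: empty libraries error on
normalization; all-zero clusters test at p = 1 with log2FC 0; zero-variance
paired differences are flagged degenerate; flat motif profiles report no
peak; methylation windows without covered cytosines are missing, not 0.

## Limitations

The NB engine is intentionally simpler than full shrinkage estimators
(no per-cluster GLM, no fold-change moderation, no independent
filtering); it preserves the decision semantics (raw counts,
padj <= 0.1) and is validated by calibration, not by numeric equality
with any external tool. Classification keys on the dominant CTSS only;
clusters straddling feature boundaries inherit the dominant base's
class. The 180-nt annotated radius is applied unsigned. PWM p-values
assume a 0-order background. On real data, parameters set here as
defaults (promoter length, shape cutoffs, detection thresholds) should
be revisited against the organism's annotation quality.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 42)
sim <- simulate_study(cfg)
res <- epicat_pipeline(sim$tracks, sim$annotation, sim$samples)
res
glance(res$de)
plot_feature_classes(res$annotated)
plot_convergence(res$convergence)
```
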