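---
title: "Models and methods behind pirnascape"
author: "pirnascape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pirnascape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The biological system

Nematode piRNAs (21U-RNAs) are unusual among animal piRNAs: each mature 21-nt,
5′-uracil small RNA is the product of its own miniature RNA polymerase II
transcription unit. The promoter is marked by an upstream "Ruby" motif with a
GTTTC core whose start sits ~42 nt upstream of the mature 21U 5′ end, and
transcription initiates 2 nt upstream of the 21U start, producing a short
capped precursor (~28 nt and longer) that is later trimmed. Species organise
these loci in two broad ways: **clustered** organisation, with thousands of
loci packed into a few chromosomal regions embedded in repressed (H3K27me3,
"regulated") chromatin, and **dispersed** organisation, with loci scattered
through introns of active (H3K36me3) genes. Downstream of the TSS the DNA
shows a characteristic melting-temperature signature — a high-Tm stretch over
the first ~20 transcribed nucleotides followed by a low-Tm "valley" at +20..+40
— consistent with sequence-encoded Pol II pausing that couples to short
precursor release.

`pirnascape` implements the quantitative machinery needed to annotate these
loci and characterise their organisation, selection, and pausing signatures,
and pairs it with a synthetic-species generator so that every stage can be
validated against planted ground truth.

# Coordinate conventions

All positional reasoning happens on `GRanges` (1-based, closed intervals),
the standard currency of the Bioconductor stack. Off-by-one conversions are
confined to the I/O boundary: BED input/output is converted from/to its
0-based half-open disk convention by `rtracklayer`, GFF3 is native 1-based,
and the read-site TSV interface stores 0-based half-open coordinates on disk
(documented in `read_sites_tsv()`). Strand-aware arithmetic — the 110/30
upstream scan window, the TSS at 21U start − 2, the +20..+40 valley — is
expressed through `GenomicRanges::promoters()` and explicit strand mirrors,
so the same code path serves both strands. Windows containing N are excluded
from motif and Tm scoring rather than scored with fabricated values.

# Motif model

`build_pwm()` turns aligned sites into a log2-odds position weight matrix
with a background-proportional pseudocount:
`log2((n_ib + pc*q_b)/(n + pc)/q_b)`. Scores are in bits by default; a
`scale` factor lets users express thresholds on any externally calibrated
log-odds scale, because published absolute thresholds are only meaningful
relative to a stated scale. `scan_window()` scans one strand only — windows
are extracted strand-aware upstream of the 21U site, which is the geometry
that defines the motif — and breaks ties toward the smallest offset.

Thresholds are not chosen by eye: motif score distributions over 21U upstream
windows are bimodal (true promoter motifs vs. background), and
`fit_score_threshold()` fits a two-component Gaussian mixture (`mclust`,
model-based deterministic initialisation) and returns the equal-posterior
point between the component means. A separation diagnostic
(|Δmean|/pooled SD < 1) flags effectively unimodal inputs where no reliable
threshold exists. When the mixture likelihood degenerates (e.g. point-mass
inputs) a k-means split with a midpoint threshold is used as a guarded
fallback.

The motif-to-21U distance is measured **motif start → 21U start** and loci
are called within 42 ± 5 nt (`call_pirna_loci()`); both the centre and the
tolerance are arguments. The tolerance is tight enough to exclude chance
upstream hits yet wide enough for small annotation jitter.

# Clustering statistics

Per-contig enrichment uses the exact one-sided binomial tail against the
uniform-placement null (contig probability = contig length / genome length).
The **span-90** statistic orders contigs by increasing p-value (ties broken
by decreasing locus density, then name — the ordering must be total for
reproducibility) and reports the cumulative span at which 90% of loci are
covered. Species-level classification fits a two-component
mixture of linear regressions of span-90 on locus count by EM with 20 random
restarts (equal residual variances by default, which is the stable choice
for tens of points); the low-span component is labelled clustered. A
collinearity check short-circuits the degenerate all-one-line case.

# Chromatin context

Loci are assigned to chromatin domains by their **TSS position** — loci are
21 bp but the TSS is the biologically operative point; results may differ
slightly from any-overlap assignment. Genes are assigned a domain state when
≥ 75% of the gene body is covered by that state, a rule that is invariant to
domain fragmentation because same-state intervals are merged first. The
genicness score is
`G = log2(observed genic/intergenic ratio / median simulated ratio)` over
uniform random placements that preserve locus count and length
(genome-wide, or per source contig to absorb regional composition biases),
with a 0.5 pseudocount guard and the (1 + exceedances)/(n_sim + 1) empirical
p-value, which can never return zero. Expression strata come from k-means
(k = 2) on log2(RPKM + 0.1); the reported threshold is the back-transformed
midpoint of the cluster centres.

# Selection on motifs

For every strain SNP inside a qualifying motif window the motif is rescored
with the alternate allele substituted (strand-aware). A SNP is *disruptive*
when the score drops by at least the disruption threshold; thresholds should
be scaled by motif information content across species
(`scale_disruption_threshold()`), since the same absolute score change means
more in a lower-information motif. The allele class (major > 0.9, minor
< 0.1 of strains) is assigned to the **low-scoring allele's** frequency —
when the reference allele is itself the low-scoring state, the relevant
question is still how many strains carry the weaker promoter. Purifying
selection then appears as a deficit of major low-scoring alleles in
functional strata, tested by Fisher's exact test between strata.

# Pausing signals

Tm profiles use nearest-neighbour thermodynamics (Breslauer 1986 parameter
table, pluggable) over 9-nt windows shifted by 1 nt, with
`Tm = 1000·ΔH/(ΔS + R·ln(C/4)) − 273.15 + 16.6·log10([Na+])` at 50 nM DNA
and 50 mM Na+. Each value is indexed by its **window start**, so "TSS to
+19" means windows whose starts lie in [0, 19]. The pausing strength is

    S = Σ_{i∈[0,19]} (Tm_i − B)  +  Σ_{i∈[20,40]} (B − Tm_i),

with background B the mean Tm over the −200..−100 and +100..+200 flanks.
The sums are **signed** (not clipped at zero); a `clip` flag provides the
rectified variant for sensitivity analysis. Note that B nearly cancels in S
(it enters with net coefficient ≈ 1), so S is robust to flank-composition
noise and invariant to adding a constant to the whole profile.

The BILD (Bayesian Integral Log-Odds) column score under a Dirichlet prior
α_b = α0·q_b (α0 = 1 by default) is

    ln[ Γ(α0)/Γ(α0+n) · Π_b Γ(α_b+n_b)/Γ(α_b) ] − Σ_b n_b ln q_b,

which is exactly zero for a single observation. The termination-peak area is
the baseline-subtracted sum over +20..+40, with the baseline taken as the
**median** flank score (robust to the TSS-proximal bump); this definition is
recorded in the output because "area of a peak" admits several readings.

Precursor length comparisons use the Wilcoxon rank-sum test, exact when both
sides are small (product of sizes ≤ 10 000) and tie-free; with ties the
normal approximation with continuity correction is used and flagged. The
abundance-weighted resampling test guards against the depth artefact that
longer precursors are rarer: each replicate draws equal-size subsamples
without replacement with probability proportional to read count, and the
null distribution repeats the identical procedure with both sides drawn from
the first library, so test and null are exchangeable when the libraries are
exchangeable. The rRNA fragment-length control replays the comparison on
rRNA degradation products, whose lengths carry no genotype signal, to flag
library size-selection artefacts.

# The synthetic-species generator

`generate_species()` plants ground truth that exercises every analysis
stage. Defaults describe a nematode-like genome: 36% GC, 20 contigs of
500 kb, 500 loci. Each locus is a construct on a random strand with the
motif consensus (mutated with probability 0.3 at one position), the 21U
start 42 nt from the motif start, a forced T at the 21U 5′ position, a
GC-rich tract over window starts [TSS, +19] and an AT-rich valley over
[+20, +40] (optionally shifted downstream). Valley depths are drawn
uniformly from 3–18 °C — spanning weak to strong pausing signatures. The
valley's per-window Tm target is a **tent**, bottoming at background − depth
at window +30 and rising to 65% of the depth at the edges, so the valley has
a well-defined centre; its three sequence segments are chosen by in-context
candidate selection minimising the squared error of the realised 21-window
profile against that target (the GC-rich high tract is likewise selected in
context, accounting for boundary-straddling windows and the forced 5′ U).
This makes the planted depth a calibrated quantity in °C rather than a loose
compositional knob. Clustered mode confines ≥ 95% of planted loci to
regulated domains on two contigs; dispersed mode hosts ≥ 90% of loci in
introns of two-exon genes within active chromatin, spread over all contigs.
Decoy 21U sites (random positions with no planted motif) emulate spurious
short-RNA mappings and make the score distribution genuinely bimodal.

Simulated libraries couple biology to the planted depth: 21U and precursor
abundance increase with depth, and precursor length is 28 + Geometric(p)
truncated at 100 nt with p increasing in depth, so strong pausing yields
shorter, more abundant precursors. miRNA normaliser genes have fixed
lognormal means multiplied by per-library scale factors; rRNA fragments have
a depth-independent length distribution. Strain panels draw per-SNP
population frequencies from Beta(0.3, 0.3) (a U-shaped spectrum with
realistic major/minor tails) sampled over n strains; the constraint knob
redraws disruptive motif alleles in regulated-chromatin loci from a
low-frequency Beta(0.5, 8) with the given probability.

What the generator does **not** emulate: sequencing error, adapters,
multi-mapping, repeat content, ping-pong amplification (absent in
nematodes), or realistic gene structure beyond two exons. Passing tests
therefore demonstrate the correctness and calibration of the statistical
machinery under the stated generative assumptions, not performance on real
sequencing data.

# Numerical choices and degenerate inputs

* Problem sizes in the test-suite and acceptance runs — 10-Mb genomes with
  500 planted loci for recovery, 200 loci for correlation checks, 10 species
  for classification, 100-seed calibration loops, 500 resampling replicates —
  were chosen as the smallest sizes at which the checked properties are
  stable, and are stated in the tests themselves.
* Empirical p-values always use the +1 correction and never return 0.
* Odds ratios use the Haldane 0.5 correction when any cell is zero, flagged.
* The mixture-of-regressions EM floors component standard deviations at a
  relative 1e-6 to survive noiseless components, and reports a degenerate
  flag instead of a forced two-component fit when all points are collinear.
* `fit_score_threshold()` requires ≥ 50 scores; fewer cannot support a
  mixture fit.
* Ties: motif-scan offsets break to the smallest; span-curve ordering breaks
  by density then contig name; decile strata break by locus id.

# Known limitations

* The Tm engine reproduces nearest-neighbour duplex thermodynamics with one
  parameter set and a single salt correction; absolute temperatures are
  parameter-set-dependent, which is why the cross-species range metric and
  the pausing strength are defined as within-profile contrasts.
* The 2×2 Fisher test of domain enrichment discretises span in bp, treating
  base pairs as exchangeable units; it is reported alongside the fold change
  rather than as the primary effect size.
* Orthology-based chromatin transfer assumes conserved domain context for
  1:1 orthologs; the concordance table against direct assignment quantifies
  how far that assumption holds in any given dataset.
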