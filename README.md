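# pirnascape

Comparative analysis of piRNA (21U-RNA) biogenesis in nematode genomes.

Nematode piRNAs are transcribed as short capped RNA polymerase II transcripts
from miniature transcription units: an upstream "Ruby" promoter motif (GTTTC
core) begins ~42 nt upstream of the mature 21-nt, 5′-U small RNA, and
transcription initiates 2 nt upstream of the 21U 5′ end. `pirnascape` is an R
package for scientists studying how these loci are organised and regulated
across species. It provides:

* **Locus annotation** — PWM construction and strand-aware scanning of 21U
  upstream windows (110 bp up / 30 bp down), score thresholds fitted from the
  bimodal score distribution by a 2-component Gaussian mixture
  (equal-posterior cut), positional filtering at the canonical 42-nt motif
  distance, and TSS placement at 21U start − 2
  (`build_pwm`, `scan_upstream_windows`, `fit_score_threshold`,
  `call_pirna_loci`).
* **Genomic clustering** — exact one-sided binomial contig enrichment,
  span-90 curves (genomic span of the most enriched contigs holding 90% of
  loci), and a mixture-of-linear-regressions EM classifier that separates
  clustered (C-type) from dispersed (P-type) species
  (`contig_enrichment`, `span_curve`, `classify_clustering`).
* **Chromatin and gene context** — domain enrichment/depletion with Fisher
  tests, the 75% coverage rule for gene states, orthology-based state
  transfer, genicness scores against placement-preserving simulation nulls,
  promoter association, and k-means expression strata
  (`domain_overlap_enrichment`, `assign_gene_state`, `genicness_score`,
  `promoter_association`, `expression_strata`).
* **Selection on motifs** — rescoring motifs under strain SNP alleles,
  disruptive-allele classification by the low-scoring allele's strain
  frequency (major > 0.9, minor < 0.1), and stratified major-allele
  fractions with Fisher contrasts
  (`motif_variant_effects`, `stratified_major_fraction`).
* **Pol II pausing signals** — nearest-neighbour DNA melting-temperature
  profiles (9-nt windows, 1-nt shift), the pausing strength
  `S = Σ_[0,19](Tm−B) + Σ_[20,40](B−Tm)` with flank background
  B (−200..−100, +100..+200), BILD (Bayesian Integral Log-Odds) column
  scores with termination-peak areas, valley-centre localisation, and
  Wilcoxon / abundance-weighted resampling tests on capped precursor length
  distributions with rRNA length controls
  (`tm_profile`, `pausing_strength`, `bild_profile`,
  `weighted_resampling_test`, `rrna_length_control`).
* **Synthetic species with planted truth** — `generate_species()` builds
  genomes with planted loci obeying the full promoter geometry, chromatin
  domains, intronic host genes, ortholog tables, decoy 21U sites; and
  simulators for small-RNA libraries and multi-strain SNP panels
  (`simulate_small_rna_libraries`, `simulate_strain_panel`), so every stage
  of the pipeline is testable end to end without external data.
* **Orchestration** — `run_pipeline()` runs the stages in order into a run
  directory with TSV outputs and a JSON summary; `make_report()` collects
  panel-style summary tables across runs.

## Worked example

```r
library(pirnascape)

# a clustered-organisation species: 10-Mb genome, 500 planted loci
cfg <- species_config(n_contigs = 20, contig_length = 5e5,
                      mode = "C", n_pirna_loci = 500, seed = 7)
bundle <- generate_species(cfg)

# scan upstream windows, fit the score threshold, call loci
hits <- scan_upstream_windows(bundle$genome, bundle$sites_21u,
                              cfg$motif_pwm)
fit <- fit_score_threshold(hits$score)
fit
#> 2-component score mixture (mclust): means -1.62 / 13.8, weights 0.48 / 0.52
#> threshold = 6.405  (separation 4.50 SD)

loci <- call_pirna_loci(bundle$sites_21u, hits, fit$threshold)
length(loci)
#> [1] 497

positional_distribution(hits, fit$threshold)$mode
#> [1] 42

# recovery against the planted truth
mean(bundle$truth$locus_id %in% mcols(loci)$site_id)
#> [1] 0.992

# clustering: span needed to hold 90% of loci
sc <- span_curve(contig_enrichment(loci, bundle$genome))
sc
#> span curve: 497 loci over 1e+07 bp; span at 90% loci = 1e+06 bp

# pausing signatures at the first 200 recovered loci
sub <- loci[mcols(loci)$site_id %in% bundle$truth$locus_id][1:200]
S <- pausing_strengths(tm_profile_matrix(bundle$genome, sub))
depth <- bundle$truth$valley_depth[
  match(mcols(sub)$site_id, bundle$truth$locus_id)]
cor(S, depth, method = "spearman")
#> [1] 0.9692357
```

The threshold separates the planted-motif mode (13.8 bits) from background
hits (−1.6 bits); 99% of planted loci are recovered with a single false call
(0.2% FDR) at the 42 ± 5 nt distance filter; the 500 clustered loci occupy 1 Mb of the
10-Mb genome (span-90 = 10% of the genome); and the recomputed pausing
strength tracks the planted valley depth with Spearman ρ = 0.97.

See the methods vignette (`vignettes/pirnascape-methods.Rmd`) for the models,
parameter defaults, and the design decisions behind them.

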