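suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
  library(S4Vectors)
})

# Memoised synthetic fixtures shared across test files (built once per run).
.fixtures <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# Large clustered species used for locus-recovery and pausing checks:
# 500 planted loci + 500 decoy sites on a 10-Mb genome.
fixture_bundle_C500 <- function() .memo("C500", {
  generate_species(species_config(n_contigs = 20, contig_length = 5e5,
                                  mode = "C", n_pirna_loci = 500, seed = 7))
})

fixture_hits_C500 <- function() .memo("hits_C500", {
  b <- fixture_bundle_C500()
  scan_upstream_windows(b$genome, b$sites_21u, b$config$motif_pwm)
})

fixture_fit_C500 <- function() .memo("fit_C500", {
  fit_score_threshold(fixture_hits_C500()$score)
})

fixture_loci_C500 <- function() .memo("loci_C500", {
  b <- fixture_bundle_C500()
  call_pirna_loci(b$sites_21u, fixture_hits_C500(),
                  fixture_fit_C500()$threshold)
})

# Smaller bundles for chromatin / organisation checks.
fixture_bundle_C200 <- function() .memo("C200", {
  generate_species(species_config(n_contigs = 20, contig_length = 1e5,
                                  mode = "C", n_pirna_loci = 200,
                                  n_decoy_sites = 0, seed = 12))
})

fixture_bundle_P200 <- function() .memo("P200", {
  generate_species(species_config(n_contigs = 20, contig_length = 1e5,
                                  mode = "P", n_pirna_loci = 200,
                                  n_decoy_sites = 0, seed = 11))
})

# Intermediate-mode bundle with loci in both chromatin strata, for the
# selection analysis and simulated libraries.
fixture_bundle_I <- function() .memo("I500", {
  generate_species(species_config(n_contigs = 20, contig_length = 2e5,
                                  mode = "intermediate", n_pirna_loci = 500,
                                  n_decoy_sites = 0, seed = 21))
})

fixture_libs_I <- function() .memo("libs_I", {
  simulate_small_rna_libraries(fixture_bundle_I(), scale_factors = c(1, 2),
                               seed = 31)
})

# GRanges of the planted loci straight from a bundle's truth table.
truth_loci <- function(bundle) {
  tr <- bundle$truth
  GRanges(tr$contig, IRanges(tr$site_start, tr$site_end),
          strand = tr$strand, tss = tr$tss, locus_id = tr$locus_id)
}

# Motif windows (the planted motif instance itself) from a truth table.
truth_motifs <- function(bundle) {
  tr <- bundle$truth
  w <- bundle$config$motif_pwm$width
  off <- bundle$config$motif_offset
  GRanges(tr$contig,
          IRanges(ifelse(tr$strand == "+", tr$u21_start - off,
                         tr$u21_start + off - w + 1L),
                  ifelse(tr$strand == "+", tr$u21_start - off + w - 1L,
                         tr$u21_start + off)),
          strand = tr$strand, motif_id = tr$locus_id,
          score = tr$motif_score)
}

# --- independent oracles -----------------------------------------------------

# One-sided (greater) exact binomial tail by direct log-space summation.
oracle_binom_tail <- function(k, N, p) {
  if (k <= 0) return(1)
  if (k > N) return(0)
  j <- k:N
  sum(exp(lchoose(N, j) + j * log(p) + (N - j) * log1p(-p)))
}

# Two-sided Fisher exact p by enumeration of all tables with fixed margins:
# sum of the hypergeometric probabilities of tables no more probable than
# the observed one (with the standard 1 + 1e-7 numerical guard).
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  probs <- exp(logp - max(logp)); probs <- probs / sum(probs)
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact Wilcoxon rank-sum p by exhaustive enumeration of group assignments
# (tie-free inputs only; alternative as in wilcox.test(x, y, ...)).
oracle_wilcox_exact <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combs <- utils::combn(n1 + n2, n1)
  rk <- rank(pooled)
  sums <- apply(combs, 2, function(ix) sum(rk[ix]))
  pg <- mean(sums >= r_obs)   # P(rank sum of x >= observed) => x greater
  pl <- mean(sums <= r_obs)
  switch(alternative,
         greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# Per-window Tm by direct per-window table lookup (independent of the
# cumulative-sum implementation).
oracle_tm_window <- function(seq_chr, dna_conc = 50e-9, na_conc = 0.05) {
  tab <- nn_parameters("breslauer1986")
  rownames(tab) <- tab$step
  chars <- strsplit(toupper(seq_chr), "")[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(chars) - 1)) {
    st <- paste0(chars[i], chars[i + 1])
    dH <- dH + tab[st, "dH"]; dS <- dS + tab[st, "dS"]
  }
  1000 * dH / (dS + 1.987 * log(dna_conc / 4)) - 273.15 +
    16.6 * log10(na_conc)
}

# BILD column score via the sequential predictive factorisation of the
# Dirichlet-multinomial: log prod_i P(x_i | x_<i) - sum_i log q(x_i).
oracle_bild_column <- function(bases, q, alpha0 = 1) {
  alpha <- alpha0 * q
  names(alpha) <- c("A", "C", "G", "T")
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  ll <- 0
  for (i in seq_along(bases)) {
    b <- bases[i]
    ll <- ll + log((alpha[[b]] + counts[[b]]) / (alpha0 + i - 1)) -
      log(q[match(b, c("A", "C", "G", "T"))])
    counts[[b]] <- counts[[b]] + 1
  }
  unname(ll)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
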