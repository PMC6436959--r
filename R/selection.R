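#' Rescore piRNA promoter motifs under strain SNP alleles
#'
#' For every SNP that falls inside the scanned window of a qualifying motif
#' (reference score at least `score_floor`), the motif is rescored with the
#' alternate allele substituted. A SNP is disruptive when the rescoring drops
#' the score by at least `disruption_delta`. The allele class is decided by
#' the strain frequency of the *low-scoring* allele: major when > 0.9 of
#' strains carry it, minor when < 0.1, intermediate otherwise. SNPs whose
#' reference base disagrees with the genome are skipped and counted.
#'
#' @param motifs `GRanges` of motif scan windows (feature strand) with mcols
#'   `motif_id` and `score` (reference best score in pipeline score units).
#' @param snps data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `freq` (fraction of strains carrying the alternate allele).
#' @param pwm A `pwm` object (same score units as `score`).
#' @param genome A `DNAStringSet` genome.
#' @param score_floor Only motifs scoring at least this are considered.
#' @param disruption_delta Minimum score drop for a SNP to count as
#'   disruptive. Species with lower motif information content warrant a lower
#'   value (see [scale_disruption_threshold()]).
#' @return data.frame of class `variant_effects`: `motif_id`, `contig`,
#'   `pos`, `ref`, `alt`, `freq`, `score_ref`, `score_alt`, `delta`,
#'   `disruptive`, `low_allele_freq`, `allele_class`; mismatch count in
#'   `attr(, "n_ref_mismatch")`.
#' @export
motif_variant_effects <- function(motifs, snps, pwm, genome,
                                  score_floor = 0, disruption_delta = 1) {
  qual <- motifs[!is.na(mcols(motifs)$score) &
                   mcols(motifs)$score >= score_floor]
  n_mm <- 0L
  keep_si <- integer(0); keep_mi <- integer(0)
  sref <- salt <- delta <- numeric(0)
  if (length(qual) && nrow(snps)) {
    snp_gr <- GRanges(snps$contig, IRanges(snps$pos, width = 1))
    ov <- findOverlaps(snp_gr, qual, ignore.strand = TRUE)
    seqs <- as.character(extract_sequence(genome, qual))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    nh <- length(ov)
    keep <- logical(nh)
    sref <- salt <- delta <- numeric(nh)
    keep_si <- queryHits(ov); keep_mi <- subjectHits(ov)
    minus <- as.character(strand(qual))[keep_mi] == "-"
    wpos <- ifelse(minus, end(qual)[keep_mi] - snps$pos[keep_si] + 1L,
                   snps$pos[keep_si] - start(qual)[keep_mi] + 1L)
    ref_w <- toupper(snps$ref[keep_si]); alt_w <- toupper(snps$alt[keep_si])
    ref_w[minus] <- comp[ref_w[minus]]; alt_w[minus] <- comp[alt_w[minus]]
    for (h in seq_len(nh)) {
      eff <- tryCatch(
        rescore_with_allele(pwm, seqs[keep_mi[h]],
                            list(pos = wpos[h], ref = ref_w[h],
                                 alt = alt_w[h])),
        error = function(e) e)
      if (inherits(eff, "error")) { n_mm <- n_mm + 1L; next }
      keep[h] <- TRUE
      sref[h] <- eff$score_ref; salt[h] <- eff$score_alt
      delta[h] <- eff$delta
    }
    keep_si <- keep_si[keep]; keep_mi <- keep_mi[keep]
    sref <- sref[keep]; salt <- salt[keep]; delta <- delta[keep]
  }
  low_freq <- ifelse(delta < 0, snps$freq[keep_si], 1 - snps$freq[keep_si])
  res <- data.frame(
    motif_id = as.character(mcols(qual)$motif_id[keep_mi]),
    contig = as.character(snps$contig[keep_si]),
    pos = snps$pos[keep_si], ref = snps$ref[keep_si],
    alt = snps$alt[keep_si], freq = snps$freq[keep_si],
    score_ref = sref, score_alt = salt, delta = delta,
    disruptive = delta <= -disruption_delta,
    low_allele_freq = low_freq,
    allele_class = ifelse(low_freq > 0.9, "major",
                          ifelse(low_freq < 0.1, "minor", "intermediate")),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_ref_mismatch") <- n_mm
  class(res) <- c("variant_effects", "data.frame")
  res
}

#' Scale a motif-disruption threshold by PWM information content
#'
#' Species whose motifs carry less information warrant a proportionally lower
#' disruption threshold (e.g. a 400-unit threshold calibrated on a
#' high-information motif maps to ~200 on a motif with half the information
#' content).
#'
#' @param reference_threshold Disruption threshold calibrated on
#'   `reference_pwm`.
#' @param reference_pwm,target_pwm `pwm` objects.
#' @return Scaled threshold for the target species.
#' @export
scale_disruption_threshold <- function(reference_threshold, reference_pwm,
                                       target_pwm) {
  reference_threshold * pwm_information_content(target_pwm) /
    pwm_information_content(reference_pwm)
}

#' Major-allele fraction of disruptive SNPs, stratified
#'
#' Among disruptive SNPs with a non-intermediate allele class, computes per
#' stratum the fraction whose low-scoring allele is the major allele (binomial
#' CI), and compares strata pairwise with a two-sided Fisher exact test on the
#' (major, minor) x (stratum A, stratum B) table. Strata with no usable SNP
#' are excluded with a warning.
#'
#' @param effects `variant_effects` data.frame from [motif_variant_effects()].
#' @param strata Named character vector mapping `motif_id` to stratum label
#'   (e.g. cluster/outside, active/regulated, high/low expression).
#' @param conf_level Binomial CI confidence level.
#' @return List with `fractions` (data.frame per stratum) and `tests`
#'   (data.frame of pairwise Fisher p-values), class
#'   `stratified_major_fraction`.
#' @export
stratified_major_fraction <- function(effects, strata, conf_level = 0.95) {
  eff <- effects[effects$disruptive &
                   effects$allele_class %in% c("major", "minor"), , drop = FALSE]
  eff$stratum <- strata[eff$motif_id]
  eff <- eff[!is.na(eff$stratum), , drop = FALSE]
  labs <- unique(strata)
  rows <- list(); counts <- list()
  for (st in labs) {
    sub <- eff[eff$stratum == st, , drop = FALSE]
    if (!nrow(sub)) {
      warning("stratum with no disruptive major/minor SNPs excluded: ", st)
      next
    }
    k <- sum(sub$allele_class == "major"); n <- nrow(sub)
    ci <- binom.test(k, n, conf.level = conf_level)$conf.int
    rows[[st]] <- data.frame(stratum = st, n = n, n_major = k,
                             fraction_major = k / n, ci_lo = ci[1],
                             ci_hi = ci[2], stringsAsFactors = FALSE)
    counts[[st]] <- c(major = k, minor = n - k)
  }
  fractions <- do.call(rbind, rows)
  rownames(fractions) <- NULL
  tests <- NULL
  nm <- names(counts)
  if (length(nm) >= 2) {
    pairs <- utils::combn(nm, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      tab <- rbind(counts[[a]], counts[[b]])
      data.frame(stratum_a = a, stratum_b = b,
                 p_value = fisher.test(tab)$p.value,
                 stringsAsFactors = FALSE)
    }))
    rownames(tests) <- NULL
  }
  structure(list(fractions = fractions, tests = tests),
            class = "stratified_major_fraction")
}

#' @export
print.stratified_major_fraction <- function(x, ...) {
  cat("major-allele fraction of disruptive SNPs by stratum:\n")
  print(x$fractions, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("pairwise Fisher tests:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Read a strain SNP panel from TSV
#'
#' TSV with header columns `contig`, `pos` (1-based), `ref`, `alt`, `freq`
#' (fraction of strains carrying the alternate allele).
#'
#' @param path Path to the TSV.
#' @return data.frame suitable for [motif_variant_effects()].
#' @export
read_snp_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt", "freq")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$ref == df$alt)) stop("SNP with ref == alt")
  if (any(df$freq < 0 | df$freq > 1)) stop("freq outside [0, 1]")
  df
}
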