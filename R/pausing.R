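# Nearest-neighbour DNA-DNA duplex parameters, Breslauer et al. 1986 style:
# dH in kcal/mol, dS in cal/(mol K), stored for duplex formation (negative).
# Rows are the 16 5'->3' dinucleotide steps on one strand.
.nn_tables <- list(
  breslauer1986 = within(data.frame(
    step = c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
             "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT"),
    dH = -c(9.1, 6.5, 7.8, 8.6, 5.8, 11.0, 11.9, 7.8,
            5.6, 11.1, 11.0, 6.5, 6.0, 5.6, 5.8, 9.1),
    dS = -c(24.0, 17.3, 20.8, 23.9, 12.9, 26.6, 27.8, 20.8,
            13.5, 26.7, 26.6, 17.3, 16.9, 13.5, 12.9, 24.0),
    stringsAsFactors = FALSE), {})
)

#' Nearest-neighbour thermodynamic parameter table
#'
#' @param set Parameter set id (currently `"breslauer1986"`).
#' @return data.frame with `step` (dinucleotide), `dH` (kcal/mol), `dS`
#'   (cal/mol/K), duplex-formation sign convention.
#' @export
nn_parameters <- function(set = "breslauer1986") {
  if (!set %in% names(.nn_tables)) stop("unknown parameter set: ", set)
  .nn_tables[[set]]
}

# Tm (deg C) for each w-mer window start of an integer-coded sequence.
# codes: 1..4 = A,C,G,T, NA = N. Returns one value per window start; NA over
# windows containing N.
.tm_windows <- function(codes, window, dna_conc, na_conc, set) {
  tab <- .nn_tables[[set]]
  L <- length(codes)
  if (L < window) return(numeric(0))
  n_steps <- L - 1L
  step_idx <- (codes[-L] - 1L) * 4L + codes[-1L]   # NA propagates
  dH <- tab$dH[order(tab$step)][step_idx]          # steps are in AA..TT order
  dS <- tab$dS[order(tab$step)][step_idx]
  bad <- is.na(step_idx)
  dH[bad] <- 0; dS[bad] <- 0
  csH <- cumsum(c(0, dH)); csS <- cumsum(c(0, dS)); csB <- cumsum(c(0, bad))
  n_win <- L - window + 1L
  i <- seq_len(n_win)
  sumH <- csH[i + window - 1L] - csH[i]
  sumS <- csS[i + window - 1L] - csS[i]
  nbad <- csB[i + window - 1L] - csB[i]
  R <- 1.987  # cal/(mol K)
  tm <- 1000 * sumH / (sumS + R * log(dna_conc / 4)) - 273.15 +
    16.6 * log10(na_conc)
  tm[nbad > 0] <- NA_real_
  tm
}

#' Melting-temperature profile around a piRNA TSS
#'
#' Computes nearest-neighbour DNA-DNA melting temperatures for sliding
#' windows (default 9 nt, shift 1 nt) over the transcribed strand in a window
#' of positions -200 to +200 relative to the TSS. Each Tm value is indexed by
#' its window start position. Positions whose window overlaps an N, or that
#' fall outside the contig (clipped, flagged), are NA.
#'
#' @param genome A `DNAStringSet` genome.
#' @param contig Contig name.
#' @param tss Genomic position (1-based) of the TSS.
#' @param strand `"+"` or `"-"` (transcribed strand).
#' @param flank Profile half-width in bp (default 200).
#' @param window Tm window size in nt (default 9).
#' @param dna_conc DNA concentration in M (default 50 nM).
#' @param na_conc Na+ concentration in M (default 50 mM).
#' @param params Nearest-neighbour parameter set id.
#' @return Object of class `tm_profile`: list with `tm` (named numeric,
#'   positions `-flank..+flank`), `clipped` flag, `params` metadata.
#' @export
tm_profile <- function(genome, contig, tss, strand = "+", flank = 200,
                       window = 9, dna_conc = 50e-9, na_conc = 0.05,
                       params = "breslauer1986") {
  lens <- genome_lengths(genome)
  if (!contig %in% names(lens)) stop("unknown contig: ", contig)
  # genomic extent needed so every window start in [-flank, +flank] is covered
  if (strand == "+") {
    lo <- tss - flank; hi <- tss + flank + window - 1L
  } else {
    lo <- tss - flank - window + 1L; hi <- tss + flank
  }
  clipped <- lo < 1L || hi > lens[[contig]]
  lo_c <- max(lo, 1L); hi_c <- min(hi, lens[[contig]])
  seq_chr <- as.character(extract_sequence(
    genome, GRanges(contig, IRanges(lo_c, hi_c), strand = strand)))
  codes <- .dna_codes(seq_chr)
  # pad clipped ends with NA so indexing by profile position stays aligned
  n_lo <- if (strand == "+") lo_c - lo else hi - hi_c
  n_hi <- if (strand == "+") hi - hi_c else lo_c - lo
  codes <- c(rep(NA_integer_, n_lo), codes, rep(NA_integer_, n_hi))
  tm <- .tm_windows(codes, window, dna_conc, na_conc, params)
  positions <- seq(-flank, flank)
  tm <- tm[seq_along(positions)]
  names(tm) <- positions
  structure(list(tm = tm, positions = positions, clipped = clipped,
                 params = list(set = params, window = window,
                               dna_conc = dna_conc, na_conc = na_conc)),
            class = "tm_profile")
}

#' Tm profiles for many loci as a matrix
#'
#' @param genome A `DNAStringSet` genome.
#' @param loci `GRanges` with `tss` mcol (from [call_pirna_loci()]) or any
#'   stranded point set.
#' @inheritParams tm_profile
#' @return Numeric matrix (loci x positions, columns named `-flank..+flank`);
#'   rownames are `locus_id` when present.
#' @export
tm_profile_matrix <- function(genome, loci, flank = 200, window = 9,
                              dna_conc = 50e-9, na_conc = 0.05,
                              params = "breslauer1986") {
  tss <- if (!is.null(mcols(loci)$tss)) mcols(loci)$tss else start(loci)
  mat <- t(vapply(seq_along(loci), function(i) {
    tm_profile(genome, as.character(seqnames(loci))[i], tss[i],
               as.character(strand(loci))[i], flank = flank, window = window,
               dna_conc = dna_conc, na_conc = na_conc, params = params)$tm
  }, numeric(2 * flank + 1)))
  colnames(mat) <- seq(-flank, flank)
  if (!is.null(mcols(loci)$locus_id)) rownames(mat) <- mcols(loci)$locus_id
  mat
}

# Positions (names) -> index helper for profile vectors.
.pos_idx <- function(positions, from, to) which(positions >= from & positions <= to)

#' Pol II pausing strength from a Tm profile
#'
#' Background B is the mean Tm over the flanks (-200..-100 and +100..+200);
#' the pausing strength is the sum of signed deviations `Tm - B` over the
#' high-Tm region (window starts TSS..+19) plus the sum of `B - Tm` over the
#' low-Tm region (+20..+40). Deviations are not clipped at zero by default.
#' Missing positions are omitted from the sums and counted; each flank must
#' be at least half defined.
#'
#' @param profile A `tm_profile`, or a named numeric vector of Tm values with
#'   positions as names.
#' @param high,low,flanks Region definitions (window-start positions relative
#'   to the TSS).
#' @param clip Clip per-position deviations at zero (`max(., 0)`) before
#'   summing (default `FALSE`).
#' @return Object of class `pausing_score`: list with `S` (degC x nt),
#'   `background`, `high_sum`, `low_sum`, `n_missing`.
#' @export
pausing_strength <- function(profile, high = c(0, 19), low = c(20, 40),
                             flanks = list(c(-200, -100), c(100, 200)),
                             clip = FALSE) {
  tm <- if (inherits(profile, "tm_profile")) profile$tm else profile
  pos <- as.integer(names(tm))
  fl_vals <- lapply(flanks, function(f) tm[.pos_idx(pos, f[1], f[2])])
  for (f in fl_vals)
    if (mean(is.na(f)) > 0.5)
      stop("insufficient flank coverage for background estimation")
  B <- mean(unlist(fl_vals), na.rm = TRUE)
  hi <- tm[.pos_idx(pos, high[1], high[2])]
  lo <- tm[.pos_idx(pos, low[1], low[2])]
  dev_hi <- hi - B
  dev_lo <- B - lo
  if (clip) { dev_hi <- pmax(dev_hi, 0); dev_lo <- pmax(dev_lo, 0) }
  structure(list(S = sum(dev_hi, na.rm = TRUE) + sum(dev_lo, na.rm = TRUE),
                 background = B,
                 high_sum = sum(dev_hi, na.rm = TRUE),
                 low_sum = sum(dev_lo, na.rm = TRUE),
                 n_missing = sum(is.na(c(hi, lo)))),
            class = "pausing_score")
}

#' @export
print.pausing_score <- function(x, ...) {
  cat(sprintf("pausing strength S = %.2f degC*nt (background %.2f degC, high %.2f, low %.2f, %d missing)\n",
              x$S, x$background, x$high_sum, x$low_sum, x$n_missing))
  invisible(x)
}

#' Pausing strengths for a profile matrix
#' @param mat Matrix from [tm_profile_matrix()].
#' @inheritParams pausing_strength
#' @return Named numeric vector of S per locus (NA where flanks are
#'   undefined).
#' @export
pausing_strengths <- function(mat, high = c(0, 19), low = c(20, 40),
                              flanks = list(c(-200, -100), c(100, 200)),
                              clip = FALSE) {
  apply(mat, 1, function(row) {
    names(row) <- colnames(mat)
    tryCatch(pausing_strength(row, high, low, flanks, clip)$S,
             error = function(e) NA_real_)
  })
}

#' BILD (Bayesian Integral Log-Odds) profile of aligned sequences
#'
#' Per alignment column, the log-odds of the observed base counts under a
#' Dirichlet prior with parameters `alpha0 * q` against the background
#' composition `q`:
#' `ln[Gamma(A)/Gamma(A+n) * prod_b Gamma(a_b+n_b)/Gamma(a_b)] - sum_b n_b ln q_b`.
#' A single observation scores exactly 0 in every column. The termination
#' region downstream of the piRNA TSS appears as a peak; its strength is
#' summarised as the baseline-subtracted area over the low-Tm window.
#'
#' @param sequences Character vector (or `DNAStringSet`) of equal-length
#'   sequences aligned on the TSS. A single sequence yields the identically
#'   zero profile. N bases are excluded column-wise.
#' @param background Background base frequencies (A, C, G, T).
#' @param alpha0 Total Dirichlet prior mass (default 1).
#' @param tss_index 1-based column index of the TSS (default
#'   `(length + 1) / 2` for a symmetric window).
#' @param term_window Window-start region (relative to TSS) over which the
#'   termination-peak area is integrated (default +20..+40).
#' @param flanks Regions (relative to TSS) whose median BILD defines the
#'   baseline.
#' @return Object of class `bild_profile`: list with `bild` (named numeric
#'   by position relative to TSS), `baseline`, `area`, `alpha0`,
#'   `background`.
#' @export
bild_profile <- function(sequences, background = rep(0.25, 4), alpha0 = 1,
                         tss_index = NULL, term_window = c(20, 40),
                         flanks = list(c(-200, -100), c(100, 200))) {
  seqs <- toupper(as.character(sequences))
  if (length(seqs) < 1) stop("need >= 1 sequence")
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must be equal length")
  if (is.null(tss_index)) tss_index <- (L + 1) %/% 2
  background <- background / sum(background)
  alpha <- alpha0 * background
  chars <- do.call(rbind, strsplit(seqs, ""))
  bild <- vapply(seq_len(L), function(j) {
    col <- chars[, j]
    nb <- vapply(DNA_BASES, function(b) sum(col == b), numeric(1))
    n <- sum(nb)
    if (n == 0) return(NA_real_)
    lgamma(alpha0) - lgamma(alpha0 + n) +
      sum(lgamma(alpha + nb) - lgamma(alpha)) -
      sum(nb * log(background))
  }, numeric(1))
  positions <- seq_len(L) - tss_index
  names(bild) <- positions
  fl <- unlist(lapply(flanks, function(f)
    bild[.pos_idx(positions, f[1], f[2])]))
  baseline <- if (length(fl[!is.na(fl)])) median(fl, na.rm = TRUE) else 0
  term <- bild[.pos_idx(positions, term_window[1], term_window[2])]
  area <- sum(term - baseline, na.rm = TRUE)
  structure(list(bild = bild, baseline = baseline, area = area,
                 alpha0 = alpha0, background = setNames(background, DNA_BASES),
                 n_sequences = length(seqs)),
            class = "bild_profile")
}

#' @export
print.bild_profile <- function(x, ...) {
  cat(sprintf("BILD profile over %d sequences: baseline %.3f nats, termination-peak area %.3f\n",
              x$n_sequences, x$baseline, x$area))
  invisible(x)
}

#' Cross-species Tm range metric
#'
#' Difference between the maximum Tm of the high-Tm region (TSS..+19) and the
#' minimum Tm of the low-Tm region (+20..+40) of a species' mean profile.
#' Invariant to adding a constant to all Tm values, hence comparable across
#' genomes of different GC content.
#'
#' @param profile A `tm_profile` or a named numeric Tm vector (mean profile).
#' @param high,low Region bounds (window-start positions).
#' @return Range metric in degC.
#' @export
cross_species_range_metric <- function(profile, high = c(0, 19),
                                       low = c(20, 40)) {
  tm <- if (inherits(profile, "tm_profile")) profile$tm else profile
  pos <- as.integer(names(tm))
  hi <- tm[.pos_idx(pos, high[1], high[2])]
  lo <- tm[.pos_idx(pos, low[1], low[2])]
  if (all(is.na(hi)) || all(is.na(lo))) stop("undefined high/low region")
  max(hi, na.rm = TRUE) - min(lo, na.rm = TRUE)
}

#' Locate the centre of the low-Tm valley
#'
#' Argmin of the 5-position moving average of the Tm profile within the
#' search window downstream of the TSS; ties break to the smallest position.
#' A flat window returns the window midpoint, flagged; an argmin on the
#' window boundary is also flagged.
#'
#' @param profile A `tm_profile` or named numeric Tm vector.
#' @param search Search window bounds relative to the TSS (default +10..+60).
#' @param ma Moving-average width (odd, default 5).
#' @return List with `center` (bp from TSS), `flagged`, `reason`.
#' @export
valley_center <- function(profile, search = c(10, 60), ma = 5) {
  tm <- if (inherits(profile, "tm_profile")) profile$tm else profile
  pos <- as.integer(names(tm))
  half <- (ma - 1) %/% 2
  idx <- .pos_idx(pos, search[1], search[2])
  if (!length(idx)) stop("search window undefined")
  sm <- vapply(idx, function(i) {
    w <- tm[pmax(1, i - half):pmin(length(tm), i + half)]
    mean(w, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(sm))) stop("search window entirely undefined")
  if (diff(range(sm, na.rm = TRUE)) < 1e-9)
    return(list(center = round(mean(search)), flagged = TRUE,
                reason = "flat window"))
  best <- which.min(sm)  # first minimum -> smallest position on ties
  center <- pos[idx][best]
  on_boundary <- center %in% search
  list(center = center, flagged = on_boundary,
       reason = if (on_boundary) "minimum on window boundary" else NA_character_)
}

#' Stratify loci into top/bottom deciles of pausing strength
#'
#' Deterministic quantile cut: loci are ordered by decreasing score with ties
#' broken by locus id, and the first/last `floor(n * fraction)` loci form the
#' strong/weak sets.
#'
#' @param scores Named numeric vector of per-locus pausing strengths
#'   (>= 20 loci).
#' @param fraction Tail fraction (default 0.10).
#' @return List with `top` and `bottom` character vectors of locus ids.
#' @export
stratify_by_signal <- function(scores, fraction = 0.10) {
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  if (n < 20) stop("need >= 20 loci")
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(-scores, ids)
  k <- max(1L, floor(n * fraction))
  list(top = ids[ord][seq_len(k)], bottom = rev(ids[ord])[seq_len(k)])
}

# Expand a precursor_set (or data.frame with length/count) into a length
# vector, by read counts or as unique sequences.
.expand_lengths <- function(x, expand = c("counts", "unique")) {
  expand <- match.arg(expand)
  if (is.numeric(x)) return(as.numeric(x))
  if (expand == "counts") rep(x$length, x$count) else as.numeric(x$length)
}

#' Wilcoxon rank-sum test on precursor length distributions
#'
#' Compares two precursor length multisets; exact when both sides are small
#' (product of sizes <= 10000) and tie-free, otherwise the normal
#' approximation with continuity correction (ties always use the
#' approximation, flagged).
#'
#' @param set_a,set_b `precursor_set` data.frames (or numeric length
#'   vectors). Each side needs >= 5 lengths after expansion.
#' @param alternative `"two.sided"`, `"less"`, or `"greater"` (a vs b, as in
#'   [stats::wilcox.test()]).
#' @param expand Expand by read `"counts"` or as `"unique"` sequences.
#' @return List with `p_value`, `statistic`, `exact`, `n_a`, `n_b`.
#' @export
precursor_length_test <- function(set_a, set_b, alternative = "two.sided",
                                  expand = "counts") {
  a <- .expand_lengths(set_a, expand)
  b <- .expand_lengths(set_b, expand)
  if (length(a) < 5 || length(b) < 5) stop("need >= 5 lengths per side")
  small <- length(a) * length(b) <= 10000
  ties <- any(duplicated(c(a, b)))
  use_exact <- small && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = use_exact,
                correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       exact = use_exact, ties = ties, n_a = length(a), n_b = length(b))
}

#' Abundance-weighted resampling test on precursor lengths
#'
#' Controls for the depth-dependence of unique precursor length distributions
#' (longer precursors are rarer): per replicate, `n_sub` unique precursor
#' sequences are drawn from each library without replacement with probability
#' proportional to read count, and a one-tailed Wilcoxon rank-sum p-value is
#' recorded. The null distribution is built by comparing two subsamples drawn
#' from library A alone. If a library holds fewer unique sequences than
#' `n_sub`, `n_sub` is lowered with a warning.
#'
#' @param prec_a,prec_b `precursor_set` data.frames; rows are unique
#'   precursor species with `length` and `count`.
#' @param n_sub Subsample size (default 2500).
#' @param n_reps Number of replicates (>= 1).
#' @param seed RNG seed.
#' @param alternative Alternative for `wilcox.test(b_sample, a_sample, ...)`;
#'   default `"greater"` tests B > A.
#' @return Object of class `resampling_result`: list with `p` (per-rep),
#'   `null_p`, `summary` (median p, fraction < 0.05, null 5th percentile),
#'   `params`.
#' @export
weighted_resampling_test <- function(prec_a, prec_b, n_sub = 2500,
                                     n_reps = 100, seed = 1,
                                     alternative = "greater") {
  if (n_reps < 1) stop("n_reps must be >= 1")
  la <- as.numeric(prec_a$length); ca <- as.numeric(prec_a$count)
  lb <- as.numeric(prec_b$length); cb <- as.numeric(prec_b$count)
  avail <- min(length(la), length(lb))
  if (avail < n_sub) {
    warning("fewer unique precursor sequences than n_sub; lowering n_sub to ",
            avail)
    n_sub <- avail
  }
  res <- local_seed(seed, {
    p <- numeric(n_reps); null_p <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      sa <- la[sample.int(length(la), n_sub, prob = ca)]
      sb <- lb[sample.int(length(lb), n_sub, prob = cb)]
      p[r] <- suppressWarnings(
        wilcox.test(sb, sa, alternative = alternative, exact = FALSE,
                    correct = TRUE)$p.value)
      # null: the same subsampling procedure with both sides drawn from A
      n1 <- la[sample.int(length(la), n_sub, prob = ca)]
      n2 <- la[sample.int(length(la), n_sub, prob = ca)]
      null_p[r] <- suppressWarnings(
        wilcox.test(n2, n1, alternative = alternative, exact = FALSE,
                    correct = TRUE)$p.value)
    }
    list(p = p, null_p = null_p)
  })
  summary <- if (n_reps > 1)
    list(median_p = median(res$p), frac_below_05 = mean(res$p < 0.05),
         null_q05 = unname(quantile(res$null_p, 0.05)))
  else NULL
  structure(list(p = res$p, null_p = res$null_p, summary = summary,
                 params = list(n_sub = n_sub, n_reps = n_reps, seed = seed,
                               alternative = alternative)),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("weighted resampling test: %d reps of %d sequences\n",
              x$params$n_reps, x$params$n_sub))
  if (!is.null(x$summary))
    cat(sprintf("  median p = %.3g; fraction p < 0.05 = %.2f; null 5th pct = %.3g\n",
                x$summary$median_p, x$summary$frac_below_05,
                x$summary$null_q05))
  else cat(sprintf("  p = %.3g\n", x$p))
  invisible(x)
}

#' rRNA fragment-length null control for library size selection
#'
#' Samples `size_n` and `size_m` rRNA structural reads longer than 23 nt from
#' libraries A and B respectively, computes a Wilcoxon rank-sum p-value, and
#' repeats `n_reps` times, yielding a null p-value distribution that reflects
#' library-preparation size selection rather than biology. A markedly
#' non-uniform null flags a size-selection artefact.
#'
#' @param rrna_a,rrna_b data.frames with `length`, `count` of rRNA fragments
#'   per library.
#' @param size_n,size_m Sample sizes matching the precursor comparison.
#' @param n_reps Number of repetitions (default 1000; must be >= 1).
#' @param seed RNG seed.
#' @param alternative Wilcoxon alternative (B vs A), matching the main test.
#' @param min_length Reads must be strictly longer than this (default 23).
#' @return Numeric vector of `n_reps` p-values.
#' @export
rrna_length_control <- function(rrna_a, rrna_b, size_n, size_m,
                                n_reps = 1000, seed = 1,
                                alternative = "greater", min_length = 23) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  a <- rrna_a[rrna_a$length > min_length, , drop = FALSE]
  b <- rrna_b[rrna_b$length > min_length, , drop = FALSE]
  la <- rep(a$length, a$count); lb <- rep(b$length, b$count)
  if (length(la) < size_n || length(lb) < size_m)
    stop("insufficient rRNA reads > ", min_length, " nt")
  local_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      sa <- sample(la, size_n)
      sb <- sample(lb, size_m)
      suppressWarnings(
        wilcox.test(sb, sa, alternative = alternative, exact = FALSE,
                    correct = TRUE)$p.value)
    }, numeric(1))
  })
}
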