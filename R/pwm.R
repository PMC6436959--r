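#' Build a position weight matrix from aligned sites
#'
#' Columns are log2 odds of base frequency (with a background-proportional
#' pseudocount) over the background frequency:
#' `log2((n_ib + pseudocount*q_b) / (n + pseudocount) / q_b)`, optionally
#' multiplied by `scale` so scores can be expressed in the same arbitrary
#' units as externally published log-odds thresholds.
#'
#' @param sites Character vector or `DNAStringSet` of equal-length, N-free
#'   aligned site sequences (>= 2).
#' @param background Background base frequencies (A, C, G, T); must be
#'   positive and sum to 1.
#' @param pseudocount Total pseudocount mass distributed as `pseudocount * q`.
#' @param scale Multiplier applied to the log2-odds matrix (default 1 = bits).
#' @return An object of class `pwm`: list with `mat` (4 x w log-odds matrix,
#'   rows A/C/G/T), `background`, `pseudocount`, `scale`, `width`, `nsites`.
#' @export
build_pwm <- function(sites, background = rep(0.25, 4), pseudocount = 1,
                      scale = 1) {
  sites <- as.character(sites)
  if (length(sites) < 2) stop("need >= 2 site sequences")
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("site sequences must be equal length")
  sites <- toupper(sites)
  if (any(grepl("[^ACGT]", sites))) stop("site sequences must be N-free A/C/G/T")
  background <- background / sum(background)
  if (any(background <= 0)) stop("background frequencies must be positive")
  counts <- consensusMatrix(DNAStringSet(sites))[DNA_BASES, , drop = FALSE]
  n <- length(sites)
  freq <- sweep(counts + pseudocount * background, 2, n + pseudocount, "/")
  mat <- log2(freq / background) * scale
  structure(list(mat = mat, background = setNames(background, DNA_BASES),
                 pseudocount = pseudocount, scale = scale,
                 width = w, nsites = n),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM: width %d, %d sites, pseudocount %g, scale %g\n",
              x$width, x$nsites, x$pseudocount, x$scale))
  cat("consensus:", pwm_consensus(x), "\n")
  print(round(x$mat, 2))
  invisible(x)
}

#' Consensus sequence and maximum attainable score of a PWM
#' @param pwm A `pwm` object.
#' @return `pwm_consensus`: consensus string; `pwm_max_score`: sum of column
#'   maxima (the score of the consensus).
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' @rdname pwm_consensus
#' @export
pwm_max_score <- function(pwm) {
  sum(apply(pwm$mat, 2, max))
}

#' Total information content of a PWM (bits)
#'
#' Sum over columns of the Kullback-Leibler divergence of the (pseudocounted)
#' column frequencies from the background; used to scale motif-disruption
#' thresholds between species whose motifs differ in information content.
#'
#' @param pwm A `pwm` object.
#' @return Information content in bits.
#' @export
pwm_information_content <- function(pwm) {
  freq <- pwm$background * 2^(pwm$mat / pwm$scale)
  sum(freq * (pwm$mat / pwm$scale))
}

# Map a DNA string to integer codes 1..4 (A,C,G,T); anything else -> NA.
.dna_codes <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  match(chars, DNA_BASES)
}

#' Scan a sequence with a PWM
#'
#' Slides the PWM over every offset of `sequence` (one strand only; windows
#' are assumed already extracted strand-aware) and returns the best-scoring
#' occurrence. Offsets overlapping an N are skipped; if all offsets are
#' skipped a no-hit sentinel (`score = NA`) is returned. Ties are broken by
#' the smallest offset.
#'
#' @param pwm A `pwm` object.
#' @param sequence A single DNA string (character or `DNAString`) with
#'   `nchar >= pwm$width`.
#' @return List with `offset` (0-based offset of the motif start in the
#'   window), `score`, and `scores` (per-offset score vector, NA where
#'   skipped).
#' @export
scan_window <- function(pwm, sequence) {
  codes <- .dna_codes(sequence)
  w <- pwm$width
  L <- length(codes)
  if (L < w) stop("sequence shorter than PWM width")
  n_off <- L - w + 1L
  scores <- numeric(n_off)
  ok <- rep(TRUE, n_off)
  for (j in seq_len(w)) {
    b <- codes[j:(j + n_off - 1L)]
    bad <- is.na(b)
    ok <- ok & !bad
    col <- pwm$mat[, j]
    scores <- scores + ifelse(bad, 0, col[ifelse(bad, 1L, b)])
  }
  scores[!ok] <- NA_real_
  if (all(is.na(scores)))
    return(list(offset = NA_integer_, score = NA_real_, scores = scores))
  best <- which.max(scores)  # first maximum: smallest offset on ties
  list(offset = best - 1L, score = scores[best], scores = scores)
}

#' Scan upstream windows of 21U sites with a PWM
#'
#' Extracts a strand-aware window around the 5' end of each 21U mapping site
#' (default 110 bp upstream, 30 bp downstream), scans it with the PWM, and
#' reports for each site the best hit together with the distance from the
#' motif start to the 21U start (so a motif beginning 42 nt upstream of the
#' 21U has `distance = 42`). Windows containing N at the best offset are
#' handled by [scan_window()]; windows that were clipped at contig bounds are
#' flagged.
#'
#' @param genome A `DNAStringSet` genome.
#' @param sites A stranded `GRanges` of 21U mapping sites (a `site_id` mcol is
#'   used if present, otherwise ids are generated).
#' @param pwm A `pwm` object.
#' @param up,down Window geometry in bp around the 21U 5' end.
#' @return data.frame with columns `site_id`, `offset` (0-based in window),
#'   `distance` (motif start to 21U start, bp), `score`, `clipped`.
#' @export
scan_upstream_windows <- function(genome, sites, pwm, up = 110, down = 30) {
  ids <- mcols(sites)$site_id
  if (is.null(ids)) ids <- paste0("site", seq_along(sites))
  win <- upstream_window(sites, up = up, down = down, genome = genome)
  seqs <- as.character(extract_sequence(genome, win))
  # offset of the 21U start within the (possibly clipped) window, 5'->3'
  up_eff <- ifelse(as.character(strand(win)) == "+",
                   start(promoters(sites, up, down)) + up - start(win),
                   end(win) - (end(promoters(sites, up, down)) - up))
  res <- lapply(seq_along(seqs), function(i) {
    hit <- scan_window(pwm, seqs[[i]])
    data.frame(site_id = ids[i],
               offset = hit$offset,
               distance = up_eff[i] - hit$offset,
               score = hit$score,
               clipped = mcols(win)$clipped[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Fit a motif-score threshold from a bimodal score distribution
#'
#' Fits a 2-component univariate Gaussian mixture to motif scores and returns
#' the equal-posterior point between the two component means as the
#' species-specific threshold separating true promoter motifs from background
#' hits. Inputs whose component means are closer than one pooled standard
#' deviation are flagged as effectively unimodal.
#'
#' @param scores Numeric vector of best-hit motif scores (>= 50 values).
#' @return Object of class `threshold_fit`: list with `threshold`, `means`,
#'   `sds`, `weights`, `separation` (|mean difference| / pooled SD),
#'   `unimodal` flag, and `method`.
#' @export
fit_score_threshold <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 50) stop("need >= 50 finite scores")
  fit <- tryCatch(
    Mclust(scores, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (!is.null(fit) && all(is.finite(unlist(fit$parameters$variance$sigmasq)))) {
    mu <- fit$parameters$mean
    sg <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sg) == 1) sg <- rep(sg, 2)
    w <- fit$parameters$pro
    method <- "mclust"
  } else {
    # variance collapse (e.g. point masses): k-means fallback
    km <- kmeans(scores, centers = 2, nstart = 10)
    mu <- as.numeric(km$centers)
    sg <- vapply(1:2, function(k) {
      s <- sd(scores[km$cluster == k])
      if (!is.finite(s) || s == 0) s <- max(diff(range(scores)) * 1e-6, 1e-12)
      s
    }, numeric(1))
    w <- as.numeric(table(factor(km$cluster, 1:2)) / length(scores))
    method <- "kmeans-fallback"
  }
  ord <- order(mu)
  mu <- mu[ord]; sg <- pmax(sg[ord], 1e-12); w <- w[ord]
  tau <- .equal_posterior_point(mu, sg, w)
  pooled <- sqrt(sum(w * sg^2))
  separation <- abs(diff(mu)) / pooled
  structure(list(threshold = tau, means = mu, sds = sg, weights = w,
                 separation = separation, unimodal = separation < 1,
                 method = method, n = length(scores)),
            class = "threshold_fit")
}

# Point x between mu[1] < mu[2] where w1*N(x;mu1,s1) == w2*N(x;mu2,s2).
.equal_posterior_point <- function(mu, sg, w) {
  a <- 1 / sg[1]^2 - 1 / sg[2]^2
  b <- -2 * (mu[1] / sg[1]^2 - mu[2] / sg[2]^2)
  cc <- mu[1]^2 / sg[1]^2 - mu[2]^2 / sg[2]^2 +
    2 * log((w[2] * sg[1]) / (w[1] * sg[2]))
  if (abs(a) < 1e-14) {  # equal variances: linear equation
    if (abs(b) < 1e-14) return(mean(mu))
    x <- -cc / b
    return(if (x > mu[1] && x < mu[2]) x else mean(mu))
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(mean(mu))
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside)) inside[1] else mean(mu)
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf(
    "2-component score mixture (%s): means %.3g / %.3g, weights %.2f / %.2f\n",
    x$method, x$means[1], x$means[2], x$weights[1], x$weights[2]))
  cat(sprintf("threshold = %.4g  (separation %.2f SD%s)\n", x$threshold,
              x$separation, if (x$unimodal) "; WARNING: unimodal" else ""))
  invisible(x)
}

#' Positional distribution of motif hits relative to the 21U start
#'
#' Histograms the motif-start-to-21U-start distances of above-threshold hits
#' and reports the modal distance; for genuine piRNA promoter motifs the mode
#' sits at 42 nt. A distribution with no dominant mode (max bin < 2x the
#' median bin count) is flagged.
#'
#' @param hits data.frame from [scan_upstream_windows()] with `distance` and
#'   `score`.
#' @param threshold Optional score threshold; hits below it are dropped before
#'   computing the mode.
#' @return List with `histogram` (table of distances), `mode` (modal
#'   distance; smallest on ties), `dominant` flag, `n`.
#' @export
positional_distribution <- function(hits, threshold = NULL) {
  d <- hits$distance[is.finite(hits$score)]
  if (!is.null(threshold)) d <- hits$distance[!is.na(hits$score) & hits$score >= threshold]
  d <- d[!is.na(d)]
  if (!length(d)) stop("no hits to histogram")
  tab <- table(d)
  mx <- max(tab)
  mode_d <- as.integer(names(tab)[which(tab == mx)])
  mode_d <- min(mode_d)
  # a single occupied distance is trivially dominant; otherwise the modal
  # bin must hold at least twice the median bin count
  dominant <- length(tab) == 1 || mx >= 2 * median(as.numeric(tab))
  list(histogram = tab, mode = mode_d, dominant = dominant, n = length(d))
}

#' Rescore a motif window after substituting a SNP allele
#'
#' Recalculates the best motif score in a window after substituting the
#' alternate allele at a given position, mirroring the recalculation of motif
#' scores under strain SNPs. When the best motif offset is unchanged and the
#' SNP falls inside it, the score change equals the single-column log-odds
#' difference.
#'
#' @param pwm A `pwm` object.
#' @param window_sequence DNA string of the scanned window (feature strand).
#' @param snp List or data.frame row with `pos` (1-based position in the
#'   window), `ref`, `alt` single bases (on the window strand).
#' @return List with `score_ref`, `score_alt`, `delta = score_alt -
#'   score_ref`, `offset_ref`, `offset_alt`.
#' @export
rescore_with_allele <- function(pwm, window_sequence, snp) {
  seq_chr <- toupper(as.character(window_sequence))
  pos <- as.integer(snp$pos)
  if (pos < 1 || pos > nchar(seq_chr)) stop("SNP position outside window")
  have <- substr(seq_chr, pos, pos)
  if (have != toupper(snp$ref))
    stop(sprintf("reference mismatch at window position %d: sequence has %s, SNP ref is %s",
                 pos, have, snp$ref))
  hit_ref <- scan_window(pwm, seq_chr)
  alt_seq <- seq_chr
  substr(alt_seq, pos, pos) <- toupper(snp$alt)
  hit_alt <- scan_window(pwm, alt_seq)
  list(score_ref = hit_ref$score, score_alt = hit_alt$score,
       delta = hit_alt$score - hit_ref$score,
       offset_ref = hit_ref$offset, offset_alt = hit_alt$offset)
}

#' Probability of a k-mer under per-site marginal base probabilities
#'
#' Sites are treated as independent, so the per-site marginal probabilities of
#' the k-mer's bases are multiplied together (used for the probability that an
#' ancestral SNAPc motif carried a GTTTC core).
#'
#' @param probs k x 4 matrix of per-site base probabilities (columns A,C,G,T;
#'   each row sums to 1).
#' @param kmer DNA string of length k.
#' @return Probability in `[0, 1]`.
#' @export
ancestral_kmer_probability <- function(probs, kmer) {
  probs <- as.matrix(probs)
  codes <- .dna_codes(kmer)
  if (length(codes) != nrow(probs))
    stop("kmer length must equal number of sites")
  if (anyNA(codes)) stop("kmer must be A/C/G/T")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6)) stop("each site's probabilities must sum to 1")
  prod(probs[cbind(seq_len(nrow(probs)), codes)])
}

#' Probability of independent motif origin in two lineages
#'
#' `(1 - p_ancestral) * p_lineage1 * p_lineage2`: the probability that the
#' motif was absent in the ancestor yet present in both descendant lineages.
#'
#' @param p_ancestral,p_lineage1,p_lineage2 Probabilities in `[0, 1]`.
#' @return Probability in `[0, 1]`.
#' @export
independent_origin_probability <- function(p_ancestral, p_lineage1, p_lineage2) {
  p <- c(p_ancestral, p_lineage1, p_lineage2)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must be in [0, 1]")
  (1 - p_ancestral) * p_lineage1 * p_lineage2
}

#' Write / read a PWM in MEME minimal motif format
#'
#' The matrix is stored as letter-probability rows; background frequencies go
#' in the `Background letter frequencies` block. Reading reconstructs the
#' log-odds matrix with the recorded background and `pseudocount = 0` applied
#' to the stored probabilities.
#'
#' @param pwm A `pwm` object.
#' @param path Output / input path.
#' @param name Motif name used in the file.
#' @return `write_meme_pwm`: invisibly `path`; `read_meme_pwm`: a `pwm`.
#' @export
write_meme_pwm <- function(pwm, path, name = "motif1") {
  freq <- pwm$background * 2^(pwm$mat / pwm$scale)
  freq <- sweep(freq, 2, colSums(freq), "/")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, pwm$background), collapse = " "),
               "",
               paste("MOTIF", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       pwm$width, pwm$nsites)), con)
  for (j in seq_len(pwm$width))
    writeLines(paste(sprintf("%.6f", freq[, j]), collapse = " "), con)
  invisible(path)
}

#' @rdname write_meme_pwm
#' @param scale Score scale applied when reconstructing log-odds.
#' @export
read_meme_pwm <- function(path, scale = 1) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  background <- rep(0.25, 4)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    background <- as.numeric(toks[seq(2, 8, by = 2)])
  }
  hdr <- grep("^letter-probability matrix", lines)[1]
  if (is.na(hdr)) stop("no letter-probability matrix in ", path)
  w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr]))
  nsites <- as.integer(sub(".*nsites= *(\\d+).*", "\\1", lines[hdr]))
  rows <- lines[(hdr + 1):(hdr + w)]
  freq <- t(vapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                   numeric(4)))
  mat <- t(log2(sweep(pmax(freq, 1e-9), 2, background, "/"))) * scale
  dimnames(mat) <- list(DNA_BASES, NULL)
  structure(list(mat = mat, background = setNames(background, DNA_BASES),
                 pseudocount = 0, scale = scale, width = w,
                 nsites = if (is.na(nsites)) 0L else nsites),
            class = "pwm")
}
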