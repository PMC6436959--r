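#' Call piRNA loci from 21U sites and upstream motif hits
#'
#' A 21U mapping site becomes a piRNA locus when its best upstream motif hit
#' scores at least `threshold` and the motif start lies at the canonical
#' distance from the 21U start (default 42 +/- 5 nt). The transcription start
#' site is placed 2 nt upstream of the 21U 5' end, strand-aware. Loci
#' overlapping a provided exclusion set (e.g. snRNA/snoRNA annotations) are
#' dropped, and the number dropped is reported.
#'
#' @param sites_21u Stranded `GRanges` of 21-nt 21U mapping sites with a
#'   `site_id` mcol (generated when absent).
#' @param motif_hits data.frame from [scan_upstream_windows()] (`site_id`,
#'   `score`, `distance`).
#' @param threshold Motif-score threshold (e.g. from [fit_score_threshold()]).
#' @param offset_center,offset_tol Motif-distance acceptance window; a hit
#'   passes when `abs(distance - offset_center) <= offset_tol`.
#' @param exclude Optional `GRanges` of intervals whose overlap disqualifies a
#'   locus (strand-insensitive overlap of the 21U site).
#' @return A `GRanges` of 21U sites that qualify as loci, with mcols
#'   `locus_id`, `site_id`, `tss` (genomic position of the TSS), `motif_score`,
#'   `motif_distance`. The number of exclusion-dropped loci is in
#'   `attr(, "n_excluded")`.
#' @export
call_pirna_loci <- function(sites_21u, motif_hits, threshold,
                            offset_center = 42, offset_tol = 5,
                            exclude = NULL) {
  ids <- mcols(sites_21u)$site_id
  if (is.null(ids)) {
    ids <- paste0("site", seq_along(sites_21u))
    mcols(sites_21u)$site_id <- ids
  }
  hits <- motif_hits[!is.na(motif_hits$score), , drop = FALSE]
  pass <- hits$score >= threshold &
    abs(hits$distance - offset_center) <= offset_tol
  keep_ids <- sort(unique(hits$site_id[pass]))
  sel <- sites_21u[ids %in% keep_ids]
  sel <- sel[order(mcols(sel)$site_id)]
  hit_idx <- match(mcols(sel)$site_id, hits$site_id)
  tss <- ifelse(as.character(strand(sel)) == "+", start(sel) - 2L, end(sel) + 2L)
  mcols(sel)$tss <- as.integer(tss)
  mcols(sel)$motif_score <- hits$score[hit_idx]
  mcols(sel)$motif_distance <- hits$distance[hit_idx]
  n_excluded <- 0L
  if (!is.null(exclude) && length(exclude)) {
    drop <- overlapsAny(sel, exclude, ignore.strand = TRUE)
    n_excluded <- sum(drop)
    sel <- sel[!drop]
  }
  mcols(sel)$locus_id <- if (length(sel)) paste0("piR", seq_along(sel)) else character(0)
  attr(sel, "n_excluded") <- n_excluded
  sel
}

# Genomic position of the 5' end of each read/site, strand-aware.
.five_prime <- function(gr) {
  ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
}

#' Extract capped precursor reads for piRNA loci
#'
#' Keeps capped reads whose 5' end sits exactly at a locus TSS (2 nt upstream
#' of the mature 21U start) on the locus strand and whose length exceeds
#' 22 nt, and groups them by locus.
#'
#' @param capped_reads `GRanges` of capped reads with `length` and `count`
#'   mcols (e.g. from [read_sites_tsv()]).
#' @param loci `GRanges` from [call_pirna_loci()] (needs `locus_id` and `tss`).
#' @param min_length Reads must be strictly longer than this (default 22).
#' @return data.frame `locus_id`, `length`, `count` (one row per locus/length
#'   combination), class `precursor_set`.
#' @export
extract_precursors <- function(capped_reads, loci, min_length = 22) {
  if (!length(loci) || !length(capped_reads)) {
    out <- data.frame(locus_id = character(0), length = integer(0),
                      count = integer(0))
    class(out) <- c("precursor_set", "data.frame")
    return(out)
  }
  r5 <- .five_prime(capped_reads)
  key_r <- paste(seqnames(capped_reads), strand(capped_reads), r5)
  key_l <- paste(seqnames(loci), strand(loci), mcols(loci)$tss)
  idx <- match(key_r, key_l)
  keep <- !is.na(idx) & mcols(capped_reads)$length > min_length
  out <- data.frame(locus_id = mcols(loci)$locus_id[idx[keep]],
                    length = mcols(capped_reads)$length[keep],
                    count = mcols(capped_reads)$count[keep],
                    stringsAsFactors = FALSE)
  out <- stats::aggregate(count ~ locus_id + length, data = out, FUN = sum)
  out <- out[order(out$locus_id, out$length), c("locus_id", "length", "count")]
  rownames(out) <- NULL
  class(out) <- c("precursor_set", "data.frame")
  out
}

#' Extract 3' cleavage fragments downstream of piRNA TSSs
#'
#' All 21U reads are removed first (exact interval match to a 21U site), then
#' uniquely mapping reads longer than 10 nt whose 5' ends fall at positions
#' +28 to +38 relative to a locus TSS (locus strand) are counted per locus.
#' Counts are normalised to the total of non-structural mapped reads, and
#' unique-sequence counts to the unique non-structural total.
#'
#' @param monop_reads `GRanges` of monophosphate reads with `length`, `count`,
#'   `unique` mcols.
#' @param loci `GRanges` from [call_pirna_loci()].
#' @param total_nonstructural,unique_nonstructural Normalisation denominators.
#' @param sites_21u Optional `GRanges` of 21U sites used to remove 21U reads
#'   by exact interval match before counting.
#' @return data.frame per locus: `locus_id`, `count`, `norm_count`,
#'   `unique_sequences`, `norm_unique`.
#' @export
extract_cleavage_fragments <- function(monop_reads, loci,
                                       total_nonstructural,
                                       unique_nonstructural,
                                       sites_21u = NULL) {
  if (length(monop_reads) &&
      (is.null(mcols(monop_reads)$unique) || anyNA(mcols(monop_reads)$unique)))
    stop("monophosphate reads must carry a complete 'unique' flag")
  reads <- monop_reads
  if (!is.null(sites_21u) && length(sites_21u) && length(reads)) {
    key_r <- paste(seqnames(reads), strand(reads), start(reads), end(reads))
    key_u <- paste(seqnames(sites_21u), strand(sites_21u),
                   start(sites_21u), end(sites_21u))
    reads <- reads[!(key_r %in% key_u)]
  }
  base <- data.frame(locus_id = mcols(loci)$locus_id, count = 0L,
                     unique_sequences = 0L, stringsAsFactors = FALSE)
  if (length(reads)) {
    keep <- mcols(reads)$unique & mcols(reads)$length > 10
    reads <- reads[keep]
    if (length(reads)) {
      r5 <- .five_prime(reads)
      # match each read to a locus on the same contig/strand with 5' end in
      # [tss+28, tss+38] downstream (strand-aware)
      for (i in seq_along(loci)) {
        same <- as.character(seqnames(reads)) == as.character(seqnames(loci))[i] &
          as.character(strand(reads)) == as.character(strand(loci))[i]
        tss <- mcols(loci)$tss[i]
        rel <- if (as.character(strand(loci))[i] == "+") r5 - tss else tss - r5
        hit <- same & rel >= 28 & rel <= 38
        base$count[i] <- sum(mcols(reads)$count[hit])
        base$unique_sequences[i] <- sum(hit)
      }
    }
  }
  base$norm_count <- base$count / total_nonstructural
  base$norm_unique <- base$unique_sequences / unique_nonstructural
  base[, c("locus_id", "count", "norm_count", "unique_sequences", "norm_unique")]
}

#' Median-of-ratios library size factors
#'
#' For each library, the size factor is the median over reference genes of the
#' gene's count divided by the gene's geometric mean across libraries; genes
#' with a zero in any library are excluded from the reference set.
#'
#' @param count_matrix Genes x libraries matrix of non-negative counts
#'   (>= 2 libraries).
#' @return Object of class `size_factors`: list with `factors` (named per
#'   library), `method = "median-of-ratios"`, `n_reference_genes`.
#' @export
size_factors_median_ratios <- function(count_matrix) {
  m <- as.matrix(count_matrix)
  if (ncol(m) < 2) stop("need >= 2 libraries")
  ref <- m[rowSums(m == 0) == 0, , drop = FALSE]
  if (!nrow(ref)) stop("no gene has nonzero counts in all libraries")
  log_gm <- rowMeans(log(ref))
  factors <- apply(ref, 2, function(col) median(exp(log(col) - log_gm)))
  if (is.null(names(factors))) names(factors) <- paste0("lib", seq_along(factors))
  structure(list(factors = factors, method = "median-of-ratios",
                 n_reference_genes = nrow(ref)),
            class = "size_factors")
}

#' Slope-based library size factors for a pair of libraries
#'
#' Fits a linear model of library-2 counts on library-1 counts over shared
#' reference genes (through the origin by default) and reports the slope with
#' a +/- 1.96 standard-error interval as the size factor estimate.
#'
#' @param counts_pair Two-column matrix/data.frame of counts over >= 10 shared
#'   genes (column 1 = reference library, column 2 = library being scaled).
#' @param intercept Fit with an intercept (`TRUE`) or through the origin
#'   (default `FALSE`).
#' @return Object of class `size_factors`: list with `slope`, `se`,
#'   `interval` (slope +/- 1.96 * SE), `intercept_fit`, `method = "slope"`.
#' @export
size_factors_slope <- function(counts_pair, intercept = FALSE) {
  m <- as.matrix(counts_pair)
  if (ncol(m) != 2) stop("counts_pair must have exactly 2 columns")
  if (nrow(m) < 10) stop("need >= 10 shared genes")
  if (all(m == 0)) stop("degenerate input: all counts zero")
  x <- m[, 1]; y <- m[, 2]
  fit <- if (intercept) lm(y ~ x) else lm(y ~ x + 0)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits have SE 0
  slope <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  if (!is.finite(se)) se <- 0
  structure(list(slope = slope, se = se,
                 interval = slope + c(-1.96, 1.96) * se,
                 intercept_fit = intercept, method = "slope",
                 n_genes = nrow(m)),
            class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  if (x$method == "median-of-ratios") {
    cat("median-of-ratios size factors (", x$n_reference_genes,
        " reference genes):\n", sep = "")
    print(round(x$factors, 4))
  } else {
    cat(sprintf("slope size factor: %.4g (95%% interval %.4g - %.4g, %d genes)\n",
                x$slope, x$interval[1], x$interval[2], x$n_genes))
  }
  invisible(x)
}
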