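#' Per-contig binomial enrichment of piRNA loci
#'
#' Tests each contig against the null of an even distribution of loci across
#' the genome: with `N` loci total and a contig carrying fraction `p_i` of the
#' genome, the one-sided (greater) exact binomial tail probability of seeing
#' at least the observed `k_i` loci is reported. Zero-length contigs are
#' excluded with a warning.
#'
#' @param loci `GRanges` of piRNA loci.
#' @param genome A `DNAStringSet` genome or a named vector of contig lengths.
#' @return data.frame per contig: `contig`, `length`, `count`, `expected`,
#'   `p_value`, `p_adj` (Benjamini-Hochberg; reported for users, the span
#'   curve ranks by raw p).
#' @export
contig_enrichment <- function(loci, genome) {
  lens <- if (is.numeric(genome)) genome else genome_lengths(genome)
  zero <- lens == 0
  if (any(zero)) {
    warning("excluding zero-length contig(s): ",
            paste(names(lens)[zero], collapse = ", "))
    lens <- lens[!zero]
  }
  N <- length(loci)
  if (N < 1) stop("need at least one locus")
  counts <- table(factor(as.character(seqnames(loci)), levels = names(lens)))
  p_i <- lens / sum(as.numeric(lens))
  k <- as.integer(counts)
  pval <- pbinom(k - 1L, N, p_i, lower.tail = FALSE)
  data.frame(contig = names(lens), length = as.numeric(lens), count = k,
             expected = N * p_i, p_value = as.numeric(pval),
             p_adj = p.adjust(pval, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cumulative span curve and span-90 of piRNA loci
#'
#' Orders contigs by increasing binomial enrichment p-value (ties broken by
#' decreasing piRNA density, then contig name), accumulates loci and genomic
#' span in that order, and reports the span needed to reach 90% (by default)
#' of all loci. Small span-90 relative to genome size indicates clustered
#' (C-type) organisation.
#'
#' @param stats data.frame from [contig_enrichment()].
#' @param quantile Fraction of loci the span must cover (default 0.9).
#' @return Object of class `span_curve`: list with `curve` (ordered per-contig
#'   data.frame with cumulative columns), `span90` (bp), `quantile`,
#'   `n_loci`, `genome_size`.
#' @export
span_curve <- function(stats, quantile = 0.9) {
  if (!nrow(stats)) stop("empty contig stats")
  dens <- stats$count / stats$length
  ord <- order(stats$p_value, -dens, stats$contig)
  curve <- stats[ord, , drop = FALSE]
  N <- sum(curve$count)
  if (N < 1) stop("no loci")
  curve$cum_loci <- cumsum(curve$count)
  curve$cum_fraction <- curve$cum_loci / N
  curve$cum_span <- cumsum(curve$length)
  rownames(curve) <- NULL
  idx <- which(curve$cum_fraction >= quantile)[1]
  structure(list(curve = curve, span90 = curve$cum_span[idx],
                 quantile = quantile, n_loci = N,
                 genome_size = sum(stats$length)),
            class = "span_curve")
}

#' @export
print.span_curve <- function(x, ...) {
  cat(sprintf("span curve: %d loci over %.3g bp; span at %.0f%% loci = %.3g bp\n",
              x$n_loci, x$genome_size, 100 * x$quantile, x$span90))
  invisible(x)
}

#' Classify species into clustering modes by mixture of linear regressions
#'
#' Fits a 2-component mixture of linear regressions (EM, multiple random
#' restarts) of span-90 on the number of piRNA loci across species, and
#' assigns each species to the component with the larger responsibility.
#' Species on the low-span component are genomically clustered (C-type);
#' species on the high-span component are dispersed (P-type).
#'
#' @param points data.frame with columns `species`, `n_pirnas`, `span90`
#'   (>= 6 rows).
#' @param n_restarts Number of random EM restarts (default 20).
#' @param seed RNG seed for the restarts.
#' @param equal_var Share one residual variance across components (default
#'   `TRUE`; stabler on few species points).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return Object of class `mixreg_fit`: list with `coefficients` (2 x 2
#'   intercept/slope), `sigma` (per component), `weights`, `responsibilities`,
#'   `assignment` (1 = lower-span component, labelled `"clustered"`),
#'   `labels`, `loglik`, `degenerate` flag.
#' @export
classify_clustering <- function(points, n_restarts = 20, seed = 1,
                                equal_var = TRUE, max_iter = 500,
                                tol = 1e-8) {
  if (nrow(points) < 6) stop("need >= 6 species points")
  x <- as.numeric(points$n_pirnas)
  y <- as.numeric(points$span90)
  n <- length(x)
  # degenerate single-line check
  single <- lm(y ~ x)
  if (all(abs(residuals(single)) < 1e-8 * max(1, diff(range(y))))) {
    co <- matrix(rep(coef(single), 2), nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, c("intercept", "slope")))
    return(structure(list(coefficients = co, sigma = c(0, 0),
                          weights = c(1, 0),
                          responsibilities = cbind(rep(1, n), rep(0, n)),
                          assignment = rep(1L, n),
                          labels = rep("clustered", n),
                          loglik = Inf, degenerate = TRUE,
                          species = points$species),
                     class = "mixreg_fit"))
  }
  best <- NULL
  local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- .mixreg_em(x, y, equal_var = equal_var, max_iter = max_iter,
                        tol = tol)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
        best <- fit
    }
  })
  if (is.null(best)) stop("mixture-of-regressions EM failed to converge")
  # order components: component 1 = lower fitted span at the mean x
  mx <- mean(x)
  fitted_mid <- best$coefficients[, 1] + best$coefficients[, 2] * mx
  ord <- order(fitted_mid)
  best$coefficients <- best$coefficients[ord, , drop = FALSE]
  best$sigma <- best$sigma[ord]
  best$weights <- best$weights[ord]
  best$responsibilities <- best$responsibilities[, ord, drop = FALSE]
  best$assignment <- max.col(best$responsibilities)
  best$labels <- c("clustered", "dispersed")[best$assignment]
  best$degenerate <- FALSE
  best$species <- points$species
  class(best) <- "mixreg_fit"
  best
}

# One EM run for a 2-component mixture of simple linear regressions.
.mixreg_em <- function(x, y, equal_var, max_iter, tol) {
  n <- length(x)
  # random soft initialisation
  resp <- matrix(runif(2 * n, 0.1, 0.9), ncol = 2)
  resp <- resp / rowSums(resp)
  loglik_old <- -Inf
  co <- matrix(0, 2, 2, dimnames = list(NULL, c("intercept", "slope")))
  sg <- c(1, 1); w <- c(0.5, 0.5)
  sd_floor <- max(sd(y), 1) * 1e-6
  for (it in seq_len(max_iter)) {
    # M step: weighted least squares per component
    for (k in 1:2) {
      wt <- pmax(resp[, k], 1e-10)
      fit <- lm.wfit(cbind(1, x), y, wt)
      co[k, ] <- fit$coefficients
      sg[k] <- sqrt(sum(wt * fit$residuals^2) / sum(wt))
    }
    if (equal_var) {
      pooled <- sqrt(sum(resp * (y - cbind(co[1, 1] + co[1, 2] * x,
                                           co[2, 1] + co[2, 2] * x))^2) / n)
      sg[] <- pooled
    }
    sg <- pmax(sg, sd_floor)
    w <- colMeans(resp)
    # E step
    dens <- cbind(w[1] * dnorm(y, co[1, 1] + co[1, 2] * x, sg[1]),
                  w[2] * dnorm(y, co[2, 1] + co[2, 2] * x, sg[2]))
    tot <- rowSums(dens)
    if (any(tot <= 0) || anyNA(tot)) return(NULL)
    resp <- dens / tot
    loglik <- sum(log(tot))
    if (is.finite(loglik) && abs(loglik - loglik_old) < tol) break
    loglik_old <- loglik
  }
  list(coefficients = co, sigma = sg, weights = w,
       responsibilities = resp, loglik = loglik)
}

#' @export
print.mixreg_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("mixture of regressions: degenerate (all points on one line)\n")
  } else {
    cat(sprintf("mixture of regressions (loglik %.2f):\n", x$loglik))
    for (k in 1:2)
      cat(sprintf("  component %d (%s): span90 = %.3g + %.3g * N, sd %.3g, weight %.2f\n",
                  k, c("clustered", "dispersed")[k], x$coefficients[k, 1],
                  x$coefficients[k, 2], x$sigma[k], x$weights[k]))
  }
  invisible(x)
}

#' Map genes on piRNA-enriched contigs to reference-genome bins
#'
#' Takes the 1:1 orthologs of genes located on piRNA-enriched contigs and
#' counts their reference-genome positions in fixed-width bins, revealing
#' whether piRNA contigs correspond to particular reference chromosomal
#' regions. Non-1:1 ortholog rows are rejected and counted.
#'
#' @param pirna_contigs Character vector of piRNA-enriched contig names.
#' @param genes `GRanges` of the species' genes with a `gene_id` mcol.
#' @param ortholog_table data.frame with columns `gene_id`, `ref_gene_id`.
#' @param reference_genes `GRanges` of reference genes with a `gene_id` mcol.
#' @param bin_bp Bin width in bp (default 100 kb).
#' @return data.frame `chrom`, `bin_start` (0-based), `bin_end`, `count`;
#'   rejected row count in `attr(, "n_rejected")`.
#' @export
map_contigs_to_reference <- function(pirna_contigs, genes, ortholog_table,
                                     reference_genes, bin_bp = 1e5) {
  ot <- ortholog_table
  dup <- duplicated(ot$gene_id) | duplicated(ot$gene_id, fromLast = TRUE) |
    duplicated(ot$ref_gene_id) | duplicated(ot$ref_gene_id, fromLast = TRUE)
  n_rejected <- sum(dup)
  ot <- ot[!dup, , drop = FALSE]
  on_pirna <- mcols(genes)$gene_id[as.character(seqnames(genes)) %in% pirna_contigs]
  ref_ids <- ot$ref_gene_id[ot$gene_id %in% on_pirna]
  ref_hit <- reference_genes[mcols(reference_genes)$gene_id %in% ref_ids]
  # bin all reference chromosomes (span taken from the reference gene extent)
  out <- do.call(rbind, lapply(unique(as.character(seqnames(reference_genes))),
    function(chr) {
      chr_genes <- reference_genes[as.character(seqnames(reference_genes)) == chr]
      chr_len <- max(end(chr_genes))
      breaks <- seq(0, ceiling(chr_len / bin_bp) * bin_bp, by = bin_bp)
      hit_pos <- start(ref_hit[as.character(seqnames(ref_hit)) == chr])
      cnt <- if (length(hit_pos))
        as.integer(table(cut(hit_pos, breaks = breaks, right = TRUE)))
      else rep(0L, length(breaks) - 1L)
      data.frame(chrom = chr, bin_start = head(breaks, -1),
                 bin_end = tail(breaks, -1), count = cnt,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Odds ratio and Fisher test for X-chromosome depletion of piRNA genes
#'
#' Builds the 2x2 table of genes with/without an associated piRNA locus by
#' X-chromosome membership and reports the cross-product odds ratio (Haldane
#' 0.5 correction when any cell is zero, flagged) with a two-sided Fisher
#' exact p-value.
#'
#' @param gene_table data.frame with logical columns `has_pirna`, `on_X`, or
#'   a 2x2 matrix `[has_pirna, !has_pirna] x [on_X, !on_X]`.
#' @return List with `odds_ratio`, `p_value`, `table`, `corrected` flag.
#' @export
x_depletion_test <- function(gene_table) {
  if (is.matrix(gene_table)) {
    tab <- gene_table
  } else {
    tab <- table(factor(gene_table$has_pirna, c(TRUE, FALSE)),
                 factor(gene_table$on_X, c(TRUE, FALSE)))
    tab <- matrix(as.integer(tab), 2, 2)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in 2x2 table")
  corrected <- any(tab == 0)
  tc <- if (corrected) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  p <- fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p, table = tab, corrected = corrected)
}
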