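# TSS point of each locus as a GRanges (strand kept, width 1).
.tss_points <- function(loci) {
  GRanges(seqnames(loci), IRanges(mcols(loci)$tss, width = 1),
          strand = strand(loci))
}

#' Enrichment/depletion of piRNA loci in chromatin domain states
#'
#' Assigns each locus to a chromatin state by the position of its TSS,
#' compares observed counts per state to the expectation under a uniform
#' distribution over the universe (expected proportional to the state's span
#' within the universe), and tests each state with a Fisher exact test on the
#' 2x2 table of (loci in state vs not) against (bp of span in state vs not).
#' Depletions are reported as fold below expectation; a state with zero
#' observed loci gets a guarded lower-bound depletion (computed with 0.5
#' pseudo-observation) and a flag.
#'
#' @param loci `GRanges` of loci with a `tss` mcol.
#' @param domains `GRanges` of chromatin domains with a `state` mcol
#'   (e.g. `"active"`, `"regulated"`); overlapping same-state intervals are
#'   merged, cross-state overlaps resolved in favour of the first state seen
#'   (with a warning).
#' @param universe `GRanges` universe the loci live in (whole genome or
#'   cluster regions).
#' @return data.frame per state: `state`, `span`, `observed`, `expected`,
#'   `fold` (observed/expected), `depletion` (expected/observed, guarded),
#'   `p_value`, `guarded` flag.
#' @export
domain_overlap_enrichment <- function(loci, domains, universe) {
  states <- unique(as.character(mcols(domains)$state))
  tss <- .tss_points(loci)
  in_universe <- overlapsAny(tss, universe, ignore.strand = TRUE)
  if (!all(in_universe))
    warning(sum(!in_universe), " locus TSS(s) outside the universe; dropped")
  tss <- tss[in_universe]
  N <- length(tss)
  span_u <- sum(width(reduce(universe, ignore.strand = TRUE)))
  res <- lapply(states, function(st) {
    dom <- reduce(domains[mcols(domains)$state == st], ignore.strand = TRUE)
    dom_u <- GenomicRanges::intersect(dom, reduce(universe, ignore.strand = TRUE),
                                      ignore.strand = TRUE)
    span <- sum(width(dom_u))
    if (span == 0) return(NULL)
    obs <- sum(overlapsAny(tss, dom_u, ignore.strand = TRUE))
    expd <- N * span / span_u
    guarded <- obs == 0
    fold <- obs / expd
    depletion <- expd / max(obs, 0.5)
    p <- fisher.test(matrix(c(obs, N - obs, span, span_u - span), 2, 2,
                            byrow = TRUE))$p.value
    data.frame(state = st, span = span, observed = obs, expected = expd,
               fold = fold, depletion = depletion, p_value = p,
               guarded = guarded, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_loci") <- N
  attr(out, "n_unassigned") <- N - sum(out$observed)
  out
}

#' Assign a chromatin state to genes by domain coverage
#'
#' A gene is assigned a state when intervals of that state cover at least
#' `min_coverage` (default 75%) of the gene's length; otherwise it is
#' `"unassigned"`. The rule is invariant to fragmentation of domain intervals
#' because same-state intervals are merged before coverage is computed.
#'
#' @param genes `GRanges` of gene bodies with a `gene_id` mcol.
#' @param domains `GRanges` with a `state` mcol.
#' @param min_coverage Minimum covered fraction (default 0.75).
#' @return data.frame `gene_id`, `state`, plus per-state coverage fractions.
#' @export
assign_gene_state <- function(genes, domains, min_coverage = 0.75) {
  states <- unique(as.character(mcols(domains)$state))
  cov <- sapply(states, function(st) {
    dom <- reduce(domains[mcols(domains)$state == st], ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(genes, dom, ignore.strand = TRUE)
    covered <- rep(0, length(genes))
    if (length(ov)) {
      w <- pmin(end(genes)[queryHits(ov)], end(dom)[subjectHits(ov)]) -
        pmax(start(genes)[queryHits(ov)], start(dom)[subjectHits(ov)]) + 1
      agg <- tapply(w, queryHits(ov), sum)
      covered[as.integer(names(agg))] <- agg
    }
    covered / width(genes)
  })
  cov <- matrix(cov, nrow = length(genes), dimnames = list(NULL, states))
  best <- apply(cov, 1, which.max)
  state <- ifelse(cov[cbind(seq_along(best), best)] >= min_coverage,
                  states[best], "unassigned")
  out <- data.frame(gene_id = mcols(genes)$gene_id, state = state,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cov))
}

#' Predict chromatin states by 1:1 orthology
#'
#' Each target gene inherits the chromatin state of its 1:1 reference
#' ortholog. When a direct assignment is also supplied, a concordance table
#' is reported.
#'
#' @param target_genes Character vector of target gene ids (or `GRanges` with
#'   `gene_id`).
#' @param ortholog_table data.frame `gene_id`, `ref_gene_id` (1:1 rows only;
#'   others dropped with a count).
#' @param reference_states data.frame `gene_id`, `state` for reference genes.
#' @param direct_states Optional data.frame `gene_id`, `state` of direct
#'   assignments for the target genes.
#' @return List with `predicted` (data.frame `gene_id`, `state`),
#'   `concordance` (table or NULL), `concordance_rate`, `n_rejected`.
#' @export
predict_states_by_orthology <- function(target_genes, ortholog_table,
                                        reference_states,
                                        direct_states = NULL) {
  ids <- if (inherits(target_genes, "GRanges")) mcols(target_genes)$gene_id
         else as.character(target_genes)
  ot <- ortholog_table
  dup <- duplicated(ot$gene_id) | duplicated(ot$gene_id, fromLast = TRUE) |
    duplicated(ot$ref_gene_id) | duplicated(ot$ref_gene_id, fromLast = TRUE)
  n_rejected <- sum(dup)
  ot <- ot[!dup, , drop = FALSE]
  ref_state <- setNames(reference_states$state, reference_states$gene_id)
  pred_state <- ref_state[ot$ref_gene_id[match(ids, ot$gene_id)]]
  predicted <- data.frame(gene_id = ids, state = unname(pred_state),
                          stringsAsFactors = FALSE)
  concordance <- NULL; rate <- NA_real_
  if (!is.null(direct_states)) {
    dmap <- setNames(direct_states$state, direct_states$gene_id)
    both <- !is.na(predicted$state) & ids %in% names(dmap)
    if (any(both)) {
      concordance <- table(predicted = predicted$state[both],
                           direct = dmap[ids[both]])
      rate <- mean(predicted$state[both] == dmap[ids[both]])
    }
  }
  list(predicted = predicted, concordance = concordance,
       concordance_rate = rate, n_rejected = n_rejected)
}

#' Chromatin-state odds ratio of piRNA-gene association
#'
#' Log2 odds ratio (with Fisher exact p) of the 2x2 table of genes with and
#' without an associated piRNA locus, in active versus regulated chromatin.
#' A zero cell triggers the Haldane correction and a flag; if either state is
#' absent the OR is undefined and flagged.
#'
#' @param gene_states data.frame `gene_id`, `state`.
#' @param pirna_gene_ids Character vector of gene ids that carry a piRNA
#'   locus.
#' @return List with `log2_or`, `odds_ratio`, `p_value`, `table`, `corrected`,
#'   `undefined` flags.
#' @export
gene_pirna_chromatin_or <- function(gene_states, pirna_gene_ids) {
  gs <- gene_states[gene_states$state %in% c("active", "regulated"), ]
  if (!nrow(gs) || length(unique(gs$state)) < 2)
    return(list(log2_or = NA_real_, odds_ratio = NA_real_, p_value = NA_real_,
                table = NULL, corrected = FALSE, undefined = TRUE))
  has <- gs$gene_id %in% pirna_gene_ids
  tab <- table(factor(has, c(TRUE, FALSE)),
               factor(gs$state, c("active", "regulated")))
  tab <- matrix(as.integer(tab), 2, 2,
                dimnames = list(c("pirna", "no_pirna"), c("active", "regulated")))
  corrected <- any(tab == 0)
  tc <- if (corrected) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  p <- fisher.test(tab)$p.value
  list(log2_or = log2(or), odds_ratio = or, p_value = p, table = tab,
       corrected = corrected, undefined = FALSE)
}

#' Genicness score of piRNA positioning with simulation nulls
#'
#' Computes the genic/intergenic ratio of observed piRNA locus positions and
#' divides it by the median ratio over `n_sim` random placements of the same
#' number and lengths of loci (genome-wide, or within each locus's contig of
#' origin when `scope = "contig"`), log2-transformed - equivalent to a log2
#' odds ratio of genic positioning. A pseudocount of 0.5 guards empty
#' categories. The empirical p-value uses the (1 + exceedances)/(n_sim + 1)
#' correction, with the tail side chosen by the direction of the observed
#' deviation.
#'
#' @param loci `GRanges` of loci (TSS point used for genic assignment when a
#'   `tss` mcol is present, otherwise the interval start).
#' @param genes `GRanges` of gene bodies.
#' @param genome Genome (`DNAStringSet`) or named contig-length vector.
#' @param n_sim Number of simulated placements (default 100).
#' @param scope `"genome"` or `"contig"` resampling scope.
#' @param seed RNG seed.
#' @return Object of class `genicness_result`: list with `score` (G),
#'   `observed_ratio`, `simulated_ratios`, `p_value`, `n_sim`, `scope`.
#' @export
genicness_score <- function(loci, genes, genome, n_sim = 100,
                            scope = c("genome", "contig"), seed = 1) {
  scope <- match.arg(scope)
  if (n_sim < 1) stop("n_sim must be >= 1")
  lens <- if (is.numeric(genome)) genome else genome_lengths(genome)
  pos <- if (!is.null(mcols(loci)$tss)) mcols(loci)$tss else start(loci)
  contig <- as.character(seqnames(loci))
  gene_red <- reduce(genes, ignore.strand = TRUE)
  ratio_of <- function(contigs, positions) {
    pts <- GRanges(contigs, IRanges(positions, width = 1))
    g <- sum(overlapsAny(pts, gene_red, ignore.strand = TRUE))
    (g + 0.5) / (length(pts) - g + 0.5)
  }
  observed <- ratio_of(contig, pos)
  sims <- local_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      if (scope == "genome") {
        sim_contig <- sample(names(lens), length(loci), replace = TRUE,
                             prob = lens / sum(as.numeric(lens)))
      } else {
        sim_contig <- contig
      }
      sim_pos <- floor(runif(length(loci), 1, lens[sim_contig] + 1))
      ratio_of(sim_contig, sim_pos)
    }, numeric(1))
  })
  G <- log2(observed / median(sims))
  p <- if (observed >= median(sims))
    (1 + sum(sims >= observed)) / (n_sim + 1)
  else
    (1 + sum(sims <= observed)) / (n_sim + 1)
  structure(list(score = G, observed_ratio = observed,
                 simulated_ratios = sims, p_value = p, n_sim = n_sim,
                 scope = scope),
            class = "genicness_result")
}

#' @export
print.genicness_result <- function(x, ...) {
  cat(sprintf("genicness G = %.3f (observed ratio %.3g, median null %.3g), p = %.3g [%s scope, %d sims]\n",
              x$score, x$observed_ratio, median(x$simulated_ratios),
              x$p_value, x$scope, x$n_sim))
  invisible(x)
}

#' Promoter association of piRNA loci
#'
#' Defines promoters as windows of `windows` bp upstream of each gene's first
#' exon (strand-aware), restricts attention to intergenic space (complement of
#' all gene bodies), and compares the density of piRNA loci in
#' promoter-intergenic space to the density in the remaining intergenic
#' space. Genes without exons are skipped with a count.
#'
#' @param loci `GRanges` of loci (TSS point used when `tss` mcol present).
#' @param genes `GRanges` of gene bodies with `gene_id`.
#' @param exons `GRanges` of exons with `gene_id` and `exon_rank` mcols (rank
#'   1 = first exon in transcription order).
#' @param genome Genome or named contig-length vector.
#' @param windows Promoter window sizes in bp (default 200, 500, 1000).
#' @return data.frame per window size: `window`, `n_promoter`,
#'   `n_nonpromoter`, `span_promoter`, `span_nonpromoter`, `fold`; skipped
#'   gene count in `attr(, "n_skipped_genes")`.
#' @export
promoter_association <- function(loci, genes, exons, genome,
                                 windows = c(200, 500, 1000)) {
  lens <- if (is.numeric(genome)) genome else genome_lengths(genome)
  si <- Seqinfo(seqnames = names(lens), seqlengths = unname(lens))
  pos <- if (!is.null(mcols(loci)$tss)) mcols(loci)$tss else start(loci)
  pts <- GRanges(as.character(seqnames(loci)), IRanges(pos, width = 1))
  first_exons <- exons[mcols(exons)$exon_rank == 1]
  n_skipped <- sum(!(mcols(genes)$gene_id %in% mcols(first_exons)$gene_id))
  gene_body <- reduce(genes, ignore.strand = TRUE)
  GenomeInfoDb::seqlevels(gene_body) <- names(lens)
  GenomeInfoDb::seqinfo(gene_body) <- si
  intergenic <- gaps(gene_body)
  intergenic <- intergenic[strand(intergenic) == "*"]
  out <- do.call(rbind, lapply(windows, function(wbp) {
    prom <- trim(promoters(first_exons, upstream = wbp, downstream = 0))
    prom <- reduce(prom, ignore.strand = TRUE)
    prom_ig <- GenomicRanges::intersect(prom, intergenic, ignore.strand = TRUE)
    nonprom_ig <- GenomicRanges::setdiff(intergenic, prom_ig, ignore.strand = TRUE)
    n_p <- sum(overlapsAny(pts, prom_ig, ignore.strand = TRUE))
    n_n <- sum(overlapsAny(pts, nonprom_ig, ignore.strand = TRUE))
    s_p <- sum(width(prom_ig)); s_n <- sum(width(nonprom_ig))
    fold <- ((n_p + 0.5) / s_p) / ((n_n + 0.5) / s_n)
    data.frame(window = wbp, n_promoter = n_p, n_nonpromoter = n_n,
               span_promoter = s_p, span_nonpromoter = s_n, fold = fold)
  }))
  attr(out, "n_skipped_genes") <- n_skipped
  out
}

#' Split genes into high/low expression strata by k-means
#'
#' Gonad expression distributions are bimodal on the log scale; genes are
#' split by k-means (k = 2, 10 restarts) on `log2(RPKM + 0.1)` and the
#' threshold is reported as the back-transformed midpoint of the two cluster
#' centres.
#'
#' @param rpkm Named numeric vector of per-gene RPKM (>= 10 genes,
#'   non-constant).
#' @param seed RNG seed for the k-means restarts.
#' @return Object of class `expression_strata`: list with `labels` (named
#'   `"high"`/`"low"`), `threshold` (RPKM units), `centers` (log2 scale).
#' @export
expression_strata <- function(rpkm, seed = 1) {
  if (length(rpkm) < 10) stop("need >= 10 genes")
  lx <- log2(rpkm + 0.1)
  if (sd(lx) == 0) stop("constant expression input")
  km <- local_seed(seed, kmeans(lx, centers = 2, nstart = 10))
  centers <- sort(as.numeric(km$centers))
  threshold <- 2^mean(centers) - 0.1
  labels <- ifelse(lx > mean(centers), "high", "low")
  names(labels) <- names(rpkm)
  structure(list(labels = labels, threshold = threshold, centers = centers),
            class = "expression_strata")
}

#' Fraction of motifs with detectable 21U expression, per chromatin state
#'
#' For each chromatin state, the fraction of promoter motifs with a
#' detectable mature 21U product, with an exact binomial confidence interval.
#' Empty states are excluded.
#'
#' @param motif_states Character vector of per-motif chromatin states.
#' @param expressed Logical vector: motif has detectable 21U expression.
#' @param conf_level Confidence level for the binomial CI (default 0.95).
#' @return data.frame per state: `state`, `n`, `n_expressed`, `fraction`,
#'   `ci_lo`, `ci_hi`.
#' @export
motif_expression_fraction <- function(motif_states, expressed,
                                      conf_level = 0.95) {
  stopifnot(length(motif_states) == length(expressed))
  states <- unique(motif_states)
  out <- do.call(rbind, lapply(states, function(st) {
    idx <- motif_states == st
    n <- sum(idx)
    if (n == 0) return(NULL)
    k <- sum(expressed[idx])
    ci <- binom.test(k, n, conf.level = conf_level)$conf.int
    data.frame(state = st, n = n, n_expressed = k, fraction = k / n,
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
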