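#' Configuration for a synthetic species bundle
#'
#' Describes a synthetic nematode-like species whose genome carries planted
#' piRNA loci with the canonical geometry: an upstream promoter motif whose
#' start sits 42 nt from the 21U mapping site, a TSS 2 nt upstream of the
#' mature 21U, a GC-rich tract over window starts TSS..+19 and an AT-rich
#' low-melting "valley" over +20..+40 whose depth couples to precursor length
#' and abundance. Organisation modes: `"C"` (clustered in regulated chromatin
#' on few contigs), `"P"` (dispersed, intronic, active chromatin),
#' `"intermediate"` (half and half).
#'
#' @param n_contigs,contig_length Genome geometry (default 20 x 500 kb).
#' @param mode `"C"`, `"P"`, or `"intermediate"`.
#' @param n_pirna_loci Number of planted loci.
#' @param n_decoy_sites Number of background 21U mapping sites without a
#'   planted motif (spurious short-RNA mappings; default = `n_pirna_loci`).
#' @param motif_pwm `pwm` used both to plant and to score motifs; default is
#'   built from the GTTTC-core consensus `CTGTTTCA`.
#' @param motif_offset Distance from motif start to 21U start (default 42).
#' @param mutation_probs Probabilities of planting 0, 1, ... mutations into
#'   the motif consensus per locus.
#' @param tm_valley_depth_range Range (degC) the planted valley depths are
#'   drawn from, uniformly.
#' @param valley_shift Downstream shift (bp) of the planted valley relative
#'   to the canonical +20..+40 window (default 0).
#' @param domain_fraction_regulated Fraction of each dispersed-mode contig in
#'   regulated chromatin.
#' @param gene_density Background genes per Mb.
#' @param gc Background genome GC fraction (default 0.36, nematode-like).
#' @param seed Integer seed recorded in all outputs (required).
#' @return List of class `species_config`.
#' @export
species_config <- function(n_contigs = 20, contig_length = 5e5,
                           mode = c("C", "P", "intermediate"),
                           n_pirna_loci = 500,
                           n_decoy_sites = n_pirna_loci,
                           motif_pwm = NULL, motif_offset = 42,
                           mutation_probs = c(0.7, 0.3),
                           tm_valley_depth_range = c(3, 18),
                           valley_shift = 0,
                           domain_fraction_regulated = 0.2,
                           gene_density = 50, gc = 0.36, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("an explicit seed is required")
  if (n_pirna_loci < 0) stop("n_pirna_loci must be >= 0")
  if (motif_offset <= 0) stop("motif_offset must be positive")
  if (is.null(motif_pwm)) motif_pwm <- default_ruby_pwm()
  structure(list(n_contigs = n_contigs, contig_length = contig_length,
                 mode = mode, n_pirna_loci = n_pirna_loci,
                 n_decoy_sites = n_decoy_sites, motif_pwm = motif_pwm,
                 motif_offset = motif_offset,
                 mutation_probs = mutation_probs,
                 tm_valley_depth_range = tm_valley_depth_range,
                 valley_shift = valley_shift,
                 domain_fraction_regulated = domain_fraction_regulated,
                 gene_density = gene_density, gc = gc,
                 seed = as.integer(seed)),
            class = "species_config")
}

#' Default Ruby-like promoter motif PWM
#'
#' An 8-column PWM with the GTTTC core (consensus `CTGTTTCA`) built from a
#' strongly conserved synthetic site set, used as the planted motif when no
#' PWM is supplied.
#'
#' @param scale Score scale (default 1 = bits).
#' @return A `pwm` object.
#' @export
default_ruby_pwm <- function(scale = 1) {
  consensus <- "CTGTTTCA"
  sites <- rep(consensus, 38)
  # a few off-consensus sites so columns are informative but not degenerate
  sites <- c(sites, "CTGTTTCT", "TTGTTTCA")
  build_pwm(sites, background = rep(0.25, 4), pseudocount = 1, scale = scale)
}

# Random DNA character vector at a given GC fraction.
.random_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

# Expected background Tm (degC) of 9-nt windows of iid sequence at a given
# GC fraction: Tm of the expected nearest-neighbour sums (deterministic,
# close to the empirical window mean).
.expected_background_tm <- function(gc, window = 9, dna_conc = 50e-9,
                                    na_conc = 0.05, set = "breslauer1986") {
  tab <- .nn_tables[[set]]
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  b1 <- substr(tab$step, 1, 1); b2 <- substr(tab$step, 2, 2)
  EdH <- sum(p[b1] * p[b2] * tab$dH)
  EdS <- sum(p[b1] * p[b2] * tab$dS)
  n <- window - 1
  1000 * n * EdH / (n * EdS + 1.987 * log(dna_conc / 4)) - 273.15 +
    16.6 * log10(na_conc)
}

# Generate a random tract whose mean 9-mer Tm is close to target_tm: draws
# candidate tracts across a GC grid and keeps the closest.
.tract_with_tm <- function(len, target_tm, gc_grid, n_per_gc = 2) {
  best <- NULL; best_err <- Inf
  for (g in gc_grid) {
    for (r in seq_len(n_per_gc)) {
      x <- .random_bases(len, g)
      tm <- .tm_windows(match(x, DNA_BASES), 9, 50e-9, 0.05, "breslauer1986")
      err <- abs(mean(tm) - target_tm)
      if (err < best_err) { best <- x; best_err <- err }
    }
  }
  best
}

# Plant the V-shaped low-Tm valley over window starts +20..+40 (shifted by
# `shift`): three segments (two 10-nt shoulders, one 9-nt core) are chosen by
# two passes of in-context candidate selection minimising the squared error
# of the realised 21-window Tm profile against a tent target that bottoms at
# B0 - depth at window +30 and rises to B0 - 0.65*depth at the edges.
.plant_valley <- function(x, tss_i, shift, depth, B0) {
  lo0 <- tss_i + 20 + shift
  segs <- list(lo0:(lo0 + 9), (lo0 + 10):(lo0 + 18), (lo0 + 19):(lo0 + 28))
  wt <- 0.65 + 0.35 * (1 - abs((20:40) - 30) / 10)
  target <- B0 - depth * wt
  ctx <- lo0:(lo0 + 28)
  realized <- function(xx)
    .tm_windows(match(xx[ctx], DNA_BASES), 9, 50e-9, 0.05, "breslauer1986")
  for (s in segs) x[s] <- .random_bases(length(s), 0.1)
  for (pass in 1:2) {
    for (s in segs) {
      best <- x[s]
      best_err <- sum((realized(x) - target)^2)
      for (g in seq(0, 0.45, length.out = 8)) {
        for (r in 1:2) {
          x[s] <- .random_bases(length(s), g)
          err <- sum((realized(x) - target)^2)
          if (err < best_err) { best <- x[s]; best_err <- err }
        }
      }
      x[s] <- best
    }
  }
  x
}

# Build the planted construct 5'->3' on the transcribed strand, from motif
# start (offset 1) to the end of the valley tract. The high-Tm tract
# (window starts TSS..+19) is planted ~8 degC above the expected background;
# the valley tract (+20..+40, optionally shifted) is planted so its mean
# window Tm sits `depth` degC below background. Returns list(seq, score).
.make_construct <- function(cfg) {
  off <- cfg$motif_offset          # motif start -> 21U start distance
  w <- cfg$motif_pwm$width
  shift <- cfg$valley_shift
  len <- off + 2 + 19 + 1 + shift + 29   # through valley end (TSS+48+shift)
  x <- .random_bases(len, cfg$gc)
  # motif instance with planted mutations
  motif <- strsplit(pwm_consensus(cfg$motif_pwm), "")[[1]]
  k <- sample(seq_along(cfg$mutation_probs), 1, prob = cfg$mutation_probs) - 1L
  if (k > 0) {
    pos <- sample(w, k)
    for (p in pos) motif[p] <- sample(setdiff(DNA_BASES, motif[p]), 1)
  }
  x[seq_len(w)] <- motif
  tss_i <- off - 2 + 1             # 1-based offset of the TSS in the construct
  B0 <- .expected_background_tm(cfg$gc)
  # AT-rich low-Tm valley over window starts +20..+40 (plus optional shift):
  # the per-window Tm target is a tent, deepest at +30 and rising to 65% of
  # the depth at +20/+40, so the valley has a defined centre; segments are
  # fitted in context against the whole realised 21-window profile
  depth <- runif(1, cfg$tm_valley_depth_range[1], cfg$tm_valley_depth_range[2])
  x <- .plant_valley(x, tss_i, shift, depth, B0)
  # GC-rich high-Tm tract over window starts TSS..+19, chosen in context so
  # windows straddling the valley boundary (and the forced 5' U) are
  # accounted for
  hi <- tss_i:(tss_i + 19)
  ctx <- tss_i:min(tss_i + 19 + 8, len)   # window starts 0..19 and their tails
  best <- NULL; best_err <- Inf
  for (g in seq(0.45, 0.85, length.out = 9)) {
    for (r in 1:3) {
      cand <- .random_bases(length(hi), g)
      cand[3] <- "T"               # 5' U of the mature 21U at TSS + 2
      x[hi] <- cand
      tmv <- .tm_windows(match(x[ctx], DNA_BASES), 9, 50e-9, 0.05,
                         "breslauer1986")
      err <- abs(mean(tmv[1:20]) - (B0 + 8))
      if (err < best_err) { best <- cand; best_err <- err }
    }
  }
  x[hi] <- best
  seq_chr <- paste(x, collapse = "")
  score <- scan_window(cfg$motif_pwm, substr(seq_chr, 1, w))$score
  list(seq = seq_chr, score = score, depth = depth, tss_i = tss_i)
}

#' Generate a synthetic species bundle with planted ground truth
#'
#' Builds a random genome, chromatin domains, genes with introns, planted
#' piRNA loci obeying the canonical promoter geometry, decoy 21U sites, a
#' 1:1 ortholog table against a virtual reference genome, and a truth table
#' recording everything planted. In `"C"` mode at least 90% of loci fall in
#' regulated domains confined to two contigs; in `"P"` mode at least 80% sit
#' inside introns of genes in active domains, spread across the contigs.
#'
#' @param config A `species_config`.
#' @return Object of class `species_bundle`: list with `genome`
#'   (`DNAStringSet`), `domains` (`GRanges`, `state` mcol), `genes`, `exons`
#'   (`GRanges` with `gene_id`/`exon_rank`), `sites_21u` (`GRanges`,
#'   `site_id` + `truth` mcols), `truth` (data.frame), `orthologs`
#'   (data.frame `gene_id`, `ref_gene_id`), `ref_genes` (`GRanges`),
#'   `config`.
#' @export
generate_species <- function(config) {
  stopifnot(inherits(config, "species_config"))
  local_seed(config$seed, .generate_species_impl(config))
}

.generate_species_impl <- function(cfg) {
  n_ctg <- cfg$n_contigs; L <- cfg$contig_length
  contigs <- sprintf("ctg%02d", seq_len(n_ctg))
  seqs <- lapply(contigs, function(ct) .random_bases(L, cfg$gc))
  names(seqs) <- contigs

  margin <- 300L                  # keep constructs and scan windows on-contig
  slot <- 450L                    # per-locus footprint incl. spacing

  # --- chromatin domains -----------------------------------------------------
  cluster_contigs <- contigs[seq_len(min(2L, n_ctg))]
  edge <- round(0.05 * L)
  dom <- list()
  for (ct in contigs) {
    if (cfg$mode == "C" || (cfg$mode == "intermediate" && ct %in% cluster_contigs)) {
      if (ct %in% cluster_contigs) {
        dom[[length(dom) + 1]] <- data.frame(
          contig = ct, start = c(1, edge + 1, L - edge + 1),
          end = c(edge, L - edge, L),
          state = c("active", "regulated", "active"))
      } else {
        dom[[length(dom) + 1]] <- data.frame(
          contig = ct, start = 1, end = L, state = "active")
      }
    } else {
      reg_end <- round(cfg$domain_fraction_regulated * L)
      dom[[length(dom) + 1]] <- data.frame(
        contig = ct, start = c(1, reg_end + 1), end = c(reg_end, L),
        state = c("regulated", "active"))
    }
  }
  dom <- do.call(rbind, dom)
  domains <- GRanges(dom$contig, IRanges(dom$start, dom$end))
  mcols(domains)$state <- dom$state

  # --- locus placement -------------------------------------------------------
  n <- cfg$n_pirna_loci
  mode_of <- character(0)
  if (n > 0) {
    if (cfg$mode == "C") {
      n_in <- ceiling(0.95 * n)
      mode_of <- c(rep("C", n_in), rep("bg", n - n_in))
    } else if (cfg$mode == "P") {
      n_intronic <- ceiling(0.9 * n)
      mode_of <- c(rep("P", n_intronic), rep("bg", n - n_intronic))
    } else {
      n_half <- ceiling(n / 2)
      mode_of <- c(rep("C", n_half), rep("P", n - n_half))
    }
  }
  # slots: C loci go into regulated blocks of cluster contigs; P and bg loci
  # into active space of all contigs (round-robin for spread)
  reg_span <- L - 2 * edge - 2 * margin
  slots_per_cluster <- floor(reg_span / slot)
  n_C <- sum(mode_of == "C")
  if (n_C > slots_per_cluster * length(cluster_contigs))
    stop("infeasible packing: too many clustered loci for the cluster span")
  placements <- vector("list", n)
  c_idx <- which(mode_of == "C")
  if (length(c_idx)) {
    ctg_assign <- rep(cluster_contigs, length.out = length(c_idx))
    slot_no <- stats::ave(seq_along(ctg_assign), ctg_assign, FUN = seq_along)
    for (j in seq_along(c_idx)) {
      base <- edge + margin + (slot_no[j] - 1L) * slot
      placements[[c_idx[j]]] <- list(
        contig = ctg_assign[j],
        u = base + sample.int(100L, 1) + 175L,
        host = FALSE)
    }
  }
  p_idx <- which(mode_of %in% c("P", "bg"))
  if (length(p_idx)) {
    disp_contigs <- if (cfg$mode == "C") setdiff(contigs, cluster_contigs) else contigs
    ctg_assign <- rep(disp_contigs, length.out = length(p_idx))
    per_ctg <- table(factor(ctg_assign, disp_contigs))
    # active space of a dispersed contig starts after the regulated block
    act_lo <- if (cfg$mode == "C") margin else
      round(cfg$domain_fraction_regulated * L) + margin
    slots_active <- floor((L - act_lo - margin) / slot)
    if (max(per_ctg) > slots_active)
      stop("infeasible packing: too many dispersed loci per contig")
    slot_no <- stats::ave(seq_along(ctg_assign), ctg_assign, FUN = seq_along)
    for (j in seq_along(p_idx)) {
      base <- act_lo + (slot_no[j] - 1L) * slot
      placements[[p_idx[j]]] <- list(
        contig = ctg_assign[j],
        u = base + sample.int(100L, 1) + 175L,
        host = mode_of[p_idx[j]] == "P")
    }
  }

  # --- plant constructs & build truth ---------------------------------------
  off <- cfg$motif_offset
  truth <- vector("list", n)
  genes <- list(); exons <- list()
  gene_no <- 0L
  state_at <- function(ct, pos) {
    hit <- dom$contig == ct & dom$start <= pos & dom$end >= pos
    if (any(hit)) dom$state[which(hit)[1]] else "other"
  }
  for (i in seq_len(n)) {
    pl <- placements[[i]]
    ct <- pl$contig
    strand_i <- sample(c("+", "-"), 1)
    cons <- .make_construct(cfg)
    clen <- nchar(cons$seq)
    if (strand_i == "+") {
      u <- pl$u
      a <- u - off; b <- a + clen - 1L
      seqs[[ct]][a:b] <- strsplit(cons$seq, "")[[1]]
      site_start <- u; site_end <- u + 20L; tss <- u - 2L
    } else {
      u <- pl$u
      a <- u + off - clen + 1L; b <- u + off
      seqs[[ct]][a:b] <- strsplit(.revcomp_chr(cons$seq), "")[[1]]
      site_start <- u - 20L; site_end <- u; tss <- u + 2L
    }
    intronic <- FALSE; gene_id <- NA_character_
    if (isTRUE(pl$host)) {
      gene_no <- gene_no + 1L
      gene_id <- sprintf("g%05d", gene_no)
      g1 <- max(1L, u - 400L); g2 <- min(L, u + 400L)
      genes[[length(genes) + 1]] <- data.frame(
        contig = ct, start = g1, end = g2, strand = strand_i,
        gene_id = gene_id)
      ex1 <- if (strand_i == "+") c(g1, g1 + 99L) else c(g2 - 99L, g2)
      ex2 <- if (strand_i == "+") c(g2 - 99L, g2) else c(g1, g1 + 99L)
      exons[[length(exons) + 1]] <- data.frame(
        contig = ct, start = c(ex1[1], ex2[1]), end = c(ex1[2], ex2[2]),
        strand = strand_i, gene_id = gene_id, exon_rank = c(1L, 2L))
      intronic <- TRUE
    }
    truth[[i]] <- data.frame(
      locus_id = sprintf("L%05d", i), contig = ct,
      site_start = site_start, site_end = site_end, strand = strand_i,
      u21_start = u, tss = tss, motif_score = cons$score,
      chromatin_state = state_at(ct, tss), intronic = intronic,
      gene_id = gene_id, valley_depth = cons$depth,
      mode = cfg$mode, stringsAsFactors = FALSE)
  }
  truth <- if (n > 0) do.call(rbind, truth) else
    data.frame(locus_id = character(0), contig = character(0),
               site_start = integer(0), site_end = integer(0),
               strand = character(0), u21_start = integer(0),
               tss = integer(0), motif_score = numeric(0),
               chromatin_state = character(0), intronic = logical(0),
               gene_id = character(0), valley_depth = numeric(0),
               mode = character(0), stringsAsFactors = FALSE)

  # --- background genes in active space -------------------------------------
  n_bg_genes <- round(cfg$gene_density * n_ctg * L / 1e6)
  planted_u <- if (n > 0) split(truth$u21_start, truth$contig) else list()
  for (k in seq_len(n_bg_genes)) {
    ct <- sample(contigs, 1)
    act <- dom[dom$contig == ct & dom$state == "active", , drop = FALSE]
    if (!nrow(act)) next
    row <- act[sample.int(nrow(act), 1), ]
    if (row$end - row$start < 2000) next
    g1 <- sample(seq(row$start + 100, row$end - 1000), 1)
    g2 <- g1 + 799L
    near <- planted_u[[ct]]
    if (!is.null(near) && any(abs(near - g1) < 1200)) next  # keep C loci intergenic
    gene_no <- gene_no + 1L
    gid <- sprintf("g%05d", gene_no)
    strand_g <- sample(c("+", "-"), 1)
    genes[[length(genes) + 1]] <- data.frame(
      contig = ct, start = g1, end = g2, strand = strand_g, gene_id = gid)
    ex1 <- if (strand_g == "+") c(g1, g1 + 99L) else c(g2 - 99L, g2)
    ex2 <- if (strand_g == "+") c(g2 - 99L, g2) else c(g1, g1 + 99L)
    exons[[length(exons) + 1]] <- data.frame(
      contig = ct, start = c(ex1[1], ex2[1]), end = c(ex1[2], ex2[2]),
      strand = strand_g, gene_id = gid, exon_rank = c(1L, 2L))
  }
  genes_df <- if (length(genes)) do.call(rbind, genes) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), gene_id = character(0))
  exons_df <- if (length(exons)) do.call(rbind, exons) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), gene_id = character(0),
               exon_rank = integer(0))

  # --- decoy 21U sites -------------------------------------------------------
  n_decoy <- cfg$n_decoy_sites
  decoys <- list()
  tries <- 0L
  while (length(decoys) < n_decoy && tries < 50L * max(1L, n_decoy)) {
    tries <- tries + 1L
    ct <- sample(contigs, 1)
    pos <- sample(seq(margin, L - margin), 1)
    near <- planted_u[[ct]]
    if (!is.null(near) && any(abs(near - pos) < 250)) next
    decoys[[length(decoys) + 1]] <- data.frame(
      contig = ct, pos = pos, strand = sample(c("+", "-"), 1))
  }
  decoys_df <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(contig = character(0), pos = integer(0), strand = character(0))

  genome <- DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- contigs

  site_df <- rbind(
    if (n > 0) data.frame(contig = truth$contig, start = truth$site_start,
                          end = truth$site_end, strand = truth$strand,
                          site_id = truth$locus_id, truth = TRUE) else NULL,
    if (nrow(decoys_df)) data.frame(
      contig = decoys_df$contig,
      start = ifelse(decoys_df$strand == "+", decoys_df$pos,
                     decoys_df$pos - 20L),
      end = ifelse(decoys_df$strand == "+", decoys_df$pos + 20L,
                   decoys_df$pos),
      strand = decoys_df$strand,
      site_id = sprintf("D%05d", seq_len(nrow(decoys_df))),
      truth = FALSE) else NULL)
  sites_21u <- if (!is.null(site_df) && nrow(site_df))
    GRanges(site_df$contig, IRanges(site_df$start, site_df$end),
            strand = site_df$strand,
            site_id = site_df$site_id, truth = site_df$truth)
  else GRanges()

  genes_gr <- GRanges(genes_df$contig,
                      IRanges(genes_df$start, genes_df$end),
                      strand = genes_df$strand, gene_id = genes_df$gene_id)
  exons_gr <- GRanges(exons_df$contig,
                      IRanges(exons_df$start, exons_df$end),
                      strand = exons_df$strand, gene_id = exons_df$gene_id,
                      exon_rank = exons_df$exon_rank)

  # --- 1:1 orthologs against a virtual reference ----------------------------
  ref_chroms <- paste0("chr", c("I", "II", "III", "IV", "V", "X"))
  orthologs <- NULL; ref_genes <- GRanges()
  if (nrow(genes_df)) {
    src_ctg <- genes_df$contig
    ref_chr <- ref_chroms[(match(src_ctg, contigs) - 1L) %% length(ref_chroms) + 1L]
    ref_ids <- sprintf("ref_%s", genes_df$gene_id)
    # genes from the same source contig cluster in a contiguous reference block
    block <- (match(src_ctg, contigs) - 1L) %/% length(ref_chroms)
    within <- stats::ave(seq_len(nrow(genes_df)),
                         paste(ref_chr, block), FUN = seq_along)
    ref_pos <- block * 2e6 + within * 2000
    orthologs <- data.frame(gene_id = genes_df$gene_id,
                            ref_gene_id = ref_ids,
                            stringsAsFactors = FALSE)
    ref_genes <- GRanges(ref_chr, IRanges(ref_pos, width = 1000),
                         gene_id = ref_ids)
  } else {
    orthologs <- data.frame(gene_id = character(0),
                            ref_gene_id = character(0))
  }

  structure(list(genome = genome, domains = domains, genes = genes_gr,
                 exons = exons_gr, sites_21u = sites_21u, truth = truth,
                 orthologs = orthologs, ref_genes = ref_genes,
                 config = cfg),
            class = "species_bundle")
}

#' @export
print.species_bundle <- function(x, ...) {
  cat(sprintf("synthetic species bundle: mode %s, %d contigs x %g bp, %d planted loci, %d decoy sites (seed %d)\n",
              x$config$mode, x$config$n_contigs, x$config$contig_length,
              nrow(x$truth), sum(!mcols(x$sites_21u)$truth),
              x$config$seed))
  invisible(x)
}

#' Simulate small-RNA libraries for a species bundle
#'
#' Generates per-library read tables: mature 21U reads (21 nt, 5' U, starting
#' 2 nt downstream of the TSS), capped precursor reads starting exactly at
#' the TSS whose mean length and abundance depend monotonically on the
#' planted valley depth (deep valley = strong pausing = shorter, more
#' abundant precursors; length = 28 + Geometric, truncated at 100 nt), miRNA
#' normaliser counts around fixed per-gene means times a library scale
#' factor, and rRNA degradation fragments with a genotype-independent length
#' distribution.
#'
#' @param bundle A `species_bundle`.
#' @param scale_factors Numeric vector of per-library scale factors (one
#'   library per element).
#' @param mean_21u Mean 21U read count per planted locus at scale 1.
#' @param n_mirna Number of miRNA normaliser genes.
#' @param n_rrna_reads rRNA fragment count per library at scale 1.
#' @param seed RNG seed.
#' @return List of class `rna_libraries`: one element per library, each with
#'   `u21` (`GRanges`), `capped` (`GRanges`), `precursors` (`precursor_set`),
#'   `mirna` (named counts), `rrna` (data.frame `length`, `count`);
#'   plus attributes `mirna_means`, `scale_factors`.
#' @export
simulate_small_rna_libraries <- function(bundle, scale_factors = c(1, 1),
                                         mean_21u = 60, n_mirna = 50,
                                         n_rrna_reads = 3000, seed = 1) {
  stopifnot(inherits(bundle, "species_bundle"))
  truth <- bundle$truth
  dr <- bundle$config$tm_valley_depth_range
  depth_norm <- if (nrow(truth))
    (truth$valley_depth - dr[1]) / max(dr[2] - dr[1], 1e-9) else numeric(0)
  local_seed(seed, {
    mirna_means <- rlnorm(n_mirna, meanlog = 4, sdlog = 1)
    names(mirna_means) <- sprintf("mir%03d", seq_len(n_mirna))
    rrna_lengths <- 18:70
    rrna_probs <- exp(-(rrna_lengths - 18) / 12)
    libs <- lapply(seq_along(scale_factors), function(j) {
      sf <- scale_factors[j]
      # mature 21U reads at planted loci and (weakly) at decoy sites
      u21_counts_t <- rpois(nrow(truth), mean_21u * (0.5 + depth_norm) * sf)
      sites <- bundle$sites_21u
      decoy <- sites[!mcols(sites)$truth]
      u21_counts_d <- rpois(length(decoy), 2 * sf)
      u21_t <- if (nrow(truth))
        GRanges(truth$contig, IRanges(truth$site_start, truth$site_end),
                strand = truth$strand, length = rep(21L, nrow(truth)),
                count = u21_counts_t,
                chemistry = rep("monophosphate", nrow(truth)),
                unique = rep(TRUE, nrow(truth)),
                site_id = truth$locus_id)
      else GRanges()
      u21_d <- if (length(decoy))
        GRanges(seqnames(decoy), IRanges(start(decoy), end(decoy)),
                strand = strand(decoy), length = rep(21L, length(decoy)),
                count = u21_counts_d,
                chemistry = rep("monophosphate", length(decoy)),
                unique = rep(TRUE, length(decoy)),
                site_id = mcols(decoy)$site_id)
      else GRanges()
      u21 <- c(u21_t, u21_d)
      # capped precursors: 5' end exactly at the TSS
      prec <- NULL
      if (nrow(truth)) {
        n_reads <- rpois(nrow(truth), (2 + 10 * depth_norm) * sf)
        p_geom <- 0.08 + 0.5 * depth_norm
        rows <- lapply(which(n_reads > 0), function(i) {
          lens <- pmin(28L + rgeom(n_reads[i], p_geom[i]), 100L)
          tab <- table(lens)
          data.frame(locus_id = truth$locus_id[i],
                     contig = truth$contig[i], strand = truth$strand[i],
                     tss = truth$tss[i],
                     length = as.integer(names(tab)),
                     count = as.integer(tab), stringsAsFactors = FALSE)
        })
        prec <- if (length(rows)) do.call(rbind, rows) else NULL
      }
      if (is.null(prec))
        prec <- data.frame(locus_id = character(0), contig = character(0),
                           strand = character(0), tss = integer(0),
                           length = integer(0), count = integer(0))
      capped <- GRanges(prec$contig,
                        IRanges(start = ifelse(prec$strand == "+", prec$tss,
                                               prec$tss - prec$length + 1L),
                                width = prec$length),
                        strand = prec$strand, length = prec$length,
                        count = prec$count, chemistry = "capped",
                        unique = TRUE, locus_id = prec$locus_id)
      precursors <- prec[, c("locus_id", "length", "count")]
      class(precursors) <- c("precursor_set", "data.frame")
      mirna <- rpois(n_mirna, mirna_means * sf)
      names(mirna) <- names(mirna_means)
      n_rr <- rpois(1, n_rrna_reads * sf)
      rr <- table(sample(rrna_lengths, n_rr, replace = TRUE,
                         prob = rrna_probs))
      rrna <- data.frame(length = as.integer(names(rr)),
                         count = as.integer(rr))
      list(u21 = u21, capped = capped, precursors = precursors,
           mirna = mirna, rrna = rrna)
    })
    names(libs) <- sprintf("lib%d", seq_along(libs))
    attr(libs, "mirna_means") <- mirna_means
    attr(libs, "scale_factors") <- scale_factors
    class(libs) <- "rna_libraries"
    libs
  })
}

#' Simulate a multi-strain SNP panel for a species bundle
#'
#' Places SNPs genome-wide at `snp_rate` per bp with allele frequencies from
#' per-SNP Beta(0.3, 0.3)-distributed population frequencies sampled over
#' `n_strains` strains (a U-shaped spectrum with substantial fractions of
#' near-fixed major and rare minor alleles). Inside planted motifs, one SNP
#' is placed per motif with probability `p_motif_snp`; alleles that lower the
#' motif score at loci in the constrained stratum (regulated chromatin) have
#' their frequencies redrawn from a low-frequency Beta(0.5, 8) with
#' probability `motif_disruption_bias`, emulating purifying selection on
#' functional promoter motifs.
#'
#' @param bundle A `species_bundle`.
#' @param n_strains Number of strains (>= 2).
#' @param snp_rate Genome-wide SNP rate per bp.
#' @param motif_disruption_bias Probability in `[0, 1]` that a disruptive
#'   motif allele in the constrained stratum is forced to low frequency.
#' @param p_motif_snp Probability each planted motif carries a SNP.
#' @param seed RNG seed.
#' @return data.frame with `contig`, `pos`, `ref`, `alt`, `freq` (fraction of
#'   strains with the alternate allele), `in_motif`, `locus_id` (NA for
#'   background SNPs); `n_strains` in `attr`.
#' @export
simulate_strain_panel <- function(bundle, n_strains = 20, snp_rate = 2e-5,
                                  motif_disruption_bias = 0,
                                  p_motif_snp = 0.8, seed = 1) {
  stopifnot(inherits(bundle, "species_bundle"))
  if (n_strains < 2) stop("need >= 2 strains")
  lens <- genome_lengths(bundle$genome)
  truth <- bundle$truth
  pwm <- bundle$config$motif_pwm
  off <- bundle$config$motif_offset
  w <- pwm$width
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  base_at <- function(ct, pos)
    as.character(subseq(bundle$genome[[ct]], pos, pos))
  local_seed(seed, {
    draw_freq <- function(low) {
      # low: logical vector; TRUE draws from the low-frequency spectrum
      theta <- ifelse(low, rbeta(length(low), 0.5, 8),
                      rbeta(length(low), 0.3, 0.3))
      rbinom(length(low), n_strains, theta) / n_strains
    }
    alt_of <- function(ref) {
      vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), character(1))
    }
    bg <- NULL
    n_bg <- rbinom(1, sum(lens), snp_rate)
    if (n_bg > 0) {
      ct <- sample(names(lens), n_bg, replace = TRUE,
                   prob = lens / sum(as.numeric(lens)))
      pos <- floor(runif(n_bg, 1, lens[ct] + 1))
      ref <- vapply(seq_len(n_bg), function(i) base_at(ct[i], pos[i]),
                    character(1))
      ok <- ref %in% DNA_BASES
      bg <- data.frame(contig = ct[ok], pos = pos[ok], ref = ref[ok],
                       alt = alt_of(ref[ok]),
                       freq = draw_freq(rep(FALSE, sum(ok))),
                       in_motif = FALSE, locus_id = NA_character_,
                       stringsAsFactors = FALSE)
    }
    mo <- NULL
    if (nrow(truth)) {
      pick <- runif(nrow(truth)) <= p_motif_snp
      tr <- truth[pick, , drop = FALSE]
      if (nrow(tr)) {
        j <- sample.int(w, nrow(tr), replace = TRUE)
        pos <- ifelse(tr$strand == "+", tr$u21_start - off + j - 1L,
                      tr$u21_start + off - j + 1L)
        ref <- vapply(seq_len(nrow(tr)),
                      function(i) base_at(tr$contig[i], pos[i]), character(1))
        ok <- ref %in% DNA_BASES
        tr <- tr[ok, , drop = FALSE]; j <- j[ok]; pos <- pos[ok]
        ref <- ref[ok]
        alt <- alt_of(ref)
        ref_m <- ifelse(tr$strand == "+", ref, comp[ref])
        alt_m <- ifelse(tr$strand == "+", alt, comp[alt])
        disruptive <- pwm$mat[cbind(match(alt_m, DNA_BASES), j)] <
          pwm$mat[cbind(match(ref_m, DNA_BASES), j)]
        constrained <- tr$chromatin_state == "regulated"
        low <- disruptive & constrained &
          runif(nrow(tr)) < motif_disruption_bias
        mo <- data.frame(contig = tr$contig, pos = pos, ref = ref,
                         alt = alt, freq = draw_freq(low), in_motif = TRUE,
                         locus_id = tr$locus_id, stringsAsFactors = FALSE)
      }
    }
    out <- rbind(bg, mo)
    if (is.null(out))
      out <- data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        freq = numeric(0), in_motif = logical(0),
                        locus_id = character(0))
    rownames(out) <- NULL
    attr(out, "n_strains") <- n_strains
    out
  })
}

#' Write a species bundle to standard file formats
#'
#' Emits genome FASTA, domain BED (state in the name column), gene/exon GFF3,
#' 21U site TSV, truth-table TSV, ortholog TSV, and the configuration as JSON
#' (seed included).
#'
#' @param bundle A `species_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_species_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  dom <- bundle$domains
  names(dom) <- mcols(dom)$state
  write_intervals_bed(dom, file.path(dir, "domains.bed"))
  gff <- c(bundle$genes, bundle$exons)
  mcols(gff)$type <- c(rep("gene", length(bundle$genes)),
                       rep("exon", length(bundle$exons)))
  rtracklayer::export(gff, file.path(dir, "genes.gff3"), format = "gff3")
  sites <- bundle$sites_21u
  mcols(sites)$length <- width(sites)
  mcols(sites)$count <- 1L
  mcols(sites)$chemistry <- "monophosphate"
  mcols(sites)$unique <- TRUE
  write_sites_tsv(sites, file.path(dir, "sites_21u.tsv"))
  write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$orthologs, file.path(dir, "orthologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  cfg$motif_pwm <- list(consensus = pwm_consensus(cfg$motif_pwm),
                        width = cfg$motif_pwm$width)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
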