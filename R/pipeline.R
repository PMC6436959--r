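#' Run the full analysis pipeline on a synthetic or loaded species
#'
#' Orchestrates the analysis stages in dependency order: motif scan and
#' threshold fit, piRNA locus calling, clustering statistics, chromatin
#' context, optional SNP selection analysis, and pausing-signal scoring.
#' Every stage writes a TSV into the run directory; a machine-readable JSON
#' summary (with the seed, parameters, and headline numbers) is written at
#' the end. Rerunning with the same configuration and seed reproduces the
#' outputs.
#'
#' @param config List with elements:
#'   * `bundle` — a `species_bundle` (from [generate_species()]), or
#'     `species` — a `species_config` to generate one;
#'   * `seed` — global seed (required);
#'   * optional `snps` — SNP panel data.frame for the selection stage;
#'   * optional `scan` — list(up, down), `call` — list(offset_center,
#'     offset_tol), `selection` — list(score_floor, disruption_delta).
#' @param outdir Output directory for the run.
#' @return Invisibly, a list with the per-stage results and `summary`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.null(config$seed)) stop("config$seed is required")
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    stop("config$seed must be an integer")
  if (is.null(config$bundle) && is.null(config$species))
    stop("config must provide 'bundle' or 'species'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bundle <- if (!is.null(config$bundle)) config$bundle
            else generate_species(config$species)
  pwm <- bundle$config$motif_pwm
  scan_par <- utils::modifyList(list(up = 110, down = 30),
                                config$scan %||% list())
  call_par <- utils::modifyList(list(offset_center = 42, offset_tol = 5),
                                config$call %||% list())

  # --- annotation ------------------------------------------------------------
  hits <- scan_upstream_windows(bundle$genome, bundle$sites_21u, pwm,
                                up = scan_par$up, down = scan_par$down)
  fit <- fit_score_threshold(hits$score)
  loci <- call_pirna_loci(bundle$sites_21u, hits, fit$threshold,
                          offset_center = call_par$offset_center,
                          offset_tol = call_par$offset_tol)
  loci_df <- data.frame(contig = as.character(seqnames(loci)),
                        start = start(loci) - 1L, end = end(loci),
                        strand = as.character(strand(loci)),
                        locus_id = mcols(loci)$locus_id,
                        site_id = mcols(loci)$site_id,
                        tss = mcols(loci)$tss,
                        motif_score = mcols(loci)$motif_score,
                        motif_distance = mcols(loci)$motif_distance)
  write.table(loci_df, file.path(outdir, "loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- clustering ------------------------------------------------------------
  enr <- contig_enrichment(loci, bundle$genome)
  sc <- span_curve(enr)
  write.table(enr, file.path(outdir, "contig_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sc$curve, file.path(outdir, "span_curve.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- chromatin context -----------------------------------------------------
  universe <- GRanges(names(bundle$genome),
                      IRanges(1, width(bundle$genome)))
  dom_enr <- domain_overlap_enrichment(loci, bundle$domains, universe)
  gen <- genicness_score(loci, bundle$genes, bundle$genome,
                         n_sim = 100, scope = "genome", seed = config$seed)
  write.table(dom_enr, file.path(outdir, "domain_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- selection (optional) --------------------------------------------------
  selection <- NULL
  if (!is.null(config$snps)) {
    sel_par <- utils::modifyList(
      list(score_floor = 0, disruption_delta = 1),
      config$selection %||% list())
    motifs <- upstream_window(bundle$sites_21u, up = scan_par$up,
                              down = scan_par$down, genome = bundle$genome)
    mcols(motifs)$motif_id <- mcols(bundle$sites_21u)$site_id
    mcols(motifs)$score <- hits$score[match(mcols(motifs)$motif_id,
                                            hits$site_id)]
    effects <- motif_variant_effects(motifs, config$snps, pwm,
                                     bundle$genome,
                                     score_floor = sel_par$score_floor,
                                     disruption_delta = sel_par$disruption_delta)
    strata <- setNames(ifelse(bundle$truth$chromatin_state == "regulated",
                              "cluster", "outside"),
                       bundle$truth$locus_id)
    selection <- stratified_major_fraction(effects, strata)
    write.table(effects, file.path(outdir, "variant_effects.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(selection$fractions))
      write.table(selection$fractions,
                  file.path(outdir, "selection_fractions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- pausing ---------------------------------------------------------------
  tm_mat <- tm_profile_matrix(bundle$genome, loci)
  S <- pausing_strengths(tm_mat)
  mean_profile <- colMeans(tm_mat, na.rm = TRUE)
  names(mean_profile) <- colnames(tm_mat)
  vc <- valley_center(mean_profile)
  pausing_df <- data.frame(locus_id = rownames(tm_mat), S = unname(S))
  write.table(pausing_df, file.path(outdir, "pausing_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = config$seed,
    n_sites = length(bundle$sites_21u),
    threshold = fit$threshold,
    n_loci = length(loci),
    span90 = sc$span90,
    genome_size = sc$genome_size,
    genicness = gen$score,
    valley_center = vc$center,
    mean_pausing_strength = mean(S, na.rm = TRUE),
    selection_run = !is.null(selection),
    stages = c("annotate", "cluster", "chromatin",
               if (!is.null(selection)) "selection", "pausing"))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(bundle = bundle, hits = hits, threshold_fit = fit,
                 loci = loci, enrichment = enr, span = sc,
                 domain_enrichment = dom_enr, genicness = gen,
                 selection = selection, pausing = pausing_df,
                 valley = vc, summary = summary, outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export figure-panel-style summary tables from a run directory
#'
#' Reads the per-stage TSVs written by [run_pipeline()] and emits compact
#' panel tables: per-species clustering points (locus count vs span-90),
#' chromatin-state locus proportions, selection major-allele fractions, and
#' pausing-strength strata summaries. Panels whose stage did not run are
#' skipped.
#'
#' @param run_dirs Character vector of run directories (one per species).
#' @param outdir Directory for the panel TSVs (default: first run dir).
#' @return Invisibly, a named list of the panel data.frames written.
#' @export
make_report <- function(run_dirs, outdir = run_dirs[1]) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  panels <- list()
  summaries <- lapply(run_dirs, function(d) {
    f <- file.path(d, "summary.json")
    if (file.exists(f)) jsonlite::read_json(f) else NULL
  })
  ok <- !vapply(summaries, is.null, logical(1))
  if (any(ok)) {
    panels$clustering_points <- do.call(rbind, lapply(which(ok), function(i) {
      s <- summaries[[i]]
      data.frame(run = run_dirs[i], n_pirnas = s$n_loci, span90 = s$span90,
                 genome_size = s$genome_size, genicness = s$genicness)
    }))
    write.table(panels$clustering_points,
                file.path(outdir, "panel_clustering_points.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (i in seq_along(run_dirs)) {
    f <- file.path(run_dirs[i], "domain_enrichment.tsv")
    if (file.exists(f)) {
      d <- read.delim(f)
      d$run <- run_dirs[i]
      panels$chromatin <- rbind(panels$chromatin, d)
    }
    f <- file.path(run_dirs[i], "selection_fractions.tsv")
    if (file.exists(f)) {
      d <- read.delim(f)
      d$run <- run_dirs[i]
      panels$selection <- rbind(panels$selection, d)
    }
    f <- file.path(run_dirs[i], "pausing_scores.tsv")
    if (file.exists(f)) {
      d <- read.delim(f)
      qs <- quantile(d$S, c(0.1, 0.5, 0.9), na.rm = TRUE)
      panels$pausing <- rbind(panels$pausing,
                              data.frame(run = run_dirs[i], n = nrow(d),
                                         S_q10 = qs[1], S_median = qs[2],
                                         S_q90 = qs[3]))
    }
  }
  if (!is.null(panels$chromatin))
    write.table(panels$chromatin, file.path(outdir, "panel_chromatin.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(panels$selection))
    write.table(panels$selection, file.path(outdir, "panel_selection.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(panels$pausing))
    write.table(panels$pausing, file.path(outdir, "panel_pausing.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(panels)
}
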