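test_that("domain enrichment compares locus counts to span expectation", {
  universe <- GRanges("c1", IRanges(1, 1000))
  loci <- GRanges("c1", IRanges(seq(10, 910, by = 100), width = 21),
                  strand = "+", tss = seq(10, 910, by = 100))
  # one state covering the whole universe: fold 1
  all_dom <- GRanges("c1", IRanges(1, 1000), state = "active")
  r <- domain_overlap_enrichment(loci, all_dom, universe)
  expect_equal(r$fold, 1, tolerance = 1e-12)
  # toy case: state spanning 300/1000 bp with 9 of 10 loci inside
  dom <- GRanges("c1", IRanges(c(1, 301), c(300, 1000)),
                 state = c("reg", "act"))
  loci2 <- GRanges("c1", IRanges(c(seq(5, 285, length.out = 9), 500),
                                 width = 21), strand = "+",
                   tss = as.integer(c(seq(5, 285, length.out = 9), 500)))
  r2 <- domain_overlap_enrichment(loci2, dom, universe)
  reg <- r2[r2$state == "reg", ]
  expect_identical(reg$observed, 9L)
  expect_equal(reg$expected, 10 * 300 / 1000, tolerance = 1e-12)
  expect_equal(reg$fold, 9 / 3, tolerance = 1e-12)
  expect_equal(reg$p_value,
               oracle_fisher_2x2(matrix(c(9, 1, 300, 700), 2, 2,
                                        byrow = TRUE)),
               tolerance = 1e-12)
  # zero observed: guarded depletion bound, flagged
  none <- GRanges("c1", IRanges(500, 520), strand = "+", tss = 500L)
  r3 <- domain_overlap_enrichment(none, dom, universe)
  reg3 <- r3[r3$state == "reg", ]
  expect_true(reg3$guarded)
  expect_true(is.finite(reg3$depletion))
})

test_that("locus counts across states account for every locus", {
  b <- fixture_bundle_C200()
  universe <- GRanges(names(b$genome), IRanges(1, width(b$genome)))
  r <- domain_overlap_enrichment(truth_loci(b), b$domains, universe)
  expect_identical(sum(r$observed) + attr(r, "n_unassigned"),
                   attr(r, "n_loci"))
})

test_that("gene state assignment uses the 75% coverage rule", {
  genes <- GRanges("c1", IRanges(c(100, 300, 500), c(199, 399, 599)),
                   gene_id = c("g_full", "g_split", "g_80"))
  dom <- GRanges("c1", IRanges(c(50, 300, 500), c(250, 349, 579)),
                 state = c("active", "active", "regulated"))
  dom <- c(dom, GRanges("c1", IRanges(350, 399), state = "regulated"))
  st <- assign_gene_state(genes, dom)
  expect_identical(st$state[st$gene_id == "g_full"], "active")
  expect_identical(st$state[st$gene_id == "g_split"], "unassigned")
  expect_identical(st$state[st$gene_id == "g_80"], "regulated")
  # fragmentation invariance: splitting a domain changes nothing
  frag <- c(GRanges("c1", IRanges(c(50, 151), c(150, 250)),
                    state = c("active", "active")),
            dom[2:4])
  st2 <- assign_gene_state(genes, frag)
  expect_identical(st$state, st2$state)
})

test_that("orthology transfers chromatin states with measurable concordance", {
  ids <- paste0("g", 1:40)
  orth <- data.frame(gene_id = ids, ref_gene_id = paste0("r", 1:40))
  ref_states <- data.frame(gene_id = paste0("r", 1:40),
                           state = rep(c("active", "regulated"), 20))
  direct <- data.frame(gene_id = ids,
                       state = rep(c("active", "regulated"), 20))
  pred <- predict_states_by_orthology(ids, orth, ref_states, direct)
  expect_identical(pred$concordance_rate, 1)
  # shuffled orthologs: concordance near the marginal expectation (0.5)
  set.seed(12)
  shuf <- orth; shuf$ref_gene_id <- sample(shuf$ref_gene_id)
  ps <- predict_states_by_orthology(ids, shuf, ref_states, direct)
  expect_lt(abs(ps$concordance_rate - 0.5), 0.25)
  # no usable orthologs: flagged undefined OR downstream
  or_none <- gene_pirna_chromatin_or(
    data.frame(gene_id = ids, state = "unassigned"), ids[1:3])
  expect_true(or_none$undefined)
})

test_that("piRNA-gene chromatin odds ratios follow the 2x2 definition", {
  gs <- data.frame(gene_id = paste0("g", 1:40),
                   state = rep(c("active", "regulated"), each = 20))
  with_p <- c(paste0("g", 1:2), paste0("g", 21:30))  # 2 active, 10 regulated
  r <- gene_pirna_chromatin_or(gs, with_p)
  expect_equal(r$odds_ratio, (2 * 10) / (18 * 10), tolerance = 1e-12)
  expect_equal(r$log2_or, log2((2 * 10) / (18 * 10)), tolerance = 1e-12)
  expect_equal(r$p_value,
               oracle_fisher_2x2(matrix(c(2, 10, 18, 10), 2, 2)),
               tolerance = 1e-12)
})

test_that("genicness scores separate dispersed from clustered organisation", {
  bP <- fixture_bundle_P200()
  gP <- genicness_score(truth_loci(bP), bP$genes, bP$genome, seed = 5)
  expect_gt(gP$score, 0)
  expect_lte(gP$p_value, 2 / 101)
  bC <- fixture_bundle_C200()
  gC <- genicness_score(truth_loci(bC), bC$genes, bC$genome, seed = 5)
  expect_lte(gC$score, 0)
  # all-genic loci at genic fraction ~0.5 reach the minimal attainable p
  lens <- c(c1 = 1e5)
  genes <- GRanges("c1", IRanges(1, 5e4))
  inloci <- GRanges("c1", IRanges(sample.int(49e3, 200), width = 21))
  gi <- genicness_score(inloci, genes, lens, n_sim = 100, seed = 2)
  expect_identical(gi$p_value, 1 / 101)
  expect_gt(gi$score, 0)
  # contig-scope resampling keeps loci on their contig of origin
  gsc <- genicness_score(truth_loci(bC), bC$genes, bC$genome,
                         scope = "contig", seed = 5)
  expect_true(is.finite(gsc$score))
})

test_that("genicness empirical p is never zero and respects the +1 rule", {
  g <- genicness_score(GRanges("c1", IRanges(1:20, width = 21)),
                       GRanges("c1", IRanges(1, 5e4)),
                       c(c1 = 1e5), n_sim = 50, seed = 3)
  expect_gte(g$p_value, 1 / 51)
  expect_lte(g$p_value, 1)
})

test_that("promoter association is strand-aware and calibrated", {
  lens <- c(c1 = 2e5)
  set.seed(41)
  gene_starts <- seq(5e3, 1.9e5, by = 5e3)
  genes <- GRanges("c1", IRanges(gene_starts, width = 1000),
                   strand = rep(c("+", "-"), length.out = length(gene_starts)),
                   gene_id = paste0("g", seq_along(gene_starts)))
  exons <- c(GRanges("c1", IRanges(gene_starts, width = 200),
                     strand = strand(genes), gene_id = mcols(genes)$gene_id,
                     exon_rank = ifelse(as.character(strand(genes)) == "+",
                                        1L, 2L)),
             GRanges("c1", IRanges(gene_starts + 800, width = 200),
                     strand = strand(genes), gene_id = mcols(genes)$gene_id,
                     exon_rank = ifelse(as.character(strand(genes)) == "+",
                                        2L, 1L)))
  # loci planted only in promoters (strand-aware upstream of first exon)
  plus <- as.character(strand(genes)) == "+"
  prom_pos <- ifelse(plus, start(genes) - 100, end(genes) + 100)
  loci <- GRanges("c1", IRanges(prom_pos, width = 1), tss = prom_pos)
  pa <- promoter_association(loci, genes, exons, lens)
  expect_true(all(pa$fold > 1))
  expect_identical(nrow(pa), 3L)
  # uniform intergenic placement: fold near 1
  intergenic_pos <- sample(setdiff(seq_len(2e5), unlist(mapply(seq,
    gene_starts, gene_starts + 999))), 400)
  unif <- GRanges("c1", IRanges(intergenic_pos, width = 1),
                  tss = intergenic_pos)
  pu <- promoter_association(unif, genes, exons, lens)
  expect_true(all(pu$fold > 0.5 & pu$fold < 2))
})

test_that("expression strata split bimodal RPKM distributions", {
  clear <- c(rep(0.01, 20), rep(100, 20))
  names(clear) <- paste0("g", 1:40)
  es <- expression_strata(clear, seed = 1)
  expect_identical(unname(es$labels[1]), "low")
  expect_identical(unname(es$labels[40]), "high")
  expect_gt(es$threshold, 0.01)
  expect_lt(es$threshold, 100)
  # planted bimodal lognormal: threshold lands between the modes
  ok <- 0
  for (s in 1:100) {
    set.seed(400 + s)
    r <- c(rlnorm(60, log(0.1), 0.5), rlnorm(60, log(50), 0.5))
    est <- expression_strata(r, seed = s)
    if (est$threshold > quantile(r[1:60], 0.99) &&
        est$threshold < quantile(r[61:120], 0.01)) ok <- ok + 1
  }
  expect_gte(ok, 95)
  expect_error(expression_strata(rep(1, 20)), "constant")
  expect_error(expression_strata(c(a = 1, b = 2, c = 3)), ">= 10")
})

test_that("motif expression fractions are counted per chromatin state", {
  states <- rep(c("active", "regulated"), c(30, 50))
  expressed <- c(rep(TRUE, 30), rep(FALSE, 50))
  r <- motif_expression_fraction(states, expressed)
  expect_identical(r$fraction[r$state == "active"], 1)
  expect_identical(r$fraction[r$state == "regulated"], 0)
  # clustered-mode bundle: expression confined to regulated domains
  b <- fixture_bundle_C200()
  st <- b$truth$chromatin_state
  expr <- st == "regulated"   # construction: only cluster loci fire
  r2 <- motif_expression_fraction(st, expr)
  expect_gt(r2$fraction[r2$state == "regulated"],
            r2$fraction[r2$state == "active"])
})
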