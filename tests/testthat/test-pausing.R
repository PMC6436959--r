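test_that("Tm profiles follow nearest-neighbour thermodynamics", {
  polyA <- DNAStringSet(c(c1 = strrep("A", 500)))
  prof <- tm_profile(polyA, "c1", tss = 250, strand = "+")
  expect_true(all(abs(diff(prof$tm)) < 1e-8))  # flat on a homopolymer
  # GC-rich windows melt above AT-rich windows
  g <- DNAStringSet(c(c1 = paste0(strrep("GC", 20), strrep("AT", 20))))
  tm_gc <- oracle_tm_window("GCGCGCGCG")
  tm_at <- oracle_tm_window("ATATATATA")
  expect_gt(tm_gc, tm_at)
  # minus-strand profiles read the transcribed strand
  seqs <- random_dna(500, gc = 0.45)
  gg <- DNAStringSet(c(c1 = seqs))
  pm <- tm_profile(gg, "c1", tss = 250, strand = "-")
  rc <- as.character(Biostrings::reverseComplement(DNAString(seqs)))
  # position +p on the minus strand is genomic tss - p; check one window
  w0 <- substr(rc, 500 - 250 + 1, 500 - 250 + 9)
  expect_equal(unname(pm$tm["0"]), oracle_tm_window(w0), tolerance = 1e-9)
  # N-containing windows are undefined; clipped profiles are flagged
  gn <- DNAStringSet(c(c1 = paste0(strrep("A", 240), "N", strrep("A", 240))))
  pn <- tm_profile(gn, "c1", tss = 230, strand = "+")
  expect_true(anyNA(pn$tm))
  expect_true(tm_profile(gn, "c1", tss = 100, strand = "+")$clipped)
})

test_that("Tm windows match the summation oracle on random sequence", {
  set.seed(71)
  s <- random_dna(417, gc = 0.36)
  g <- DNAStringSet(c(c1 = s))
  prof <- tm_profile(g, "c1", tss = 209, strand = "+")
  for (pos in seq(-200, 200, by = 13)) {
    wseq <- substr(s, 209 + pos, 209 + pos + 8)
    expect_equal(unname(prof$tm[as.character(pos)]), oracle_tm_window(wseq),
                 tolerance = 1e-9)
  }
})

test_that("pausing strength sums signed deviations from the flank background", {
  pos <- seq(-200, 200)
  base <- setNames(rep(20, 401), pos)
  expect_identical(pausing_strength(base)$S, 0)
  step <- base
  step[pos >= 0 & pos <= 19] <- 27
  step[pos >= 20 & pos <= 40] <- 16
  ps <- pausing_strength(step)
  expect_equal(ps$S, 20 * 7 + 21 * 4, tolerance = 1e-12)
  expect_equal(ps$background, 20, tolerance = 1e-12)
  # shift invariance: adding a constant to every Tm leaves S unchanged
  expect_equal(pausing_strength(step + 11.5)$S, ps$S, tolerance = 1e-9)
  # clipping variant never reports less than the signed version here
  expect_gte(pausing_strength(step, clip = TRUE)$S, ps$S)
  # insufficient flank coverage is an error
  gap <- step; gap[pos <= -80] <- NA
  expect_error(pausing_strength(gap), "flank")
})

test_that("BILD columns reward conservation and integrate a peak area", {
  q <- rep(0.25, 4)
  conserved <- rep(strrep("G", 30), 100)
  matched <- vapply(1:100, function(i) random_dna(30), character(1))
  bc <- bild_profile(conserved, q, tss_index = 15)
  bm <- bild_profile(matched, q, tss_index = 15)
  expect_true(all(bc$bild > mean(bm$bild)))
  # termination-peak area: conserved block over +20..+40 only
  set.seed(81)
  left <- vapply(1:60, function(i) random_dna(230), character(1))
  term <- rep(strrep("T", 21), 60)
  right <- vapply(1:60, function(i) random_dna(170), character(1))
  aln <- paste0(left, term, right)   # TSS at column 211, +20 at 231
  bp <- bild_profile(aln, q, tss_index = 211)
  expect_gt(bp$area, 0)
  expect_lt(abs(bp$baseline), max(abs(bp$bild[as.character(20:40)])) / 2)
})

test_that("cross-species range metric is shift-invariant", {
  pos <- seq(-200, 200)
  flat <- setNames(rep(12, 401), pos)
  expect_identical(cross_species_range_metric(flat), 0)
  prof <- setNames(rnorm(401, 20, 3), pos)
  expect_equal(cross_species_range_metric(prof + 7),
               cross_species_range_metric(prof), tolerance = 1e-9)
  none <- flat; none[pos >= 0 & pos <= 19] <- NA
  expect_error(cross_species_range_metric(none), "undefined")
})

test_that("valley centres locate the low-Tm minimum deterministically", {
  pos <- seq(-200, 200)
  v <- setNames(rep(20, 401), pos)
  v[pos >= 10 & pos <= 60] <- 20 - pmax(0, 10 - abs(pos[pos >= 10 & pos <= 60] - 30))
  r <- valley_center(v)
  expect_identical(r$center, 30L)
  expect_false(r$flagged)
  # monotone decreasing window: boundary minimum, flagged
  mono <- setNames(20 - 0.05 * (pos + 200), pos)
  rm_ <- valley_center(mono)
  expect_identical(rm_$center, 60L)
  expect_true(rm_$flagged)
  # flat window: midpoint, flagged
  rf <- valley_center(setNames(rep(5, 401), pos))
  expect_identical(rf$center, 35)
  expect_true(rf$flagged)
})

test_that("signal strata cut deterministic top and bottom deciles", {
  s <- setNames(seq(1, 100), sprintf("L%03d", 1:100))
  st <- stratify_by_signal(s)
  expect_length(st$top, 10)
  expect_length(st$bottom, 10)
  expect_identical(st$top, sprintf("L%03d", 100:91))
  expect_identical(st$bottom, sprintf("L%03d", 1:10))
  # massive ties: stable id-based rule
  tied <- setNames(c(rep(1, 50), rep(2, 50)), sprintf("L%03d", 1:100))
  t1 <- stratify_by_signal(tied)
  t2 <- stratify_by_signal(tied[sample(100)])
  expect_identical(sort(t1$top), sort(t2$top))
  expect_error(stratify_by_signal(s[1:10]), ">= 20")
  # synthetic coupling: strong-pausing loci make shorter precursors
  b <- fixture_bundle_I()
  libs <- fixture_libs_I()
  loci <- truth_loci(b)
  S <- setNames(b$truth$valley_depth, b$truth$locus_id)  # planted signal
  st2 <- stratify_by_signal(S)
  pr <- libs$lib1$precursors
  med_len <- function(ids) {
    p <- pr[pr$locus_id %in% ids, ]
    median(rep(p$length, p$count))
  }
  expect_lt(med_len(st2$top), med_len(st2$bottom))
})

test_that("precursor length tests are exact when possible", {
  same <- list(length = c(25, 26, 27, 28, 29), count = rep(2L, 5))
  p_same <- precursor_length_test(as.data.frame(same), as.data.frame(same))
  expect_equal(p_same$p_value, 1, tolerance = 1e-12)
  # complete separation: one-sided exact p = 1 / choose(20, 10)
  r <- precursor_length_test(1:10, 11:20, alternative = "less")
  expect_true(r$exact)
  expect_equal(r$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  # enumeration oracle on a small tie-free case
  x <- c(3, 9, 14, 27, 31); y <- c(5, 11, 16, 22, 40)
  expect_equal(precursor_length_test(x, y)$p_value,
               oracle_wilcox_exact(x, y), tolerance = 1e-12)
  # planted +10 nt shift is highly significant at n = 50 per side
  set.seed(61)
  a <- sample(28:45, 50, replace = TRUE)
  p <- precursor_length_test(a, a + 10, alternative = "less")
  expect_lt(p$p_value, 0.001)
  expect_error(precursor_length_test(1:3, 1:10), ">= 5")
})

test_that("weighted resampling lowers n_sub with a warning and handles reps", {
  pr <- data.frame(locus_id = "L", length = 28:47,
                   count = rep(5L, 20))
  expect_warning(r <- weighted_resampling_test(pr, pr, n_sub = 100,
                                               n_reps = 3, seed = 1),
                 "lowering")
  expect_identical(r$params$n_sub, 20L)
  one <- suppressWarnings(weighted_resampling_test(pr, pr, n_sub = 10,
                                                   n_reps = 1, seed = 1))
  expect_length(one$p, 1)
  expect_null(one$summary)
})

test_that("rRNA length controls flag size-selection artefacts only", {
  b <- fixture_bundle_I()
  libs <- fixture_libs_I()
  pr <- rrna_length_control(libs$lib1$rrna, libs$lib2$rrna, 300, 300,
                            n_reps = 200, seed = 3,
                            alternative = "two.sided")
  expect_length(pr, 200)
  expect_lt(mean(pr < 0.05), 0.25)   # same length distribution: calibrated
  # planted truncation (size selection) shifts the null p distribution
  trunc <- libs$lib2$rrna[libs$lib2$rrna$length <= 40, ]
  pt <- rrna_length_control(libs$lib1$rrna, trunc, 300, 300,
                            n_reps = 200, seed = 3,
                            alternative = "two.sided")
  expect_gt(mean(pt < 0.05), 0.5)
  expect_error(rrna_length_control(libs$lib1$rrna, libs$lib2$rrna,
                                   300, 300, n_reps = 0), "n_reps")
  expect_error(rrna_length_control(libs$lib1$rrna[1:2, ],
                                   libs$lib2$rrna, 1e6, 300, n_reps = 10),
               "insufficient")
})
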