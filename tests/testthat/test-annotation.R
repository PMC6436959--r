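test_that("locus calling applies score, distance and exclusion rules", {
  sites <- GRanges(c("c1", "c1", "c1", "c2"),
                   IRanges(c(201, 501, 801, 301), width = 21),
                   strand = c("+", "-", "+", "+"),
                   site_id = paste0("s", 1:4))
  hits <- data.frame(site_id = paste0("s", 1:4),
                     score = c(12, 11, 3, 10),
                     distance = c(42, 44, 42, 60))
  loci <- call_pirna_loci(sites, hits, threshold = 8)
  # s3 fails the score, s4 fails the 42 +/- 5 distance window
  expect_identical(sort(mcols(loci)$site_id), c("s1", "s2"))
  expect_identical(mcols(loci)$tss[mcols(loci)$site_id == "s1"], 199L)
  expect_identical(mcols(loci)$tss[mcols(loci)$site_id == "s2"], 523L)
  # exclusion set drops overlapping loci and counts them
  excl <- GRanges("c1", IRanges(190, 230))
  loci2 <- call_pirna_loci(sites, hits, threshold = 8, exclude = excl)
  expect_identical(attr(loci2, "n_excluded"), 1L)
  expect_identical(mcols(loci2)$site_id, "s2")
})

test_that("locus calling is order-independent and idempotent", {
  b <- fixture_bundle_C200()
  hits <- scan_upstream_windows(b$genome, b$sites_21u, b$config$motif_pwm)
  l1 <- call_pirna_loci(b$sites_21u, hits, threshold = 6)
  perm <- sample(length(b$sites_21u))
  l2 <- call_pirna_loci(b$sites_21u[perm], hits[sample(nrow(hits)), ],
                        threshold = 6)
  expect_identical(mcols(l1)$site_id, mcols(l2)$site_id)
  expect_identical(start(l1), start(l2))
})

test_that("precursor extraction keeps >22 nt reads anchored at the TSS", {
  loci <- GRanges(c("c1", "c1"), IRanges(c(101, 301), width = 21),
                  strand = c("+", "-"),
                  locus_id = c("L1", "L2"), tss = c(99L, 323L))
  mk <- function(contig, p5, len, strand, count = 1L) {
    GRanges(contig,
            IRanges(start = if (strand == "+") p5 else p5 - len + 1L,
                    width = len),
            strand = strand, length = len, count = count,
            chemistry = "capped", unique = TRUE)
  }
  reads <- c(mk("c1", 99, 21, "+"),    # too short (not >22)
             mk("c1", 99, 23, "+"),    # kept
             mk("c1", 98, 30, "+"),    # 5' end off the TSS
             mk("c1", 99, 30, "-"),    # wrong strand
             mk("c1", 323, 35, "-", count = 4L),  # kept (minus locus)
             mk("c1", 99, 40, "+", count = 2L))   # kept
  ps <- extract_precursors(reads, loci)
  expect_identical(nrow(ps), 3L)
  expect_true(all(ps$length > 22))
  expect_identical(sum(ps$count[ps$locus_id == "L1"]), 3L)
  expect_identical(ps$count[ps$locus_id == "L2"], 4L)
  # brute-force filter oracle on a random 20-read table
  set.seed(14)
  rnd <- do.call(c, lapply(1:20, function(i)
    mk("c1", sample(c(97:101, 321:325), 1), sample(20:35, 1),
       sample(c("+", "-"), 1), sample(1:5, 1))))
  got <- extract_precursors(rnd, loci)
  p5 <- ifelse(as.character(strand(rnd)) == "+", start(rnd), end(rnd))
  keep <- (p5 == 99 & as.character(strand(rnd)) == "+" |
             p5 == 323 & as.character(strand(rnd)) == "-") &
    mcols(rnd)$length > 22
  expect_identical(sum(got$count), sum(mcols(rnd)$count[keep]))
})

test_that("cleavage fragments are counted in the +28..+38 window only", {
  loci <- GRanges("c1", IRanges(101, 121), strand = "+",
                  locus_id = "L1", tss = 99L)
  mk <- function(p5, len, unique = TRUE, count = 1L) {
    GRanges("c1", IRanges(p5, width = len), strand = "+",
            length = len, count = count, chemistry = "monophosphate",
            unique = unique)
  }
  empty <- extract_cleavage_fragments(GRanges(), loci, 1000, 100)
  expect_identical(empty$count, 0L)
  reads <- c(mk(99 + 27, 15),            # +27: excluded
             mk(99 + 28, 15),            # +28: included
             mk(99 + 38, 15, count = 3L),# +38: included
             mk(99 + 39, 15),            # +39: excluded
             mk(99 + 30, 9),             # too short (not >10)
             mk(99 + 30, 15, unique = FALSE))  # non-unique
  cl <- extract_cleavage_fragments(reads, loci, 1000, 100)
  expect_identical(cl$count, 4L)
  expect_identical(cl$unique_sequences, 2L)
  expect_equal(cl$norm_count, 4 / 1000, tolerance = 1e-12)
  expect_equal(cl$norm_unique, 2 / 100, tolerance = 1e-12)
  # 21U reads are removed before counting, and uniqueness flags are required
  u21 <- GRanges("c1", IRanges(99 + 28, width = 15), strand = "+")
  cl2 <- extract_cleavage_fragments(reads, loci, 1000, 100, sites_21u = u21)
  expect_identical(cl2$count, 3L)
  bad <- mk(99 + 30, 15); mcols(bad)$unique <- NA
  expect_error(extract_cleavage_fragments(bad, loci, 1000, 100), "unique")
  # brute-force oracle on a random 15-read table
  set.seed(15)
  rnd <- do.call(c, lapply(1:15, function(i)
    mk(99 + sample(20:45, 1), sample(8:20, 1),
       unique = sample(c(TRUE, FALSE), 1), count = sample(1:4, 1))))
  got <- extract_cleavage_fragments(rnd, loci, 1000, 100)
  rel <- start(rnd) - 99
  keep <- mcols(rnd)$unique & mcols(rnd)$length > 10 & rel >= 28 & rel <= 38
  expect_identical(got$count, sum(mcols(rnd)$count[keep]))
  expect_identical(got$unique_sequences, sum(keep))
})

test_that("no read counts as both precursor and cleavage fragment", {
  b <- fixture_bundle_I()
  libs <- fixture_libs_I()
  loci <- truth_loci(b)
  mcols(loci)$locus_id <- b$truth$locus_id
  prec <- extract_precursors(libs$lib1$capped, loci)
  # precursor reads start at the TSS; cleavage fragments start at +28..+38,
  # so the same read interval can never satisfy both filters
  cl <- extract_cleavage_fragments(libs$lib1$capped, loci, 1e6, 1e5)
  expect_identical(sum(cl$count), 0L)
  expect_gt(sum(prec$count), 0L)
})

test_that("median-of-ratios size factors behave like the reference method", {
  ident <- matrix(rep(c(10, 60, 200, 35), 3), ncol = 3)
  sf <- size_factors_median_ratios(ident)
  expect_equal(unname(sf$factors), rep(1, 3), tolerance = 1e-12)
  # Poisson counts with planted factors recovered within 5%
  set.seed(77)
  mu <- rlnorm(400, 5, 1)
  m <- cbind(rpois(400, mu * 0.5), rpois(400, mu * 1), rpois(400, mu * 2))
  sf2 <- size_factors_median_ratios(m)
  norm <- sf2$factors / exp(mean(log(sf2$factors)))
  planted <- c(0.5, 1, 2) / exp(mean(log(c(0.5, 1, 2))))
  expect_true(all(abs(norm / planted - 1) < 0.05))
  # agreement with the DESeq2 implementation (independent cross-check)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf2$factors), unname(ref), tolerance = 1e-8)
  expect_error(size_factors_median_ratios(matrix(c(0, 1, 1, 0), 2)),
               "nonzero")
})

test_that("slope size factors report OLS slope with a 1.96 SE interval", {
  x <- c(3, 8, 15, 22, 40, 51, 66, 72, 80, 95)
  perfect <- size_factors_slope(cbind(x, 3 * x))
  expect_equal(perfect$slope, 3, tolerance = 1e-10)
  expect_lt(perfect$se, 1e-10)
  # coverage of the interval under noise
  set.seed(55)
  hit <- 0
  for (r in 1:1000) {
    xx <- runif(100, 10, 100)
    yy <- xx + rnorm(100, 0, 5)
    sfs <- size_factors_slope(cbind(xx, yy))
    if (sfs$interval[1] <= 1 && 1 <= sfs$interval[2]) hit <- hit + 1
  }
  expect_gte(hit, 930)
  expect_error(size_factors_slope(cbind(1, 3)), ">= 10")
  expect_error(size_factors_slope(matrix(0, 12, 2)), "degenerate")
})
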