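test_that("PWM construction matches the counting formula", {
  # identical consensus sites with vanishing pseudocount: 2 bits per column
  pwm <- build_pwm(rep("GTTTC", 10), pseudocount = 1e-9)
  expect_equal(pwm_max_score(pwm), 5 * log2(4), tolerance = 1e-6)
  expect_identical(pwm_consensus(pwm), "GTTTC")

  # counts matching the background exactly give zero log-odds everywhere
  flat <- build_pwm(c("AAAA", "CCCC", "GGGG", "TTTT"), pseudocount = 1e-9)
  expect_true(all(abs(flat$mat) < 1e-6))

  # mixed site set against a direct counting oracle
  sites <- c("ACGT", "ACGA", "TCGT", "ACGT", "GCAT")
  q <- c(0.3, 0.2, 0.2, 0.3)
  pc <- 2
  pwm2 <- build_pwm(sites, background = q, pseudocount = pc)
  chars <- do.call(rbind, strsplit(sites, ""))
  for (j in 1:4) for (b in 1:4) {
    cnt <- sum(chars[, j] == c("A", "C", "G", "T")[b])
    expect_equal(unname(pwm2$mat[b, j]),
                 log2((cnt + pc * q[b]) / (length(sites) + pc) / q[b]),
                 tolerance = 1e-12)
  }
  expect_error(build_pwm(c("ACG", "ACGT")), "equal length")
  expect_error(build_pwm("ACGT"), ">= 2")
  expect_error(build_pwm(c("ACNT", "ACGT")), "N-free")
})

test_that("window scanning finds the best offset with deterministic ties", {
  pwm <- build_pwm(rep("GTTTC", 10), pseudocount = 1e-9)
  hit <- scan_window(pwm, "AAAAGTTTCAAAA")
  expect_identical(hit$offset, 4L)
  expect_equal(hit$score, pwm_max_score(pwm), tolerance = 1e-6)
  # two equal occurrences: smallest offset wins
  tie <- scan_window(pwm, "GTTTCAGTTTC")
  expect_identical(tie$offset, 0L)
  # brute-force enumeration oracle on random sequence
  set.seed(11)
  pwm2 <- default_ruby_pwm()
  for (r in 1:20) {
    s <- random_dna(60)
    hit <- scan_window(pwm2, s)
    brute <- vapply(1:(60 - pwm2$width + 1), function(o) {
      sum(pwm2$mat[cbind(match(strsplit(substr(s, o, o + pwm2$width - 1),
                                        "")[[1]], c("A", "C", "G", "T")),
                         1:pwm2$width)])
    }, numeric(1))
    expect_equal(hit$score, max(brute), tolerance = 1e-9)
    # floating-point near-ties between distinct windows are legitimate;
    # the hit must lie in the tolerance set of maxima, and be the unique
    # argmax when there is no tie
    best_set <- which(brute >= max(brute) - 1e-9) - 1L
    expect_true(hit$offset %in% best_set)
    if (length(best_set) == 1) expect_identical(hit$offset, best_set)
  }
  # N handling: offsets overlapping N are skipped; all-N gives a sentinel
  hitN <- scan_window(pwm, "GTNTCAAGTTTCA")
  expect_identical(hitN$offset, 7L)
  allN <- scan_window(pwm, "NNNNNNNN")
  expect_true(is.na(allN$score))
})

test_that("the artificial locus upstream region contains the GTTTC motif", {
  up60 <- "aaaaaattttgtaatgtttcacatttaccataaaattgtcctaatttaaaactgaattga"
  pwm <- build_pwm(rep("GTTTC", 10), pseudocount = 1e-9)
  hit <- scan_window(pwm, toupper(up60))
  expect_identical(hit$offset, 15L)  # gtttc at positions 16-20
  expect_equal(hit$score, pwm_max_score(pwm), tolerance = 1e-6)
})

test_that("score thresholds are recovered from bimodal distributions", {
  set.seed(2)
  scores <- c(rnorm(500, 0, 1), rnorm(500, 20, 1))
  fit <- fit_score_threshold(scores)
  expect_gt(fit$threshold, 5)
  expect_lt(fit$threshold, 15)
  expect_false(fit$unimodal)

  uni <- fit_score_threshold(rnorm(500))
  expect_true(uni$unimodal)

  masses <- fit_score_threshold(rep(c(0, 1000), each = 100))
  expect_gt(masses$threshold, 0)
  expect_lt(masses$threshold, 1000)
  expect_equal(sort(masses$means), c(0, 1000), tolerance = 1)

  expect_error(fit_score_threshold(rnorm(10)), ">= 50")
})

test_that("mixture means are recovered within 10% across seeds", {
  for (s in 1:20) {
    set.seed(300 + s)
    mu2 <- runif(1, 15, 30)   # separation >= 5 pooled SD at unit variances
    x <- c(rnorm(500, 0, 1), rnorm(500, mu2, 1))
    fit <- fit_score_threshold(x)
    expect_lt(abs(fit$means[1] - 0), 0.1 * mu2)
    expect_lt(abs(fit$means[2] - mu2), 0.1 * mu2)
  }
})

test_that("positional distributions expose the 42-nt mode and flag noise", {
  hits <- data.frame(site_id = paste0("s", 1:60),
                     distance = rep(42, 60), score = rnorm(60, 10))
  pd <- positional_distribution(hits)
  expect_identical(pd$mode, 42L)
  expect_true(pd$dominant)
  set.seed(8)
  unif <- data.frame(site_id = paste0("u", 1:5000),
                     distance = sample(0:100, 5000, replace = TRUE),
                     score = rnorm(5000, 10))
  pdu <- positional_distribution(unif)
  expect_false(pdu$dominant)
  expect_error(positional_distribution(
    data.frame(site_id = character(0), distance = numeric(0),
               score = numeric(0))), "no hits")
})

test_that("allele rescoring equals a full rescan and a column delta", {
  pwm <- default_ruby_pwm()
  set.seed(21)
  win <- paste0(random_dna(30), pwm_consensus(pwm), random_dna(30))
  # alt == ref: zero delta
  r0 <- rescore_with_allele(pwm, win, list(pos = 5, ref = substr(win, 5, 5),
                                           alt = substr(win, 5, 5)))
  expect_identical(r0$delta, 0)
  # SNP far from the best occurrence leaves the score unchanged
  far <- rescore_with_allele(pwm, win,
                             list(pos = 3, ref = substr(win, 3, 3),
                                  alt = setdiff(c("A", "C", "G", "T"),
                                                substr(win, 3, 3))[1]))
  expect_identical(far$delta, 0)
  # SNP inside the motif: matches the brute-force rescan and, with the
  # offset unchanged, the single-column log-odds difference
  pos <- 33  # third column of the planted consensus
  ref <- substr(win, pos, pos)
  alt <- "A"
  r <- rescore_with_allele(pwm, win, list(pos = pos, ref = ref, alt = alt))
  alt_win <- win; substr(alt_win, pos, pos) <- alt
  expect_equal(r$score_alt, scan_window(pwm, alt_win)$score,
               tolerance = 1e-12)
  if (r$offset_alt == r$offset_ref) {
    j <- pos - r$offset_ref
    expect_equal(r$delta, unname(pwm$mat["A", j] - pwm$mat[ref, j]),
                 tolerance = 1e-12)
  }
  expect_error(rescore_with_allele(pwm, win, list(pos = 5, ref = "Z", alt = "A")),
               "mismatch")
})

test_that("pushing a base toward the column maximum never lowers the score", {
  pwm <- default_ruby_pwm()
  set.seed(31)
  for (r in 1:30) {
    s <- random_dna(40)
    base_hit <- scan_window(pwm, s)
    pos <- sample(40, 1)
    j_rel <- pos - base_hit$offset
    best_base <- c("A", "C", "G", "T")[which.max(
      if (j_rel >= 1 && j_rel <= pwm$width) pwm$mat[, j_rel] else rep(1, 4))]
    s2 <- s; substr(s2, pos, pos) <- best_base
    expect_gte(scan_window(pwm, s2)$score + 1e-12, base_hit$score)
  }
})

test_that("ancestral k-mer probabilities multiply across independent sites", {
  sure <- matrix(0, 5, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  sure[cbind(1:5, match(c("G", "T", "T", "T", "C"), colnames(sure)))] <- 1
  expect_identical(ancestral_kmer_probability(sure, "GTTTC"), 1)
  half <- sure * 0 + 1 / 6
  half[cbind(1:5, match(c("G", "T", "T", "T", "C"), colnames(half)))] <- 0.5
  expect_equal(ancestral_kmer_probability(half, "GTTTC"), 0.5^5,
               tolerance = 1e-12)
  set.seed(5)
  mx <- t(apply(matrix(runif(20), 5, 4), 1, function(r) r / sum(r)))
  hand <- prod(vapply(1:5, function(i)
    mx[i, match(substr("GTTTC", i, i), c("A", "C", "G", "T"))], numeric(1)))
  expect_equal(ancestral_kmer_probability(mx, "GTTTC"), hand,
               tolerance = 1e-12)
  expect_error(ancestral_kmer_probability(mx, "GTTT"), "length")
})

test_that("independent-origin probability follows (1-pa)*p1*p2", {
  expect_identical(independent_origin_probability(1, 0.8, 0.9), 0)
  expect_identical(independent_origin_probability(0, 1, 1), 1)
  expect_equal(independent_origin_probability(0.5, 0.5, 0.5), 0.125,
               tolerance = 1e-12)
  expect_error(independent_origin_probability(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("MEME minimal format round-trips a PWM", {
  pwm <- default_ruby_pwm()
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme_pwm(pwm, f, name = "ruby")
  back <- read_meme_pwm(f)
  expect_identical(back$width, pwm$width)
  expect_identical(pwm_consensus(back), pwm_consensus(pwm))
  expect_equal(back$mat, pwm$mat, tolerance = 1e-4)
})
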