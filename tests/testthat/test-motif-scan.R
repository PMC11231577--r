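test_that("log-odds scoring matches closed forms", {
  uni <- pwm("uni", matrix(0.25, 4, 3))
  expect_equal(score_window(uni, "ACG"), 0, tolerance = 1e-3)
  # single sharp column: log2(0.97/0.25) after the 1e-4 pseudocount
  p1 <- pwm("one", matrix(c(0.97, 0.01, 0.01, 0.01), 4, 1))
  expected <- log2(((0.97 + 1e-4) / (1 + 4e-4)) / 0.25)
  expect_equal(score_window(p1, "A"), expected)
  expect_equal(expected, 1.956, tolerance = 1e-3)
  # N never scores
  expect_identical(score_window(p1, "N"), -Inf)
  expect_error(score_window(p1, "AA"), "width")
  # consensus dominates every other word
  set.seed(3)
  rp <- random_pwm(4)
  cons <- score_window(rp, pwm_consensus(rp))
  words <- expand.grid(rep(list(c("A", "C", "G", "T")), 4))
  all_scores <- apply(words, 1, function(w) {
    score_window(rp, paste(w, collapse = ""))
  })
  expect_true(all(cons >= all_scores - 1e-12))
})

test_that("DP p-value tables match exhaustive enumeration (W <= 6)", {
  set.seed(21)
  for (W in c(2, 4, 6)) {
    p <- random_pwm(W)
    tab <- pvalue_table(p, precision = 0.01)
    oracle <- brute_pwm_survival(p, precision = 0.01)
    # probe the whole lattice at a spread of scores
    probes <- unique(round(seq(tab$min_total, tab$max_total, length.out = 40)))
    for (s in probes) {
      expect_equal(tab$survival[s - tab$min_total + 1], oracle(s),
                   tolerance = 1e-12)
    }
  }
  # W = 1 uniform: P(score >= 0) = 1
  uni <- pwm("u", matrix(0.25, 4, 1))
  tu <- pvalue_table(uni)
  expect_equal(pvalue_lookup(tu, 0), 1)
  # most extreme score: product of max-column background masses
  sharp <- sharp_pwm("ACG")
  ts <- pvalue_table(sharp)
  expect_equal(ts$survival[length(ts$survival)], 0.25^3, tolerance = 1e-12)
  # survival is monotone non-increasing
  expect_true(all(diff(ts$survival) <= 1e-15))
})

test_that("scanning recovers a planted consensus site at the window center", {
  set.seed(8)
  p <- sharp_pwm("ACGTACGTAC", id = "M1")
  g <- random_seq(9000)
  center <- 4500L
  substr(g, center + 1, center + 10) <- "ACGTACGTAC"
  genome <- c(chrS = g)
  regions <- region_set("chrS", center - 250L, center + 250L, name = "r1")
  cfg <- analysis_config(scan_window_halfwidth = 500L)
  sc <- scan_regions(genome, regions, list(M1 = p), cfg)
  expect_true(sc$indicator["r1", "M1"])
  expect_equal(sc$best$offset, 0L)
  expect_equal(sc$best$strand, "+")
  expect_lte(sc$best$p_value, 1e-5)
})

test_that("strand handling is symmetric", {
  set.seed(9)
  p <- random_pwm(6, id = "M")
  g <- random_seq(4000)
  genome <- c(chrS = g)
  genome_rc <- c(chrS = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(g))))
  regions <- region_set("chrS", 1900, 2100, name = "r1")   # center 2000
  # center maps to 4000 - 1 - 2000 = 1999 on the reverse complement
  regions_rc <- region_set("chrS", 1899, 2099, name = "r1")
  cfg <- analysis_config(scan_window_halfwidth = 300L, fimo_p_cutoff = 1e-2)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  fwd <- scan_regions(genome, regions, list(M = p), cfg, background = bg)
  rev <- scan_regions(genome_rc, regions_rc, list(M = p), cfg,
                      background = bg)
  # same multiset of (score, p) hits on the reverse-complemented genome
  expect_equal(sort(fwd$hits$score_bits), sort(rev$hits$score_bits))
  expect_equal(sort(fwd$hits$p_value), sort(rev$hits$p_value))
  expect_equal(table(fwd$hits$strand)[["+"]], table(rev$hits$strand)[["-"]])

  # palindromic PWM: + and - hits coincide position-wise with equal scores
  pal <- sharp_pwm("ACGT", id = "pal")
  sc <- scan_regions(genome, regions, list(pal = pal), cfg, background = bg)
  plus <- sc$hits[sc$hits$strand == "+", ]
  minus <- sc$hits[sc$hits$strand == "-", ]
  expect_equal(plus$offset, minus$offset)
  expect_equal(plus$score_bits, minus$score_bits)
})

test_that("a cutoff of 1 reports every scannable position on both strands", {
  set.seed(10)
  genome <- c(chrS = random_seq(3000))
  regions <- region_set("chrS", c(1000, 2000), c(1200, 2100),
                        name = c("a", "b"))
  W <- 5L
  p <- random_pwm(W)
  cfg <- analysis_config(scan_window_halfwidth = 100L, fimo_p_cutoff = 1)
  sc <- scan_regions(genome, regions, list(M = p), cfg)
  win_len <- 201L
  expect_equal(nrow(sc$hits), 2L * 2L * (win_len - W + 1L))
  # windows are clipped at the chromosome end
  edge <- region_set("chrS", 2900, 2990, name = "e")
  sce <- scan_regions(genome, edge, list(M = p), cfg)
  clipped_len <- 3000 - (2945 - 100)   # center 2945, right side clipped
  expect_equal(nrow(sce$hits), 2L * (clipped_len - W + 1L))
})

test_that("empirical false-positive rate respects exact p-values", {
  set.seed(77)
  genome <- c(chrS = random_seq(3e5, gc = 0.41))
  regions <- region_set("chrS", seq(0, 290000, by = 3000),
                        seq(500, 290500, by = 3000),
                        name = sprintf("r%03d", 1:97))
  p <- random_pwm(8)
  cfg <- analysis_config(scan_window_halfwidth = 1500L, fimo_p_cutoff = 1e-3)
  sc <- scan_regions(genome, regions, list(M = p), cfg)
  centers <- region_center(regions)
  wlen <- pmin(3e5, centers + 1501) - pmax(0, centers - 1500)
  n_scanned <- 2 * sum(wlen - 8 + 1)
  fpr <- nrow(sc$hits) / n_scanned
  # conservative bound with discretization slack
  expect_lte(fpr, 1e-3 * 1.3)
})

test_that("MEME and TSV motif round-trips preserve matrices", {
  set.seed(4)
  pwms <- list(A1 = random_pwm(5, "A1"), B2 = sharp_pwm("ACGTT", id = "B2"))
  meme <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, meme)
  back <- read_meme(meme)
  expect_equal(names(back), c("A1", "B2"))
  expect_equal(back$A1$mat, pwms$A1$mat, tolerance = 1e-5)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pwm_tsv(pwms, tsv)
  back2 <- read_pwm_tsv(tsv)
  expect_equal(back2$B2$mat, pwms$B2$mat, tolerance = 1e-10)
  # malformed PWMs are rejected
  expect_error(pwm("bad", matrix(c(0.5, 0.5, 0.1, 0.1), 4, 1)), "sum to 1")
})
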