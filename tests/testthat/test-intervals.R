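test_that("BED round-trip preserves regions and rejects malformed lines", {
  set.seed(11)
  rs <- random_regions(1000, max_pos = 50000, max_len = 200)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(rs, path)
  back <- read_bed(path)
  expect_equal(back$chrom, rs$chrom)
  expect_equal(back$start, rs$start)
  expect_equal(back$end, rs$end)
  expect_equal(back$name, rs$name)

  p3 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", p3)
  one <- read_bed(p3)
  expect_equal(one$start, 100L)
  expect_equal(one$end, 200L)

  writeLines(c("chr1\t10\t20", "chr1\t200\t100"), p3)
  expect_error(read_bed(p3), "line 2")
  writeLines("chr1\t100", p3)
  expect_error(read_bed(p3), "3 columns")
})

test_that("merge coalesces overlapping and book-ended intervals", {
  m <- merge_regions(list(region_set("chr1", 0, 10),
                          region_set("chr1", 5, 15)))
  expect_equal(m$start, 0L)
  expect_equal(m$end, 15L)
  # book-ended intervals are contiguous chromatin
  m2 <- merge_regions(region_set("chr1", c(0, 10), c(10, 20)))
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$end, 20L)
  # disjoint inputs pass through sorted
  m3 <- merge_regions(region_set("chr1", c(50, 0), c(60, 10)))
  expect_equal(m3$start, c(0L, 50L))
})

test_that("interval operations match brute-force oracles on random inputs", {
  set.seed(42)
  for (rep in 1:60) {
    a <- random_regions(sample(2:40, 1))
    b <- random_regions(sample(2:40, 1))

    m <- merge_regions(a)
    bm <- brute_merge(a)
    expect_equal(m$start, bm$start, info = paste("merge rep", rep))
    expect_equal(m$end, bm$end)
    # idempotence
    expect_equal(merge_regions(m)[c("start", "end")], m[c("start", "end")])

    s <- subtract_blacklist(a, b)
    bs <- brute_subtract(a, b)
    expect_equal(s$name, bs$name, info = paste("subtract rep", rep))

    frac <- sample(c(0.25, 0.5, 0.9, 1), 1)
    f <- intersect_fraction(a, b, frac)
    bf <- brute_intersect_fraction(a, b, frac)
    expect_equal(f$name, bf$name, info = paste("fraction rep", rep))
  }
  # self-subtraction annihilates
  a <- random_regions(30)
  expect_equal(nrow(subtract_blacklist(a, a)), 0L)
})

test_that("fraction-overlap filter implements the 50% peak-coverage rule", {
  a <- region_set("chr1", 100, 200, name = "peak")
  expect_equal(nrow(intersect_fraction(a, region_set("chr1", 150, 300), 0.5)),
               1L)  # overlap 50/100
  expect_equal(nrow(intersect_fraction(a, region_set("chr1", 160, 300), 0.5)),
               0L)  # overlap 40/100
  # any 1-bp overlap passes as min_frac -> 0+
  expect_equal(nrow(intersect_fraction(a, region_set("chr1", 199, 300),
                                       1e-9)), 1L)
  # retained intervals come back unmodified
  kept <- intersect_fraction(a, region_set("chr1", 0, 1000), 0.5)
  expect_equal(kept$start, 100L)
  expect_equal(kept$end, 200L)
  # fragmented coverage accumulates across the union of b
  b <- region_set("chr1", c(100, 160), c(130, 190))
  expect_equal(nrow(intersect_fraction(a, b, 0.5)), 1L)   # 30 + 30 >= 50
  expect_equal(nrow(intersect_fraction(a, b, 0.7)), 0L)
  # bedtools-style: fraction of the b interval
  bb <- region_set("chr1", 150, 170)   # fully inside a
  expect_equal(nrow(intersect_fraction(a, bb, 0.9, fraction_of = "b")), 1L)
  expect_equal(nrow(intersect_fraction(a, bb, 0.9, fraction_of = "a")), 0L)
})

test_that("promoter/genic/nongenic annotation follows TSS strand rules", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tx_start = c(5000L, 20000L), tx_end = c(9000L, 26000L),
                      strand = c("+", "-"))
  cfg <- analysis_config()
  lab <- annotate_regions(
    region_set("chr1",
               c(4500L, 6000L, 12000L, 26200L, 3000L),
               c(4800L, 6400L, 12500L, 26500L, 3500L)),
    genes, cfg)
  # regions come back sorted by start: 3000 nongenic, 4500 in the + gene
  # promoter, 6000 in its body, 12000 between genes, 26200 in the - gene
  # promoter (downstream of tx_end)
  expect_equal(lab, c("nongenic", "promoter", "genic", "nongenic",
                      "promoter"))
  # promoter takes precedence over an overlapping gene body
  genes2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                       tx_start = c(1000L, 1500L), tx_end = c(3000L, 4000L),
                       strand = c("+", "+"))
  lab2 <- annotate_regions(region_set("chr1", 1100L, 1300L), genes2, cfg)
  expect_equal(lab2, "promoter")
  # promoter clipped at chromosome start
  genes3 <- data.frame(gene_id = "g", chrom = "chr1", tx_start = 400L,
                       tx_end = 2000L, strand = "+")
  expect_equal(annotate_regions(region_set("chr1", 0L, 50L), genes3, cfg),
               "promoter")
  # chromosome without genes
  expect_equal(annotate_regions(region_set("chr9", 0L, 50L), genes, cfg),
               "nongenic")
  # labels partition the set
  set.seed(5)
  rs <- random_regions(200, chroms = "chr1", max_pos = 30000)
  labs <- annotate_regions(rs, genes, cfg)
  expect_true(all(labs %in% c("promoter", "genic", "nongenic")))
  expect_length(labs, nrow(rs))
})

test_that("region centers use the floor convention", {
  # constructor sorts by start, so centers come back in coordinate order
  expect_equal(region_center(region_set("chr1", c(100L, 0L, 10L),
                                        c(200L, 1L, 13L))),
               c(0L, 11L, 150L))
})

test_that("region_set enforces interval invariants", {
  expect_error(region_set("chr1", 200, 100), "start must be <")
  expect_error(region_set("chr1", -5, 10), ">= 0")
  # duplicates collapse; sorting is canonical
  rs <- as_region_set(data.frame(chrom = c("chr2", "chr1", "chr1"),
                                 start = c(5L, 7L, 7L),
                                 end = c(9L, 9L, 9L)))
  expect_equal(nrow(rs), 2L)
  expect_equal(rs$chrom, c("chr1", "chr2"))
})
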