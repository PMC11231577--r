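small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, genome_length = 120000, n_regions = 50L,
         region_length = 500L, n_motifs = 3L),
    list(...))
  do.call(synth_config, args)
}

test_that("genome simulation is deterministic with disjoint regions", {
  cfg <- small_cfg(seed = 1)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$regions, g2$regions)
  # GC content within 3 binomial SDs
  cfg5 <- small_cfg(seed = 2, gc_fraction = 0.5, genome_length = 100000)
  g <- make_genome(cfg5)
  gc <- sum(strsplit(g$genome[[1]], "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 100000))
  # pairwise disjointness, brute force
  r <- g1$regions
  for (i in seq_len(nrow(r) - 1)) {
    expect_true(all(r$start[(i + 1):nrow(r)] >= r$end[i] |
                    r$end[(i + 1):nrow(r)] <= r$start[i]))
  }
  expect_error(make_genome(small_cfg(genome_length = 10000)),
               "too small")
})

test_that("motif planting records truth and perturbs only chosen regions", {
  cfg <- small_cfg(seed = 3)
  g <- make_genome(cfg)
  p <- synth_pwms(cfg)[[cfg$planted_motif_id]]
  # plant_fraction 0 leaves the genome untouched
  none <- plant_motifs(g$genome, g$regions, p, 0, seed = 5)
  expect_identical(none$genome, g$genome)
  expect_equal(nrow(none$truth), 0L)
  # truth rows = ceiling(fraction * n)
  planted <- plant_motifs(g$genome, g$regions, p, 0.37, seed = 5)
  expect_equal(nrow(planted$truth), ceiling(0.37 * 50))
  # planted sequence present at the recorded coordinates and strand
  tr <- planted$truth
  for (i in seq_len(nrow(tr))) {
    found <- substr(planted$genome[[tr$chrom[i]]],
                    tr$genomic_start[i] + 1,
                    tr$genomic_start[i] + nchar(tr$sequence[i]))
    want <- if (tr$strand[i] == "-") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tr$sequence[i])))
    } else {
      tr$sequence[i]
    }
    expect_equal(found, want)
  }
  expect_error(plant_motifs(g$genome, region_set("chrS", 0, 5), p, 1),
               "width exceeds")
})

test_that("scanner recovers nearly all planted sites at p < 1e-5", {
  cfg <- synth_config(seed = 11, genome_length = 400000, n_regions = 120L,
                      n_motifs = 2L)
  g <- make_genome(cfg)
  p <- synth_pwms(cfg)[[cfg$planted_motif_id]]
  planted <- plant_motifs(g$genome, g$regions, p, 1, seed = 17)
  sc <- scan_regions(planted$genome, g$regions,
                     stats::setNames(list(p), cfg$planted_motif_id),
                     analysis_config())
  recovered <- mean(planted$truth$region_id %in%
                    sc$hits$region_id[sc$hits$p_value <= 1e-5])
  expect_gte(recovered, 0.95)
})

test_that("count simulation matches its negative-binomial contract", {
  cfg <- small_cfg(seed = 4, nb_mean = 100, nb_dispersion = 0)
  g <- make_genome(cfg)
  sim <- simulate_counts(g$regions, data.frame(region_id = character(0)),
                         cfg)
  expect_identical(dim(sim$cm$counts), c(50L, 10L))
  # Poisson limit: variance/mean ratio near 1 after depth correction
  y <- sweep(sim$cm$counts, 2, sim$truth$depth_factor, "/")
  ratio <- mean(apply(y, 1, var) / rowMeans(y))
  expect_lt(abs(ratio - 1), 0.25)
  expect_error(simulate_counts(g$regions, data.frame(),
                               small_cfg(nb_mean = -5)), "nb_mean")

  # determinism and the planted effect size
  cfg2 <- synth_config(seed = 5, genome_length = 2.2e6, n_regions = 1000L,
                       effect_log2fc = 1, plant_fraction = 0.3)
  g2 <- make_genome(cfg2)
  pw <- synth_pwms(cfg2)[[cfg2$planted_motif_id]]
  pl <- plant_motifs(g2$genome, g2$regions, pw, cfg2$plant_fraction,
                     seed = derive_seed(cfg2$seed, "plant"))
  s1 <- simulate_counts(g2$regions, pl$truth, cfg2)
  s2 <- simulate_counts(g2$regions, pl$truth, cfg2)
  expect_identical(s1$cm$counts, s2$cm$counts)
  # generator contract: normalized by the recorded true depth factors,
  # motif-bearing regions carry the planted log2 fold-change of 1
  # (median-of-ratios normalization is deliberately not used here: with
  # 30% one-directional effects it absorbs part of the shift, see the
  # methods vignette)
  y <- sweep(s1$cm$counts, 2, s1$truth$depth_factor, "/")
  eff <- rownames(y) %in% s1$effect_regions
  med <- median(log2(rowMeans(y[eff, 6:10]) / rowMeans(y[eff, 1:5])))
  expect_lt(abs(med - 1), 0.15)
})

test_that("qPCR simulation follows the log-linear amplification model", {
  cfg <- small_cfg(seed = 6, qpcr = list(ct_noise_sd = 0))
  sim <- simulate_qpcr(cfg)
  inputs <- sim$plate[sim$plate$sample_class == "input_dilution" &
                      sim$plate$target == "CDKN1A" &
                      sim$plate$condition == "control" &
                      sim$plate$bio_rep == 1, ]
  cts <- tapply(inputs$ct, inputs$dilution_factor, mean)
  # each 10-fold dilution adds |slope| = 3.3219 cycles
  expect_equal(as.numeric(diff(cts[c("1", "10", "100", "1000")])),
               rep(1 / log10(2), 3), tolerance = 1e-9)
  # no-template controls are undetermined
  expect_true(all(is.na(sim$plate$ct[sim$plate$sample_class == "ntc"])))
})

test_that("on-disk writers are deterministic and round-trip", {
  cfg <- small_cfg(seed = 7)
  g <- make_genome(cfg)
  sim <- simulate_counts(g$regions, data.frame(region_id = character(0)),
                         cfg)
  d <- withr::local_tempdir()
  fa1 <- file.path(d, "g1.fa"); fa2 <- file.path(d, "g2.fa")
  write_genome_fasta(g$genome, fa1)
  write_genome_fasta(g$genome, fa2)
  expect_identical(unname(tools::md5sum(fa1)), unname(tools::md5sum(fa2)))
  expect_identical(read_genome_fasta(fa1), g$genome)
  cpath <- file.path(d, "counts.tsv")
  write_counts_tsv(sim$cm, cpath)
  back <- read_counts_tsv(cpath)
  expect_identical(back$counts, sim$cm$counts)
  expect_identical(back$conditions, sim$cm$conditions)
})
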