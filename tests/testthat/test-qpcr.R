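test_that("technical replicate averaging follows the stated policy", {
  plate <- data.frame(target = "T", condition = "control",
                      sample_class = "ip_plus_ab", dilution_factor = 1,
                      bio_rep = 1, tech_rep = 1:2, ct = c(24.0, 24.4))
  expect_equal(average_technical_replicates(plate)$ct, 24.2)
  plate$ct <- c(24.0, NA)
  expect_warning(avg <- average_technical_replicates(plate),
                 "undetermined")
  expect_equal(avg$ct, 24.0)
  plate1 <- plate[1, ]
  expect_equal(average_technical_replicates(plate1)$ct, 24.0)
  # fully undetermined group is flagged, not imputed
  plate$ct <- c(NA, NA)
  expect_true(is.na(suppressWarnings(
    average_technical_replicates(plate)$ct)))
})

test_that("standard curves recover slope, efficiency and quantities", {
  # perfect doubling chemistry
  wells <- data.frame(dilution_factor = c(1, 10, 100, 1000),
                      ct = 20 + log10(c(1, 10, 100, 1000)) / log10(2))
  curve <- fit_standard_curve(wells)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(curve$slope, -3.3219, tolerance = 1e-4)
  expect_equal(curve$efficiency, 1.0, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1.0)
  # one dilution decade adds |slope| cycles
  expect_equal(absolute_quantity(curve$intercept, curve), 1)
  expect_equal(absolute_quantity(curve$intercept + curve$slope, curve), 10)
  # affine shift moves the intercept only
  shifted <- transform(wells, ct = ct + 3)
  cs <- fit_standard_curve(shifted)
  expect_equal(cs$slope, curve$slope)
  expect_equal(cs$intercept, curve$intercept + 3)
  # degenerate and insufficient inputs are rejected
  expect_error(fit_standard_curve(transform(wells, ct = 20)), "negative")
  expect_error(fit_standard_curve(wells[1:2, ]), "3 distinct")
})

test_that("percent input accounts for eluate and chromatin volumes", {
  vols <- list(vol_chip_eluate = 200, vol_input_eluate = 200,
               vol_chromatin_for_chip = 45, vol_chromatin_as_input = 10)
  # equal per-chromatin quantities give 100%
  q_equal <- (45 / 200) * (200 / 10)
  expect_equal(percent_ip(q_equal, 1, vols), 100)
  # linearity in the ChIP eluate volume
  v2 <- vols; v2$vol_chip_eluate <- 400
  expect_equal(percent_ip(q_equal, 1, v2), 200)
  expect_warning(out <- percent_ip(1, 0, vols), "undefined")
  expect_true(is.na(out))
})

test_that("noiseless plates invert to the true bound fractions", {
  cfg <- synth_config(seed = 6, qpcr = list(ct_noise_sd = 0))
  sim <- simulate_qpcr(cfg)
  quants <- quantify_plate(sim$plate)
  merged <- merge(quants, sim$truth, by = c("target", "condition",
                                            "bio_rep"))
  expect_equal(merged$percent_ip_plus, merged$percent_ip_plus_true,
               tolerance = 1e-9)
  expect_equal(merged$percent_ip_minus, merged$percent_ip_minus_true,
               tolerance = 1e-9)
  # %IP = 2.0 for a 2% bound fraction under the default protocol volumes
  cfg2 <- synth_config(seed = 6, qpcr = list(
    ct_noise_sd = 0,
    targets = data.frame(target = "T1", condition = "control",
                         bound_plus = 0.02, bound_minus = 0.004),
    n_bio_replicates = 1L))
  q2 <- quantify_plate(simulate_qpcr(cfg2)$plate)
  expect_equal(q2$percent_ip_plus, 2.0, tolerance = 1e-6)
  expect_equal(q2$slope, -1 / log10(2), tolerance = 1e-9)
})

test_that("SNR and fold enrichment identities hold", {
  quants <- expand.grid(target = "T", condition = c("control", "tpa"),
                        bio_rep = 1:4, stringsAsFactors = FALSE)
  quants$percent_ip_plus <- ifelse(quants$condition == "tpa", 10, 5)
  quants$percent_ip_minus <- 2
  quants$snr <- quants$percent_ip_plus / quants$percent_ip_minus
  res <- snr_and_enrichment(quants)
  s <- res$summary
  expect_equal(s$snr[s$condition == "tpa"], 5)
  expect_equal(s$mean_fold_enrichment[s$condition == "control"], 1)
  expect_equal(s$mean_fold_enrichment[s$condition == "tpa"], 2)
  expect_true(all(s$snr_above_reference))
  expect_error(snr_and_enrichment(quants[quants$condition == "tpa", ]),
               "control")
})

test_that("IQR outlier rule flags Tukey-fence violations only", {
  expect_equal(iqr_outliers(c(1, 1.1, 0.9, 1.05, 8)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(iqr_outliers(rep(2, 6)), rep(FALSE, 6))
  # permutation invariance
  set.seed(2)
  v <- c(rnorm(10), 50)
  perm <- sample(length(v))
  expect_equal(iqr_outliers(v)[perm], iqr_outliers(v[perm]))
  expect_warning(out <- iqr_outliers(c(1, 2, 3)), "fewer than 4")
  expect_equal(out, rep(FALSE, 3))
})

test_that("noisy plates recover percent input within tolerance", {
  cfg <- synth_config(seed = 13)   # ct_noise_sd = 0.15, 6 bio reps
  sim <- simulate_qpcr(cfg)
  quants <- quantify_plate(sim$plate)
  res <- snr_and_enrichment(quants)
  merged <- merge(quants, sim$truth, by = c("target", "condition",
                                            "bio_rep"))
  med_ratio <- tapply(merged$percent_ip_plus / merged$percent_ip_plus_true,
                      paste(merged$target, merged$condition), median)
  expect_true(all(abs(med_ratio - 1) < 0.15))
  # negative-control target shows SNR ~ 1, real targets well above
  s <- res$summary
  expect_true(all(s$snr[s$target != "NEG_CTRL"] >
                  s$snr[s$target == "NEG_CTRL"]))
})
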