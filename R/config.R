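#' Analysis configuration
#'
#' Collects the thresholds and window sizes used throughout the pipeline.
#' Defaults follow the published analysis: promoters are the 1,000 bp
#' directly upstream of a transcription start site, motifs are scanned in a
#' +/-1,500 bp window around each region-of-interest center at a p-value
#' cutoff of 1e-5, differential sites are called at BH-adjusted p <= 0.1,
#' ChIP peaks must overlap transcribed regions by at least 50% of their
#' length, and a signal-to-noise ratio of 1.5 is the reference line for
#' ChIP-qPCR.
#'
#' @param promoter_length Promoter width upstream of the TSS, bp.
#' @param scan_window_halfwidth Half-width of the motif scan window around
#'   each region center, bp.
#' @param fimo_p_cutoff Motif-hit p-value cutoff.
#' @param padj_cutoff BH-adjusted significance cutoff for differential
#'   accessibility.
#' @param min_overlap_fraction Minimum fraction of a ChIP peak that must be
#'   covered by transcribed regions for it to be retained.
#' @param snr_reference Reference signal-to-noise ratio for ChIP-qPCR.
#' @param n_permutations Number of label permutations for enrichment
#'   p-values.
#' @param score_precision Discretization bin width (bits) for exact PWM
#'   p-value tables.
#' @param seed Integer seed governing all randomness downstream.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(promoter_length = 1000L,
                            scan_window_halfwidth = 1500L,
                            fimo_p_cutoff = 1e-5,
                            padj_cutoff = 0.1,
                            min_overlap_fraction = 0.5,
                            snr_reference = 1.5,
                            n_permutations = 1000L,
                            score_precision = 0.01,
                            seed = 1L) {
  stopifnot_scalar_number(promoter_length, "promoter_length", positive = TRUE)
  stopifnot_scalar_number(scan_window_halfwidth, "scan_window_halfwidth",
                          positive = TRUE)
  stopifnot_scalar_number(fimo_p_cutoff, "fimo_p_cutoff", positive = TRUE)
  stopifnot_scalar_number(padj_cutoff, "padj_cutoff", positive = TRUE)
  stopifnot_scalar_number(min_overlap_fraction, "min_overlap_fraction",
                          positive = TRUE)
  if (min_overlap_fraction > 1) stop("min_overlap_fraction must be in (0, 1]")
  if (fimo_p_cutoff > 1) stop("fimo_p_cutoff must be in (0, 1]")
  stopifnot_scalar_number(n_permutations, "n_permutations", positive = TRUE)
  stopifnot_scalar_number(score_precision, "score_precision", positive = TRUE)
  structure(list(
    promoter_length = as.integer(promoter_length),
    scan_window_halfwidth = as.integer(scan_window_halfwidth),
    fimo_p_cutoff = fimo_p_cutoff,
    padj_cutoff = padj_cutoff,
    min_overlap_fraction = min_overlap_fraction,
    snr_reference = snr_reference,
    n_permutations = as.integer(n_permutations),
    score_precision = score_precision,
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Synthetic-data configuration
#'
#' One seeded configuration object drives every generator in the package.
#' Defaults describe the canonical synthetic world used by the recovery
#' experiments: a 4 Mbp single-chromosome genome at human-like 41% GC with
#' 2,000 non-overlapping 500 bp accessible regions; 21 sharp position
#' probability matrices of width 15 of which one ("M_PLANTED") is planted
#' into 30% of the regions; negative-binomial counts (mean 200, dispersion
#' 0.05, Var = mu + alpha mu^2) for 5 control and 5 treatment replicates
#' with a log2 fold-change of 1 in motif-bearing regions; FRET traces for
#' the nuclear sensor (Kd' = 5.3 nM, Hill n = 0.29) with rest at 150 pM and
#' treatment at 75 nM; and qPCR plates built from a log-linear amplification
#' model with a 10-fold input dilution series.
#'
#' @param seed Integer master seed; fans out deterministically to each
#'   generator stage.
#' @param genome_length,gc_fraction Genome size in bp and GC content.
#' @param n_regions,region_length Number and width of accessible regions.
#' @param n_motifs,motif_width Number of PPMs generated and their width.
#' @param planted_motif_id Identifier of the motif planted into regions.
#' @param plant_fraction Fraction of regions receiving a planted instance.
#' @param effect_log2fc log2 accessibility shift of motif-bearing regions
#'   under treatment.
#' @param nb_mean,nb_dispersion Negative-binomial mean and dispersion alpha
#'   of control counts (Var = mu + alpha mu^2).
#' @param n_replicates Replicates per condition.
#' @param depth_log_sd Log-normal SD of per-sample depth factors.
#' @param fret List of FRET simulation parameters: true Zn2+ (nM) in the
#'   rest and treatment phases, sensor constants `kd_nM`, `hill_n`,
#'   `r_min`, `r_max`, per-frame ratio `noise_sd`, `n_cells`,
#'   `frames_per_phase`, frame interval `dt_s`, and channel levels.
#' @param qpcr List of qPCR simulation parameters: `targets` data frame
#'   (target, condition, bound_plus, bound_minus), `ct_intercept`,
#'   `ct_slope`, `ct_noise_sd`, `n_bio_replicates`, `n_tech_replicates`,
#'   and the four `volumes` (ul) used in percent-input accounting.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         genome_length = 4e6,
                         gc_fraction = 0.41,
                         n_regions = 2000L,
                         region_length = 500L,
                         n_motifs = 21L,
                         motif_width = 15L,
                         planted_motif_id = "M_PLANTED",
                         plant_fraction = 0.3,
                         effect_log2fc = 1,
                         nb_mean = 200,
                         nb_dispersion = 0.05,
                         n_replicates = 5L,
                         depth_log_sd = 0.15,
                         fret = list(),
                         qpcr = list()) {
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  if (plant_fraction < 0 || plant_fraction > 1) {
    stop("plant_fraction must be in [0, 1]")
  }
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (nb_mean < 0) stop("nb_mean must be >= 0")
  if (region_length < motif_width) stop("region_length must be >= motif_width")

  fret_defaults <- list(
    zn_rest_nM = 0.15,        # 150 pM resting nuclear Zn2+
    zn_treatment_nM = 75,     # 75 nM after ZnCl2 addition
    kd_nM = 5.3, hill_n = 0.29,
    r_min = 1, r_max = 3,
    noise_sd = 0.02,
    n_cells = 50L, frames_per_phase = 20L, dt_s = 30,
    donor_level = 1000, background_level = 100
  )
  fret <- utils::modifyList(fret_defaults, fret)
  if (fret$r_max <= fret$r_min) stop("fret r_max must exceed r_min")
  if (fret$zn_rest_nM <= 0 || fret$zn_treatment_nM <= 0) {
    stop("phase Zn2+ values must be positive")
  }

  qpcr_defaults <- list(
    targets = default_qpcr_targets(),
    ct_intercept = 20,
    ct_slope = -1 / log10(2),   # perfect doubling: -3.3219 cycles/decade
    ct_noise_sd = 0.15,
    n_bio_replicates = 6L,
    n_tech_replicates = 2L,
    dilution_factors = c(1, 10, 100, 1000),
    volumes = list(vol_chip_eluate = 200, vol_input_eluate = 200,
                   vol_chromatin_for_chip = 45, vol_chromatin_as_input = 10)
  )
  qpcr <- utils::modifyList(qpcr_defaults, qpcr)
  if (qpcr$ct_slope >= 0) stop("qpcr ct_slope must be negative")
  if (any(qpcr$targets$bound_plus <= 0 | qpcr$targets$bound_plus > 1)) {
    stop("bound fractions must be in (0, 1]")
  }

  structure(list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    gc_fraction = gc_fraction,
    n_regions = as.integer(n_regions),
    region_length = as.integer(region_length),
    n_motifs = as.integer(n_motifs),
    motif_width = as.integer(motif_width),
    planted_motif_id = planted_motif_id,
    plant_fraction = plant_fraction,
    effect_log2fc = effect_log2fc,
    nb_mean = nb_mean,
    nb_dispersion = nb_dispersion,
    n_replicates = as.integer(n_replicates),
    depth_log_sd = depth_log_sd,
    fret = fret,
    qpcr = qpcr
  ), class = "synth_config")
}

# Default ChIP-qPCR truth: the six probed p53 targets plus the positive
# (CDKN1A) and negative primer-set controls. Bound fractions (+Ab) give
# percent-input values of a few percent with SNR around 5 against the
# beads-only (-Ab) background, except the negative control at SNR ~ 1.
default_qpcr_targets <- function() {
  grid <- expand.grid(
    target = c("CDKN1A", "ERGIC1", "NFIB", "SFN", "EGR1", "PLD5",
               "LRIG3_DT", "NEG_CTRL"),
    condition = c("control", "tpa", "zncl2"),
    stringsAsFactors = FALSE
  )
  base_plus <- c(CDKN1A = 0.05, ERGIC1 = 0.02, NFIB = 0.02, SFN = 0.015,
                 EGR1 = 0.01, PLD5 = 0.02, LRIG3_DT = 0.015,
                 NEG_CTRL = 0.002)
  # condition-specific binding fold-changes (control == 1)
  fold <- matrix(1, nrow = 8, ncol = 3,
                 dimnames = list(names(base_plus),
                                 c("control", "tpa", "zncl2")))
  fold["ERGIC1", ] <- c(1, 0.5, 1)
  fold["NFIB", ]   <- c(1, 0.6, 1)
  fold["SFN", ]    <- c(1, 1.6, 1)
  fold["EGR1", ]   <- c(1, 1, 1.8)
  fold["PLD5", ]   <- c(1, 1, 0.7)
  fold["LRIG3_DT", ] <- c(1, 1, 0.7)
  grid$bound_plus <- base_plus[grid$target] *
    fold[cbind(grid$target, grid$condition)]
  snr <- ifelse(grid$target == "NEG_CTRL", 1, 5)
  grid$bound_minus <- grid$bound_plus / snr
  grid
}

#' Read and write pipeline configuration as YAML
#'
#' The YAML file holds two top-level blocks, `analysis` and `synthetic`,
#' whose entries override the defaults of [analysis_config()] and
#' [synth_config()].
#'
#' @param path File path.
#' @return `read_config()` returns `list(analysis =, synthetic =)`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  analysis <- do.call(analysis_config, raw$analysis %||% list())
  synth_args <- raw$synthetic %||% list()
  if (!is.null(synth_args$qpcr$targets)) {
    synth_args$qpcr$targets <- as.data.frame(synth_args$qpcr$targets)
  }
  synthetic <- do.call(synth_config, synth_args)
  list(analysis = analysis, synthetic = synthetic)
}

#' @rdname read_config
#' @param config List with `analysis` and `synthetic` entries.
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.data.frame(v)) as.list(v) else v)
  }
  yaml::write_yaml(list(analysis = strip(config$analysis),
                        synthetic = strip(config$synthetic)), path)
  invisible(path)
}
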