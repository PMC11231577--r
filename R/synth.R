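#' Simulate a genome with non-overlapping accessible regions
#'
#' Draws an i.i.d. base sequence at the configured GC fraction (C and G
#' equally likely, likewise A and T) and places `n_regions`
#' non-overlapping regions of `region_length` bp uniformly at random on a
#' single chromosome `"chrS"`, recorded 0-based half-open. Placement
#' retries a bounded number of times and fails explicitly if the regions
#' cannot be placed.
#'
#' @param cfg A [synth_config()].
#' @return List: `genome` (named character vector), `regions`
#'   (`region_set` with unique names).
#' @export
make_genome <- function(cfg) {
  if (cfg$genome_length < cfg$n_regions * cfg$region_length) {
    stop("genome_length too small for the requested regions")
  }
  set.seed(derive_seed(cfg$seed, "genome"))
  p_gc <- cfg$gc_fraction
  probs <- c(A = (1 - p_gc) / 2, C = p_gc / 2, G = p_gc / 2,
             T = (1 - p_gc) / 2)
  seq <- paste(sample(DNA_BASES, cfg$genome_length, replace = TRUE,
                      prob = probs), collapse = "")
  genome <- stats::setNames(seq, "chrS")

  n <- cfg$n_regions
  L <- cfg$region_length
  starts <- place_disjoint(cfg$genome_length, n, L, max_tries = 200L)
  regions <- region_set(rep("chrS", n), starts, starts + L,
                        name = sprintf("region_%05d", seq_len(n)))
  list(genome = genome, regions = regions)
}

# Uniform placement of n disjoint intervals of width L on [0, glen):
# distribute the slack among the n+1 gaps via sorted uniform draws, an
# exchangeable disjoint placement in one shot (book-ended intervals can
# occur and are still disjoint under half-open coordinates).
place_disjoint <- function(glen, n, L, max_tries = 200L) {
  slack <- glen - n * L
  if (slack < 0) {
    stop("could not place ", n, " disjoint regions of width ", L,
         " on a genome of length ", glen)
  }
  cuts <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  cuts + (seq_len(n) - 1L) * L
}

#' Generate synthetic position probability matrices
#'
#' Draws `n_motifs` sharp PPMs of width `motif_width`: each column puts
#' probability 0.97 on a uniformly drawn consensus base and 0.01 on each
#' alternative. The motif named by `planted_motif_id` is the one later
#' planted into regions; the rest act as decoys.
#'
#' @param cfg A [synth_config()].
#' @return Named list of [pwm()] objects.
#' @export
synth_pwms <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "pwm"))
  ids <- c(cfg$planted_motif_id,
           sprintf("M_DECOY_%02d", seq_len(cfg$n_motifs - 1L)))
  out <- list()
  for (id in ids) {
    cons <- sample.int(4L, cfg$motif_width, replace = TRUE)
    m <- matrix(0.01, nrow = 4, ncol = cfg$motif_width,
                dimnames = list(DNA_BASES, NULL))
    m[cbind(cons, seq_len(cfg$motif_width))] <- 0.97
    out[[id]] <- pwm(id, m)
  }
  out
}

#' Plant motif instances into regions
#'
#' In a seeded random subset of `ceiling(plant_fraction * n)` regions, a
#' sequence sampled from the PPM replaces the genome bases at a uniformly
#' drawn offset within the region, on a random strand (minus-strand
#' instances are inserted as the reverse complement). The returned truth
#' table records region, offset, strand and the planted sequence.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param regions A `region_set`.
#' @param p A [pwm()] to plant.
#' @param plant_fraction Fraction of regions receiving one instance.
#' @param seed Integer seed.
#' @return List: `genome` (modified), `truth` (data frame: `region_id`,
#'   `chrom`, `genomic_start`, `offset_in_region`, `strand`, `sequence`).
#' @export
plant_motifs <- function(genome, regions, p, plant_fraction, seed = 1L) {
  regions <- as_region_set(regions)
  W <- pwm_width(p)
  if (any(regions$end - regions$start < W)) {
    stop("motif width exceeds region length")
  }
  n_plant <- ceiling(plant_fraction * nrow(regions))
  truth <- data.frame(region_id = character(0), chrom = character(0),
                      genomic_start = integer(0),
                      offset_in_region = integer(0),
                      strand = character(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  if (n_plant == 0) return(list(genome = genome, truth = truth))
  set.seed(seed)
  chosen <- sort(sample.int(nrow(regions), n_plant))
  probs <- p$mat
  seqs <- vapply(seq_len(n_plant), function(i) {
    paste(vapply(seq_len(W), function(k) {
      sample(DNA_BASES, 1, prob = probs[, k])
    }, ""), collapse = "")
  }, "")
  offs <- vapply(chosen, function(i) {
    len <- regions$end[i] - regions$start[i]
    sample.int(len - W + 1L, 1) - 1L
  }, 0L)
  strands <- sample(c("+", "-"), n_plant, replace = TRUE)
  for (i in seq_len(n_plant)) {
    ri <- chosen[i]
    chrom <- regions$chrom[ri]
    gstart <- regions$start[ri] + offs[i]
    ins <- if (strands[i] == "-") revcomp_seq(seqs[i]) else seqs[i]
    substr(genome[[chrom]], gstart + 1L, gstart + W) <- ins
  }
  truth <- data.frame(region_id = regions$name[chosen],
                      chrom = regions$chrom[chosen],
                      genomic_start = regions$start[chosen] + offs,
                      offset_in_region = offs,
                      strand = strands, sequence = seqs,
                      stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

revcomp_seq <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate region counts for two conditions
#'
#' Counts are negative binomial with `Var = mu + alpha * mu^2`
#' (`size = 1/alpha`); motif-bearing regions (rows of the planting truth
#' table) have their treatment mean multiplied by `2^effect_log2fc`.
#' Per-sample depth factors are drawn log-normally and recorded as truth.
#'
#' @param regions A `region_set`.
#' @param truth Planting truth table (may have zero rows).
#' @param cfg A [synth_config()].
#' @return List: `cm` (a [count_matrix()]), `truth` (data frame of
#'   per-sample depth factors), `effect_regions` (region ids carrying the
#'   planted effect).
#' @export
simulate_counts <- function(regions, truth, cfg) {
  if (cfg$nb_mean < 0) stop("nb_mean must be non-negative")
  if (cfg$n_replicates < 2) stop("need >= 2 replicates per condition")
  regions <- as_region_set(regions)
  set.seed(derive_seed(cfg$seed, "counts"))
  n <- nrow(regions)
  reps <- cfg$n_replicates
  samples <- c(sprintf("ctrl_%d", seq_len(reps)),
               sprintf("treat_%d", seq_len(reps)))
  conditions <- rep(c("control", "treatment"), each = reps)
  depth <- exp(stats::rnorm(2 * reps, 0, cfg$depth_log_sd))
  has_motif <- regions$name %in% truth$region_id
  mu_c <- rep(cfg$nb_mean, n)
  mu_t <- ifelse(has_motif, cfg$nb_mean * 2^cfg$effect_log2fc, cfg$nb_mean)
  k <- matrix(0L, n, 2 * reps, dimnames = list(regions$name, samples))
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
  for (j in seq_len(2 * reps)) {
    mu <- if (conditions[j] == "control") mu_c else mu_t
    k[, j] <- if (is.finite(size)) {
      stats::rnbinom(n, mu = mu * depth[j], size = size)
    } else {
      stats::rpois(n, lambda = mu * depth[j])
    }
  }
  list(cm = count_matrix(k, conditions),
       truth = data.frame(sample_id = samples, condition = conditions,
                          depth_factor = depth, stringsAsFactors = FALSE),
       effect_regions = regions$name[has_motif])
}

#' Simulate FRET sensor traces
#'
#' Emits per-cell donor/acceptor channel intensities (with recorded
#' backgrounds) over four annotated phases. In the rest and treatment
#' phases the true ratio follows the forward Hill model
#' `R = (r_min + r_max * u) / (1 + u)` with `u = (Zn / Kd)^n`; the
#' chelation phase holds the sensor fully apo (`R = r_min`) and the
#' saturation phase fully bound (`R = r_max`), mirroring the in situ
#' calibration's assumption of complete chelation and saturation. Channel
#' intensities are emitted so that the background-corrected ratio equals
#' the true ratio plus Gaussian noise of SD `noise_sd`.
#'
#' @param cfg A [synth_config()] (`fret` block).
#' @return List: `traces` (data frame: `cell_id`, `time_s`, `phase`,
#'   `donor`, `acceptor`, `donor_bg`, `acceptor_bg`), `truth` (per-phase
#'   true Zn2+ and ratios).
#' @export
simulate_fret <- function(cfg) {
  f <- cfg$fret
  if (f$r_max <= f$r_min) stop("r_max must exceed r_min")
  set.seed(derive_seed(cfg$seed, "fret"))
  phases <- c("rest", "treatment", "chelation", "saturation")
  R_true <- c(
    rest = hill_forward_ratio(f$zn_rest_nM, f$kd_nM, f$hill_n,
                              f$r_min, f$r_max),
    treatment = hill_forward_ratio(f$zn_treatment_nM, f$kd_nM, f$hill_n,
                                   f$r_min, f$r_max),
    chelation = f$r_min,
    saturation = f$r_max
  )
  nf <- f$frames_per_phase
  n_time <- length(phases) * nf
  rows <- lapply(seq_len(f$n_cells), function(cell) {
    ratio <- rep(R_true, each = nf) +
      stats::rnorm(n_time, 0, f$noise_sd)
    donor_corr <- rep(f$donor_level, n_time)
    data.frame(
      cell_id = sprintf("cell_%03d", cell),
      time_s = seq_len(n_time) * f$dt_s,
      phase = rep(phases, each = nf),
      donor = donor_corr + f$background_level,
      acceptor = ratio * donor_corr + f$background_level,
      donor_bg = f$background_level,
      acceptor_bg = f$background_level,
      stringsAsFactors = FALSE
    )
  })
  truth <- data.frame(phase = phases, ratio_true = unname(R_true),
                      zn_true_nM = c(f$zn_rest_nM, f$zn_treatment_nM,
                                     0, Inf),
                      stringsAsFactors = FALSE)
  list(traces = do.call(rbind, rows), truth = truth)
}

#' Simulate a ChIP-qPCR plate
#'
#' Generates Ct values from the log-linear amplification model
#' `Ct = intercept + slope * log10(quantity) + noise` for the input
#' dilution series (1, 1:10, 1:100, 1:1,000), the +Ab and -Ab IP samples
#' and a no-template control, per target, condition and biological
#' replicate, in technical duplicate. Quantities are expressed relative to
#' the undiluted input of the same sample; the IP quantity incorporates
#' the chromatin/eluate volume accounting so that the analysis pipeline
#' recovers `%IP = 100 * bound_fraction` exactly at zero noise.
#'
#' @param cfg A [synth_config()] (`qpcr` block).
#' @return List: `plate` (well table with a `volumes` attribute), `truth`
#'   (per target x condition x replicate true percent input).
#' @export
simulate_qpcr <- function(cfg) {
  qc <- cfg$qpcr
  set.seed(derive_seed(cfg$seed, "qpcr"))
  v <- qc$volumes
  ip_scale <- (v$vol_chromatin_for_chip / v$vol_chip_eluate) *
    (v$vol_input_eluate / v$vol_chromatin_as_input)
  wells <- list()
  truths <- list()
  well_no <- 0L
  for (i in seq_len(nrow(qc$targets))) {
    tg <- qc$targets$target[i]
    cond <- qc$targets$condition[i]
    for (rep_i in seq_len(qc$n_bio_replicates)) {
      add_well <- function(sample_class, dilution, q_rel) {
        nt <- qc$n_tech_replicates
        ct <- rep(NA_real_, nt)
        if (!is.na(q_rel)) {
          ct <- qc$ct_intercept + qc$ct_slope * log10(q_rel) +
            stats::rnorm(nt, 0, qc$ct_noise_sd)
        }
        ids <- well_no + seq_len(nt)
        well_no <<- well_no + nt
        wells[[length(wells) + 1L]] <<- data.frame(
          well = sprintf("W%05d", ids),
          target = tg, condition = cond, sample_class = sample_class,
          dilution_factor = dilution, bio_rep = rep_i,
          tech_rep = seq_len(nt), ct = ct,
          stringsAsFactors = FALSE)
      }
      for (d in qc$dilution_factors) add_well("input_dilution", d, 1 / d)
      f_plus <- qc$targets$bound_plus[i]
      f_minus <- qc$targets$bound_minus[i]
      add_well("ip_plus_ab", 1, f_plus * ip_scale)
      add_well("ip_minus_ab", 1, f_minus * ip_scale)
      add_well("ntc", 1, NA)
      truths[[length(truths) + 1L]] <- data.frame(
        target = tg, condition = cond, bio_rep = rep_i,
        percent_ip_plus_true = 100 * f_plus,
        percent_ip_minus_true = 100 * f_minus,
        stringsAsFactors = FALSE)
    }
  }
  plate <- do.call(rbind, wells)
  rownames(plate) <- NULL
  attr(plate, "volumes") <- v
  list(plate = plate, truth = do.call(rbind, truths))
}

#' Simulate a gene annotation
#'
#' Places `n_genes` non-overlapping gene bodies (5-20 kb) with random
#' strands on the synthetic chromosome, providing the TSS annotation used
#' for promoter/genic/nongenic stratification. Plumbing for the pipeline
#' demo, not a model of real gene architecture.
#'
#' @param cfg A [synth_config()].
#' @param n_genes Number of genes (default: one per ~40 kb).
#' @return Data frame: `gene_id`, `chrom`, `tx_start`, `tx_end`, `strand`.
#' @export
synth_genes <- function(cfg, n_genes = max(10L, cfg$genome_length %/% 40000L)) {
  set.seed(derive_seed(cfg$seed, "genes"))
  lens <- sample(5000:20000, n_genes, replace = TRUE)
  max_len <- max(lens)
  starts <- place_disjoint(cfg$genome_length, n_genes, max_len)
  data.frame(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
             chrom = "chrS",
             tx_start = starts,
             tx_end = starts + lens,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Write synthetic datasets to disk
#'
#' FASTA genome via Biostrings; BED6 regions; TSV counts, truth tables,
#' FRET traces and qPCR plates. All writers produce byte-identical output
#' for identical inputs.
#'
#' @param genome Named character vector of sequences.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*", "", names(out))
  out
}

#' @rdname write_genome_fasta
#' @param cm A [count_matrix()].
#' @export
write_counts_tsv <- function(cm, path) {
  df <- data.frame(region_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
  cond_path <- sub("(\\.tsv)?$", ".conditions.tsv", path)
  write_tsv_file(data.frame(sample_id = colnames(cm$counts),
                            condition = cm$conditions), cond_path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv_file(path)
  cond <- read_tsv_file(sub("(\\.tsv)?$", ".conditions.tsv", path))
  k <- as.matrix(df[, -1, drop = FALSE])
  rownames(k) <- df$region_id
  count_matrix(k, cond$condition[match(colnames(k), cond$sample_id)])
}
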