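DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrices
#'
#' A PWM is a position probability matrix over A/C/G/T together with a
#' 0-order background model and a pseudocount. Scores are log-odds in bits:
#' `sum_k log2(P_k(b_k) / pi_{b_k})`, computed after adding the pseudocount
#' to every matrix entry and renormalizing columns, so no base scores
#' `-Inf` (windows containing `N` do, and are never reported as hits).
#'
#' @param motif_id Motif identifier.
#' @param mat 4 x W numeric matrix (rows A, C, G, T); columns must sum to 1
#'   within 1e-6.
#' @param background Named background frequencies for A, C, G, T; must sum
#'   to 1.
#' @param pseudocount Added to every matrix entry before log-odds; default
#'   1e-4.
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, mat, background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                pseudocount = 1e-4) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM matrix must have 4 rows (A, C, G, T)")
  dimnames(mat) <- list(DNA_BASES, NULL)
  csums <- colSums(mat)
  if (any(abs(csums - 1) > 1e-6)) {
    stop("PWM columns must each sum to 1 (max deviation ",
         format(max(abs(csums - 1))), ")")
  }
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  background <- background[DNA_BASES]
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  if (any(background <= 0)) stop("background frequencies must be positive")
  structure(list(motif_id = motif_id, mat = mat,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$motif_id, "width", ncol(x$mat),
      "consensus", pwm_consensus(x), "\n")
  invisible(x)
}

pwm_width <- function(p) ncol(p$mat)

#' @rdname pwm
#' @param p A `pwm`.
#' @export
pwm_consensus <- function(p) {
  paste(DNA_BASES[apply(p$mat, 2, which.max)], collapse = "")
}

# Pseudocounted probability matrix (columns renormalized).
pwm_probs <- function(p) {
  m <- p$mat + p$pseudocount
  sweep(m, 2, colSums(m), "/")
}

# Log-odds score matrix in bits.
pwm_score_matrix <- function(p) {
  log2(pwm_probs(p) / p$background)
}

#' Reverse complement of a PWM
#'
#' Columns reversed, A/T and C/G rows swapped; scanning a sequence with
#' `revcomp_pwm(p)` is equivalent to scanning the reverse complement of the
#' sequence with `p`.
#'
#' @param p A `pwm`.
#' @return A `pwm`.
#' @export
revcomp_pwm <- function(p) {
  m <- p$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(p$mat))), drop = FALSE]
  rownames(m) <- DNA_BASES
  bg <- p$background[c("T", "G", "C", "A")]
  names(bg) <- DNA_BASES
  pwm(p$motif_id, m, background = bg, pseudocount = p$pseudocount)
}

set_pwm_background <- function(p, background) {
  pwm(p$motif_id, p$mat, background = background,
      pseudocount = p$pseudocount)
}

#' Score one sequence window against a PWM
#'
#' @param p A `pwm`.
#' @param seq Character string of length equal to the motif width, over
#'   A/C/G/T/N.
#' @return Log-odds score in bits; `-Inf` if the window contains `N`.
#' @export
score_window <- function(p, seq) {
  bases <- strsplit(toupper(seq), "")[[1]]
  if (length(bases) != pwm_width(p)) {
    stop("sequence length ", length(bases), " does not match motif width ",
         pwm_width(p))
  }
  idx <- match(bases, DNA_BASES)
  if (anyNA(idx)) {
    if (!all(bases[is.na(idx)] == "N")) stop("sequence contains non-ACGTN base")
    return(-Inf)
  }
  sm <- pwm_score_matrix(p)
  sum(sm[cbind(idx, seq_along(idx))])
}

#' Exact PWM score null distribution and p-values
#'
#' Discretizes the per-column log-odds scores to integer multiples of
#' `precision` bits and convolves the per-column score distributions under
#' the background model by dynamic programming, yielding the exact survival
#' function `P(score >= s | background)` on the discretized score lattice.
#' Scanning uses the same quantized matrix, so hit scores and p-values are
#' mutually consistent; the quantization error of any window score is at
#' most `W * precision / 2` bits.
#'
#' @param p A `pwm`.
#' @param precision Score bin width in bits (default 0.01).
#' @return An object of class `pwm_pvalue_table` with the integer score
#'   matrix, the lattice origin, and the survival function.
#' @export
pvalue_table <- function(p, precision = 0.01) {
  stopifnot_scalar_number(precision, "precision", positive = TRUE)
  B <- round(pwm_score_matrix(p) / precision)   # 4 x W integer bins
  storage.mode(B) <- "integer"
  W <- ncol(B)
  bg <- p$background
  min_tot <- sum(apply(B, 2, min))
  max_tot <- sum(apply(B, 2, max))
  width <- as.integer(max_tot - min_tot + 1)
  # dist[i] = P(partial score == min_partial + i - 1)
  dist <- 1
  min_partial <- 0
  for (k in seq_len(W)) {
    col <- B[, k]
    lo <- min(col)
    new_len <- length(dist) + (max(col) - lo)
    acc <- numeric(new_len)
    for (b in 1:4) {
      sh <- col[b] - lo
      acc[(1 + sh):(length(dist) + sh)] <-
        acc[(1 + sh):(length(dist) + sh)] + dist * bg[b]
    }
    dist <- acc
    min_partial <- min_partial + lo
  }
  stopifnot(length(dist) == width, min_partial == min_tot)
  surv <- rev(cumsum(rev(dist)))
  surv <- pmin(surv, 1)
  structure(list(motif_id = p$motif_id, precision = precision,
                 score_int = B, min_total = min_tot, max_total = max_tot,
                 density = dist, survival = surv),
            class = "pwm_pvalue_table")
}

#' Look up exact p-values for scores
#'
#' @param tab A [pvalue_table()].
#' @param score_bits Numeric scores in bits (quantized or continuous; they
#'   are snapped to the table's lattice).
#' @return `P(score >= s)` under the background model; `NA` for non-finite
#'   scores.
#' @export
pvalue_lookup <- function(tab, score_bits) {
  s_int <- round(score_bits / tab$precision)
  p <- rep(NA_real_, length(s_int))
  fin <- is.finite(s_int)
  idx <- pmax(1, pmin(length(tab$survival),
                      s_int[fin] - tab$min_total + 1))
  p[fin] <- ifelse(s_int[fin] > tab$max_total, 0, tab$survival[idx])
  p[fin][s_int[fin] < tab$min_total] <- 1
  p
}

# map an ASCII-coded sequence to base codes 1..4, N/other -> 5
encode_bases <- function(seq_string) {
  lut <- rep(5L, 256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt(seq_string)]
}

# Sentinel for N bases: far below any attainable quantized score, yet
# W * N_SENTINEL stays well inside integer range for realistic widths.
N_SENTINEL <- -1000000L

# quantized score at every start position of `codes` (5 = N, never a hit)
scan_scores <- function(codes, B) {
  M5 <- rbind(B, rep(N_SENTINEL, ncol(B)))
  storage.mode(M5) <- "integer"
  .scan_scores_int(codes, M5)
}

#' Estimate 0-order background frequencies from a genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @return Named frequency vector over A, C, G, T (N ignored).
#' @export
genome_background <- function(genome) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in genome) {
    code <- encode_bases(s)
    tab <- tabulate(code, nbins = 5)
    counts <- counts + tab[1:4]
  }
  if (sum(counts) == 0) stop("genome contains no A/C/G/T bases")
  counts / sum(counts)
}

#' Scan regions for motif occurrences
#'
#' FIMO-style double-stranded scan of the +/-1,500 bp window (configurable)
#' around each region center. Both strands are scanned by scoring the
#' forward sequence with the PWM and its reverse complement; every position
#' with exact p-value at or below the cutoff is reported. Windows are
#' clipped at chromosome ends. Unless an explicit background is supplied,
#' the 0-order background is estimated from the scanned genome.
#'
#' @param genome Named character vector of chromosome sequences (or a
#'   single unnamed sequence, taken as chromosome `"chrS"`).
#' @param regions A `region_set`; names must be unique region ids.
#' @param pwms List of [pwm()] objects.
#' @param cfg An [analysis_config()] (`scan_window_halfwidth`,
#'   `fimo_p_cutoff`, `score_precision`).
#' @param background Optional named background frequencies; default:
#'   estimated from `genome`.
#' @return List with `hits` (data frame: region_id, motif_id, offset,
#'   strand, score_bits, p_value), `indicator` (regions x motifs logical
#'   matrix: any passing hit), and `best` (best hit per region/motif:
#'   lowest p, then smallest |offset|, then + strand).
#' @export
scan_regions <- function(genome, regions, pwms, cfg = analysis_config(),
                         background = NULL) {
  genome <- normalize_genome(genome)
  regions <- as_region_set(regions)
  if (anyDuplicated(regions$name)) stop("region names must be unique ids")
  if (is.null(names(pwms))) names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
  if (is.null(background)) background <- genome_background(genome)
  hw <- cfg$scan_window_halfwidth
  prec <- cfg$score_precision

  chrom_len <- vapply(genome, nchar, 0L)
  bad <- !regions$chrom %in% names(genome)
  if (any(bad)) stop("regions on chromosomes absent from genome")
  centers <- region_center(regions)
  if (any(centers < 0 | centers >= chrom_len[regions$chrom])) {
    stop("region center off-chromosome")
  }

  codes_by_chrom <- lapply(genome, encode_bases)
  wstart <- pmax(0L, centers - hw)
  wend <- pmin(as.integer(chrom_len[regions$chrom]), centers + hw + 1L)
  wlen <- wend - wstart

  max_w <- max(vapply(pwms, pwm_width, 0L))
  sep <- rep(5L, max_w)
  chunks <- vector("list", 2L * nrow(regions))
  for (i in seq_len(nrow(regions))) {
    chunks[[2L * i - 1L]] <-
      codes_by_chrom[[regions$chrom[i]]][(wstart[i] + 1L):wend[i]]
    chunks[[2L * i]] <- sep
  }
  cat_codes <- unlist(chunks, use.names = FALSE)
  win_offset <- cumsum(c(0L, wlen[-length(wlen)] + max_w))  # 0-based offsets

  n_reg <- nrow(regions)
  indicator <- matrix(FALSE, n_reg, length(pwms),
                      dimnames = list(regions$name, names(pwms)))
  hit_list <- list()
  best_list <- list()

  for (m in seq_along(pwms)) {
    pw <- set_pwm_background(pwms[[m]], background)
    W <- pwm_width(pw)
    tab <- pvalue_table(pw, precision = prec)
    # reverse-complement scoring matrix: row-swapped, column-reversed copy
    # of the forward matrix, so both strands share one score lattice and
    # one null distribution
    B_rc <- tab$score_int[c(4:1), rev(seq_len(W)), drop = FALSE]
    # survival is monotone, so "p <= cutoff" is "score >= threshold"
    thr_i <- which(tab$survival <= cfg$fimo_p_cutoff)
    thr <- if (length(thr_i)) tab$min_total + thr_i[1] - 1L else Inf
    valid_lens <- pmax(0L, wlen - W + 1L)
    starts <- sequence(valid_lens) + rep(win_offset, valid_lens)  # 1-based
    reg_of <- rep(seq_len(n_reg), valid_lens)

    for (strand in c("+", "-")) {
      B <- if (strand == "+") tab$score_int else B_rc
      S <- scan_scores(cat_codes, B)[starts]
      pass <- which(S >= thr)
      if (!length(pass)) next
      ri <- reg_of[pass]
      genomic_start <- wstart[ri] + (starts[pass] - 1L) - win_offset[ri]
      hit_list[[length(hit_list) + 1L]] <- data.frame(
        region_id = regions$name[ri],
        motif_id = names(pwms)[m],
        offset = as.integer(genomic_start - centers[ri]),
        strand = strand,
        score_bits = S[pass] * prec,
        p_value = tab$survival[S[pass] - tab$min_total + 1L],
        stringsAsFactors = FALSE
      )
      indicator[cbind(ri, m)] <- TRUE
    }
  }

  hits <- if (length(hit_list)) {
    do.call(rbind, hit_list)
  } else {
    data.frame(region_id = character(0), motif_id = character(0),
               offset = integer(0), strand = character(0),
               score_bits = numeric(0), p_value = numeric(0))
  }
  if (nrow(hits)) {
    ord <- order(hits$region_id, hits$motif_id, hits$p_value,
                 abs(hits$offset), hits$strand)
    hs <- hits[ord, , drop = FALSE]
    best <- hs[!duplicated(hs[c("region_id", "motif_id")]), , drop = FALSE]
    rownames(best) <- NULL
  } else {
    best <- hits
  }
  list(hits = hits, indicator = indicator, best = best)
}

normalize_genome <- function(genome) {
  if (is.list(genome) && !is.null(genome$seq)) {
    out <- genome$seq
    names(out) <- genome$name %||% "chrS"
    return(out)
  }
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- "chrS"
    return(genome)
  }
  stop("unsupported genome representation")
}

#' Read and write motifs in MEME minimal format
#'
#' Supports the letter-probability-matrix blocks of MEME's minimal motif
#' format, plus an optional `Background letter frequencies` line.
#'
#' @param path File path.
#' @param pseudocount Pseudocount attached to the returned PWMs.
#' @return `read_meme()` returns a named list of [pwm()] objects.
#' @export
read_meme <- function(path, pseudocount = 1e-4) {
  if (!file.exists(path)) stop("MEME file not found: ", path)
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), 2)])
    names(vals) <- toks[seq(1, length(toks), 2)]
    bg <- vals[DNA_BASES]
  }
  motif_i <- grep("^MOTIF", lines)
  if (!length(motif_i)) stop("no MOTIF blocks found in ", path)
  out <- list()
  for (mi in motif_i) {
    id <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    lp <- grep("^letter-probability matrix", lines)
    lp <- lp[lp > mi][1]
    if (is.na(lp)) stop("motif ", id, ": missing letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[lp]))
    rows <- lines[(lp + 1):(lp + w)]
    m <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }, numeric(4)))
    out[[id]] <- pwm(id, t(m), background = bg, pseudocount = pseudocount)
  }
  out
}

#' @rdname read_meme
#' @param pwms Named list of [pwm()] objects.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies"), con)
  bg <- pwms[[1]]$background
  writeLines(sprintf("A %.6f C %.6f G %.6f T %.6f",
                     bg["A"], bg["C"], bg["G"], bg["T"]), con)
  for (p in pwms) {
    writeLines(c("", paste("MOTIF", p$motif_id),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         pwm_width(p))), con)
    writeLines(apply(p$mat, 2, function(col) {
      sprintf(" %.8f %.8f %.8f %.8f", col[1], col[2], col[3], col[4])
    }), con)
  }
  invisible(path)
}

#' Read and write motifs as a plain TSV matrix dialect
#'
#' Long-format TSV with columns `motif_id`, `position` (1-based), `A`,
#' `C`, `G`, `T`.
#'
#' @param path File path.
#' @param pseudocount Pseudocount attached to the returned PWMs.
#' @return `read_pwm_tsv()` returns a named list of [pwm()] objects.
#' @export
read_pwm_tsv <- function(path, pseudocount = 1e-4) {
  df <- read_tsv_file(path)
  stopifnot(all(c("motif_id", "position", DNA_BASES) %in% names(df)))
  out <- list()
  for (id in unique(df$motif_id)) {
    d <- df[df$motif_id == id, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    out[[id]] <- pwm(id, t(as.matrix(d[DNA_BASES])),
                     pseudocount = pseudocount)
  }
  out
}

#' @rdname read_pwm_tsv
#' @param pwms Named list of [pwm()] objects.
#' @export
write_pwm_tsv <- function(pwms, path) {
  rows <- lapply(pwms, function(p) {
    data.frame(motif_id = p$motif_id, position = seq_len(pwm_width(p)),
               t(p$mat), stringsAsFactors = FALSE)
  })
  write_tsv_file(do.call(rbind, rows), path)
}
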