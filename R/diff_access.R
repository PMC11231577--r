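#' Count matrix for differential accessibility
#'
#' Integer region-by-sample counts with a condition label per sample.
#'
#' @param counts Integer matrix, regions x samples; rownames are region
#'   ids, colnames sample ids.
#' @param conditions Character vector (one per sample); one level must be
#'   the reference (control) condition.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, conditions) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("region_%05d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%02d", seq_len(ncol(counts)))
  }
  if (length(conditions) != ncol(counts)) {
    stop("one condition label per sample required")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, conditions = as.character(conditions)),
            class = "count_matrix")
}

#' Count fragments into regions by midpoint
#'
#' A fragment is assigned to a region iff its midpoint
#' (`floor((start + end)/2)`) lies within the region; each fragment is
#' assigned at most once (to the first containing region in sort order
#' when regions overlap).
#'
#' @param fragments,regions `region_set` objects.
#' @return Integer vector of counts, one per region (in `regions` order).
#' @export
count_fragments <- function(fragments, regions) {
  fragments <- as_region_set(fragments)
  regions <- as_region_set(regions)
  out <- integer(nrow(regions))
  if (nrow(fragments) == 0 || nrow(regions) == 0) return(out)
  mids <- region_center(fragments)
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    fi <- which(fragments$chrom == chr)
    if (!length(fi)) next
    mir <- IRanges::IRanges(start = mids[fi] + 1L, width = 1L)
    rir <- regions_to_iranges(regions[ri, , drop = FALSE])
    ov <- IRanges::findOverlaps(mir, rir, select = "first")
    tab <- table(ov[!is.na(ov)])
    out[ri[as.integer(names(tab))]] <- out[ri[as.integer(names(tab))]] +
      as.integer(tab)
  }
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over regions (with
#' all-positive counts) of the ratio of the sample's count to the
#' geometric mean across samples, rescaled so the factors have geometric
#' mean 1.
#'
#' @param cm A [count_matrix()] or plain counts matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(cm) {
  k <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  pos <- rowSums(k > 0) == ncol(k)
  if (!any(pos)) {
    stop("no region has all-positive counts; filter low-count regions first")
  }
  lg <- log(k[pos, , drop = FALSE])
  loggeo <- rowMeans(lg)
  s <- apply(lg, 2, function(col) exp(stats::median(col - loggeo)))
  s <- s / exp(mean(log(s)))
  names(s) <- colnames(k)
  s
}

#' Simplified negative-binomial Wald test for differential accessibility
#'
#' A defined, testable stand-in for a DESeq2-style analysis (numerical
#' parity with DESeq2 is a non-goal): counts are normalized by
#' median-of-ratios size factors; the log2 fold-change is
#' `log2((mu_t + 0.5) / (mu_c + 0.5))` on group means of normalized counts;
#' a per-region dispersion `alpha` is estimated by method of moments pooled
#' across both groups (floored at 1e-8); the standard error follows from
#' the delta method under `Var(y) = mu + alpha mu^2`; and the Wald
#' statistic is referred to a Student-t distribution with
#' `n_c + n_t - 2` degrees of freedom (the plug-in dispersion makes the
#' normal reference anticonservative at typical replicate numbers; the t
#' reference restores nominal type-I error, see the methods vignette).
#' The signed ranking statistic `sign(log2FC) * (-log10 p)` orders regions
#' for motif enrichment.
#'
#' @param cm A [count_matrix()].
#' @param reference Name of the control condition (default `"control"`);
#'   the other condition is the treatment.
#' @param treatment Optional treatment label when `cm` holds more than two
#'   conditions.
#' @return Data frame (one row per region): `region_id`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`,
#'   `signed_rank_stat`, `zero_group` flag.
#' @export
nb_wald_test <- function(cm, reference = "control", treatment = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  conds <- cm$conditions
  if (!reference %in% conds) stop("reference condition '", reference,
                                  "' not present")
  others <- setdiff(unique(conds), reference)
  if (is.null(treatment)) {
    if (length(others) != 1) {
      stop("specify `treatment` when more than two conditions are present")
    }
    treatment <- others
  }
  sel <- conds %in% c(reference, treatment)
  k <- cm$counts[, sel, drop = FALSE]
  grp <- conds[sel]
  if (sum(grp == reference) < 2 || sum(grp == treatment) < 2) {
    stop("at least 2 replicates per condition required")
  }
  # median-of-ratios needs a region observed in every sample; degenerate
  # matrices (e.g. an all-zero condition) fall back to library-size
  # factors so zero-group regions can still be reported, flagged
  s <- tryCatch(size_factors(k), error = function(e) {
    tot <- colSums(k)
    tot[tot == 0] <- 1
    tot / exp(mean(log(tot)))
  })
  y <- sweep(k, 2, s, "/")
  yc <- y[, grp == reference, drop = FALSE]
  yt <- y[, grp == treatment, drop = FALSE]
  nc <- ncol(yc); nt <- ncol(yt)
  mc <- rowMeans(yc); mt <- rowMeans(yt)
  c0 <- 0.5
  # pseudocount engaged only when a group mean is zero: keeps zero-count
  # groups finite while leaving the fold-change exactly scale-invariant
  # (an always-on absolute pseudocount breaks invariance to the overall
  # rescaling induced by geometric-mean-1 size factors)
  zero_group <- (mc == 0) | (mt == 0)
  l2fc <- ifelse(zero_group, log2((mt + c0) / (mc + c0)), log2(mt / mc))

  vc <- apply(yc, 1, stats::var)
  vt <- apply(yt, 1, stats::var)
  num <- (nc - 1) * (vc - mc) + (nt - 1) * (vt - mt)
  den <- (nc - 1) * mc^2 + (nt - 1) * mt^2
  alpha <- ifelse(den > 0, pmax(num / den, 1e-8), 1e-8)

  vlog2 <- function(m, n) {
    (m + alpha * m^2) / (n * pmax(m, c0)^2 * log(2)^2)
  }
  se <- sqrt(vlog2(mc, nc) + vlog2(mt, nt))
  stat <- ifelse(se > 0, l2fc / se, 0)
  df <- nc + nt - 2
  pvalue <- ifelse(se > 0, 2 * stats::pt(-abs(stat), df), 1)
  padj <- bh_adjust(pvalue)
  mlp <- -log10(pmax(pvalue, .Machine$double.xmin))
  data.frame(
    region_id = rownames(k),
    baseMean = rowMeans(y),
    log2FoldChange = l2fc,
    lfcSE = se,
    stat = stat,
    pvalue = pvalue,
    padj = padj,
    signed_rank_stat = sign(l2fc) * mlp,
    zero_group = zero_group,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#' `NA`/`NaN` p-values are propagated and excluded from the number of
#' tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
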