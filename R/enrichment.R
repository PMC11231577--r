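#' Rank regions by differential accessibility
#'
#' Orders regions by the signed ranking statistic
#' `sign(log2FC) * (-log10 p)` in decreasing order (most
#' treatment-increased first), after optional filtering to an annotation
#' stratum. Ties are broken deterministically by region id.
#'
#' @param diff A [nb_wald_test()] result data frame.
#' @param labels Optional character vector of annotation labels (from
#'   [annotate_regions()]), aligned with `diff` rows; required for
#'   `stratum != "all"`.
#' @param stratum One of `"all"`, `"promoter"`, `"nongenic"` (or
#'   `"genic"`).
#' @return Data frame of class `ranked_regions` with columns `region_id`,
#'   `signed_rank_stat`, `rank`, plus the stratum label.
#' @export
rank_regions <- function(diff, labels = NULL, stratum = "all") {
  stopifnot(all(c("region_id", "signed_rank_stat") %in% names(diff)))
  keep <- rep(TRUE, nrow(diff))
  if (stratum != "all") {
    if (is.null(labels)) stop("labels required for stratum '", stratum, "'")
    if (length(labels) != nrow(diff)) {
      stop("labels must align with diff rows")
    }
    keep <- labels == stratum
  }
  d <- diff[keep, , drop = FALSE]
  if (nrow(d) == 0) stop("stratum '", stratum, "' contains no regions")
  ord <- order(-d$signed_rank_stat, d$region_id)
  out <- data.frame(region_id = d$region_id[ord],
                    signed_rank_stat = d$signed_rank_stat[ord],
                    rank = seq_len(nrow(d)),
                    stringsAsFactors = FALSE)
  attr(out, "stratum") <- stratum
  class(out) <- c("ranked_regions", "data.frame")
  out
}

#' Motif enrichment score over a ranked region list
#'
#' With `N` regions ranked 1..N (most treatment-increased first) and motif
#' hits at ranks `r_1..r_H`, the enrichment score is
#' `E = 1 - 2 * mean((r_h - 0.5) / N)`, a rescaled Mann-Whitney statistic
#' in (-1, 1). Positive E means the motif's hit regions concentrate among
#' regions that gain accessibility under treatment; E is exactly negated
#' when the ranking is reversed. A motif hitting every region or none is
#' uninformative and returns `E = 0` with a flag.
#'
#' @param hits Logical vector in ranked order (`TRUE` = region carries at
#'   least one passing motif hit).
#' @return List: `e_score`, `n_hit`, `uninformative`.
#' @export
e_score <- function(hits) {
  stopifnot(is.logical(hits))
  N <- length(hits)
  H <- sum(hits)
  if (H == 0 || H == N) {
    return(list(e_score = 0, n_hit = H, uninformative = TRUE))
  }
  r <- which(hits)
  # 1 - 2 * mean((r - 0.5)/N) via the integer rank sum: the numerator is
  # exactly negated under rank reversal, making antisymmetry bitwise exact
  e <- (N * H + H - 2 * sum(r)) / (N * H)
  list(e_score = e, n_hit = H, uninformative = FALSE)
}

#' Permutation p-value for an enrichment score
#'
#' Hit labels are permuted uniformly over ranks; the two-sided p-value is
#' `(1 + #\{|E_perm| >= |E_obs|\}) / (n_permutations + 1)`. A normal
#' approximation to the rank-sum null (mean 0, exact finite-sample
#' variance `(N - H)(N + 1) / (3 H N^2)`) is reported alongside as
#' `p_normal`.
#'
#' @param hits Logical vector in ranked order.
#' @param n_permutations Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return List: `p_value`, `p_normal`, `e_score`, `n_hit`,
#'   `uninformative`.
#' @export
permutation_p <- function(hits, n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  obs <- e_score(hits)
  N <- length(hits)
  H <- obs$n_hit
  if (obs$uninformative) {
    return(list(p_value = 1, p_normal = 1, e_score = 0, n_hit = H,
                uninformative = TRUE))
  }
  set.seed(seed)
  # E depends on hit ranks only through their mean, so permuting labels
  # reduces to drawing H ranks without replacement
  e_perm <- vapply(seq_len(n_permutations), function(i) {
    (N * H + H - 2 * sum(sample.int(N, H))) / (N * H)
  }, 0)
  p <- (1 + sum(abs(e_perm) >= abs(obs$e_score) - 1e-12)) /
    (n_permutations + 1)
  var_e <- (N - H) * (N + 1) / (3 * H * N^2)
  z <- obs$e_score / sqrt(var_e)
  list(p_value = p, p_normal = 2 * stats::pnorm(-abs(z)),
       e_score = obs$e_score, n_hit = H, uninformative = FALSE)
}

#' Quartile barcode of motif hits
#'
#' Partitions the ranked list into four contiguous blocks (sizes differing
#' by at most one; earlier quartiles take the extra regions) and counts
#' hits per block, summarizing where along the accessibility ranking a
#' motif's occurrences fall.
#'
#' @param hits Logical vector in ranked order, length >= 4.
#' @return Integer vector `c(Q1, Q2, Q3, Q4)`; sums to the number of hit
#'   regions.
#' @export
barcode <- function(hits) {
  N <- length(hits)
  if (N < 4) stop("barcode requires at least 4 ranked regions")
  sizes <- rep(N %/% 4L, 4L)
  extra <- N %% 4L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block <- rep(1:4, sizes)
  out <- vapply(1:4, function(q) sum(hits[block == q]), 0L)
  names(out) <- c("Q1", "Q2", "Q3", "Q4")
  out
}

#' Run motif enrichment across strata
#'
#' For each stratum (`all`, `promoter`, `nongenic`) and each motif:
#' regions are ranked by signed differential-accessibility significance,
#' the E-score is computed from the motif's hit indicator, a permutation
#' p-value (with fixed seed per motif) is attached, p-values are
#' BH-adjusted across motifs within the stratum, and the quartile barcode
#' is recorded.
#'
#' @param diff A [nb_wald_test()] result.
#' @param labels Annotation labels aligned with `diff` rows (may be `NULL`
#'   to run only the `"all"` stratum).
#' @param hit_table Logical regions x motifs indicator matrix from
#'   [scan_regions()]; rownames must cover `diff$region_id`.
#' @param cfg An [analysis_config()] (`n_permutations`, `seed`).
#' @param strata Strata to evaluate.
#' @return Data frame: `motif_id`, `stratum`, `n_regions`, `n_hit_regions`,
#'   `e_score`, `p_value`, `p_normal`, `padj`, `uninformative`,
#'   `q1..q4`.
#' @export
run_enrichment <- function(diff, labels, hit_table,
                           cfg = analysis_config(),
                           strata = c("all", "promoter", "nongenic")) {
  if (is.null(labels)) strata <- "all"
  missing_regions <- setdiff(diff$region_id, rownames(hit_table))
  if (length(missing_regions)) {
    stop("hit_table lacks rows for ", length(missing_regions), " regions")
  }
  res <- list()
  base_seed <- derive_seed(cfg$seed, "permutation")
  for (stratum in strata) {
    n_in <- if (stratum == "all") nrow(diff) else sum(labels == stratum)
    if (n_in < 4) {
      warning("stratum '", stratum, "' has ", n_in,
              " regions; skipped", call. = FALSE)
      next
    }
    ranked <- rank_regions(diff, labels, stratum)
    rows <- lapply(seq_len(ncol(hit_table)), function(m) {
      motif <- colnames(hit_table)[m]
      hits <- hit_table[ranked$region_id, m]
      pp <- permutation_p(hits, cfg$n_permutations,
                          seed = (base_seed + m) %% .Machine$integer.max)
      bc <- barcode(hits)
      data.frame(motif_id = motif, stratum = stratum,
                 n_regions = nrow(ranked), n_hit_regions = pp$n_hit,
                 e_score = pp$e_score, p_value = pp$p_value,
                 p_normal = pp$p_normal, uninformative = pp$uninformative,
                 q1 = bc[1], q2 = bc[2], q3 = bc[3], q4 = bc[4],
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$padj <- bh_adjust(tab$p_value)
    res[[stratum]] <- tab[order(tab$padj, tab$p_value, tab$motif_id), ]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[c("motif_id", "stratum", "n_regions", "n_hit_regions", "e_score",
        "p_value", "p_normal", "padj", "uninformative",
        "q1", "q2", "q3", "q4")]
}
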