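# Brute-force oracles and fixture builders. Oracles deliberately use
# naive O(n*m) or exhaustive algorithms, independent of the package's
# implementation paths.

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 2000,
                           max_len = 80) {
  starts <- sample.int(max_pos, n, replace = TRUE) - 1L
  lens <- sample.int(max_len, n, replace = TRUE)
  region_set(sample(chroms, n, replace = TRUE), starts, starts + lens,
             name = sprintf("r%04d", seq_len(n)))
}

# union-merge via explicit base coverage (book-ended intervals become
# contiguous coverage automatically)
brute_merge <- function(rs) {
  out <- list()
  for (chr in sort(unique(rs$chrom))) {
    d <- rs[rs$chrom == chr, , drop = FALSE]
    cov <- logical(max(d$end) + 1)
    for (i in seq_len(nrow(d))) cov[(d$start[i] + 1):d$end[i]] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[chr]] <- data.frame(chrom = chr, start = starts[keep],
                               end = ends[keep])
    }
  }
  do.call(rbind, unname(out))
}

brute_subtract <- function(a, b) {
  keep <- rep(TRUE, nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        keep[i] <- FALSE
      }
    }
  }
  a[keep, , drop = FALSE]
}

brute_intersect_fraction <- function(a, b, min_frac) {
  keep <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(a))) {
    bases <- a$start[i]:(a$end[i] - 1)
    covered <- rep(FALSE, length(bases))
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j]) {
        covered <- covered | (bases >= b$start[j] & bases < b$end[j])
      }
    }
    keep[i] <- sum(covered) >= min_frac * length(bases)
  }
  a[keep, , drop = FALSE]
}

# definition-based BH step-up
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, p[ord[i]] * m / i)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- adj
  out
}

# exhaustive PWM null: survival function over all 4^W words under the
# background, evaluated on the quantized score lattice
brute_pwm_survival <- function(p, precision) {
  sm <- zincatac::pvalue_table(p, precision)$score_int
  W <- ncol(sm)
  bg <- p$background
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  scores <- integer(nrow(words))
  probs <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    scores[i] <- sum(sm[cbind(words[i, ], seq_len(W))])
    probs[i] <- prod(bg[words[i, ]])
  }
  function(s_int) sum(probs[scores >= s_int])
}

# exact permutation null of the enrichment score by full enumeration of
# hit placements
enum_permutation_p <- function(hits) {
  N <- length(hits)
  H <- sum(hits)
  e_of <- function(r) 1 - 2 * mean((r - 0.5) / N)
  obs <- e_of(which(hits))
  placements <- utils::combn(N, H)
  e_all <- apply(placements, 2, e_of)
  mean(abs(e_all) >= abs(obs) - 1e-12)
}

# tiny consensus-style PWM builder
sharp_pwm <- function(consensus, p_max = 0.97, id = "test") {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p_max) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- p_max
  pwm(id, m)
}

random_pwm <- function(W, id = "rand") {
  m <- matrix(stats::rgamma(4 * W, 1), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  pwm(id, m)
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
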