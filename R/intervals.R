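#' Genomic region sets
#'
#' Regions are stored as a data frame with BED-like columns `chrom`,
#' `start`, `end`, `name`, `score`, `strand` in 0-based half-open
#' coordinates (`start` inclusive, `end` exclusive). `region_set()` builds
#' one from vectors; `as_region_set()` validates, sorts by
#' (chrom, start, end) and drops exact duplicate
#' (chrom, start, end, strand) rows.
#'
#' @param chrom Character chromosome names.
#' @param start,end Integer 0-based half-open coordinates, `start < end`.
#' @param name,score,strand Optional BED6 columns; defaults `"."`, `0`,
#'   `"."`.
#' @return A data frame of class `region_set`.
#' @export
region_set <- function(chrom, start, end, name = NULL, score = NULL,
                       strand = NULL) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = if (is.null(name)) rep(".", n) else as.character(name),
    score = if (is.null(score)) rep(0, n) else as.numeric(score),
    strand = if (is.null(strand)) rep(".", n) else as.character(strand),
    stringsAsFactors = FALSE
  )
  as_region_set(df)
}

#' @rdname region_set
#' @param df Data frame with at least `chrom`, `start`, `end` columns.
#' @export
as_region_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nrow(df) > 0) {
    if (any(!is.finite(df$start)) || any(!is.finite(df$end))) {
      stop("non-numeric region coordinates")
    }
    if (any(df$start < 0)) stop("region start must be >= 0")
    if (any(df$start >= df$end)) stop("region start must be < end")
  }
  if (is.null(df$name)) df$name <- rep(".", nrow(df))
  if (is.null(df$score)) df$score <- rep(0, nrow(df))
  if (is.null(df$strand)) df$strand <- rep(".", nrow(df))
  bad <- !df$strand %in% c("+", "-", ".")
  if (any(bad)) stop("strand must be one of '+', '-', '.'")
  df <- df[!duplicated(df[c("chrom", "start", "end", "strand")]), , drop = FALSE]
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

# 0-based half-open [start, end)  <->  1-based closed IRanges [start+1, end]
regions_to_iranges <- function(rs) {
  IRanges::IRanges(start = rs$start + 1L, end = rs$end)
}

#' Read and write BED files
#'
#' Minimal BED3/BED6 I/O in 0-based half-open coordinates. `read_bed()`
#' rejects malformed lines with an error naming the line number;
#' `write_bed()` always emits six columns so that read-after-write is the
#' identity on canonical BED6.
#'
#' @param path File path.
#' @return `read_bed()` returns a `region_set`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(#|track|browser)", lines)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(region_set(character(0), integer(0), integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) stop("BED line ", i, ": fewer than 3 columns")
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) stop("BED line ", i, ": non-integer coordinates")
    if (s >= e) stop("BED line ", i, ": start (", s, ") must be < end (",
                     e, ")")
    if (s < 0) stop("BED line ", i, ": negative start")
  }
  get <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, "")
  }
  region_set(
    chrom = get(1, "."),
    start = as.integer(get(2, "0")),
    end = as.integer(get(3, "0")),
    name = get(4, "."),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = get(6, ".")
  )
}

#' @rdname read_bed
#' @param regions A `region_set`.
#' @export
write_bed <- function(regions, path) {
  regions <- as_region_set(regions)
  out <- data.frame(regions$chrom, regions$start, regions$end,
                    regions$name, regions$score, regions$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge region sets into disjoint regions
#'
#' Takes the union of one or more region sets and coalesces overlapping or
#' book-ended (abutting) intervals on the same chromosome, mirroring how
#' accessible-chromatin peaks from several treatments are combined into
#' regions of interest before counting and scanning. Merged regions carry
#' fresh names and no strand.
#'
#' @param sets A `region_set` or list of them.
#' @return A disjoint, sorted `region_set`.
#' @export
merge_regions <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  if (length(sets) < 1) stop("merge_regions needs at least one region set")
  all <- do.call(rbind, lapply(sets, function(s) {
    as_region_set(s)[c("chrom", "start", "end")]
  }))
  if (nrow(all) == 0) {
    return(region_set(character(0), integer(0), integer(0)))
  }
  pieces <- lapply(split(all, all$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  region_set(out$chrom, out$start, out$end,
             name = sprintf("region_%05d", seq_len(nrow(out))))
}

#' Remove regions overlapping a blacklist
#'
#' Any region overlapping any blacklist interval by at least one base is
#' removed entirely (no trimming), matching the removal of peaks that fall
#' in blacklisted genomic regions.
#'
#' @param regions,blacklist `region_set` objects.
#' @return The retained subset of `regions`.
#' @export
subtract_blacklist <- function(regions, blacklist) {
  regions <- as_region_set(regions)
  blacklist <- as_region_set(blacklist)
  if (nrow(regions) == 0 || nrow(blacklist) == 0) return(regions)
  drop <- rep(FALSE, nrow(regions))
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    bl <- blacklist[blacklist$chrom == chr, , drop = FALSE]
    if (nrow(bl) == 0) next
    hit <- IRanges::overlapsAny(regions_to_iranges(regions[ri, ]),
                                regions_to_iranges(bl))
    drop[ri] <- hit
  }
  out <- regions[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain regions covered by another set at a minimum fraction
#'
#' Keeps each interval of `a` whose total overlap with the union of `b`
#' covers at least `min_frac` of the `a`-interval's length, and returns the
#' retained `a` intervals unmodified. This realizes the "-F 0.5"-style
#' filter used to retain ChIP peaks that overlap transcribed regions by at
#' least 50%; the fraction is taken relative to the `a` (ChIP peak)
#' interval.
#'
#' @param a Query `region_set` (e.g., ChIP peaks).
#' @param b Subject `region_set` (e.g., transcribed regions).
#' @param min_frac Minimum covered fraction of each `a` interval, in (0, 1].
#' @param fraction_of Which interval the fraction refers to: `"a"` (the
#'   prose reading, default) or `"b"` (bedtools' -F convention, where the
#'   fraction applies to each b interval and an a interval is retained if
#'   any single b interval is covered at `min_frac` by the overlap).
#' @return The retained subset of `a`.
#' @export
intersect_fraction <- function(a, b, min_frac, fraction_of = c("a", "b")) {
  fraction_of <- match.arg(fraction_of)
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1) {
    stop("min_frac must be in (0, 1]")
  }
  a <- as_region_set(a)
  b <- as_region_set(b)
  if (nrow(a) == 0) return(a)
  keep <- rep(FALSE, nrow(a))
  for (chr in unique(a$chrom)) {
    ai <- which(a$chrom == chr)
    bc <- b[b$chrom == chr, , drop = FALSE]
    if (nrow(bc) == 0) next
    air <- regions_to_iranges(a[ai, , drop = FALSE])
    if (fraction_of == "a") {
      bir <- IRanges::reduce(regions_to_iranges(bc))
      ov <- IRanges::findOverlaps(air, bir)
      if (length(ov) == 0) next
      w <- IRanges::width(IRanges::pintersect(
        air[S4Vectors::queryHits(ov)], bir[S4Vectors::subjectHits(ov)]))
      covered <- tapply(w, S4Vectors::queryHits(ov), sum)
      idx <- as.integer(names(covered))
      keep[ai[idx]] <- covered >= min_frac * IRanges::width(air[idx])
    } else {
      bir <- regions_to_iranges(bc)
      ov <- IRanges::findOverlaps(air, bir)
      if (length(ov) == 0) next
      w <- IRanges::width(IRanges::pintersect(
        air[S4Vectors::queryHits(ov)], bir[S4Vectors::subjectHits(ov)]))
      ok <- w >= min_frac * IRanges::width(bir[S4Vectors::subjectHits(ov)])
      keep[ai[unique(S4Vectors::queryHits(ov)[ok])]] <- TRUE
    }
  }
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label regions as promoter, genic or nongenic
#'
#' The promoter of a gene on the + strand is the `promoter_length` bases
#' directly upstream of its transcription start
#' (`[tx_start - L, tx_start)`, clipped at 0); on the - strand it is
#' `[tx_end, tx_end + L)`. A region overlapping any promoter is labeled
#' `"promoter"`; otherwise, overlapping any gene body makes it `"genic"`;
#' everything else is `"nongenic"` (the distal regulatory stratum).
#'
#' @param regions A `region_set`.
#' @param genes Data frame with columns `gene_id`, `chrom`, `tx_start`,
#'   `tx_end`, `strand` (0-based half-open, strand in `+`/`-`).
#' @param cfg An [analysis_config()]; `promoter_length` is used.
#' @return Character vector of labels, one per region (in `regions` order).
#' @export
annotate_regions <- function(regions, genes, cfg = analysis_config()) {
  regions <- as_region_set(regions)
  stopifnot(all(c("chrom", "tx_start", "tx_end", "strand") %in% names(genes)))
  if (any(!genes$strand %in% c("+", "-"))) stop("genes must be stranded")
  if (any(genes$tx_start >= genes$tx_end)) stop("gene tx_start must be < tx_end")
  L <- cfg$promoter_length
  prom_start <- ifelse(genes$strand == "+",
                       pmax(0L, genes$tx_start - L), genes$tx_end)
  prom_end <- ifelse(genes$strand == "+",
                     genes$tx_start, genes$tx_end + L)
  ok <- prom_start < prom_end
  promoters <- data.frame(chrom = genes$chrom[ok],
                          start = prom_start[ok], end = prom_end[ok])
  bodies <- data.frame(chrom = genes$chrom, start = genes$tx_start,
                       end = genes$tx_end)
  overlaps_set <- function(set) {
    hit <- rep(FALSE, nrow(regions))
    if (nrow(set) == 0) return(hit)
    for (chr in unique(regions$chrom)) {
      ri <- which(regions$chrom == chr)
      sc <- set[set$chrom == chr, , drop = FALSE]
      if (nrow(sc) == 0) next
      hit[ri] <- IRanges::overlapsAny(
        regions_to_iranges(regions[ri, , drop = FALSE]),
        IRanges::IRanges(start = sc$start + 1L, end = sc$end))
    }
    hit
  }
  in_prom <- overlaps_set(promoters)
  in_gene <- overlaps_set(bodies)
  ifelse(in_prom, "promoter", ifelse(in_gene, "genic", "nongenic"))
}

#' Region center
#'
#' Center base of an interval, `floor((start + end) / 2)`, the anchor for
#' the +/-1,500 bp motif scan window.
#'
#' @param regions A `region_set` (or data frame with `start`, `end`).
#' @return Integer vector of center coordinates.
#' @export
region_center <- function(regions) {
  as.integer((regions$start + regions$end) %/% 2L)
}
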