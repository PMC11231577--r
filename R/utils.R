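# Internal helpers shared across modules.

# Deterministic fan-out of one user-facing seed into per-stage child seeds.
# Each generator stage seeds its own RNG stream so that, e.g., regenerating
# FRET traces does not perturb the count simulation. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(
    genome = 101L, plant = 211L, counts = 307L, fret = 401L,
    qpcr = 503L, permutation = 601L, genes = 701L, chip = 809L,
    pwm = 907L
  )
  if (!stage %in% names(offsets)) {
    stop("unknown seed stage: ", stage)
  }
  (as.integer(seed) %% 2096000L) * 1000L + offsets[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a single finite number")
  }
  if (positive && x <= 0) stop(name, " must be positive")
  invisible(x)
}

# Write a data.frame as a TSV with stable formatting (deterministic bytes
# for a given input, required for manifest hash reproducibility).
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
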