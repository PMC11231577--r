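#' Average technical replicates of qPCR Ct values
#'
#' Ct values are averaged arithmetically within each well group (target x
#' condition x sample class x dilution x biological replicate).
#' Undetermined Cts (`NA`) are excluded; a group with no determined Ct is
#' flagged undetermined, and partially determined groups raise a warning.
#'
#' @param plate Plate data frame with columns `target`, `condition`,
#'   `sample_class`, `dilution_factor`, `bio_rep`, `tech_rep`, `ct`.
#' @return Data frame with one row per well group and columns `ct`
#'   (mean of determined Cts) and `n_determined`.
#' @export
average_technical_replicates <- function(plate) {
  req <- c("target", "condition", "sample_class", "dilution_factor",
           "bio_rep", "ct")
  stopifnot(all(req %in% names(plate)))
  key <- interaction(plate$target, plate$condition, plate$sample_class,
                     plate$dilution_factor, plate$bio_rep, drop = TRUE)
  pieces <- lapply(split(plate, key), function(d) {
    cts <- d$ct[!is.na(d$ct)]
    if (length(cts) < nrow(d) && length(cts) > 0) {
      warning("well group ", d$target[1], "/", d$sample_class[1],
              ": some technical replicates undetermined", call. = FALSE)
    }
    data.frame(target = d$target[1], condition = d$condition[1],
               sample_class = d$sample_class[1],
               dilution_factor = d$dilution_factor[1],
               bio_rep = d$bio_rep[1],
               ct = if (length(cts)) mean(cts) else NA_real_,
               n_determined = length(cts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Fit a qPCR input standard curve
#'
#' Least-squares regression of Ct against `log10(relative quantity)`,
#' where the relative quantity of an input dilution is
#' `1 / dilution_factor` (undiluted input = 1). Returns slope, intercept,
#' R-squared, and amplification efficiency `10^(-1/slope) - 1` (1.0 for
#' perfect doubling, slope -3.3219).
#'
#' @param input_wells Averaged input wells for one target (columns
#'   `dilution_factor`, `ct`), at >= 3 distinct dilution levels.
#' @return List of class `std_curve`: `slope`, `intercept`, `r_squared`,
#'   `efficiency`.
#' @export
fit_standard_curve <- function(input_wells) {
  d <- input_wells[!is.na(input_wells$ct), , drop = FALSE]
  if (length(unique(d$dilution_factor)) < 3) {
    stop("standard curve needs >= 3 distinct dilution levels with ",
         "determined Ct")
  }
  x <- log10(1 / d$dilution_factor)
  fit <- stats::lm(ct ~ x, data = data.frame(ct = d$ct, x = x))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("standard curve slope must be negative; plate flagged")
  }
  ss_tot <- sum((d$ct - mean(d$ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "std_curve")
}

#' Absolute (dilution-relative) quantity from a Ct value
#'
#' `q = 10^((Ct - intercept) / slope)`, on the scale where the undiluted
#' input of the same sample has quantity 1.
#'
#' @param ct Numeric Ct values.
#' @param curve A [fit_standard_curve()] result.
#' @return Numeric quantities.
#' @export
absolute_quantity <- function(ct, curve) {
  10^((ct - curve$intercept) / curve$slope)
}

#' Percent input (%IP)
#'
#' Scales the IP and input quantities to their total eluates and to the
#' chromatin volumes they represent before taking the ratio:
#' `%IP = 100 * (q_ip * vol_chip_eluate / vol_chromatin_for_chip) /
#' (q_input * vol_input_eluate / vol_chromatin_as_input)`.
#'
#' @param q_ip,q_input Quantities (same relative scale) of the IP sample
#'   and the undiluted input.
#' @param volumes Named list with `vol_chip_eluate`, `vol_input_eluate`,
#'   `vol_chromatin_for_chip`, `vol_chromatin_as_input` (same units).
#' @return Percent input; `NA` (flagged by warning) when `q_input` is 0.
#' @export
percent_ip <- function(q_ip, q_input, volumes) {
  v <- volumes
  req <- c("vol_chip_eluate", "vol_input_eluate", "vol_chromatin_for_chip",
           "vol_chromatin_as_input")
  stopifnot(all(req %in% names(v)))
  if (any(unlist(v[req]) <= 0)) stop("volumes must be positive")
  out <- ifelse(q_input > 0,
                100 * (q_ip * v$vol_chip_eluate / v$vol_chromatin_for_chip) /
                  (q_input * v$vol_input_eluate / v$vol_chromatin_as_input),
                NA_real_)
  if (anyNA(out)) warning("zero input quantity: %IP undefined", call. = FALSE)
  out
}

#' Quantify a ChIP-qPCR plate
#'
#' Full per-plate analysis: technical replicates are averaged; a standard
#' curve is fit per target x condition x biological replicate from its
#' input dilution series; +Ab and -Ab IP quantities are interpolated and
#' converted to percent input with volume accounting.
#'
#' @param plate Plate table (schema of [simulate_qpcr()]).
#' @param volumes Named volume list (see [percent_ip()]); defaults to the
#'   plate's `volumes` attribute if present.
#' @return Data frame with one row per target x condition x bio_rep:
#'   `percent_ip_plus`, `percent_ip_minus`, `snr`, and the standard-curve
#'   `slope`, `efficiency`, `r_squared`.
#' @export
quantify_plate <- function(plate, volumes = attr(plate, "volumes")) {
  if (is.null(volumes)) stop("volumes metadata required")
  avg <- average_technical_replicates(plate)
  key <- interaction(avg$target, avg$condition, avg$bio_rep, drop = TRUE)
  rows <- lapply(split(avg, key), function(d) {
    inputs <- d[d$sample_class == "input_dilution", , drop = FALSE]
    curve <- fit_standard_curve(inputs)
    get_q <- function(cls) {
      ct <- d$ct[d$sample_class == cls]
      if (!length(ct) || is.na(ct[1])) return(NA_real_)
      absolute_quantity(ct[1], curve)
    }
    q_plus <- get_q("ip_plus_ab")
    q_minus <- get_q("ip_minus_ab")
    ip_plus <- percent_ip(q_plus, 1, volumes)
    ip_minus <- percent_ip(q_minus, 1, volumes)
    data.frame(target = d$target[1], condition = d$condition[1],
               bio_rep = d$bio_rep[1],
               percent_ip_plus = ip_plus, percent_ip_minus = ip_minus,
               snr = ifelse(is.na(ip_minus) || ip_minus <= 0, NA_real_,
                            ip_plus / ip_minus),
               slope = curve$slope, efficiency = curve$efficiency,
               r_squared = curve$r_squared, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$target, out$condition, out$bio_rep), ]
  rownames(out) <- NULL
  out
}

#' Signal-to-noise and fold enrichment summaries
#'
#' Per target and condition: SNR is the +Ab percent input divided by the
#' -Ab (beads only) percent input; fold enrichment divides each treated
#' replicate's +Ab percent input by the matched control replicate's (so
#' the control condition is identically 1). Enrichment ratios are screened
#' with Tukey's IQR outlier rule and compared against the reference SNR
#' line (default 1.5).
#'
#' @param quants Output of [quantify_plate()].
#' @param control Name of the control condition.
#' @param cfg An [analysis_config()] (`snr_reference`).
#' @return List with `per_replicate` (adds `fold_enrichment` and
#'   `outlier`) and `summary` (per target x condition means:
#'   `percent_ip_plus`, `percent_ip_minus`, `snr`, `mean_fold_enrichment`,
#'   `snr_above_reference`, `n_outliers`).
#' @export
snr_and_enrichment <- function(quants, control = "control",
                               cfg = analysis_config()) {
  if (!control %in% quants$condition) stop("missing control condition")
  q <- quants
  q$fold_enrichment <- NA_real_
  for (tg in unique(q$target)) {
    ctrl <- q[q$target == tg & q$condition == control, , drop = FALSE]
    for (i in which(q$target == tg)) {
      match_rep <- ctrl$percent_ip_plus[ctrl$bio_rep == q$bio_rep[i]]
      if (length(match_rep) == 1 && !is.na(match_rep) && match_rep > 0) {
        q$fold_enrichment[i] <- q$percent_ip_plus[i] / match_rep
      }
    }
  }
  q$outlier <- FALSE
  for (key in unique(paste(q$target, q$condition))) {
    idx <- which(paste(q$target, q$condition) == key)
    vals <- q$fold_enrichment[idx]
    flags <- iqr_outliers(vals[!is.na(vals)])
    q$outlier[idx[!is.na(vals)]] <- flags
  }
  agg <- lapply(split(q, interaction(q$target, q$condition, drop = TRUE)),
                function(d) {
    data.frame(target = d$target[1], condition = d$condition[1],
               percent_ip_plus = mean(d$percent_ip_plus, na.rm = TRUE),
               percent_ip_minus = mean(d$percent_ip_minus, na.rm = TRUE),
               snr = mean(d$snr, na.rm = TRUE),
               mean_fold_enrichment = mean(d$fold_enrichment, na.rm = TRUE),
               n_outliers = sum(d$outlier),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, agg)
  summary$snr_above_reference <- summary$snr > cfg$snr_reference
  summary <- summary[order(summary$target, summary$condition), ]
  rownames(summary) <- NULL
  list(per_replicate = q, summary = summary)
}

#' Tukey IQR outlier flags
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with quartiles by
#' the linear-interpolation method (R's default, type 7). Values are
#' flagged, never dropped. Fewer than 4 values: nothing is flagged and a
#' warning is raised.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return Logical vector of flags, aligned with `values`.
#' @export
iqr_outliers <- function(values, k = 1.5) {
  if (length(values) < 4) {
    warning("fewer than 4 values: outlier test not run", call. = FALSE)
    return(rep(FALSE, length(values)))
  }
  qs <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  values < qs[1] - k * iqr | values > qs[2] + k * iqr
}
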