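#' FRET sensor calibration parameters
#'
#' Constants for converting a background-corrected FRET ratio into a
#' labile Zn2+ concentration via the Hill-form calibration
#' `[Zn2+] = Kd * ((R - Rmin) / (Rmax - R))^(1/n)`. Defaults are the
#' nuclear sensor's published constants, `Kd' = 5.3` nM and Hill
#' coefficient `n = 0.29`. `R_min`/`R_max` are normally extracted per cell
#' from the chelation and saturation phases of an in situ calibration;
#' supply them here only to bypass per-cell extraction.
#'
#' The default censoring threshold `eps_low` (on `u = (R - Rmin)/(Rmax - R)`)
#' is chosen so that the quantification floor is ~1 pM: concentrations at
#' or below 0.001 nM are reported as `below_range`. `eps_high` censors
#' ratios within a small fraction of `R_max`, where the inversion diverges.
#'
#' @param kd_nM Apparent dissociation constant, nM.
#' @param hill_n Hill coefficient.
#' @param r_min,r_max Optional fixed sensor limits.
#' @param plateau_window Frames used for per-phase plateau medians.
#' @param floor_nM Quantification floor in nM (sets `eps_low`).
#' @param eps_high Fraction of the dynamic range below `R_max` treated as
#'   saturated.
#' @return List of class `calibration_params`.
#' @export
calibration_params <- function(kd_nM = 5.3, hill_n = 0.29,
                               r_min = NULL, r_max = NULL,
                               plateau_window = 10L,
                               floor_nM = 0.001, eps_high = 0.01) {
  stopifnot_scalar_number(kd_nM, "kd_nM", positive = TRUE)
  stopifnot_scalar_number(hill_n, "hill_n", positive = TRUE)
  if (hill_n > 1) stop("hill_n must be in (0, 1]")
  if (!is.null(r_min) && !is.null(r_max) && r_max <= r_min) {
    stop("r_max must exceed r_min")
  }
  structure(list(kd_nM = kd_nM, hill_n = hill_n, r_min = r_min,
                 r_max = r_max, plateau_window = as.integer(plateau_window),
                 eps_low = (floor_nM / kd_nM)^hill_n, floor_nM = floor_nM,
                 eps_high = eps_high),
            class = "calibration_params")
}

#' Background-corrected FRET ratio
#'
#' `R = (acceptor - acceptor_bg) / (donor - donor_bg)` per timepoint.
#' Timepoints with non-positive corrected donor signal are flagged invalid
#' and excluded from plateau estimation.
#'
#' @param trace Data frame with columns `donor`, `acceptor`, `donor_bg`,
#'   `acceptor_bg` (and typically `cell_id`, `time_s`, `phase`).
#' @return The trace with added columns `ratio` and `valid`.
#' @export
fret_ratio <- function(trace) {
  stopifnot(all(c("donor", "acceptor", "donor_bg", "acceptor_bg")
                %in% names(trace)))
  d <- trace$donor - trace$donor_bg
  a <- trace$acceptor - trace$acceptor_bg
  trace$ratio <- ifelse(d > 0, a / d, NA_real_)
  trace$valid <- d > 0
  trace
}

#' Extract per-phase plateau FRET ratios for one cell
#'
#' Each phase ratio is the median of the last `plateau_window` valid
#' frames of that phase (robust to transients after solution changes). The
#' chelation phase defines `R_min`, the saturation phase `R_max`; a cell
#' is excluded (with a reason) if a calibration phase is missing or if
#' `R_max <= R_min`.
#'
#' @param trace One cell's trace (rows in time order) with columns
#'   `time_s`, `phase`, and channel columns as in [fret_ratio()].
#' @param params A [calibration_params()].
#' @return List with `R_rest`, `R_treat`, `R_min`, `R_max`, `ok`,
#'   `reason`.
#' @export
extract_phase_ratios <- function(trace, params = calibration_params()) {
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    stop("trace times must be strictly increasing")
  }
  trace <- fret_ratio(trace)
  phase_median <- function(ph) {
    r <- trace$ratio[trace$phase == ph & trace$valid]
    if (!length(r)) return(NA_real_)
    stats::median(utils::tail(r, params$plateau_window))
  }
  out <- list(R_rest = phase_median("rest"),
              R_treat = phase_median("treatment"),
              R_min = phase_median("chelation"),
              R_max = phase_median("saturation"),
              ok = TRUE, reason = "")
  if (is.na(out$R_min) || is.na(out$R_max)) {
    out$ok <- FALSE
    out$reason <- "missing calibration phase"
  } else if (out$R_max <= out$R_min) {
    out$ok <- FALSE
    out$reason <- "R_max <= R_min"
  }
  out
}

#' Convert FRET ratios to labile Zn2+ concentrations
#'
#' Inverts the Hill calibration: with `u = (R - R_min) / (R_max - R)`,
#' `[Zn2+] = Kd * u^(1/n)` in nM. Ratios at or below the quantification
#' floor (`u <= eps_low`, ~1 pM at defaults) are censored as
#' `below_range`; ratios within `eps_high` of `R_max` (where the
#' inversion diverges) as `above_range`. Censored estimates carry
#' `NA` concentrations.
#'
#' @param R Numeric vector of background-corrected ratios.
#' @param params A [calibration_params()] with `r_min`/`r_max` set (pass
#'   per-cell values from [extract_phase_ratios()]).
#' @param r_min,r_max Optional overrides of the sensor limits.
#' @return Data frame: `R`, `zn_nM`, `censor` in
#'   `{quantified, below_range, above_range}`.
#' @export
zn_concentration <- function(R, params = calibration_params(),
                             r_min = params$r_min, r_max = params$r_max) {
  if (is.null(r_min) || is.null(r_max)) {
    stop("r_min and r_max are required (per-cell calibration values)")
  }
  if (r_max <= r_min) stop("r_max must exceed r_min")
  u <- (R - r_min) / (r_max - R)
  above <- R >= r_max - params$eps_high * (r_max - r_min)
  below <- !above & (u <= params$eps_low)
  zn <- ifelse(above | below, NA_real_,
               params$kd_nM * u^(1 / params$hill_n))
  data.frame(R = R, zn_nM = zn,
             censor = ifelse(above, "above_range",
                             ifelse(below, "below_range", "quantified")),
             stringsAsFactors = FALSE)
}

#' Quantify nuclear Zn2+ for every cell in a trace table
#'
#' Runs per-cell calibration (plateau extraction of `R_min`/`R_max`) and
#' converts the rest- and treatment-phase ratios to concentrations.
#'
#' @param traces Trace table for many cells (schema of
#'   [simulate_fret()]).
#' @param params A [calibration_params()].
#' @return Data frame: `cell_id`, `phase`, `R`, `zn_nM`, `censor`,
#'   `excluded`, `reason`.
#' @export
quantify_zinc <- function(traces, params = calibration_params()) {
  rows <- lapply(split(traces, traces$cell_id), function(tr) {
    tr <- tr[order(tr$time_s), , drop = FALSE]
    ph <- extract_phase_ratios(tr, params)
    cell <- tr$cell_id[1]
    if (!ph$ok) {
      return(data.frame(cell_id = cell, phase = c("rest", "treatment"),
                        R = NA_real_, zn_nM = NA_real_,
                        censor = NA_character_, excluded = TRUE,
                        reason = ph$reason, stringsAsFactors = FALSE))
    }
    est <- zn_concentration(c(ph$R_rest, ph$R_treat), params,
                            r_min = ph$R_min, r_max = ph$R_max)
    data.frame(cell_id = cell, phase = c("rest", "treatment"),
               R = est$R, zn_nM = est$zn_nM, censor = est$censor,
               excluded = FALSE, reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Forward Hill model: ratio produced by a given Zn2+ concentration.
hill_forward_ratio <- function(zn_nM, kd_nM, hill_n, r_min, r_max) {
  u <- (zn_nM / kd_nM)^hill_n
  (r_min + r_max * u) / (1 + u)
}
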