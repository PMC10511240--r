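#' Isotope-dilution quantification of one analyte peak
#'
#' Absolute quantification by ratioing the analyte peak area to the peak
#' area of its co-injected stable-isotope-labelled standard of known
#' amount: `moles = (analyte_area / standard_area) * standard_moles /
#' response_ratio`. The response ratio is the detector response of the
#' analyte relative to the 13C standard and defaults to 1 (equimolar
#' response assumed for 13C isotopologues).
#'
#' @param analyte_area Peak area of the 12C analyte (>= 0).
#' @param standard_area Peak area of the 13C internal standard (> 0).
#' @param standard_moles Moles of internal standard co-injected (> 0); the
#'   result is returned in the same unit.
#' @param response_ratio Analyte/standard response factor (> 0, default 1).
#' @return Moles of analyte in the injected aliquot, in the unit of
#'   `standard_moles`.
#' @export
#' @examples
#' quantify_isotope_dilution(2000, 4000, 7.5)  # 3.75
quantify_isotope_dilution <- function(analyte_area, standard_area, standard_moles,
                                      response_ratio = 1) {
  if (any(standard_area <= 0)) {
    stop("no internal standard detected: standard_area must be > 0")
  }
  stopifnot(all(standard_moles > 0), all(response_ratio > 0), all(analyte_area >= 0))
  (analyte_area / standard_area) * standard_moles / response_ratio
}

#' Scale an aliquot amount to the whole extract
#'
#' Only part of the extract is spiked and injected; the amount found in the
#' aliquot is scaled by `extract_volume / aliquot_volume` to the amount in
#' the whole extract.
#'
#' @param aliquot_moles Moles in the measured aliquot.
#' @param aliquot_volume,extract_volume Volumes in the same unit, with
#'   `0 < aliquot_volume <= extract_volume`.
#' @return Moles in the whole extract.
#' @export
scale_to_extract <- function(aliquot_moles, aliquot_volume, extract_volume) {
  if (any(aliquot_volume <= 0) || any(extract_volume <= 0)) {
    stop("volumes must be positive")
  }
  if (any(aliquot_volume > extract_volume)) {
    stop("aliquot_volume must not exceed extract_volume")
  }
  aliquot_moles * extract_volume / aliquot_volume
}

#' Correct an extract amount for extraction losses
#'
#' Divides the amount found in the extract by the species' recovery
#' fraction to estimate the amount present in the cells before extraction.
#'
#' @param extract_moles Moles found in the extract.
#' @param recovery_fraction Recovery fraction in (0, 1].
#' @return Estimated pre-extraction moles.
#' @export
#' @examples
#' correct_recovery(153.26, 0.89)
correct_recovery <- function(extract_moles, recovery_fraction) {
  if (any(recovery_fraction <= 0) || any(recovery_fraction > 1)) {
    stop("recovery_fraction must lie in (0, 1]")
  }
  extract_moles / recovery_fraction
}

#' Recovery fraction from a pre-extraction spike
#'
#' The recovery of a species is determined by adding a known quantity of
#' synthetic standard to the cells before extraction and measuring how much
#' survives sample preparation.
#'
#' @param known_spiked_moles Moles spiked before extraction (> 0).
#' @param measured_moles Moles measured after extraction (>= 0).
#' @param as_percent Return percent rather than a fraction.
#' @return Recovery fraction (or percent).
#' @export
recovery_from_spike <- function(known_spiked_moles, measured_moles, as_percent = FALSE) {
  if (any(known_spiked_moles <= 0)) stop("known_spiked_moles must be > 0")
  if (any(measured_moles < 0)) stop("measured_moles must be >= 0")
  r <- measured_moles / known_spiked_moles
  if (as_percent) 100 * r else r
}

#' Per-cell amount in zeptomoles
#'
#' Normalises a total amount by the number of cells harvested. With the
#' total in femtomoles and around 1e7 cells per sample, the natural
#' per-cell unit is the zeptomole (1e-21 mol).
#'
#' @param total_fmol Total amount in femtomoles.
#' @param n_cells Number of cells harvested (> 0).
#' @return Per-cell amount in zmol (1 fmol / 1e6 cells = 1 zmol).
#' @export
per_cell_amount <- function(total_fmol, n_cells) {
  if (any(n_cells <= 0)) stop("n_cells must be > 0")
  total_fmol * 1e6 / n_cells
}

#' Cytosolic concentration from a per-cell amount
#'
#' Divides the per-cell amount by the Pi-accessible volume of the cell:
#' zmol (1e-21 mol) over fL (1e-15 L) is 1e-6 M, i.e. uM directly.
#'
#' @param zmol_per_cell Per-cell amount in zeptomoles.
#' @param volume Either a [volume_model()] or an accessible volume in fL.
#' @return Concentration in uM.
#' @export
#' @examples
#' cytosolic_concentration(17.22, volume_model())  # 0.5 uM
cytosolic_concentration <- function(zmol_per_cell, volume = volume_model()) {
  v <- if (inherits(volume, "volume_model")) volume$v_accessible_fl else volume
  if (!is.numeric(v) || any(v <= 0)) stop("accessible volume must be > 0")
  zmol_per_cell / v
}

#' Fold change of a concentration relative to a reference
#'
#' @param test_conc Concentration in the test condition.
#' @param reference_conc Reference concentration (> 0).
#' @return `test_conc / reference_conc`.
#' @export
fold_change <- function(test_conc, reference_conc) {
  if (any(reference_conc <= 0)) stop("reference_conc must be > 0")
  test_conc / reference_conc
}

#' Percent decline and percent remaining between two concentrations
#'
#' @param c0 Initial concentration (> 0).
#' @param ct Concentration at the later time (>= 0).
#' @return List with `decline_pct = 100 * (c0 - ct) / c0` and
#'   `remaining_pct = 100 * ct / c0`.
#' @export
#' @examples
#' percent_change(0.30, 0.075)$decline_pct  # 75
percent_change <- function(c0, ct) {
  if (any(c0 <= 0)) stop("c0 must be > 0")
  list(
    decline_pct   = 100 * (c0 - ct) / c0,
    remaining_pct = 100 * ct / c0
  )
}

#' Replicate summary: mean, sample sd, n
#'
#' @param values Numeric vector of replicate values (length >= 1).
#' @return List with `mean`, `sd` (n-1 denominator; 0 with `single_rep =
#'   TRUE` flag when n = 1) and `n`.
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no replicate values supplied")
  list(
    mean = mean(values),
    sd = if (n > 1) stats::sd(values) else 0,
    n = n,
    single_rep = n == 1
  )
}
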