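#' MRM transition definitions for inositol (pyro)phosphates
#'
#' Returns the multiple-reaction-monitoring transition table used to map
#' precursor/product m/z pairs plus the isotope label flag to an analyte
#' class. Defaults are the acquisition settings of the triple-quadrupole
#' method: doubly charged precursors, six heavy carbons in the internal
#' standards, hence a +3.0 m/z shift of every 13C precursor relative to its
#' 12C analyte. Dwell time, collision energy, cell-acceleration voltage and
#' polarity are carried as metadata and take no part in quantification.
#'
#' @return A data.frame with one row per monitored transition and columns
#'   `compound` (IP8/IP7/IP6), `label` ("12C" or "13C"), `precursor_mz`,
#'   `product_mz`, `dwell_ms`, `ce_v`, `cell_acc_v`, `polarity`.
#' @export
#' @examples
#' transition_table()
transition_table <- function() {
  data.frame(
    compound     = c("IP8", "IP8", "IP7", "IP7", "IP6", "IP6"),
    label        = c("13C", "12C", "13C", "12C", "13C", "12C"),
    precursor_mz = c(411.9, 408.9, 371.9, 368.9, 331.9, 328.9),
    product_mz   = c(362.9, 359.9, 322.9, 319.9, 486.9, 480.9),
    dwell_ms     = 80,
    ce_v         = c(10, 10, 10, 10, 17, 17),
    cell_acc_v   = 1,
    polarity     = "Negative",
    stringsAsFactors = FALSE
  )
}

#' Species-level recovery fractions for the TiO2 extraction
#'
#' Fraction of each species surviving perchloric-acid extraction and TiO2
#' enrichment, determined by spiking known quantities of synthetic
#' standards onto cells before extraction. Measured amounts are divided by
#' these fractions to correct extraction losses.
#'
#' @param ip7_1,ip7_5,ip8_15 Recovery fractions in (0, 1] for 1-IP7, 5-IP7
#'   and 1,5-IP8. Defaults 0.89, 0.90, 0.75.
#' @param ip6 Recovery fraction for IP6 (carried for completeness; IP6 is
#'   excluded from concentration reporting by default).
#' @return Named numeric vector of recovery fractions keyed by species.
#' @export
recovery_table <- function(ip7_1 = 0.89, ip7_5 = 0.90, ip8_15 = 0.75, ip6 = 0.90) {
  r <- c("1-IP7" = ip7_1, "5-IP7" = ip7_5, "1,5-IP8" = ip8_15, "IP6" = ip6)
  if (any(r <= 0) || any(r > 1)) {
    stop("recovery fractions must lie in (0, 1]")
  }
  r
}

#' Cell-volume model defining the Pi-accessible volume
#'
#' A soluble metabolite distributes in the cell volume minus the volume of
#' membrane-bound organelles. The nucleus is permeable to small molecules,
#' so the nuclear fraction is carried for reporting but not subtracted:
#' `V_accessible = V_cell * (1 - f_organelles)`. With the default 42 fL
#' cell, 8 % nucleus and 18 % organelles this gives 34.44 fL.
#'
#' @param v_cell_fl Mean cell volume in femtolitres (default 42).
#' @param f_nucleus Nuclear volume fraction (default 0.08; reported, not
#'   subtracted).
#' @param f_organelles Collective volume fraction of all other organelles
#'   (default 0.18; subtracted).
#' @param exclude_nucleus Set `TRUE` to also subtract the nuclear fraction,
#'   i.e. treat the nucleus as inaccessible.
#' @return An object of class `volume_model`: a list with `v_cell_fl`,
#'   `f_nucleus`, `f_organelles`, `exclude_nucleus` and the derived
#'   `v_accessible_fl`.
#' @export
#' @examples
#' volume_model()$v_accessible_fl  # 34.44
volume_model <- function(v_cell_fl = 42, f_nucleus = 0.08, f_organelles = 0.18,
                         exclude_nucleus = FALSE) {
  stopifnot(v_cell_fl > 0, f_nucleus >= 0, f_organelles >= 0)
  if (f_nucleus + f_organelles >= 1) {
    stop("compartment fractions must sum to less than 1")
  }
  f_excluded <- f_organelles + if (exclude_nucleus) f_nucleus else 0
  structure(
    list(
      v_cell_fl       = v_cell_fl,
      f_nucleus       = f_nucleus,
      f_organelles    = f_organelles,
      exclude_nucleus = exclude_nucleus,
      v_accessible_fl = v_cell_fl * (1 - f_excluded)
    ),
    class = "volume_model"
  )
}

#' @export
print.volume_model <- function(x, ...) {
  cat(sprintf(
    "Cell volume model: V_cell = %g fL, nucleus %.0f%%, organelles %.0f%% -> V_accessible = %g fL%s\n",
    x$v_cell_fl, 100 * x$f_nucleus, 100 * x$f_organelles, x$v_accessible_fl,
    if (x$exclude_nucleus) " (nucleus excluded)" else " (nucleus included)"
  ))
  invisible(x)
}

#' 13C internal-standard spike mixture
#'
#' Describes the isotopic internal-standard mixture added to each spiked
#' aliquot: per-species standard concentration and the spiked volume, from
#' which the moles co-injected with every sample follow directly.
#'
#' @param conc_um Named numeric vector of standard concentrations in uM.
#'   Defaults: 2 (1,5-IP8), 10 (5-IP7), 10 (1-IP7), 40 (IP6).
#' @param volume_ul Spiked volume in uL (default 0.75).
#' @return An object of class `spike_mix`: list with `conc_um`,
#'   `volume_ul` and derived `fmol` per species (uM * uL = pmol, x1000).
#' @export
#' @examples
#' spike_mix()$fmol  # 1500 / 7500 / 7500 / 30000 fmol
spike_mix <- function(conc_um = c("1,5-IP8" = 2, "5-IP7" = 10, "1-IP7" = 10, "IP6" = 40),
                      volume_ul = 0.75) {
  stopifnot(all(conc_um > 0), volume_ul > 0)
  structure(
    list(
      conc_um   = conc_um,
      volume_ul = volume_ul,
      fmol      = conc_um * volume_ul * 1000
    ),
    class = "spike_mix"
  )
}

# Species handled by the quantification chain, in migration order, with the
# transition compound class each one maps onto. 1-IP7 labels the
# 1/3-indistinguishable isomer: the MRM transition cannot differentiate
# pyrophosphorylation at the 1- and 3-positions of the inositol ring.
ipp_species <- function() {
  data.frame(
    species  = c("1,5-IP8", "5-IP7", "1-IP7", "IP6"),
    compound = c("IP8", "IP7", "IP7", "IP6"),
    stringsAsFactors = FALSE
  )
}

#' Default migration times of the monitored species
#'
#' Nominal capillary-electrophoresis migration times (minutes) used by the
#' synthetic generator and as reference expectations for peak assignment.
#' Only the ordering and the co-migration of each analyte with its 13C
#' standard are meaningful; absolute values are arbitrary.
#'
#' @return Named numeric vector of migration times in minutes.
#' @export
default_migration_times <- function() {
  c("1,5-IP8" = 18.0, "5-IP7" = 19.5, "1-IP7" = 20.1, "IP6" = 21.5)
}
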