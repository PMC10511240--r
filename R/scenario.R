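#' Default per-cell ground-truth amounts (zmol) by strain and timepoint
#'
#' The fixture truth table for the yeast strains and Pi-starvation
#' timepoints carried by the synthetic MRM generator. Values are per-cell
#' amounts in zeptomoles chosen so that, through the default quantification
#' chain (42 fL cell, 18 % organelle exclusion), wild-type replete cells
#' sit at 0.5 / 0.7 / 0.3 uM for 1-IP7 / 5-IP7 / 1,5-IP8, starvation
#' produces the characteristic 47 / 40 / 75 % declines at 30 min with 3 %
#' of 5-IP7 remaining at 4 h, and the mutants show their fold-changes
#' (20x 5-IP7 in vip1d, 10x 1-IP7 in ddp1d, 5x 5-IP7 in siw14d, epistatic
#' loss in kcs1d and vip1d kcs1d). IP6 is carried as a non-pyrophosphate
#' bystander analyte.
#'
#' @return Data frame with columns `strain`, `time_min`, `species`,
#'   `zmol_per_cell`.
#' @export
default_truth_table <- function() {
  row <- function(strain, time_min, ip7_1, ip7_5, ip8, ip6 = 700) {
    data.frame(
      strain = strain, time_min = time_min,
      species = c("1-IP7", "5-IP7", "1,5-IP8", "IP6"),
      zmol_per_cell = c(ip7_1, ip7_5, ip8, ip6),
      stringsAsFactors = FALSE
    )
  }
  rbind(
    row("wt",          0,  17.22,  24.11,  10.33),
    row("wt",         30,   9.127, 14.47,   2.583),
    row("wt",        240,   0,      0.723,  0),
    row("vip1d",       0,   1.0,  482.2,    2.583),
    row("kcs1d",       0,   6.89,   0,      0),
    row("ddp1d",       0, 172.2,   24.11,  10.33),
    row("siw14d",      0,  17.22, 120.55,  10.33),
    row("vip1d_kcs1d", 0,   1.0,    2.0,    0)
  )
}

#' Scenario describing one synthetic MRM experiment
#'
#' Bundles everything the MRM fixture generator needs: which strains and
#' starvation timepoints to emit, the per-cell ground-truth amounts, the
#' species-specific extraction survival fractions, the replicate noise
#' model and the sample bookkeeping (cells harvested, extract volume,
#' spiked aliquot volume, internal-standard mixture).
#'
#' @param name Scenario identifier.
#' @param strains Strain labels to include; must appear in `truth`.
#' @param timepoints Minutes since Pi withdrawal; must appear in `truth`.
#' @param truth Ground-truth table, see [default_truth_table()].
#' @param loss_factors Named per-species extraction survival fractions in
#'   (0, 1]; defaults 0.89 / 0.90 / 0.75 for 1-IP7 / 5-IP7 / 1,5-IP8.
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   lognormal replicate noise on per-cell amounts (0 = noise-free).
#' @param n_replicates Biological replicates per strain x timepoint.
#' @param n_cells Cells harvested per sample (default 1e7: 1 mL at 1e7
#'   cells/mL).
#' @param extract_volume_ul Water volume the dried extract is resuspended
#'   in (default 20).
#' @param aliquot_volume_ul Volume of extract spiked with standards and
#'   injected (default 15).
#' @param spike [spike_mix()] describing the 13C standards.
#' @param response_per_fmol Detector response factor: peak-area units per
#'   fmol, identical for 12C analytes and 13C standards.
#' @param migration_times Named nominal migration times (min).
#' @param mt_jitter_sd Migration-time jitter sd in minutes; a shared
#'   co-migration jitter per sample x species plus a smaller independent
#'   per-peak component.
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return Object of class `fixture_scenario`.
#' @export
fixture_scenario <- function(name = "wt_replete",
                             strains = "wt",
                             timepoints = 0,
                             truth = default_truth_table(),
                             loss_factors = c("1-IP7" = 0.89, "5-IP7" = 0.90,
                                              "1,5-IP8" = 0.75, "IP6" = 0.90),
                             replicate_cv = 0.15,
                             n_replicates = 4,
                             n_cells = 1e7,
                             extract_volume_ul = 20,
                             aliquot_volume_ul = 15,
                             spike = spike_mix(),
                             response_per_fmol = 10,
                             migration_times = default_migration_times(),
                             mt_jitter_sd = 0.05,
                             seed = 1L) {
  known_strains <- unique(truth$strain)
  bad <- setdiff(strains, known_strains)
  if (length(bad)) stop("unknown strain label(s): ", paste(bad, collapse = ", "))
  bad_t <- setdiff(timepoints, unique(truth$time_min))
  if (length(bad_t)) stop("unknown timepoint(s): ", paste(bad_t, collapse = ", "))
  if (any(truth$zmol_per_cell < 0)) stop("truth amounts must be >= 0")
  if (any(loss_factors <= 0) || any(loss_factors > 1)) {
    stop("loss factors must lie in (0, 1]")
  }
  stopifnot(replicate_cv >= 0, n_replicates >= 1, n_cells > 0,
            aliquot_volume_ul > 0, aliquot_volume_ul <= extract_volume_ul)
  structure(
    list(
      name = name, strains = strains, timepoints = timepoints,
      truth = truth, loss_factors = loss_factors,
      replicate_cv = replicate_cv, n_replicates = as.integer(n_replicates),
      n_cells = n_cells,
      extract_volume_ul = extract_volume_ul,
      aliquot_volume_ul = aliquot_volume_ul,
      spike = spike, response_per_fmol = response_per_fmol,
      migration_times = migration_times, mt_jitter_sd = mt_jitter_sd,
      seed = as.integer(seed)
    ),
    class = "fixture_scenario"
  )
}

#' Canned scenarios used throughout the analyses
#'
#' * `"wt_replete"` — wild type, t = 0 only, noise-free, single replicate.
#' * `"mutants_replete"` — all strains at t = 0, noise-free.
#' * `"wt_starvation"` — wild type at 0 / 30 / 240 min, noise-free.
#' * `"wt_starvation_noisy"` — same, replicate CV 0.15, n = 4.
#'
#' @param name One of the scenario names above.
#' @param seed Seed passed through to [fixture_scenario()].
#' @return A `fixture_scenario`.
#' @export
canned_scenario <- function(name = c("wt_replete", "mutants_replete",
                                     "wt_starvation", "wt_starvation_noisy"),
                            seed = 1L) {
  name <- match.arg(name)
  switch(name,
    wt_replete = fixture_scenario(
      name = name, strains = "wt", timepoints = 0,
      replicate_cv = 0, n_replicates = 1, seed = seed
    ),
    mutants_replete = fixture_scenario(
      name = name,
      strains = c("wt", "vip1d", "kcs1d", "ddp1d", "siw14d", "vip1d_kcs1d"),
      timepoints = 0, replicate_cv = 0, n_replicates = 1, seed = seed
    ),
    wt_starvation = fixture_scenario(
      name = name, strains = "wt", timepoints = c(0, 30, 240),
      replicate_cv = 0, n_replicates = 1, seed = seed
    ),
    wt_starvation_noisy = fixture_scenario(
      name = name, strains = "wt", timepoints = c(0, 30, 240),
      replicate_cv = 0.15, n_replicates = 4, seed = seed
    )
  )
}
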