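#' Generate a synthetic MRM peak table with known ground truth
#'
#' Emulates the CE-MS sample flow: each biological sample starts from the
#' scenario's per-cell ground-truth amounts, multiplied by the number of
#' cells harvested, a lognormal replicate-noise factor (biological
#' variation on the cells, so the isotope-dilution step itself stays
#' exact), the species' extraction survival fraction and the spiked
#' aliquot fraction (aliquot/extract volume). Peak areas are amounts times
#' a common detector response factor; the 13C internal-standard rows carry
#' the spike-mix amounts noise-free. Each analyte co-migrates with its 13C
#' standard: both share a per-sample, per-species migration jitter plus a
#' smaller independent per-peak component.
#'
#' @param scenario A [fixture_scenario()].
#' @return List with `peaks` (columns `sample_id`, `strain`, `time_min`,
#'   `replicate`, `precursor_mz`, `product_mz`, `migration_time_min`,
#'   `peak_area`, `label`) and `truth` (columns `strain`, `time_min`,
#'   `species`, `zmol_per_cell`, echoing the scenario truth restricted to
#'   the emitted strains/timepoints).
#' @export
#' @examples
#' fx <- generate_ms_fixture(canned_scenario("wt_replete"))
#' head(fx$peaks)
generate_ms_fixture <- function(scenario) {
  stopifnot(inherits(scenario, "fixture_scenario"))
  set.seed(scenario$seed)

  tt <- transition_table()
  sp <- ipp_species()
  species <- sp$species
  compound_of <- stats::setNames(sp$compound, sp$species)
  mz12 <- tt[tt$label == "12C", ]
  mz13 <- tt[tt$label == "13C", ]
  rownames(mz12) <- mz12$compound
  rownames(mz13) <- mz13$compound

  truth <- scenario$truth
  truth <- truth[truth$strain %in% scenario$strains &
                   truth$time_min %in% scenario$timepoints, , drop = FALSE]

  cv <- scenario$replicate_cv
  sdlog <- sqrt(log(1 + cv^2))
  aliquot_frac <- scenario$aliquot_volume_ul / scenario$extract_volume_ul

  rows <- list()
  for (strain in scenario$strains) {
    for (tp in scenario$timepoints) {
      for (rep_i in seq_len(scenario$n_replicates)) {
        sid <- sprintf("%s_t%d_r%d", strain, as.integer(tp), rep_i)
        for (s in species) {
          z <- truth$zmol_per_cell[truth$strain == strain &
                                     truth$time_min == tp &
                                     truth$species == s]
          if (!length(z)) {
            stop(sprintf("no truth amount for strain %s, species %s, t=%s",
                         strain, s, tp))
          }
          noise <- if (cv > 0) {
            exp(stats::rnorm(1, mean = -sdlog^2 / 2, sd = sdlog))
          } else 1
          total_fmol <- z * scenario$n_cells / 1e6
          loss <- scenario$loss_factors[[s]]
          aliquot_fmol <- total_fmol * noise * loss * aliquot_frac

          mt0 <- scenario$migration_times[[s]]
          shared <- stats::rnorm(1, 0, scenario$mt_jitter_sd)
          eps <- stats::rnorm(2, 0, scenario$mt_jitter_sd / 5)
          cmp <- compound_of[[s]]

          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sid, strain = strain, time_min = tp,
            replicate = rep_i,
            precursor_mz = c(mz12[cmp, "precursor_mz"], mz13[cmp, "precursor_mz"]),
            product_mz = c(mz12[cmp, "product_mz"], mz13[cmp, "product_mz"]),
            migration_time_min = mt0 + shared + eps,
            peak_area = scenario$response_per_fmol *
              c(aliquot_fmol, scenario$spike$fmol[[s]]),
            label = c("12C", "13C"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  rownames(truth) <- NULL
  list(peaks = peaks, truth = truth)
}

#' Write an MRM fixture to CSV files
#'
#' @param fixture Result of [generate_ms_fixture()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths of the written `_peaks.csv` and
#'   `_truth.csv` files.
#' @export
write_ms_fixture <- function(fixture, dir, prefix = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    peaks = file.path(dir, paste0(prefix, "_peaks.csv")),
    truth = file.path(dir, paste0(prefix, "_truth.csv"))
  )
  utils::write.csv(fixture$peaks, paths[["peaks"]], row.names = FALSE)
  utils::write.csv(fixture$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
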