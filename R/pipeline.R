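#' Configuration for the quantification pipeline
#'
#' Collects every tunable of the MRM-to-concentration chain with the
#' defaults of the reference protocol: 1e7 cells extracted, 20 uL extract
#' of which 15 uL are spiked with the 13C standard mixture, species
#' recoveries 0.89 / 0.90 / 0.75, 42 fL cells with 18 % organelle volume
#' excluded.
#'
#' @param n_cells Cells harvested per sample.
#' @param extract_volume_ul,aliquot_volume_ul Extract and spiked-aliquot
#'   volumes (uL).
#' @param spike [spike_mix()] of the 13C standards.
#' @param recoveries Named recovery fractions, see [recovery_table()].
#' @param apply_recovery Divide by recovery fractions (default TRUE); set
#'   FALSE to treat recoveries as QC only.
#' @param volume [volume_model()] for the concentration step.
#' @param response_ratio Analyte/standard detector response (default 1).
#' @param mt_tolerance Migration-time matching tolerance (min).
#' @param include_ip6 Keep IP6 in the concentration output (default FALSE:
#'   IP6 is quantified but excluded from reporting, not being a
#'   pyrophosphate endpoint).
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(n_cells = 1e7,
                         extract_volume_ul = 20,
                         aliquot_volume_ul = 15,
                         spike = spike_mix(),
                         recoveries = recovery_table(),
                         apply_recovery = TRUE,
                         volume = volume_model(),
                         response_ratio = 1,
                         mt_tolerance = 0.2,
                         include_ip6 = FALSE) {
  structure(
    list(
      n_cells = n_cells,
      extract_volume_ul = extract_volume_ul,
      aliquot_volume_ul = aliquot_volume_ul,
      spike = spike, recoveries = recoveries,
      apply_recovery = apply_recovery, volume = volume,
      response_ratio = response_ratio, mt_tolerance = mt_tolerance,
      include_ip6 = include_ip6
    ),
    class = "quant_config"
  )
}

#' Read a quantification config from a YAML file
#'
#' Scalar fields override the [quant_config()] defaults; `recoveries` and
#' `spike_conc_um` may be given as named maps.
#'
#' @param path Path to a YAML file.
#' @return A `quant_config`.
#' @export
read_quant_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  cfg <- quant_config()
  for (f in c("n_cells", "extract_volume_ul", "aliquot_volume_ul",
              "response_ratio", "mt_tolerance")) {
    # as.numeric guards against YAML parsers reading "1.0e7" as a string
    if (!is.null(y[[f]])) cfg[[f]] <- as.numeric(y[[f]])
  }
  for (f in c("apply_recovery", "include_ip6")) {
    if (!is.null(y[[f]])) cfg[[f]] <- isTRUE(y[[f]])
  }
  if (!is.null(y$recoveries)) cfg$recoveries <- unlist(y$recoveries)
  if (!is.null(y$spike_conc_um)) {
    cfg$spike <- spike_mix(conc_um = unlist(y$spike_conc_um),
                           volume_ul = y$spike_volume_ul %||% 0.75)
  }
  if (!is.null(y$v_cell_fl) || !is.null(y$exclude_nucleus)) {
    cfg$volume <- volume_model(
      v_cell_fl = y$v_cell_fl %||% 42,
      f_nucleus = y$f_nucleus %||% 0.08,
      f_organelles = y$f_organelles %||% 0.18,
      exclude_nucleus = isTRUE(y$exclude_nucleus)
    )
  }
  cfg
}

#' Run the full MRM quantification chain
#'
#' Composition of the elemental steps, per sample and species: assign
#' peaks to species against the co-injected 13C references; isotope-dilution
#' quantification of the spiked aliquot; scaling to the whole extract;
#' recovery correction; normalisation by the number of cells harvested;
#' conversion to cytosolic concentration over the Pi-accessible volume;
#' replicate summary per strain x timepoint x species.
#'
#' @param peaks Peak table data frame or path to a peak CSV (columns as in
#'   [generate_ms_fixture()]).
#' @param config A [quant_config()].
#' @param out_dir Optional directory; when given, the per-sample table, the
#'   summary table and a JSON run report are written there.
#' @return List of class `quant_result` with `per_sample` (columns
#'   `sample_id`, `strain`, `time_min`, `replicate`, `species`,
#'   `aliquot_fmol`, `extract_fmol`, `recovered_fmol`, `zmol_per_cell`,
#'   `conc_uM`), `summary` (per strain x time x species: `mean_uM`,
#'   `sd_uM`, `n`) and `config`.
#' @export
#' @examples
#' fx <- generate_ms_fixture(canned_scenario("wt_replete"))
#' res <- run_quant_pipeline(fx$peaks, quant_config())
#' res$summary
run_quant_pipeline <- function(peaks, config = quant_config(), out_dir = NULL) {
  stopifnot(inherits(config, "quant_config"))
  if (is.character(peaks)) {
    peaks <- utils::read.csv(peaks, stringsAsFactors = FALSE, check.names = FALSE)
  }

  assigned <- assign_peaks(peaks, mt_tolerance = config$mt_tolerance)
  ana <- assigned[assigned$label == "12C" & assigned$assigned, , drop = FALSE]
  refs <- assigned[assigned$label == "13C" & assigned$assigned, , drop = FALSE]
  if (!nrow(ana)) stop("no assignable analyte peaks in the table")

  ref_key <- paste(refs$sample_id, refs$species)
  std_area <- stats::setNames(refs$peak_area, ref_key)

  per_sample <- do.call(rbind, lapply(seq_len(nrow(ana)), function(i) {
    row <- ana[i, ]
    key <- paste(row$sample_id, row$species)
    sa <- std_area[[key]]
    if (is.null(sa)) {
      stop(sprintf("sample %s, species %s: no 13C internal standard peak",
                   row$sample_id, row$species))
    }
    aliquot_fmol <- quantify_isotope_dilution(
      row$peak_area, sa, config$spike$fmol[[row$species]],
      response_ratio = config$response_ratio
    )
    extract_fmol <- scale_to_extract(aliquot_fmol, config$aliquot_volume_ul,
                                     config$extract_volume_ul)
    recovered_fmol <- if (config$apply_recovery) {
      correct_recovery(extract_fmol, config$recoveries[[row$species]])
    } else {
      extract_fmol
    }
    zmol <- per_cell_amount(recovered_fmol, config$n_cells)
    data.frame(
      sample_id = row$sample_id,
      strain = row$strain %||% NA_character_,
      time_min = row$time_min %||% NA_real_,
      replicate = row$replicate %||% NA_integer_,
      species = row$species,
      aliquot_fmol = aliquot_fmol,
      extract_fmol = extract_fmol,
      recovered_fmol = recovered_fmol,
      zmol_per_cell = zmol,
      conc_uM = cytosolic_concentration(zmol, config$volume),
      stringsAsFactors = FALSE
    )
  }))
  if (!config$include_ip6) {
    per_sample <- per_sample[per_sample$species != "IP6", , drop = FALSE]
  }
  rownames(per_sample) <- NULL

  grp <- interaction(per_sample$strain, per_sample$time_min,
                     per_sample$species, drop = TRUE)
  summary <- do.call(rbind, lapply(split(per_sample, grp), function(d) {
    s <- summarize_replicates(d$conc_uM)
    data.frame(
      strain = d$strain[1], time_min = d$time_min[1], species = d$species[1],
      mean_uM = s$mean, sd_uM = s$sd, n = s$n, stringsAsFactors = FALSE
    )
  }))
  summary <- summary[order(summary$strain, summary$time_min, summary$species), ]
  rownames(summary) <- NULL

  res <- structure(
    list(per_sample = per_sample, summary = summary, config = config),
    class = "quant_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_sample, file.path(out_dir, "quant_per_sample.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "quant_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(
        n_samples = length(unique(per_sample$sample_id)),
        species = unique(per_sample$species),
        v_accessible_fl = config$volume$v_accessible_fl,
        apply_recovery = config$apply_recovery
      ),
      file.path(out_dir, "quant_report.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  res
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("Quantification of %d samples, %d species\n",
              length(unique(x$per_sample$sample_id)),
              length(unique(x$per_sample$species))))
  print(x$summary, digits = 3)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
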