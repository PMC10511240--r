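test_that("isotope dilution, volume scaling and recovery steps follow the protocol arithmetic", {
  # half area ratio, 7.5 pmol standard
  expect_equal(quantify_isotope_dilution(2000, 4000, 7.5), 3.75)
  expect_equal(quantify_isotope_dilution(0, 4000, 7.5), 0)
  expect_error(quantify_isotope_dilution(100, 0, 7.5), "internal standard")
  # response ratio rescales inversely
  expect_equal(quantify_isotope_dilution(2000, 4000, 7.5, response_ratio = 0.5), 7.5)

  # the wild-type 1-IP7 fixture value, by hand through the aliquot/loss
  # factors: 17.22 zmol/cell x 1e7 cells x 0.89 x 15/20 = 114.9435 fmol
  aliquot <- quantify_isotope_dilution(0.0153258 * 75000, 75000, 7500)
  expect_equal(aliquot, 114.9435, tolerance = 1e-6)

  expect_equal(scale_to_extract(114.9435, 15, 20), 153.258)
  expect_equal(scale_to_extract(5, 10, 10), 5)
  expect_equal(scale_to_extract(0, 15, 20), 0)
  expect_error(scale_to_extract(1, 0, 20), "positive")
  expect_error(scale_to_extract(1, 25, 20), "exceed")

  expect_equal(correct_recovery(153.258, 0.89), 172.2, tolerance = 1e-12)
  expect_equal(correct_recovery(7, 1), 7)
  expect_error(correct_recovery(7, 0), "recovery_fraction")
  expect_error(correct_recovery(7, 1.2), "recovery_fraction")

  expect_equal(recovery_from_spike(200, 178), 0.89)
  expect_equal(recovery_from_spike(200, 200), 1.0)
  expect_equal(recovery_from_spike(200, 150), 0.75)
  expect_equal(recovery_from_spike(200, 178, as_percent = TRUE), 89)
  expect_error(recovery_from_spike(0, 10), "known_spiked_moles")

  expect_equal(per_cell_amount(172.2, 1e7), 17.22)
  expect_equal(per_cell_amount(1, 1e6), 1)
  expect_equal(per_cell_amount(0, 1e7), 0)
  expect_error(per_cell_amount(1, 0), "n_cells")
})

test_that("cytosolic concentration uses the Pi-accessible volume", {
  vm <- volume_model()
  expect_equal(vm$v_accessible_fl, 34.44)
  expect_equal(cytosolic_concentration(17.22, vm), 0.5)
  expect_equal(cytosolic_concentration(24.11, vm), 0.7, tolerance = 1e-4)
  expect_equal(cytosolic_concentration(0, vm), 0)
  # nucleus optionally excluded: 42 * (1 - 0.26) = 31.08 fL
  vm2 <- volume_model(exclude_nucleus = TRUE)
  expect_equal(vm2$v_accessible_fl, 31.08)
  expect_gt(cytosolic_concentration(17.22, vm2), 0.5)
  expect_error(volume_model(f_nucleus = 0.5, f_organelles = 0.6), "less than 1")
})

test_that("fold change and percent change match their closed forms", {
  expect_equal(fold_change(14.0, 0.70), 20.0)
  expect_equal(fold_change(3, 3), 1.0)
  expect_equal(fold_change(5.0, 0.50), 10.0)
  expect_error(fold_change(1, 0), "reference")

  pc <- percent_change(0.30, 0.075)
  expect_equal(pc$decline_pct, 75)
  expect_equal(percent_change(2, 2)$decline_pct, 0)
  expect_equal(percent_change(0.70, 0.021)$remaining_pct, 3)
  expect_error(percent_change(0, 1), "c0")
})

test_that("replicate summaries use the sample (n-1) standard deviation", {
  s <- summarize_replicates(c(1, 1, 1))
  expect_equal(s$mean, 1); expect_equal(s$sd, 0); expect_equal(s$n, 3)
  s2 <- summarize_replicates(c(0.4, 0.5, 0.6))
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$sd, 0.1)
  s1 <- summarize_replicates(5)
  expect_true(s1$single_rep)
  expect_equal(s1$sd, 0)
  expect_error(summarize_replicates(numeric(0)), "no replicate")
})

test_that("transition table matches the acquisition method and 13C shift", {
  tt <- transition_table()
  expect_equal(nrow(tt), 6)
  ip7_12 <- tt[tt$compound == "IP7" & tt$label == "12C", ]
  expect_equal(ip7_12$precursor_mz, 368.9)
  expect_equal(ip7_12$product_mz, 319.9)
  # every 13C precursor sits +3.0 m/z above its 12C analyte (z = 2, 6 13C)
  for (cmp in unique(tt$compound)) {
    d <- tt$precursor_mz[tt$compound == cmp & tt$label == "13C"] -
      tt$precursor_mz[tt$compound == cmp & tt$label == "12C"]
    expect_equal(d, 3.0)
  }
})

test_that("peaks are assigned by transition then migration order of the 13C references", {
  mk_peak <- function(mt, label, pre = 368.9, pro = 319.9, area = 1000) {
    data.frame(sample_id = "s1", precursor_mz = pre, product_mz = pro,
               migration_time_min = mt, peak_area = area, label = label)
  }
  refs <- rbind(mk_peak(19.5, "13C", 371.9, 322.9), mk_peak(20.1, "13C", 371.9, 322.9))
  out <- assign_peaks(rbind(mk_peak(19.5, "12C"), refs))
  ana <- out[out$label == "12C", ]
  expect_true(ana$assigned)
  expect_equal(ana$species, "5-IP7")

  out2 <- assign_peaks(rbind(mk_peak(20.1, "12C"), refs))
  expect_equal(out2$species[out2$label == "12C"], "1-IP7")

  # no reference within tolerance -> unassigned, not an error
  out3 <- assign_peaks(rbind(mk_peak(18.9, "12C"), refs))
  expect_false(out3$assigned[out3$label == "12C"])

  # constructed tie: two analytes, one reference, equal residuals
  tie <- rbind(mk_peak(19.48, "12C"), mk_peak(19.52, "12C"),
               mk_peak(19.5, "13C", 371.9, 322.9))
  expect_error(assign_peaks(tie), class = "ippdyn_ambiguity")
})

test_that("a global migration shift is removed by median alignment", {
  fx <- generate_ms_fixture(canned_scenario("mutants_replete"))
  base <- assign_peaks(fx$peaks)
  shifted_peaks <- fx$peaks
  shifted_peaks$migration_time_min <-
    shifted_peaks$migration_time_min + 0.30 * (shifted_peaks$label == "12C")
  shifted <- assign_peaks(shifted_peaks)
  expect_equal(shifted$species, base$species)
  expect_equal(shifted$assigned, base$assigned)

  # oracle: brute-force all-pairs matching on one sample's IP7 peaks
  p <- fx$peaks[fx$peaks$sample_id == fx$peaks$sample_id[1] &
                  fx$peaks$precursor_mz %in% c(368.9, 371.9), ]
  ana <- p[p$label == "12C", ]; ref <- p[p$label == "13C", ]
  ref <- ref[order(ref$migration_time_min), ]
  bf <- brute_force_match(ana$migration_time_min + 0.30,
                          ref$migration_time_min, shift = 0.30)
  species_order <- c("5-IP7", "1-IP7")
  got <- shifted[shifted$label == "12C" &
                   shifted$sample_id == p$sample_id[1] &
                   shifted$compound == "IP7", ]
  got <- got[match(ana$migration_time_min + 0.30, got$migration_time_min), ]
  expect_equal(got$species, species_order[bf])
})

test_that("the full pipeline reproduces the closed-form chain on every fixture", {
  fx <- generate_ms_fixture(canned_scenario("mutants_replete"))
  res <- run_quant_pipeline(fx$peaks)
  spike_fmol <- spike_mix()$fmol
  rec <- recovery_table()

  peaks <- assign_peaks(fx$peaks)
  for (i in seq_len(nrow(res$per_sample))) {
    row <- res$per_sample[i, ]
    a <- peaks[peaks$sample_id == row$sample_id & peaks$species == row$species, ]
    oracle <- chain_oracle_uM(
      a$peak_area[a$label == "12C"], a$peak_area[a$label == "13C"],
      spike_fmol[[row$species]], recovery = rec[[row$species]]
    )
    expect_rel_equal(row$conc_uM, oracle)
  }
})

test_that("round trip: noise-free fixtures return the ground-truth amounts", {
  for (scen in c("wt_replete", "wt_starvation", "mutants_replete")) {
    fx <- generate_ms_fixture(canned_scenario(scen))
    res <- run_quant_pipeline(fx$peaks)
    truth <- fx$truth[fx$truth$species != "IP6", ]
    key_r <- paste(res$per_sample$strain, res$per_sample$time_min,
                   res$per_sample$species)
    key_t <- paste(truth$strain, truth$time_min, truth$species)
    expect_rel_equal(res$per_sample$zmol_per_cell,
                     truth$zmol_per_cell[match(key_r, key_t)])
  }
})

test_that("emitted peak areas conserve truth x cells x loss x aliquot fraction", {
  sc <- canned_scenario("wt_replete")
  fx <- generate_ms_fixture(sc)
  ana <- fx$peaks[fx$peaks$label == "12C", ]
  assigned <- assign_peaks(fx$peaks)
  ana_sp <- assigned$species[assigned$label == "12C"]
  for (i in seq_len(nrow(ana))) {
    s <- ana_sp[i]
    z <- fx$truth$zmol_per_cell[fx$truth$species == s]
    expected_fmol <- z * sc$n_cells / 1e6 * sc$loss_factors[[s]] * 15 / 20
    expect_rel_equal(ana$peak_area[i] / sc$response_per_fmol, expected_fmol)
  }
})

test_that("the chain is linear in analyte area and truth amounts", {
  sc <- canned_scenario("wt_replete")
  fx <- generate_ms_fixture(sc)
  res1 <- run_quant_pipeline(fx$peaks)

  doubled <- fx$peaks
  doubled$peak_area[doubled$label == "12C"] <-
    2 * doubled$peak_area[doubled$label == "12C"]
  res2 <- run_quant_pipeline(doubled)
  expect_rel_equal(res2$per_sample$conc_uM, 2 * res1$per_sample$conc_uM)

  # doubling the generator truth doubles concentrations end to end
  tr2 <- default_truth_table()
  tr2$zmol_per_cell <- 2 * tr2$zmol_per_cell
  fx2 <- generate_ms_fixture(fixture_scenario(
    strains = "wt", timepoints = 0, truth = tr2,
    replicate_cv = 0, n_replicates = 1
  ))
  res3 <- run_quant_pipeline(fx2$peaks)
  expect_rel_equal(res3$per_sample$conc_uM, 2 * res1$per_sample$conc_uM)
})

test_that("disabling recovery correction scales concentrations by the recovery fraction", {
  fx <- generate_ms_fixture(canned_scenario("wt_replete"))
  with_rec <- run_quant_pipeline(fx$peaks)
  without <- run_quant_pipeline(fx$peaks, quant_config(apply_recovery = FALSE))
  r <- recovery_table()
  expect_rel_equal(
    without$per_sample$conc_uM,
    with_rec$per_sample$conc_uM * r[without$per_sample$species]
  )
})

test_that("noise-free starvation concentrations are non-increasing in time", {
  fx <- generate_ms_fixture(canned_scenario("wt_starvation"))
  res <- run_quant_pipeline(fx$peaks)
  for (s in unique(res$summary$species)) {
    d <- res$summary[res$summary$species == s, ]
    d <- d[order(d$time_min), ]
    expect_true(all(diff(d$mean_uM) <= 1e-12))
  }
})

test_that("replicate noise at CV 0.15, n = 4 keeps seed-averaged means within 10% of truth", {
  concs <- sapply(1:6, function(seed) {
    fx <- generate_ms_fixture(fixture_scenario(
      strains = "wt", timepoints = 0, replicate_cv = 0.15,
      n_replicates = 4, seed = seed
    ))
    res <- run_quant_pipeline(fx$peaks)
    res$summary$mean_uM[res$summary$species == "5-IP7"]
  })
  expect_lt(abs(mean(concs) / 0.700058 - 1), 0.10)
})

test_that("doubling the cell volume halves all concentrations", {
  fx <- generate_ms_fixture(canned_scenario("wt_replete"))
  res42 <- run_quant_pipeline(fx$peaks)
  res84 <- run_quant_pipeline(
    fx$peaks, quant_config(volume = volume_model(v_cell_fl = 84))
  )
  expect_rel_equal(res84$per_sample$conc_uM, res42$per_sample$conc_uM / 2)
})

test_that("IP6 is quantified but excluded from reporting unless requested", {
  fx <- generate_ms_fixture(canned_scenario("wt_replete"))
  res <- run_quant_pipeline(fx$peaks)
  expect_false("IP6" %in% res$per_sample$species)
  res_ip6 <- run_quant_pipeline(fx$peaks, quant_config(include_ip6 = TRUE))
  expect_true("IP6" %in% res_ip6$per_sample$species)
})

test_that("the shipped YAML config reproduces the default configuration", {
  path <- system.file("extdata", "quant_config.yaml", package = "ippdyn")
  skip_if(path == "", "example config not installed")
  cfg <- read_quant_config(path)
  ref <- quant_config()
  expect_equal(cfg$n_cells, ref$n_cells)
  expect_equal(cfg$recoveries, ref$recoveries)
  expect_equal(cfg$spike$fmol, ref$spike$fmol)
  expect_equal(cfg$volume$v_accessible_fl, ref$volume$v_accessible_fl)
  fx <- generate_ms_fixture(canned_scenario("wt_replete"))
  expect_equal(run_quant_pipeline(fx$peaks, cfg)$summary,
               run_quant_pipeline(fx$peaks, ref)$summary)
})
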