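test_that("segmentation handles degenerate and clean fields", {
  flat <- matrix(500, 128, 128)
  lab <- segment_cells(flat)
  expect_equal(max(lab), 0)

  empty <- generate_image_fixture(small_field_spec(n_cells = 0, noise_sd = 0))
  expect_equal(max(segment_cells(empty$field)), 0)

  clean <- generate_image_fixture(small_field_spec(n_cells = 20, seed = 4,
                                                   noise_sd = 0))
  seg <- segment_cells(clean$field)
  ev <- evaluate_segmentation(seg, clean$labels$cell)
  expect_equal(ev$detection_fraction, 1.0)
  expect_true(all(ev$matches$iou >= 0.5))
})

test_that("segmentation recall is high on noisy fields and non-increasing in noise", {
  recalls <- vapply(c(0, 60, 400), function(ns) {
    fr <- vapply(c(31, 32), function(seed) {
      fix <- generate_image_fixture(small_field_spec(n_cells = 20, seed = seed,
                                                     noise_sd = ns))
      evaluate_segmentation(segment_cells(fix$field),
                            fix$labels$cell)$detection_fraction
    }, numeric(1))
    mean(fr)
  }, numeric(1))
  expect_equal(recalls[1], 1.0)
  expect_true(all(diff(recalls) <= 1e-12))
})

test_that("nucleus segmentation recovers the nuclear area fraction and flags edge cases", {
  fix <- generate_image_fixture(small_field_spec(n_cells = 20, seed = 8))
  seg <- segment_cells(fix$field)
  nuc <- segment_nuclei(fix$field, seg)
  flags <- attr(nuc, "flags")
  ok <- flags$cell_id[!flags$nucleus_free]
  expect_gt(length(ok), 0.8 * max(seg))
  frac <- vapply(ok, function(id) sum(nuc == id) / sum(seg == id), numeric(1))
  expect_lt(abs(mean(frac) - 0.08), 0.03)
  # nucleus containment within the measuring cell
  for (id in ok) {
    expect_true(all(seg[nuc == id] == id))
  }

  # all-zero nuclear channel: every cell flagged nucleus-free
  zero_field <- fix$field
  zero_field$nuclear <- matrix(0, nrow(fix$field$nuclear), ncol(fix$field$nuclear))
  nuc0 <- segment_nuclei(zero_field, seg)
  expect_true(all(attr(nuc0, "flags")$nucleus_free))
  expect_equal(max(nuc0), 0)
})

test_that("two nuclear blobs in one cell keep the larger and flag multinucleate", {
  cell <- matrix(0L, 64, 64)
  cell[10:50, 10:50] <- 1L
  nuclear <- matrix(100, 64, 64)
  nuclear[20:28, 20:28] <- 3000   # 81 px blob
  nuclear[38:42, 38:42] <- 3000   # 25 px blob
  nuc <- segment_nuclei(nuclear, cell)
  flags <- attr(nuc, "flags")
  expect_true(flags$multinucleate[flags$cell_id == 1])
  expect_equal(sum(nuc == 1), 81)
  expect_equal(sum(nuc[20:28, 20:28] == 1), 81)
})

test_that("uniform reporter gives ratio 1 and ratios are background/gain invariant", {
  fix <- generate_image_fixture(small_field_spec(n_cells = 15, seed = 9,
                                                 noise_sd = 0))
  seg <- segment_cells(fix$field)
  nuc <- segment_nuclei(fix$field, seg)

  # uniform reporter over the cells, measured in manual-ROI mode (masks
  # supplied directly): every ratio is exactly 1
  uniform <- fix$field
  uniform$reporter <- matrix(800, nrow(seg), ncol(seg))
  uniform$reporter[fix$labels$cell > 0] <- 1500
  rec_u <- measure_nc_ratio(uniform, fix$labels$cell, fix$labels$nucleus)
  expect_true(all(abs(rec_u$ratio[rec_u$included] - 1) < 1e-6))

  rec <- measure_nc_ratio(fix$field, seg, nuc)
  # multiplicative gain: exactly invariant
  gained <- fix$field
  gained$reporter <- fix$field$reporter * 3.7
  rec_g <- measure_nc_ratio(gained, seg, nuc)
  expect_equal(rec_g$ratio[rec_g$included], rec$ratio[rec$included],
               tolerance = 1e-12)
  # additive offset: invariant within 1% once the background re-estimates
  offset <- fix$field
  offset$reporter <- fix$field$reporter + 250
  rec_o <- measure_nc_ratio(offset, seg, nuc)
  expect_true(all(abs(rec_o$ratio[rec_o$included] /
                        rec$ratio[rec$included] - 1) < 0.01))
})

test_that("measured ratios track generator truth without material bias", {
  # pooled over enough default-noise cells to see a systematic bias
  rel <- c()
  for (seed in 41:45) {
    fix <- generate_image_fixture(small_field_spec(n_cells = 22, seed = seed))
    seg <- segment_cells(fix$field)
    nuc <- segment_nuclei(fix$field, seg)
    rec <- measure_nc_ratio(fix$field, seg, nuc)
    ev <- evaluate_segmentation(seg, fix$labels$cell)
    m <- ev$matches[ev$matches$iou >= 0.5 & !is.na(ev$matches$pred_id), ]
    tr <- fix$truth$true_ratio[match(m$truth_id, fix$truth$cell_id)]
    mr <- rec$ratio[match(m$pred_id, rec$cell_id)]
    keep <- rec$included[match(m$pred_id, rec$cell_id)]
    rel <- c(rel, (mr / tr)[keep])
  }
  expect_gt(length(rel), 100)
  expect_lt(abs(mean(rel, na.rm = TRUE) - 1), 0.02)

  # zero-noise single fixture: each cell within 0.05 of truth at ratio ~3
  fx3 <- generate_image_fixture(small_field_spec(n_cells = 12, seed = 46,
                                                 noise_sd = 0,
                                                 ratio_mean = 3, ratio_sd = 0))
  seg3 <- segment_cells(fx3$field)
  nuc3 <- segment_nuclei(fx3$field, seg3)
  rec3 <- measure_nc_ratio(fx3$field, seg3, nuc3)
  expect_true(all(abs(rec3$ratio[rec3$included] - 3) < 0.05))
})

test_that("starved fields show higher measured ratios than replete fields", {
  measure_mean <- function(name, seed) {
    fix <- generate_image_fixture(
      canned_field_spec(name, seed = seed, width = 256, height = 256,
                        n_cells = 25))
    seg <- segment_cells(fix$field)
    nuc <- segment_nuclei(fix$field, seg)
    rec <- measure_nc_ratio(fix$field, seg, nuc)
    mean(rec$ratio[rec$included])
  }
  expect_gt(measure_mean("starved", 51), measure_mean("replete", 52))
})

test_that("segmentation evaluation follows greedy one-to-one IoU matching", {
  fix <- generate_image_fixture(small_field_spec(n_cells = 10, seed = 13,
                                                 noise_sd = 0))
  truth <- fix$labels$cell
  ev_id <- evaluate_segmentation(truth, truth)
  expect_equal(ev_id$detection_fraction, 1.0)
  expect_true(all(ev_id$matches$iou == 1.0))

  emptym <- matrix(0L, nrow(truth), ncol(truth))
  expect_equal(evaluate_segmentation(emptym, truth)$detection_fraction, 0)

  half <- truth
  drop_ids <- fix$truth$cell_id[1:5]
  half[half %in% drop_ids] <- 0L
  expect_equal(evaluate_segmentation(half, truth)$detection_fraction, 0.5)

  expect_error(evaluate_segmentation(matrix(0L, 5, 5), truth), "shape")
})

test_that("population summaries group, compute and warn as specified", {
  rec <- data.frame(
    cell_id = 1:5, ratio = c(1, 2, 3, 10, 12),
    condition = c("a", "a", "a", "b", "b"),
    included = TRUE
  )
  out <- suppressWarnings(summarize_population(rec, "condition"))
  expect_equal(out$mean_ratio[out$condition == "a"], 2)
  expect_equal(out$mean_ratio[out$condition == "b"], 11)
  expect_equal(out$n, c(3, 2))
  expect_warning(summarize_population(rec, "condition"), "expected")

  one <- rec[1, ]
  s1 <- suppressWarnings(summarize_population(one, "condition"))
  expect_equal(s1$mean_ratio, 1)
  expect_equal(s1$sd_ratio, 0)

  rec$included <- FALSE
  expect_error(summarize_population(rec, "condition"), "excluded")
})
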