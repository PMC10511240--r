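#' Segment cells in a bright-field-like channel
#'
#' Deterministic classical pipeline: Gaussian smoothing, absolute
#' deviation from the median background level, Otsu threshold on the
#' deviation image, hole filling (cells read as bright-rimmed discs, so
#' thresholding yields filled or ring-like blobs), distance-transform
#' watershed to split touching objects, then a size filter. Cells touching
#' the image border are kept in the mask but flagged so downstream
#' statistics can exclude them.
#'
#' @param field A field list as produced by [generate_image_fixture()] (or
#'   any list with a `brightfield` matrix), or a bare numeric matrix.
#' @param sigma Smoothing sd in pixels (default 2).
#' @param min_area,max_area Object area bounds in pixels.
#' @param watershed_tolerance Minimum object-separation depth in the
#'   distance map (default 2; larger merges more).
#' @param shrink_px Erosion radius in pixels applied to the thresholded
#'   mask (default 3). Smoothing spreads the dark rim outwards, so the raw
#'   threshold overshoots the cell boundary by about the smoothing width;
#'   eroding by the same amount keeps the mask inside the cell so cytosolic
#'   means are not diluted with background pixels.
#' @return Integer label matrix (0 = background) with attribute
#'   `"border_ids"`: labels of cells touching the field border.
#' @export
segment_cells <- function(field, sigma = 2, min_area = 80, max_area = 5000,
                          watershed_tolerance = 2, shrink_px = 3) {
  bf <- if (is.list(field)) field$brightfield else field
  stopifnot(is.matrix(bf), all(bf >= 0))
  if (length(bf) == 0) stop("empty field")

  if (max(bf) == min(bf)) {
    lab <- matrix(0L, nrow(bf), ncol(bf))
    attr(lab, "border_ids") <- integer(0)
    return(lab)
  }

  sm <- ebimage_blur(bf, sigma = sigma)
  dev <- abs(sm - stats::median(sm))
  dev_img <- EBImage::Image(dev / max(dev))
  thr <- EBImage::otsu(dev_img, range = c(0, 1))
  mask <- EBImage::fillHull(dev_img > thr)
  if (shrink_px > 0) {
    mask <- EBImage::erode(mask, EBImage::makeBrush(2 * shrink_px + 1, "disc"))
  }

  dmap <- EBImage::distmap(mask)
  lab_img <- EBImage::watershed(dmap, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(lab_img)), nrow(bf), ncol(bf))

  # size filter + relabel consecutively
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area & sizes <= max_area)
  remap <- integer(max(lab, 1))
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]

  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  attr(lab, "border_ids") <- sort(border[border > 0])
  lab
}

#' Segment nuclei within segmented cells
#'
#' Per cell, an automatic (Otsu) threshold on the nuclear-marker channel
#' restricted to that cell's pixels; connected components of the
#' thresholded region are labelled and only the largest is kept as the
#' nucleus. Cells whose nuclear signal is absent (degenerate histogram or
#' sub-minimal foreground) are flagged nucleus-free; cells with more than
#' one component are flagged multinucleate (largest kept).
#'
#' @param field Field list with a `nuclear` matrix, or a bare matrix.
#' @param cell_mask Integer cell label matrix from [segment_cells()].
#' @param min_nucleus_area Minimum nucleus area in pixels (default 4).
#' @return Integer nucleus label matrix sharing the cell labels, with
#'   attribute `"flags"`: data.frame (`cell_id`, `nucleus_free`,
#'   `multinucleate`).
#' @export
segment_nuclei <- function(field, cell_mask, min_nucleus_area = 4) {
  nuc <- if (is.list(field)) field$nuclear else field
  stopifnot(is.matrix(nuc), all(dim(nuc) == dim(cell_mask)))

  out <- matrix(0L, nrow(nuc), ncol(nuc))
  ids <- setdiff(sort(unique(as.vector(cell_mask))), 0L)
  flags <- data.frame(cell_id = ids, nucleus_free = FALSE, multinucleate = FALSE)

  for (k in seq_along(ids)) {
    id <- ids[k]
    px <- which(cell_mask == id)
    v <- nuc[px]
    rng <- range(v)
    if (diff(rng) < 1e-8) {  # constant signal: nothing to threshold
      flags$nucleus_free[k] <- TRUE
      next
    }
    v01 <- (v - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1)), range = c(0, 1))
    fg <- px[v01 > thr]
    # guard against threshold splitting pure noise: require clear contrast
    bgv <- v[v01 <= thr]
    bg_sd <- if (length(bgv) > 1) stats::sd(bgv) else 0
    if (length(fg) < min_nucleus_area ||
        (mean(v[v01 > thr]) - mean(bgv)) < 4 * bg_sd) {
      flags$nucleus_free[k] <- TRUE
      next
    }
    sel <- matrix(0L, nrow(nuc), ncol(nuc))
    sel[fg] <- 1L
    comp <- EBImage::bwlabel(EBImage::Image(sel))
    comp <- matrix(as.integer(EBImage::imageData(comp)), nrow(nuc), ncol(nuc))
    sizes <- tabulate(comp)
    big <- sizes >= min_nucleus_area
    if (!any(big)) {
      flags$nucleus_free[k] <- TRUE
      next
    }
    if (sum(big) > 1) flags$multinucleate[k] <- TRUE
    out[comp == which.max(sizes)] <- id
  }
  attr(out, "flags") <- flags
  out
}

#' Measure per-cell nuclear/cytosolic reporter ratios
#'
#' For each non-border, nucleus-bearing cell: the background (median
#' reporter intensity outside all cells) is subtracted from the mean
#' reporter intensity over the nucleus (I_N) and over the cytosol (I_C),
#' where the cytosol is the cell minus the nucleus dilated by a 1 px guard
#' ring to limit bleed-through. The ratio I_N/I_C is the nuclear
#' localisation readout.
#'
#' @param field Field list with a `reporter` matrix, or a bare matrix.
#' @param cell_mask Cell label matrix ([segment_cells()] or external
#'   manually drawn ROIs).
#' @param nucleus_mask Nucleus label matrix sharing the cell labels.
#' @param guard_px Guard-ring width in pixels around the nucleus (default 1).
#' @return Data frame, one row per cell: `cell_id`, `cell_area_px`,
#'   `nucleus_area_px`, `i_n`, `i_c`, `ratio`, `border_touching`,
#'   `nucleus_free`, `nonpositive_cytosol`, `included`. Attribute
#'   `"background"` carries the estimated background level.
#' @export
measure_nc_ratio <- function(field, cell_mask, nucleus_mask, guard_px = 1) {
  rep_ch <- if (is.list(field)) field$reporter else field
  stopifnot(is.matrix(rep_ch),
            all(dim(rep_ch) == dim(cell_mask)),
            all(dim(cell_mask) == dim(nucleus_mask)))

  bg <- stats::median(rep_ch[cell_mask == 0])
  border_ids <- attr(cell_mask, "border_ids")
  if (is.null(border_ids)) {
    border_ids <- unique(c(cell_mask[1, ], cell_mask[nrow(cell_mask), ],
                           cell_mask[, 1], cell_mask[, ncol(cell_mask)]))
    border_ids <- border_ids[border_ids > 0]
  }

  guard <- if (guard_px > 0) {
    kern <- EBImage::makeBrush(2 * guard_px + 1, shape = "box")
    m <- EBImage::dilate(EBImage::Image((nucleus_mask > 0) * 1), kern)
    matrix(as.numeric(EBImage::imageData(m)) > 0, nrow(nucleus_mask))
  } else {
    nucleus_mask > 0
  }

  ids <- setdiff(sort(unique(as.vector(cell_mask))), 0L)
  rows <- lapply(ids, function(id) {
    cell_px <- cell_mask == id
    nuc_px <- nucleus_mask == id
    cyt_px <- cell_px & !guard
    nucleus_free <- !any(nuc_px)
    i_n <- if (nucleus_free) NA_real_ else mean(rep_ch[nuc_px]) - bg
    i_c <- if (!any(cyt_px)) NA_real_ else mean(rep_ch[cyt_px]) - bg
    nonpos <- !is.na(i_c) && i_c <= 0
    data.frame(
      cell_id = id,
      cell_area_px = sum(cell_px),
      nucleus_area_px = sum(nuc_px),
      i_n = i_n, i_c = i_c,
      ratio = if (!nucleus_free && !is.na(i_c) && i_c > 0) i_n / i_c else NA_real_,
      border_touching = id %in% border_ids,
      nucleus_free = nucleus_free,
      nonpositive_cytosol = nonpos,
      stringsAsFactors = FALSE
    )
  })
  rec <- do.call(rbind, rows)
  if (is.null(rec)) {
    rec <- data.frame(cell_id = integer(0), cell_area_px = integer(0),
                      nucleus_area_px = integer(0), i_n = numeric(0),
                      i_c = numeric(0), ratio = numeric(0),
                      border_touching = logical(0), nucleus_free = logical(0),
                      nonpositive_cytosol = logical(0))
  }
  rec$included <- !rec$border_touching & !rec$nucleus_free &
    !rec$nonpositive_cytosol & !is.na(rec$ratio)
  attr(rec, "background") <- bg
  rec
}

#' Evaluate a segmentation against ground-truth labels
#'
#' Greedy one-to-one matching of predicted to truth objects by descending
#' intersection-over-union; a truth cell counts as detected when its match
#' reaches `iou_threshold`.
#'
#' @param pred_mask,truth_mask Integer label matrices of identical shape.
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @return List with `detection_fraction`, `n_truth`, `n_pred`, `n_matched`
#'   and `matches` (data.frame `truth_id`, `pred_id`, `iou`, including
#'   unmatched truth cells with `iou = 0`).
#' @export
evaluate_segmentation <- function(pred_mask, truth_mask, iou_threshold = 0.5) {
  if (!all(dim(pred_mask) == dim(truth_mask))) {
    stop("prediction and truth masks differ in shape")
  }
  truth_ids <- setdiff(sort(unique(as.vector(truth_mask))), 0L)
  pred_ids <- setdiff(sort(unique(as.vector(pred_mask))), 0L)
  n_truth <- length(truth_ids)
  if (n_truth == 0) {
    return(list(detection_fraction = NA_real_, n_truth = 0,
                n_pred = length(pred_ids), n_matched = 0,
                matches = data.frame(truth_id = integer(0),
                                     pred_id = integer(0), iou = numeric(0))))
  }

  both <- pred_mask > 0 & truth_mask > 0
  if (any(both)) {
    inter <- table(truth = truth_mask[both], pred = pred_mask[both])
    t_area <- tabulate(truth_mask[truth_mask > 0])
    p_area <- tabulate(pred_mask[pred_mask > 0])
    pairs <- as.data.frame(inter, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$Freq > 0, ]
    pairs$truth <- as.integer(pairs$truth)
    pairs$pred <- as.integer(pairs$pred)
    pairs$iou <- pairs$Freq /
      (t_area[pairs$truth] + p_area[pairs$pred] - pairs$Freq)
    pairs <- pairs[order(-pairs$iou), ]
  } else {
    pairs <- data.frame(truth = integer(0), pred = integer(0),
                        Freq = integer(0), iou = numeric(0))
  }

  matched_t <- integer(0); matched_p <- integer(0)
  matches <- list()
  for (e in seq_len(nrow(pairs))) {
    ti <- pairs$truth[e]; pi <- pairs$pred[e]
    if (ti %in% matched_t || pi %in% matched_p) next
    if (pairs$iou[e] < iou_threshold) break
    matched_t <- c(matched_t, ti); matched_p <- c(matched_p, pi)
    matches[[length(matches) + 1]] <-
      data.frame(truth_id = ti, pred_id = pi, iou = pairs$iou[e])
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(truth_id = integer(0), pred_id = integer(0), iou = numeric(0))
  unmatched <- setdiff(truth_ids, matches$truth_id)
  if (length(unmatched)) {
    matches <- rbind(matches, data.frame(truth_id = unmatched,
                                         pred_id = NA_integer_, iou = 0))
  }
  matches <- matches[order(matches$truth_id), ]
  rownames(matches) <- NULL
  list(
    detection_fraction = length(matched_t) / n_truth,
    n_truth = n_truth, n_pred = length(pred_ids),
    n_matched = length(matched_t), matches = matches
  )
}

#' Summarise per-cell ratios by condition
#'
#' @param records Data frame of [measure_nc_ratio()] records (rows from
#'   several fields/conditions bound together), containing the grouping
#'   columns; only rows with `included = TRUE` enter the statistics.
#' @param group_keys Character vector of grouping column names.
#' @param expected_n Soft range for cells per condition; a warning is
#'   issued outside it (default `c(100, 200)`).
#' @return Data frame with group columns plus `mean_ratio`, `sd_ratio`, `n`.
#' @export
summarize_population <- function(records, group_keys,
                                 expected_n = c(100, 200)) {
  if (!nrow(records)) stop("no records supplied")
  inc <- records[records$included, , drop = FALSE]
  if (!nrow(inc)) stop("all records are flagged/excluded")
  missing_keys <- setdiff(group_keys, names(inc))
  if (length(missing_keys)) {
    stop("missing grouping columns: ", paste(missing_keys, collapse = ", "))
  }
  grp <- interaction(inc[group_keys], drop = TRUE)
  out <- do.call(rbind, lapply(split(inc, grp), function(d) {
    s <- summarize_replicates(d$ratio)
    cbind(d[1, group_keys, drop = FALSE],
          data.frame(mean_ratio = s$mean, sd_ratio = s$sd, n = s$n))
  }))
  rownames(out) <- NULL
  low <- out$n < expected_n[1] | out$n > expected_n[2]
  if (any(low)) {
    warning(sprintf("%d condition(s) outside the expected %d-%d cells per condition",
                    sum(low), expected_n[1], expected_n[2]))
  }
  out
}
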