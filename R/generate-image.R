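#' Specification of one synthetic microscopy field
#'
#' Describes a multi-channel field emulating the imaging setup: a
#' bright-field-like channel where cells appear as discs with darker rims,
#' a nuclear-marker channel with one bright nucleus per cell and a
#' reporter channel whose per-cell nuclear:cytosolic intensity ratio is
#' drawn from a configurable distribution (the quantity the downstream
#' analysis estimates). Intensities are 16-bit-style counts.
#'
#' @param width,height Field size in pixels.
#' @param n_cells Number of cells to place (>= 0); placement is
#'   non-overlapping with a minimum 3 px gap and errors out after bounded
#'   retries.
#' @param r_range Cell radius range in pixels, drawn uniformly.
#' @param nuclear_fraction Nuclear area fraction of the cell (default
#'   0.08); the nucleus radius is `sqrt(nuclear_fraction) * r`.
#' @param ratio_mean,ratio_sd Mean and sd of the per-cell true N:C reporter
#'   ratio (normal, truncated at 0.05).
#' @param cytosol_range Range of the per-cell cytosolic reporter intensity
#'   above background, drawn uniformly.
#' @param background Named channel background levels (counts).
#' @param rim_depth Bright-field rim darkening (counts) over the outer
#'   2 px of each cell.
#' @param interior_lift Bright-field interior brightening (counts).
#' @param nuclear_signal Nuclear-marker intensity above background.
#' @param noise_sd Additive Gaussian noise sd applied to every channel.
#' @param seed Integer seed; same seed, same field.
#' @return Object of class `image_field_spec`.
#' @export
image_field_spec <- function(width = 512, height = 512, n_cells = 100,
                             r_range = c(10, 16),
                             nuclear_fraction = 0.08,
                             ratio_mean = 1.0, ratio_sd = 0.2,
                             cytosol_range = c(1000, 1400),
                             background = c(brightfield = 1000, nuclear = 100,
                                            reporter = 200),
                             rim_depth = 400, interior_lift = 150,
                             nuclear_signal = 2900,
                             noise_sd = 60, seed = 1L) {
  stopifnot(width > 0, height > 0, n_cells >= 0,
            length(r_range) == 2, r_range[1] > 2, r_range[2] >= r_range[1],
            nuclear_fraction > 0, nuclear_fraction < 1,
            noise_sd >= 0)
  structure(
    list(width = width, height = height, n_cells = as.integer(n_cells),
         r_range = r_range, nuclear_fraction = nuclear_fraction,
         ratio_mean = ratio_mean, ratio_sd = ratio_sd,
         cytosol_range = cytosol_range, background = background,
         rim_depth = rim_depth, interior_lift = interior_lift,
         nuclear_signal = nuclear_signal, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "image_field_spec"
  )
}

#' Canned field specifications
#'
#' `"default"` uses a mid-range ratio; `"replete"` and `"starved"` match
#' the two ends of the relocation curves (cytosolic reporter, mean ratio
#' 0.45, vs nuclear-enriched, mean ratio 1.8).
#'
#' @param name One of "default", "replete", "starved", "clean" (no noise).
#' @param seed Seed passed through.
#' @param ... Further overrides forwarded to [image_field_spec()].
#' @return An `image_field_spec`.
#' @export
canned_field_spec <- function(name = c("default", "replete", "starved", "clean"),
                              seed = 7L, ...) {
  name <- match.arg(name)
  switch(name,
    default = image_field_spec(seed = seed, ...),
    replete = image_field_spec(ratio_mean = 0.45, ratio_sd = 0.10, seed = seed, ...),
    starved = image_field_spec(ratio_mean = 1.80, ratio_sd = 0.30, seed = seed, ...),
    clean   = image_field_spec(noise_sd = 0, seed = seed, ...)
  )
}

#' Generate a synthetic multi-channel field with ground truth
#'
#' @param spec An [image_field_spec()].
#' @param max_tries Total rejection-sampling attempts for non-overlapping
#'   placement before giving up with an error.
#' @return List of class `image_fixture` with
#'   * `field`: list of numeric matrices `brightfield`, `nuclear`,
#'     `reporter` (rows = y, cols = x);
#'   * `labels`: integer matrices `cell` and `nucleus` (0 = background);
#'   * `truth`: data.frame per cell (`cell_id`, `cx`, `cy`, `r_px`,
#'     `r_nucleus_px`, `cell_area_px`, `nucleus_area_px`, `true_ratio`,
#'     `i_c_true`);
#'   * `spec`.
#' @export
generate_image_fixture <- function(spec, max_tries = 200 * max(spec$n_cells, 1)) {
  stopifnot(inherits(spec, "image_field_spec"))
  set.seed(spec$seed)
  W <- spec$width; H <- spec$height
  bf  <- matrix(spec$background[["brightfield"]], H, W)
  nuc <- matrix(spec$background[["nuclear"]], H, W)
  rep_ch <- matrix(spec$background[["reporter"]], H, W)
  cell_lab <- matrix(0L, H, W)
  nuc_lab <- matrix(0L, H, W)

  centers <- matrix(numeric(0), ncol = 3)  # cx, cy, r
  tries <- 0
  while (nrow(centers) < spec$n_cells) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop(sprintf("could not place %d non-overlapping cells in %d attempts",
                   spec$n_cells, max_tries))
    }
    r <- stats::runif(1, spec$r_range[1], spec$r_range[2])
    cx <- stats::runif(1, r + 2, W - r - 1)
    cy <- stats::runif(1, r + 2, H - r - 1)
    if (nrow(centers)) {
      d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      if (any(d < centers[, 3] + r + 3)) next
    }
    centers <- rbind(centers, c(cx, cy, r))
  }

  n <- nrow(centers)
  truth <- data.frame(
    cell_id = integer(0), cx = numeric(0), cy = numeric(0), r_px = numeric(0),
    r_nucleus_px = numeric(0), cell_area_px = integer(0),
    nucleus_area_px = integer(0), true_ratio = numeric(0), i_c_true = numeric(0)
  )

  for (i in seq_len(n)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; r <- centers[i, 3]
    r_n <- sqrt(spec$nuclear_fraction) * r
    ratio <- max(0.05, stats::rnorm(1, spec$ratio_mean, spec$ratio_sd))
    i_c <- stats::runif(1, spec$cytosol_range[1], spec$cytosol_range[2])

    xs <- max(1, floor(cx - r - 1)):min(W, ceiling(cx + r + 1))
    ys <- max(1, floor(cy - r - 1)):min(H, ceiling(cy + r + 1))
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    dist <- sqrt(dx^2 + dy^2)

    in_cell <- dist <= r
    in_rim <- dist <= r & dist > r - 2
    in_nuc <- dist <= r_n

    bf[ys, xs][in_cell] <- spec$background[["brightfield"]] + spec$interior_lift
    bf[ys, xs][in_rim] <- spec$background[["brightfield"]] - spec$rim_depth
    nuc[ys, xs][in_nuc] <- spec$background[["nuclear"]] + spec$nuclear_signal
    rep_ch[ys, xs][in_cell] <- spec$background[["reporter"]] + i_c
    rep_ch[ys, xs][in_nuc] <- spec$background[["reporter"]] + ratio * i_c
    cell_lab[ys, xs][in_cell] <- i
    nuc_lab[ys, xs][in_nuc] <- i

    truth <- rbind(truth, data.frame(
      cell_id = i, cx = cx, cy = cy, r_px = r, r_nucleus_px = r_n,
      cell_area_px = sum(in_cell), nucleus_area_px = sum(in_nuc),
      true_ratio = ratio, i_c_true = i_c
    ))
  }

  # optics: mild blur on the bright-field and nuclear channels; the
  # reporter channel is kept sharp so region means are exactly the drawn
  # intensities (stated limitation of the emulation)
  bf <- ebimage_blur(bf, sigma = 1)
  nuc <- ebimage_blur(nuc, sigma = 0.8)

  if (spec$noise_sd > 0) {
    bf <- bf + stats::rnorm(length(bf), 0, spec$noise_sd)
    nuc <- nuc + stats::rnorm(length(nuc), 0, spec$noise_sd)
    rep_ch <- rep_ch + stats::rnorm(length(rep_ch), 0, spec$noise_sd)
  }
  clip <- function(m) pmin(pmax(m, 0), 65535)

  structure(
    list(
      field = list(brightfield = clip(bf), nuclear = clip(nuc),
                   reporter = clip(rep_ch)),
      labels = list(cell = cell_lab, nucleus = nuc_lab),
      truth = truth,
      spec = spec
    ),
    class = "image_fixture"
  )
}

ebimage_blur <- function(m, sigma) {
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

#' Write an image fixture to TIFF + JSON files
#'
#' Emits a multi-page 16-bit TIFF (channel order brightfield, nuclear,
#' reporter), 16-bit label TIFFs for cells and nuclei, and a JSON truth
#' file listing per-cell centroid, radii, areas and true ratio.
#'
#' @param fixture Result of [generate_image_fixture()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_image_fixture <- function(fixture, dir, prefix = "field") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    image = file.path(dir, paste0(prefix, ".tif")),
    cell_labels = file.path(dir, paste0(prefix, "_cells.tif")),
    nucleus_labels = file.path(dir, paste0(prefix, "_nuclei.tif")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  # counts -> [0,1]; the half-count offset makes the writer's truncation to
  # 16-bit land on the rounded count exactly
  to_unit <- function(m) pmin((pmin(pmax(round(m), 0), 65535) + 0.5) / 65535, 1)
  tiff::writeTIFF(
    lapply(fixture$field, to_unit),
    paths[["image"]], bits.per.sample = 16
  )
  tiff::writeTIFF(to_unit(fixture$labels$cell), paths[["cell_labels"]],
                  bits.per.sample = 16)
  tiff::writeTIFF(to_unit(fixture$labels$nucleus), paths[["nucleus_labels"]],
                  bits.per.sample = 16)
  jsonlite::write_json(fixture$truth, paths[["truth"]], digits = NA)
  invisible(paths)
}

#' Read a multi-channel field (and optional labels) back from TIFF
#'
#' @param image_path Multi-page TIFF as written by [write_image_fixture()].
#' @param channels Channel names in page order.
#' @param label_path Optional 16-bit label TIFF.
#' @return List with `field` (named matrices, counts) and, if requested,
#'   `labels` (integer matrix).
#' @export
read_image_field <- function(image_path,
                             channels = c("brightfield", "nuclear", "reporter"),
                             label_path = NULL) {
  pages <- tiff::readTIFF(image_path, all = TRUE)
  if (length(pages) != length(channels)) {
    stop(sprintf("expected %d channels, found %d pages",
                 length(channels), length(pages)))
  }
  field <- stats::setNames(lapply(pages, function(p) round(p * 65535)), channels)
  out <- list(field = field)
  if (!is.null(label_path)) {
    out$labels <- matrix(as.integer(round(tiff::readTIFF(label_path) * 65535)),
                         nrow = nrow(field[[1]]))
  }
  out
}
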