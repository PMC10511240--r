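#' Normalise plate-reader reporter fluorescence
#'
#' Subtracts the mean blank fluorescence (wells of untagged cells, or a
#' dark-count constant when no blank wells exist) and divides by the
#' number of cells per well, yielding per-cell reporter fluorescence.
#' Negative values after subtraction are clipped to zero and flagged.
#'
#' @param records Data frame with columns `well`, `strain`, `condition`,
#'   `time_h`, `fluorescence`, `cells`.
#' @param blank_records Data frame of blank wells with a `fluorescence`
#'   column, or NULL to use `dark_count`.
#' @param dark_count Constant blank level used when `blank_records` is
#'   NULL; an error is raised if both are missing.
#' @return `records` with added columns `norm_fluor` (per-cell,
#'   blank-subtracted) and `clipped`.
#' @export
normalize_plate <- function(records, blank_records = NULL, dark_count = NULL) {
  stopifnot(all(c("fluorescence", "cells") %in% names(records)))
  if (any(records$fluorescence < 0)) stop("fluorescence must be >= 0")
  if (any(records$cells <= 0)) stop("cell counts must be > 0")
  blank <- if (!is.null(blank_records) && nrow(blank_records)) {
    mean(blank_records$fluorescence)
  } else if (!is.null(dark_count)) {
    dark_count
  } else {
    stop("no blank wells and no dark_count configured")
  }
  raw <- (records$fluorescence - blank) / records$cells
  records$norm_fluor <- pmax(raw, 0)
  records$clipped <- raw < 0
  attr(records, "blank") <- blank
  records
}

#' Fold induction of a reporter between starved and replete conditions
#'
#' @param starved,replete Numeric vectors of normalised per-cell
#'   fluorescence in the two conditions.
#' @return `mean(starved) / mean(replete)`.
#' @export
induction_ratio <- function(starved, replete) {
  m_rep <- mean(replete)
  if (!is.finite(m_rep) || m_rep <= 0) {
    stop("replete mean must be positive")
  }
  mean(starved) / m_rep
}

#' Significance star coding used in the figure annotations
#'
#' @param p P-value(s).
#' @return Character vector: `"****"` p < 1e-4, `"***"` p < 1e-3,
#'   `"**"` p < 1e-2, `"*"` p < 0.05, otherwise `"n.s."`.
#' @export
star_code <- function(p) {
  cut(p,
      breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "n.s."),
      right = FALSE) |> as.character()
}

#' Group comparisons used across the reporter figures
#'
#' Two-sided tests between condition groups: Student's t (equal-variance,
#' the test quoted in the figure legends), Tukey's HSD over all pairs with
#' family-wise correction, or the Mann-Whitney rank-sum test. Results
#' carry the star coding of the figure annotations.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 groups).
#' @param method One of `"student_t"`, `"tukey_hsd"`, `"mann_whitney"`.
#'   `student_t` and `mann_whitney` run all pairwise comparisons
#'   (uncorrected, as in the figure legends); `tukey_hsd` corrects
#'   family-wise via the studentized range.
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `statistic` (t statistic, mean difference for Tukey, or W),
#'   `p_value`, `stars`.
#' @export
#' @examples
#' compare_groups(list(a = c(1, 2, 3), b = c(11, 12, 13)), "student_t")
compare_groups <- function(values_by_group,
                           method = c("student_t", "tukey_hsd", "mann_whitney")) {
  method <- match.arg(method)
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  if (is.null(names(values_by_group)) || any(!nzchar(names(values_by_group)))) {
    names(values_by_group) <- paste0("group", seq_along(values_by_group))
  }
  ns <- vapply(values_by_group, length, integer(1))
  if (method %in% c("student_t", "tukey_hsd") && any(ns < 2)) {
    stop("each group needs n >= 2 for t / Tukey tests")
  }

  if (method == "tukey_hsd") {
    df <- data.frame(
      value = unlist(values_by_group, use.names = FALSE),
      group = factor(rep(names(values_by_group), ns))
    )
    tk <- stats::TukeyHSD(stats::aov(value ~ group, data = df))$group
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    out <- data.frame(
      group1 = vapply(pairs, `[`, character(1), 1),
      group2 = vapply(pairs, `[`, character(1), 2),
      statistic = tk[, "diff"],
      p_value = tk[, "p adj"],
      stringsAsFactors = FALSE
    )
  } else {
    combos <- utils::combn(names(values_by_group), 2)
    out <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
      g1 <- combos[1, j]; g2 <- combos[2, j]
      x <- values_by_group[[g1]]; y <- values_by_group[[g2]]
      if (method == "student_t") {
        ht <- tryCatch(
          stats::t.test(x, y, var.equal = TRUE),
          error = function(e) NULL
        )
        if (is.null(ht)) {
          # degenerate: zero variance in both groups
          stat <- 0; p <- if (mean(x) == mean(y)) 1 else 0
        } else {
          stat <- unname(ht$statistic); p <- ht$p.value
        }
      } else {
        ht <- stats::wilcox.test(x, y, exact = FALSE)
        stat <- unname(ht$statistic); p <- ht$p.value
      }
      data.frame(group1 = g1, group2 = g2, statistic = stat, p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }
  out$stars <- star_code(out$p_value)
  rownames(out) <- NULL
  out
}
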