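#' Assign species labels to MRM peaks by transition and migration time
#'
#' Isobaric isomers (1-IP7 and 5-IP7) share an MRM transition and are
#' discriminated by their capillary-electrophoresis migration time relative
#' to the co-injected 13C standards. Each 12C peak is matched first by
#' transition (m/z pair within `mz_tol`), then to the nearest
#' same-transition 13C reference within `mt_tolerance` minutes after a
#' median-offset alignment of analyte against reference migration times.
#' Within a transition the 13C references themselves are ordered by
#' migration time and labelled with the species in migration order (5-IP7
#' migrates before 1-IP7).
#'
#' Conflicts where two analyte peaks claim the same reference are resolved
#' in favour of the smaller residual, the loser falling back to its
#' next-nearest in-tolerance reference; an exact residual tie raises an
#' ambiguity error (condition class `ippdyn_ambiguity`) listing the
#' candidate peaks. An analyte with no reference in tolerance is returned
#' with `assigned = FALSE`, not an error.
#'
#' @param peaks Data frame with columns `sample_id`, `precursor_mz`,
#'   `product_mz`, `migration_time_min`, `peak_area`, `label`
#'   ("12C"/"13C").
#' @param transitions Transition table, see [transition_table()].
#' @param reference_migration_times Named vector of nominal species
#'   migration times used only to fix the species order of isomers
#'   (default [default_migration_times()]).
#' @param mt_tolerance Matching tolerance in minutes after alignment
#'   (default 0.2).
#' @param mz_tol m/z tolerance for transition matching (default 0.3).
#' @return The input rows with added columns `compound`, `species`,
#'   `assigned`, `residual_min` (analyte rows; alignment residual against
#'   the matched reference) and, for 13C rows, their species label. The
#'   per-sample median migration offsets are attached as attribute
#'   `"offsets"`.
#' @export
assign_peaks <- function(peaks, transitions = transition_table(),
                         reference_migration_times = default_migration_times(),
                         mt_tolerance = 0.2, mz_tol = 0.3) {
  required <- c("sample_id", "precursor_mz", "product_mz",
                "migration_time_min", "peak_area", "label")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols)) {
    stop("peak table lacks columns: ", paste(missing_cols, collapse = ", "))
  }

  peaks$compound <- match_transition(peaks, transitions, mz_tol)
  peaks$species <- NA_character_
  peaks$assigned <- FALSE
  peaks$residual_min <- NA_real_

  sp <- ipp_species()
  out <- split(peaks, peaks$sample_id)
  offsets <- stats::setNames(numeric(length(out)), names(out))

  for (sid in names(out)) {
    p <- out[[sid]]
    is_ref <- p$label == "13C" & !is.na(p$compound)
    is_ana <- p$label == "12C" & !is.na(p$compound)

    # label the references: within each compound, migration order fixes the
    # species order (species sharing a compound are isomers)
    for (cmp in unique(p$compound[is_ref])) {
      ref_idx <- which(is_ref & p$compound == cmp)
      ref_idx <- ref_idx[order(p$migration_time_min[ref_idx])]
      expect <- sp$species[sp$compound == cmp]
      expect <- expect[order(reference_migration_times[expect])]
      k <- min(length(ref_idx), length(expect))
      if (k > 0) {
        p$species[ref_idx[seq_len(k)]] <- expect[seq_len(k)]
        p$assigned[ref_idx[seq_len(k)]] <- TRUE
      }
    }

    ana_idx <- which(is_ana)
    ref_ok <- which(is_ref & p$assigned)
    if (length(ana_idx) && length(ref_ok)) {
      # provisional nearest-reference offsets -> global alignment shift
      raw_off <- vapply(ana_idx, function(i) {
        cand <- ref_ok[p$compound[ref_ok] == p$compound[i]]
        if (!length(cand)) return(NA_real_)
        d <- p$migration_time_min[i] - p$migration_time_min[cand]
        d[which.min(abs(d))]
      }, numeric(1))
      # a robust drift estimate needs a few peaks; with fewer, trust the
      # raw migration times rather than letting one stray peak define the
      # alignment
      shift <- if (sum(is.finite(raw_off)) >= 3) {
        stats::median(raw_off, na.rm = TRUE)
      } else 0
      if (is.na(shift)) shift <- 0
      offsets[sid] <- shift

      assignment <- match_aligned(
        ana_mt = p$migration_time_min[ana_idx] - shift,
        ana_compound = p$compound[ana_idx],
        ref_mt = p$migration_time_min[ref_ok],
        ref_compound = p$compound[ref_ok],
        tolerance = mt_tolerance,
        sample_id = sid
      )
      hit <- !is.na(assignment$ref)
      p$species[ana_idx[hit]] <- p$species[ref_ok[assignment$ref[hit]]]
      p$assigned[ana_idx[hit]] <- TRUE
      p$residual_min[ana_idx] <- assignment$residual
    }
    out[[sid]] <- p
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "offsets") <- offsets
  res
}

# Map peaks onto transition-table compounds by m/z pair + label.
match_transition <- function(peaks, transitions, mz_tol) {
  vapply(seq_len(nrow(peaks)), function(i) {
    hit <- which(
      transitions$label == peaks$label[i] &
        abs(transitions$precursor_mz - peaks$precursor_mz[i]) <= mz_tol &
        abs(transitions$product_mz - peaks$product_mz[i]) <= mz_tol
    )
    if (length(hit) == 1) transitions$compound[hit] else NA_character_
  }, character(1))
}

# Greedy nearest matching of aligned analyte times onto reference times,
# one-to-one within each compound; smaller residual wins a contested
# reference, exact ties abort with an ambiguity error.
match_aligned <- function(ana_mt, ana_compound, ref_mt, ref_compound,
                          tolerance, sample_id) {
  n <- length(ana_mt)
  ref_assigned_to <- rep(NA_integer_, length(ref_mt))
  ana_ref <- rep(NA_integer_, n)
  ana_res <- rep(NA_real_, n)

  # candidate edges sorted by residual: globally greedy is one-to-one optimal
  # enough here because co-migrating species are well separated
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    cand <- which(ref_compound == ana_compound[i])
    if (!length(cand)) return(NULL)
    d <- abs(ana_mt[i] - ref_mt[cand])
    keep <- d <= tolerance
    if (!any(keep)) return(NULL)
    data.frame(ana = i, ref = cand[keep], res = d[keep])
  }))
  if (is.null(edges) || !nrow(edges)) {
    return(list(ref = ana_ref, residual = ana_res))
  }
  edges <- edges[order(edges$res), , drop = FALSE]

  for (e in seq_len(nrow(edges))) {
    i <- edges$ana[e]; r <- edges$ref[e]
    if (!is.na(ana_ref[i]) || !is.na(ref_assigned_to[r])) next
    # exact-tie check: another unassigned analyte with identical residual
    # for the same reference cannot be ordered
    tie <- edges$ref == r & abs(edges$res - edges$res[e]) < 1e-12 &
      edges$ana != i & is.na(ana_ref[edges$ana])
    if (any(tie)) {
      cands <- sort(unique(c(i, edges$ana[tie])))
      stop(structure(
        class = c("ippdyn_ambiguity", "error", "condition"),
        list(
          message = sprintf(
            "sample %s: analyte peaks %s claim reference at %.3f min with equal residual %.4f",
            sample_id, paste(cands, collapse = ", "), ref_mt[r], edges$res[e]
          ),
          call = NULL, candidates = cands
        )
      ))
    }
    ana_ref[i] <- r
    ref_assigned_to[r] <- i
    ana_res[i] <- edges$res[e]
  }
  list(ref = ana_ref, residual = ana_res)
}
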