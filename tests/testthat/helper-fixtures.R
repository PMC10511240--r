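# Shared fixtures and independent oracles for the suite.

# Small field spec: keeps image tests fast while preserving the default
# noise and geometry statistics.
small_field_spec <- function(n_cells = 25, seed = 7L, ...) {
  image_field_spec(width = 256, height = 256, n_cells = n_cells,
                   seed = seed, ...)
}

# Closed-form oracle for the whole quantification chain, written directly
# from the protocol arithmetic and independent of the pipeline code:
# conc_uM = (area ratio x IS fmol) x (V_extract / V_aliquot) / recovery
#           / n_cells x 1e6 / V_accessible.
chain_oracle_uM <- function(analyte_area, standard_area, standard_fmol,
                            aliquot_ul = 15, extract_ul = 20,
                            recovery = 1, n_cells = 1e7,
                            v_accessible_fl = 42 * (1 - 0.18)) {
  (analyte_area / standard_area) * standard_fmol *
    (extract_ul / aliquot_ul) / recovery / n_cells * 1e6 / v_accessible_fl
}

# Brute-force one-to-one matcher: enumerates every assignment of analyte
# peaks to same-compound references (after subtracting a given shift) and
# returns the one minimising the total absolute residual, ignoring
# out-of-tolerance pairs. Exponential, only for tiny cases.
brute_force_match <- function(ana_mt, ref_mt, shift = 0, tolerance = 0.2) {
  n <- length(ana_mt)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  # pad references with NA (= unassigned) so n_ana may exceed n_ref
  cand <- c(seq_along(ref_mt), rep(NA_integer_, n))
  best <- NULL; best_cost <- Inf
  for (p in unique(lapply(perms(cand), function(x) x[seq_len(n)]))) {
    used <- p[!is.na(p)]
    if (anyDuplicated(used)) next
    res <- abs((ana_mt - shift) - ref_mt[p])
    if (any(!is.na(p) & res > tolerance, na.rm = TRUE)) next
    cost <- sum(res, na.rm = TRUE) - 1e3 * sum(!is.na(p))  # maximise matches
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}

# relative comparison with an absolute floor so exact zeros compare cleanly
expect_rel_equal <- function(object, expected, rel_tol = 1e-9) {
  err <- abs(object - expected) / (abs(expected) + 1e-12)
  expect_true(all(err <= rel_tol),
              label = sprintf("max rel err %.3g vs tol %.3g", max(err), rel_tol))
}
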