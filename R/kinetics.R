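#' Fit a single-exponential decay to a concentration time course
#'
#' Least-squares fit of `C(t) = C0 * exp(-k t)`, initialised from a
#' log-linear regression on the positive points and refined by
#' Levenberg-Marquardt nonlinear least squares with `k >= 0`.
#' Concentrations at or below zero (below detection) are treated as
#' missing in the log-space initialisation but kept in the nonlinear
#' refinement.
#'
#' @param times Time points (>= 3 distinct values).
#' @param concentrations Concentrations (>= 0), same length.
#' @return Object of class `decay_fit`: list with `c0`, `k`, `sse`,
#'   `method` and the fitted model.
#' @export
#' @examples
#' t <- seq(0, 240, 20)
#' fit_exponential_decay(t, 14 * exp(-0.01716 * t))
fit_exponential_decay <- function(times, concentrations) {
  keep <- is.finite(times) & is.finite(concentrations)
  times <- times[keep]; concentrations <- concentrations[keep]
  if (length(unique(times)) < 3) stop("need at least 3 distinct time points")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (all(concentrations == 0)) stop("all-zero series cannot be fitted")

  pos <- concentrations > 0
  if (sum(pos) >= 2 && length(unique(times[pos])) >= 2) {
    init_fit <- stats::lm(log(concentrations[pos]) ~ times[pos])
    c0_0 <- exp(stats::coef(init_fit)[[1]])
    k_0 <- max(0, -stats::coef(init_fit)[[2]])
  } else {
    c0_0 <- max(concentrations)
    k_0 <- 0.01
  }

  fit <- minpack.lm::nlsLM(
    y ~ c0 * exp(-k * t),
    data = data.frame(t = times, y = concentrations),
    start = list(c0 = c0_0, k = k_0),
    lower = c(c0 = 1e-12, k = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  structure(
    list(c0 = cf[["c0"]], k = cf[["k"]],
         sse = sum(stats::resid(fit)^2),
         method = "log-linear init + Levenberg-Marquardt",
         model = fit),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay: C0 = %.4g, k = %.4g per unit time (SSE %.3g)\n",
              x$c0, x$k, x$sse))
  invisible(x)
}

#' Fit a four-parameter logistic to a relocation time course
#'
#' Least-squares fit of `R(t) = baseline + amplitude / (1 + exp(-(t -
#' t_half) / width))` with bounds `amplitude >= 0`, `t_half` inside the
#' observed time range and `width > 0`. Fitting restarts from a small grid
#' of initial half-times; non-convergence after all restarts is flagged
#' rather than thrown. A fitted amplitude indistinguishable from the
#' residual noise is flagged `flat` ("no transition"), which downstream
#' threshold inference refuses to anchor on.
#'
#' @param times Time points (>= 5).
#' @param ratios Response values, same length.
#' @param flat_tol Amplitude below `flat_tol * max(sd(ratios), eps)` flags
#'   a flat series (default 0.1).
#' @return Object of class `logistic_fit`: list with `baseline`,
#'   `amplitude`, `t_half`, `width`, `sse`, `flat`, `converged`.
#' @export
fit_logistic <- function(times, ratios, flat_tol = 0.1) {
  keep <- is.finite(times) & is.finite(ratios)
  times <- times[keep]; ratios <- ratios[keep]
  if (length(times) < 5) stop("need at least 5 points for a logistic fit")

  spread <- stats::sd(ratios)
  if (!is.finite(spread) || spread < 1e-12) {
    # perfectly flat input: no transition by construction
    return(structure(
      list(baseline = mean(ratios), amplitude = 0,
           t_half = NA_real_, width = NA_real_, sse = 0,
           flat = TRUE, converged = TRUE),
      class = "logistic_fit"
    ))
  }

  rng <- range(times)
  base0 <- min(ratios); amp0 <- max(ratios) - min(ratios)
  # initial t_half: first crossing of the half level, plus grid restarts
  half_level <- base0 + amp0 / 2
  cross <- times[which(ratios >= half_level)[1]]
  starts_t <- unique(c(cross, stats::quantile(times, c(0.25, 0.5, 0.75))))
  starts_t <- starts_t[is.finite(starts_t)]

  best <- NULL
  for (t0 in starts_t) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + a / (1 + exp(-(t - th) / w)),
        data = data.frame(t = times, y = ratios),
        start = list(b = base0, a = amp0, th = t0, w = diff(rng) / 20),
        lower = c(b = -Inf, a = 0, th = rng[1], w = 1e-6),
        upper = c(b = Inf, a = Inf, th = rng[2], w = diff(rng)),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }

  if (is.null(best)) {
    return(structure(
      list(baseline = NA_real_, amplitude = NA_real_, t_half = NA_real_,
           width = NA_real_, sse = NA_real_, flat = FALSE, converged = FALSE),
      class = "logistic_fit"
    ))
  }
  cf <- stats::coef(best$fit)
  resid_sd <- sqrt(best$sse / max(1, length(times) - 4))
  flat <- cf[["a"]] < flat_tol * max(spread, 1e-12) ||
    cf[["a"]] < 2 * resid_sd * flat_tol
  structure(
    list(baseline = cf[["b"]], amplitude = cf[["a"]],
         t_half = cf[["th"]], width = cf[["w"]],
         sse = best$sse, flat = flat, converged = TRUE),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Logistic fit: did not converge\n")
  } else if (x$flat) {
    cat(sprintf("Logistic fit: flat series (baseline %.3g, no transition)\n",
                x$baseline))
  } else {
    cat(sprintf(
      "Logistic fit: baseline %.3g + %.3g / (1 + exp(-(t - %.4g)/%.3g)), SSE %.3g\n",
      x$baseline, x$amplitude, x$t_half, x$width, x$sse))
  }
  invisible(x)
}

#' Infer the repressive concentration threshold
#'
#' Anchors the threshold at the relocation half-maximum: the concentration
#' the fitted decay has reached when the logistic relocation crosses half
#' of its amplitude, `threshold = C0 * exp(-k * t_half)`. An alternative
#' onset anchor uses the time at which the logistic has risen by a given
#' fraction of its amplitude (`t_half + width * log(f / (1 - f))`).
#'
#' @param decay_fit A [fit_exponential_decay()] result.
#' @param logistic_fit A [fit_logistic()] result; must not be flat.
#' @param anchor `"half_max"` (default) or `"onset"`.
#' @param onset_fraction Rise fraction defining the onset anchor
#'   (default 0.05).
#' @return Object of class `threshold_estimate`: list with
#'   `threshold_uM`, `t_anchor_min`, `anchor`, `decay_fit`, `logistic_fit`.
#' @export
#' @examples
#' tc <- generate_relocation_timecourse(seed = 1)
#' dec <- fit_exponential_decay(tc$concentration$time_min, tc$concentration$value)
#' rel <- subset(tc$relocation, series_id == "vip1d")
#' log_fit <- fit_logistic(rel$time_min, rel$value)
#' infer_threshold(dec, log_fit)$threshold_uM  # 5.0
infer_threshold <- function(decay_fit, logistic_fit,
                            anchor = c("half_max", "onset"),
                            onset_fraction = 0.05) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(decay_fit, "decay_fit"),
            inherits(logistic_fit, "logistic_fit"))
  if (!logistic_fit$converged) stop("logistic fit did not converge")
  if (logistic_fit$flat) {
    stop("flat relocation series: no transition to anchor the threshold on")
  }
  t_anchor <- switch(anchor,
    half_max = logistic_fit$t_half,
    onset = logistic_fit$t_half + logistic_fit$width *
      log(onset_fraction / (1 - onset_fraction))
  )
  structure(
    list(
      threshold_uM = decay_fit$c0 * exp(-decay_fit$k * t_anchor),
      t_anchor_min = t_anchor,
      anchor = anchor,
      decay_fit = decay_fit,
      logistic_fit = logistic_fit
    ),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "Repression threshold: %.3g uM (decay evaluated at the %s anchor, t = %.4g min)\n",
    x$threshold_uM, x$anchor, x$t_anchor_min))
  invisible(x)
}
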