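#' Generate paired concentration-decay and relocation time courses
#'
#' Emulates the kinetic experiment linking metabolite depletion to
#' transcription-factor relocation. The vip1d-like fixture pairs a 5-IP7
#' decay starting from its 20-fold overaccumulated level,
#' `C(t) = 14.0 * exp(-0.01716 t)` uM (t in minutes), with a delayed
#' sigmoidal nuclear relocation
#' `R(t) = 0.45 + 1.35 / (1 + exp(-(t - 60) / 12))`; the wt-like fixture
#' uses the same logistic with a fast half-time of 10 min. Optional
#' additive Gaussian noise on both series.
#'
#' @param seed Integer seed for the noise draws.
#' @param times Sampling times in minutes (default 0-240 every 10 min).
#' @param c0 Initial concentration in uM (default 14.0).
#' @param k Decay rate constant in 1/min (default 0.01716).
#' @param baseline,amplitude Logistic baseline and amplitude of the I_N/I_C
#'   ratio (defaults 0.45 and 1.35).
#' @param t_half_vip1,t_half_wt Relocation half-times in minutes (60 and 10).
#' @param width Logistic width in minutes (default 12).
#' @param conc_noise_sd,ratio_noise_sd Additive Gaussian noise sd on the
#'   concentration (uM) and ratio series; 0 = noise-free.
#' @return List with `concentration` (data.frame `time_min`, `value`,
#'   `series_id = "vip1d_5IP7"`) and `relocation` (data.frame `time_min`,
#'   `value`, `series_id` in `"vip1d"`, `"wt"`), plus `truth` carrying the
#'   generating parameters.
#' @export
#' @examples
#' tc <- generate_relocation_timecourse(seed = 1)
#' subset(tc$concentration, time_min == 60)  # 5.0 uM, noise-free default
generate_relocation_timecourse <- function(seed = 1L,
                                           times = seq(0, 240, by = 10),
                                           c0 = 14.0, k = 0.01716,
                                           baseline = 0.45, amplitude = 1.35,
                                           t_half_vip1 = 60, t_half_wt = 10,
                                           width = 12,
                                           conc_noise_sd = 0,
                                           ratio_noise_sd = 0) {
  set.seed(as.integer(seed))
  conc <- c0 * exp(-k * times)
  r_vip1 <- baseline + amplitude / (1 + exp(-(times - t_half_vip1) / width))
  r_wt <- baseline + amplitude / (1 + exp(-(times - t_half_wt) / width))
  if (conc_noise_sd > 0) {
    conc <- pmax(0, conc + stats::rnorm(length(times), 0, conc_noise_sd))
  }
  if (ratio_noise_sd > 0) {
    r_vip1 <- pmax(0, r_vip1 + stats::rnorm(length(times), 0, ratio_noise_sd))
    r_wt <- pmax(0, r_wt + stats::rnorm(length(times), 0, ratio_noise_sd))
  }
  list(
    concentration = data.frame(time_min = times, value = conc,
                               series_id = "vip1d_5IP7"),
    relocation = rbind(
      data.frame(time_min = times, value = r_vip1, series_id = "vip1d"),
      data.frame(time_min = times, value = r_wt, series_id = "wt")
    ),
    truth = list(c0 = c0, k = k, baseline = baseline, amplitude = amplitude,
                 t_half_vip1 = t_half_vip1, t_half_wt = t_half_wt,
                 width = width)
  )
}

#' Generate a synthetic plate-reader reporter table
#'
#' Emulates a transcriptional-reporter readout on a microplate
#' fluorimeter: wells of cells carrying a promoter-GFP construct measured
#' under Pi-replete and Pi-starved conditions, with blank (untagged) wells
#' for background subtraction. The true per-cell signal of starved wells is
#' `induction_fold` times the replete per-cell signal; well-to-well noise
#' is lognormal on the signal.
#'
#' @param seed Integer seed.
#' @param n_wells Wells per condition (default 3).
#' @param cells_per_well Cells per well (default 1e7, suspension adjusted
#'   to equal cell numbers before measurement).
#' @param replete_signal True per-cell fluorescence (a.u. per cell) in the
#'   replete condition.
#' @param induction_fold True starved/replete per-cell induction (default 8).
#' @param blank_level Mean blank fluorescence (a.u.).
#' @param well_cv Lognormal CV of the per-well signal (default 0.05).
#' @return List with `records` (well, strain, condition, time_h,
#'   fluorescence, cells), `blanks` (same shape, strain "blank") and
#'   `truth` (the generating parameters).
#' @export
generate_plate_fixture <- function(seed = 1L, n_wells = 3,
                                   cells_per_well = 1e7,
                                   replete_signal = 2e-4,
                                   induction_fold = 8,
                                   blank_level = 50,
                                   well_cv = 0.05) {
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + well_cv^2))
  noise <- function(n) {
    if (well_cv > 0) exp(stats::rnorm(n, -sdlog^2 / 2, sdlog)) else rep(1, n)
  }
  mk <- function(condition, per_cell) {
    data.frame(
      well = sprintf("%s_%d", condition, seq_len(n_wells)),
      strain = "reporter", condition = condition, time_h = 4,
      fluorescence = blank_level + per_cell * cells_per_well * noise(n_wells),
      cells = cells_per_well,
      stringsAsFactors = FALSE
    )
  }
  records <- rbind(mk("replete", replete_signal),
                   mk("starved", replete_signal * induction_fold))
  blanks <- data.frame(
    well = sprintf("blank_%d", seq_len(n_wells)),
    strain = "blank", condition = "blank", time_h = 4,
    fluorescence = blank_level,  # blanks carry the dark level only
    cells = cells_per_well,
    stringsAsFactors = FALSE
  )
  list(
    records = records, blanks = blanks,
    truth = list(induction_fold = induction_fold,
                 replete_signal = replete_signal, blank_level = blank_level)
  )
}
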