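# Derived kinetics from fitted residence times.
#
# For an exponentially distributed residence time with characteristic time
# tau, the dissociation rate is k_off = 1/tau. The intrinsic processivity
# of a processive enzyme is its turnover number divided by the dissociation
# rate, P = k_cat * tau, and with a known advance per catalytic cycle the
# processivity converts to a translation distance per binding run.

#' Dissociation rate from a characteristic residence time
#'
#' @param tau_s Characteristic residence time, seconds (> 0).
#' @param sig_figs Significant figures to report (default 2, the convention
#'   used for such rates; e.g. tau = 15 s gives 0.067 s^-1).
#' @return `1 / tau_s`, rounded to `sig_figs` significant figures.
#' @export
dissociation_rate <- function(tau_s, sig_figs = 2L) {
  stopifnot_scalar_pos(tau_s, "tau_s")
  signif(1 / tau_s, sig_figs)
}

#' Intrinsic processivity range
#'
#' Expected consecutive catalytic cycles per binding run:
#' `P = k_cat * tau`, evaluated at the low and high ends of the reported
#' turnover-number range and rounded to whole turnovers.
#'
#' @param kcat_range `c(low, high)` turnover numbers, s^-1, both > 0.
#' @param tau_s Characteristic residence time, seconds.
#' @return Integer `c(low, high)` turnovers.
#' @export
intrinsic_processivity <- function(kcat_range, tau_s) {
  if (length(kcat_range) != 2L || any(kcat_range <= 0) ||
      kcat_range[1] > kcat_range[2])
    stop("`kcat_range` must be c(low, high) with 0 < low <= high", call. = FALSE)
  stopifnot_scalar_pos(tau_s, "tau_s")
  round(kcat_range * tau_s)
}

#' Translation distance per binding run
#'
#' @param processivity_range `c(low, high)` turnovers.
#' @param step_nm Advance per catalytic cycle, nm (default 1 nm, one
#'   cellobiose unit along the cellulose chain).
#' @return `c(low, high)` nm.
#' @export
translation_distance <- function(processivity_range, step_nm = 1) {
  if (step_nm <= 0) stop("`step_nm` must be > 0", call. = FALSE)
  processivity_range * step_nm
}

#' Observation window length in minutes
#'
#' @param n_frames Number of frames.
#' @param frame_interval_s Frame interval, seconds.
#' @param digits Decimal places (default 1; 2500 frames at 1 s = 41.7 min).
#' @return Window length in minutes.
#' @export
observation_window_min <- function(n_frames, frame_interval_s = 1, digits = 1L) {
  stopifnot_scalar_pos(n_frames, "n_frames")
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  round(n_frames * frame_interval_s / 60, digits)
}

#' Kinetics summary for a fitted short-lived population
#'
#' @param tau_s Characteristic residence time of the (non-bleach-limited)
#'   population of interest, seconds.
#' @param kcat_range `c(low, high)` turnover numbers, s^-1.
#' @param step_nm Advance per turnover, nm.
#' @return A list of class `kinetics_result`: `koff` (s^-1),
#'   `kcat_range`, `processivity_range` (turnovers),
#'   `translation_range_nm`, `step_nm`.
#' @export
kinetics_summary <- function(tau_s, kcat_range = c(2, 11), step_nm = 1) {
  pr <- intrinsic_processivity(kcat_range, tau_s)
  structure(list(tau_s = tau_s,
                 koff = dissociation_rate(tau_s),
                 kcat_range = kcat_range,
                 processivity_range = pr,
                 translation_range_nm = translation_distance(pr, step_nm),
                 step_nm = step_nm),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("kinetics: tau = %g s -> k_off = %g s^-1\n", x$tau_s, x$koff))
  cat(sprintf("  processivity %d-%d turnovers (kcat %g-%g s^-1)\n",
              x$processivity_range[1], x$processivity_range[2],
              x$kcat_range[1], x$kcat_range[2]))
  cat(sprintf("  translation %g-%g nm at %g nm/turnover\n",
              x$translation_range_nm[1], x$translation_range_nm[2], x$step_nm))
  invisible(x)
}
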