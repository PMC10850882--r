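#' Forward tissue-enhancement model
#'
#' Discrete convolution of the baseline-subtracted arterial input function
#' with a single-compartment exponential residue `R(s) = exp(-s / tc)`,
#' delayed by `t0` and scaled by flow:
#' `C(t) = (mbf / 6000) * dt * sum_j aif(t_j) R(t - t0 - t_j)`.
#' The 1/6000 converts MBF in mL/100 mL/min into the per-second, per-mL
#' fractional rate the convolution needs. The same operator is used by the
#' synthetic generator and by the fitting routine, so noiseless curves invert
#' exactly.
#'
#' @param times Uniform time grid (s).
#' @param aif_enh Baseline-subtracted AIF (HU).
#' @param mbf Myocardial blood flow (mL/100 mL/min).
#' @param tc Residue time constant (s); mean transit time of the compartment.
#' @param t0 Arrival delay (s).
#' @return Tissue enhancement (HU) on `times`.
#' @export
tac_forward_model <- function(times, aif_enh, mbf, tc, t0 = 0) {
  (mbf / 6000) * conv_basis(times, aif_enh, tc, t0)
}

# Residue-convolution basis (model is linear in MBF). The quadrature runs on
# an internally refined grid with linearly interpolated AIF: at the
# acquisition rate alone, a fractional delay only rescales the basis by
# exp(t0/tc) within each sample cell and is exactly confounded with flow.
conv_basis <- function(times, aif_enh, tc, t0, refine = 10L) {
  dt <- times[2] - times[1]
  dt_f <- dt / refine
  t_f <- seq(times[1], times[length(times)], by = dt_f)
  aif_f <- stats::approx(times, aif_enh, t_f, rule = 2)$y
  lag <- outer(times, t_f + t0, "-") # [i, j] = t_i - t0 - t_f_j
  r <- exp(-pmax(lag, 0) / tc) * (lag >= 0)
  as.vector(r %*% aif_f) * dt_f
}

# gamma-variate bolus: 0 before onset, peak `amp` at onset + tp
gamma_variate <- function(times, amp, onset, tp, alpha) {
  s <- pmax(times - onset, 0) / tp
  amp * s^alpha * exp(alpha * (1 - s))
}

#' Generate a synthetic time-attenuation curve set
#'
#' The arterial input function is a gamma-variate bolus; each segment's
#' tissue curve is the flow-scaled residue convolution of the AIF
#' ([tac_forward_model()]) plus Gaussian HU noise. Hypoperfused (scar)
#' segments carry the reduced `true_mbf` already drawn in the ground truth.
#' A delayed-phase HU value per segment is also emitted: scar segments show
#' late enhancement only with probability `late_enh_prob` (late enhancement
#' is an insensitive scar marker).
#'
#' @param truth Ground-truth list (uses `true_mbf`, `scar_segments`).
#' @param params The `perfusion` block of [plan_config()].
#' @param seed Integer seed.
#' @return A tibble in the TAC interchange layout: `time_s`, `aif_hu`,
#'   `seg01_hu` .. `seg16_hu`, with attributes `baseline_hu` and
#'   `delayed_hu` (length-16).
#' @export
generate_tacs <- function(truth, params = plan_config()$perfusion, seed = 1L) {
  if (params$dt_s <= 0) stop("sampling interval must be positive")
  if (params$noise_sd_hu < 0) stop("noise SD must be non-negative")
  if (any(truth$true_mbf < 0)) stop("MBF must be non-negative")
  set.seed(as.integer(seed))

  times <- (seq_len(params$n_t) - 1) * params$dt_s
  aif_enh <- gamma_variate(times, params$aif_amp, params$aif_onset_s,
                           params$aif_tp_s, params$aif_alpha)
  curves <- vapply(1:16, function(s) {
    clean <- tac_forward_model(times, aif_enh, truth$true_mbf[s],
                               params$tc_s, params$t0_s)
    clean + stats::rnorm(length(times), 0, params$noise_sd_hu)
  }, numeric(length(times)))
  colnames(curves) <- sprintf("seg%02d_hu", 1:16)

  out <- dplyr::bind_cols(
    tibble::tibble(time_s = times, aif_hu = params$baseline_hu + aif_enh),
    tibble::as_tibble(curves + params$baseline_hu)
  )

  delayed <- params$baseline_hu + 30 + stats::rnorm(16, 0, 2)
  if (length(truth$scar_segments) && stats::runif(1) < params$late_enh_prob) {
    delayed[truth$scar_segments] <- delayed[truth$scar_segments] * 1.8
  }
  attr(out, "baseline_hu") <- params$baseline_hu
  attr(out, "delayed_hu") <- delayed
  out
}
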