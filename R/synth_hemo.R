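#' Generate baseline and biventricular-paced LV pressure traces
#'
#' Simulates high-fidelity pressure-wire recordings for one tested segment.
#' Each beat is a raised-cosine systolic upstroke on a diastolic floor; the
#' baseline trace realizes the configured reference dP/dt_max, and the paced
#' trace scales the systolic amplitude so its realized acute hemodynamic
#' response (AHR) is a draw from the class-conditional normal distribution
#' (defaults: target 25.5 +/- 8.8 %, viable non-target 15.4 +/- 8.0 %,
#' scarred 5.9 +/- 4.0 %). Beat-to-beat amplitude jitter and isolated
#' ectopic beats (amplitude outliers at the configured rate) are injected in
#' both traces. Scarred segments may fail to capture, in which case the
#' paced trace is just another baseline recording.
#'
#' @param ahr_class `"target"`, `"nontarget_viable"` or `"scarred"`.
#' @param params The `hemo` block of [plan_config()].
#' @param seed Integer seed.
#' @return A list of class `hemo_record_raw`: `baseline` and `paced` tibbles
#'   (`time_s`, `pressure_mmhg`), `true_ahr` (%), `capture`, `ahr_class`.
#' @export
generate_pressure_traces <- function(ahr_class,
                                     params = plan_config()$hemo, seed = 1L) {
  cls <- c("target", "nontarget_viable", "scarred")
  if (!ahr_class %in% cls) {
    stop("ahr_class must be one of ", paste(cls, collapse = ", "))
  }
  if (params$baseline_dpdt <= 0) stop("baseline dP/dt_max must be positive")
  if (params$duration_s < 10) stop("window length must be at least 10 s")
  set.seed(as.integer(seed))

  mu <- switch(ahr_class,
    target = params$ahr_target_mean,
    nontarget_viable = params$ahr_nontarget_viable_mean,
    scarred = params$ahr_scarred_mean
  )
  sd <- switch(ahr_class,
    target = params$ahr_target_sd,
    nontarget_viable = params$ahr_nontarget_viable_sd,
    scarred = params$ahr_scarred_sd
  )
  true_ahr <- stats::rnorm(1, mu, sd)

  capture <- TRUE
  if (ahr_class == "scarred" && stats::runif(1) < params$scar_capture_failure) {
    capture <- FALSE
  }

  baseline <- pressure_trace(params$baseline_dpdt, params)
  paced_dpdt <- params$baseline_dpdt * (1 + true_ahr / 100)
  paced <- if (capture) pressure_trace(paced_dpdt, params) else
    pressure_trace(params$baseline_dpdt, params)

  structure(
    list(baseline = baseline, paced = paced, true_ahr = true_ahr,
         capture = capture, ahr_class = ahr_class),
    class = "hemo_record_raw"
  )
}

# One pressure recording. `target_dpdt` sets the mean per-beat amplitude via
# dP/dt_max = A * pi / T_systole for the raised-cosine upstroke.
pressure_trace <- function(target_dpdt, params) {
  fs <- params$fs_hz
  t <- seq(0, params$duration_s, by = 1 / fs)
  beat_len <- 60 / params$hr_bpm
  n_beats <- ceiling(params$duration_s / beat_len) + 1L
  amp0 <- target_dpdt * params$systole_s / pi
  amps <- amp0 * (1 + stats::rnorm(n_beats, 0, params$beat_noise_frac))
  ect <- stats::runif(n_beats) < params$ectopy_rate
  # isolated ectopics only: never two in a row
  if (any(ect)) ect[which(ect)[c(FALSE, diff(which(ect)) == 1)]] <- FALSE
  amps[ect] <- amps[ect] * params$ectopy_factor

  p <- numeric(length(t)) + 10 # diastolic floor, mmHg
  onset <- (seq_len(n_beats) - 1) * beat_len
  for (b in seq_len(n_beats)) {
    in_sys <- t >= onset[b] & t < onset[b] + params$systole_s
    tau <- (t[in_sys] - onset[b]) / params$systole_s
    p[in_sys] <- 10 + amps[b] * 0.5 * (1 - cos(2 * pi * pmin(tau, 1)))
    # smooth diastolic dip so each beat has a unique pressure minimum
    in_dia <- t >= onset[b] + params$systole_s & t < onset[b] + beat_len
    if (any(in_dia)) {
      frac <- (t[in_dia] - onset[b] - params$systole_s) /
        (beat_len - params$systole_s)
      p[in_dia] <- 10 - 2 * sin(pi * frac)
    }
  }
  tibble::tibble(time_s = t, pressure_mmhg = p)
}
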