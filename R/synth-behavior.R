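#' Generate running-speed and pupil traces for a session
#'
#' Emulates the behavioural signature of omission detection: a transient
#' running-speed slowdown whose onset lags the omitted-stimulus onset (so the
#' speed minimum falls after the post-omission image has appeared), and a
#' slight further constriction of the pupil after omissions. The pupil trace
#' is median-normalised per session.
#'
#' @param schedule Schedule from [generate_schedule()].
#' @param base_speed_cm_s Mean running speed (default 40 cm/s).
#' @param slowdown_lag_s Lag from omission onset to slowdown onset
#'   (default 0.5 s).
#' @param slowdown_depth Peak speed reduction in cm/s (default 8).
#' @param pupil_constriction Peak fractional pupil constriction after an
#'   omission (default 0.03).
#' @param sample_rate_hz Sampling rate of the traces (default 60 Hz).
#' @param speed_noise_sd SD of the smooth speed noise (cm/s).
#' @param seed Integer seed.
#'
#' @return A tibble with columns `time_s`, `running_speed`, `pupil_diameter`.
#' @export
generate_behavior <- function(schedule,
                              base_speed_cm_s = 40,
                              slowdown_lag_s = 0.5,
                              slowdown_depth = 8,
                              pupil_constriction = 0.03,
                              sample_rate_hz = 60,
                              speed_noise_sd = 2,
                              seed = 1) {
  assert_schedule(schedule)
  if (slowdown_lag_s < 0) abort("`slowdown_lag_s` must be non-negative.")
  P <- schedule_param(schedule, "cycle_period_s", 0.75)
  t_end <- max(schedule$onset_s) + P
  dt <- 1 / sample_rate_hz
  tt <- seq(0, t_end, by = dt)
  om_onsets <- event_onsets(schedule, omitted = TRUE)

  # Alpha-function dip peaking 0.3 s after its onset.
  dip <- function(tt, onsets, lag, tau = 0.3) {
    out <- numeric(length(tt))
    for (o in onsets) {
      x <- (tt - o - lag) / tau
      idx <- x > 0 & x < 12
      out[idx] <- out[idx] + x[idx] * exp(1 - x[idx])
    }
    out
  }

  with_seed(seed, {
    speed <- base_speed_cm_s +
      gauss_smooth(rnorm(length(tt), 0, speed_noise_sd * 6), sd_bins = sample_rate_hz / 4) -
      slowdown_depth * dip(tt, om_onsets, slowdown_lag_s)
    pupil <- 1 +
      gauss_smooth(rnorm(length(tt), 0, 0.3), sd_bins = sample_rate_hz) -
      pupil_constriction * dip(tt, om_onsets, 0.2, tau = 0.5)
    tibble(
      time_s = tt,
      running_speed = pmax(as.numeric(speed), 0),
      pupil_diameter = as.numeric(pupil) / median(as.numeric(pupil))
    )
  })
}

#' Event-triggered average of a behaviour variable
#'
#' @param trace Behaviour tibble from [generate_behavior()].
#' @param events Event onset times (seconds).
#' @param var Column to average (default `running_speed`).
#' @param window `c(pre, post)` in seconds around each event.
#' @return A tibble with `lag_s` and the event-triggered mean `value`.
#' @export
event_triggered_average <- function(trace, events, var = "running_speed",
                                    window = c(-1, 2)) {
  dt <- median(diff(trace$time_s))
  lags <- seq(window[1], window[2], by = dt)
  idx0 <- round(events / dt) + 1L
  offs <- round(lags / dt)
  mat <- vapply(idx0, function(i) {
    j <- i + offs
    ok <- j >= 1L & j <= nrow(trace)
    v <- rep(NA_real_, length(offs))
    v[ok] <- trace[[var]][j[ok]]
    v
  }, numeric(length(offs)))
  tibble(lag_s = lags, value = rowMeans(mat, na.rm = TRUE))
}
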