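#' Event-aligned peri-stimulus time histogram
#'
#' Counts spikes around each event into fixed-width bins and converts to a
#' trial-averaged rate: total count per bin divided by bin width and number
#' of events. The z-scored rate is normalised against the PSTH's own mean and
#' SD over the full window.
#'
#' @param spikes Sorted spike times (seconds).
#' @param events Event onset times (seconds); must be non-empty.
#' @param window `c(pre, post)` in seconds relative to each event.
#' @param bin_s Bin width (default 0.010 s).
#' @return A tibble with `time` (bin centres, seconds relative to the event),
#'   `rate` (Hz) and `zrate`; attributes `n_events` and `zero_variance`.
#' @export
compute_psth <- function(spikes, events, window = c(-0.75, 0.75), bin_s = 0.010) {
  if (length(events) == 0L) abort("`events` must be non-empty.")
  edges <- seq(window[1], window[2], by = bin_s)
  nb <- length(edges) - 1L
  # Gather spikes falling in each event window via index ranges on the sorted
  # train (no per-event loop).
  first <- findInterval(events + window[1], spikes, left.open = TRUE) + 1L
  last <- findInterval(events + edges[nb + 1L], spikes, left.open = TRUE)
  len <- pmax(last - first + 1L, 0L)
  idx <- sequence(len) + rep(first - 1L, len)
  rel <- spikes[idx] - rep(events, len)
  bins <- pmin(pmax(floor((rel - window[1]) / bin_s) + 1L, 1L), nb)
  counts <- tabulate(bins, nbins = nb)
  rate <- counts / (bin_s * length(events))
  s <- sd(rate)
  zero_var <- s < 1e-12
  zrate <- if (zero_var) rep(0, nb) else (rate - mean(rate)) / s
  out <- tibble(time = edges[-length(edges)] + bin_s / 2, rate = rate, zrate = zrate)
  attr(out, "n_events") <- length(events)
  attr(out, "zero_variance") <- zero_var
  out
}

#' Omission-modulation scores for a set of units
#'
#' For each unit, computes the omission-aligned PSTH, the mean z-scored rate
#' over the omission window (`delta_z`), a two-sample Wilcoxon rank-sum test
#' of per-event rates in the omission window against the immediately
#' preceding baseline window, a sign class (`up`/`down` when P < `alpha`,
#' else `ns`), and the ramping index over the omitted-stimulus window.
#'
#' @param units Units tibble (with `spikes` list-column).
#' @param schedule Schedule from [generate_schedule()].
#' @param windows List with `omission` and `baseline` windows in seconds
#'   relative to omission onset (defaults `c(0, 0.25)` and `c(-0.25, 0)`).
#' @param alpha Significance level (default 0.05).
#' @param bin_s PSTH bin width for `delta_z`/RI (default 0.010 s).
#' @param psth_window Window of the underlying z-scored PSTH.
#' @return A tibble with one row per unit: `unit_id`, `delta_z`, `p_value`,
#'   `sign_class`, `RI`, `R_early`, `R_late`, `n_omissions`, `flag`.
#' @export
omission_modulation <- function(units, schedule,
                                windows = list(omission = c(0, 0.25),
                                               baseline = c(-0.25, 0)),
                                alpha = 0.05,
                                bin_s = 0.010,
                                psth_window = c(-0.75, 0.75)) {
  assert_units(units)
  assert_schedule(schedule)
  om <- event_onsets(schedule, omitted = TRUE)
  wid_o <- diff(windows$omission)
  wid_b <- diff(windows$baseline)

  purrr::map2_dfr(units$unit_id, units$spikes, function(id, sp) {
    if (length(om) < 2L) {
      return(tibble(unit_id = id, delta_z = NA_real_, p_value = NA_real_,
                    sign_class = "ns", RI = NA_real_, R_early = NA_real_,
                    R_late = NA_real_, n_omissions = length(om), flag = "too_few_omissions"))
    }
    psth <- compute_psth(sp, om, window = psth_window, bin_s = bin_s)
    in_om <- psth$time >= windows$omission[1] & psth$time < windows$omission[2]
    delta_z <- mean(psth$zrate[in_om])
    rate_o <- count_in_windows(sp, om + windows$omission[1], wid_o) / wid_o
    rate_b <- count_in_windows(sp, om + windows$baseline[1], wid_b) / wid_b
    p <- suppressWarnings(wilcox.test(rate_o, rate_b)$p.value)
    if (is.na(p)) p <- 1
    sign_class <- if (p < alpha) (if (delta_z > 0) "up" else "down") else "ns"
    ri <- ramping_index(psth$zrate[in_om], psth$time[in_om])
    tibble(unit_id = id, delta_z = delta_z, p_value = p, sign_class = sign_class,
           RI = ri$RI, R_early = ri$R_early, R_late = ri$R_late,
           n_omissions = length(om),
           flag = if (attr(psth, "zero_variance")) "zero_variance" else ri$flag)
  })
}

#' Ramping index of a response over the omitted-stimulus window
#'
#' `RI = log2(R_late - R_early)`, where `R_early` and `R_late` are the mean
#' responses during the first and last 100 ms of the omitted-stimulus window.
#' Computed on z-scored responses by default (the formula is not
#' scale-invariant; pass raw rates to score in Hz). When
#' `R_late <= R_early` the log argument is non-positive and the index is
#' returned as `NaN` with a flag.
#'
#' @param response Response values over the omitted-stimulus window.
#' @param time Bin-centre times (seconds from omission onset); the window
#'   must span at least 200 ms.
#' @param edge_s Width of the early/late segments (default 0.1 s).
#' @return A list with `RI`, `R_early`, `R_late`, `flag`.
#' @export
ramping_index <- function(response, time, edge_s = 0.1) {
  if (diff(range(time)) < 0.2 - 1e-9) abort("ramping index needs a window of at least 200 ms.")
  r_early <- mean(response[time < min(time) + edge_s])
  r_late <- mean(response[time >= max(time) - edge_s + 1e-12])
  d <- r_late - r_early
  if (is.na(d) || d <= 0) {
    list(RI = NaN, R_early = r_early, R_late = r_late, flag = "ri_undefined")
  } else {
    list(RI = log2(d), R_early = r_early, R_late = r_late, flag = "")
  }
}

#' Stimulus-specificity of omission responses
#'
#' Tests, for units tuned to exactly one image, whether omission of the
#' preferred image evokes a different omission-window rate than omission of
#' non-preferred images. Tuning is operationalised as a one-vs-rest rank-sum
#' win for exactly one image at `alpha` with Bonferroni correction over the
#' image set; the preferred image is the one with maximal mean evoked rate.
#'
#' @param units Units tibble.
#' @param schedule Schedule from [generate_schedule()].
#' @param stim_window Evoked-response window relative to stimulus onset.
#' @param om_window Omission-response window relative to omission onset.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `unit_id`, `tuned`, `preferred_image`, `p_value`,
#'   `significant`, `flag` (p-values only for tuned units with enough
#'   omissions in both groups).
#' @export
omission_specificity <- function(units, schedule,
                                 stim_window = c(0, 0.25),
                                 om_window = c(0, 0.25),
                                 alpha = 0.05) {
  assert_units(units)
  assert_schedule(schedule)
  n_images <- schedule_param(schedule, "n_images", max(schedule$image_id) + 1L)
  stim <- schedule[!schedule$omitted, ]
  om <- schedule[schedule$omitted, ]
  wid_s <- diff(stim_window)
  wid_o <- diff(om_window)

  purrr::map2_dfr(units$unit_id, units$spikes, function(id, sp) {
    ev <- count_in_windows(sp, stim$onset_s + stim_window[1], wid_s) / wid_s
    means <- vapply(0:(n_images - 1L), function(im) mean(ev[stim$image_id == im]), 0)
    pref <- which.max(means) - 1L
    wins <- vapply(0:(n_images - 1L), function(im) {
      a <- ev[stim$image_id == im]
      b <- ev[stim$image_id != im]
      if (length(a) < 2L || length(b) < 2L) return(FALSE)
      p <- suppressWarnings(wilcox.test(a, b, alternative = "greater")$p.value)
      !is.na(p) && p < alpha / n_images
    }, logical(1))
    tuned <- sum(wins) == 1L
    if (tuned) pref <- which(wins) - 1L
    r_om <- count_in_windows(sp, om$onset_s + om_window[1], wid_o) / wid_o
    grp_pref <- r_om[om$image_id == pref]
    grp_other <- r_om[om$image_id != pref]
    if (!tuned) {
      tibble(unit_id = id, tuned = FALSE, preferred_image = pref,
             p_value = NA_real_, significant = NA, flag = "not_tuned")
    } else if (length(grp_pref) < 2L || length(grp_other) < 2L) {
      tibble(unit_id = id, tuned = TRUE, preferred_image = pref,
             p_value = NA_real_, significant = NA, flag = "too_few_omissions")
    } else {
      p <- suppressWarnings(wilcox.test(grp_pref, grp_other)$p.value)
      if (is.na(p)) p <- 1
      tibble(unit_id = id, tuned = TRUE, preferred_image = pref,
             p_value = p, significant = p < alpha, flag = "")
    }
  })
}
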