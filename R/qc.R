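#' Filter units by quality metrics
#'
#' Keeps units that strictly satisfy all four inclusion criteria: ISI
#' violation rate below `max_isi_viol`, presence ratio above `min_presence`,
#' amplitude cutoff below `max_amp_cutoff`, and mean firing rate above
#' `min_rate_hz`. All inequalities are strict; a unit sitting exactly on a
#' threshold is excluded.
#'
#' @param units Units tibble with columns `isi_violation_rate`,
#'   `presence_ratio`, `amplitude_cutoff`, `mean_rate_hz`.
#' @param max_isi_viol,min_presence,max_amp_cutoff,min_rate_hz Thresholds
#'   (defaults 0.005, 0.9, 0.1, 0.1).
#' @return The filtered units tibble.
#' @export
filter_units <- function(units,
                         max_isi_viol = 0.005,
                         min_presence = 0.9,
                         max_amp_cutoff = 0.1,
                         min_rate_hz = 0.1) {
  stopifnot(max_isi_viol > 0, min_presence > 0, max_amp_cutoff > 0, min_rate_hz > 0)
  dplyr::filter(
    units,
    .data$isi_violation_rate < max_isi_viol,
    .data$presence_ratio > min_presence,
    .data$amplitude_cutoff < max_amp_cutoff,
    .data$mean_rate_hz > min_rate_hz
  )
}

#' Classify units into putative cell types
#'
#' Optogenetically tagged lines (`Sst`, `Vip`) are labelled by their response
#' to light pulses: a unit is SST/VIP if its stimulation-window rate is at
#' least 1 SD above the pre-pulse baseline mean and the two distributions
#' differ (Kolmogorov-Smirnov P < 0.05). Untagged units are putative PV cells
#' if their waveform is shorter than 0.4 ms and their rate above 10 Hz, and
#' putative pyramidal cells if the waveform is wider than 0.4 ms and the rate
#' below 10 Hz; everything else (including waveforms exactly at 0.4 ms) is
#' unclassified.
#'
#' @param units Units tibble with `genotype_line`, `waveform_duration_ms`,
#'   `mean_rate_hz`.
#' @param opto_stats Optional named list (by `unit_id`) of lists with
#'   `baseline_rates_per_trial` and `stim_rates_per_trial` for tagged lines.
#' @param alpha KS-test significance level (default 0.05).
#' @return The units tibble with added `cell_type` and `cell_type_warning`
#'   columns.
#' @export
classify_cell_type <- function(units, opto_stats = NULL, alpha = 0.05) {
  lab <- character(nrow(units))
  warn_flag <- logical(nrow(units))
  for (i in seq_len(nrow(units))) {
    line <- units$genotype_line[i]
    wf <- units$waveform_duration_ms[i]
    rate <- units$mean_rate_hz[i]
    tagged <- FALSE
    if (line %in% c("Sst", "Vip")) {
      st <- opto_stats[[units$unit_id[i]]]
      if (is.null(st)) {
        warn_flag[i] <- TRUE  # tagged line without opto trials: waveform rules only
      } else {
        base <- st$baseline_rates_per_trial
        stim <- st$stim_rates_per_trial
        crossed <- mean(stim) >= mean(base) + sd(base)
        p <- suppressWarnings(ks.test(stim, base)$p.value)
        tagged <- crossed && p < alpha
      }
    }
    lab[i] <- if (tagged) {
      toupper(line)
    } else if (wf < 0.4 && rate > 10) {
      "putative_PV"
    } else if (wf > 0.4 && rate < 10) {
      "putative_pyramidal"
    } else {
      "unclassified"
    }
  }
  dplyr::mutate(units, cell_type = lab, cell_type_warning = warn_flag)
}

#' Summarise opto-stimulation trials into per-trial rates
#'
#' Counts spikes in each pulse window and in an equal-duration window
#' immediately preceding each pulse (the baseline), returning per-trial rates
#' for [classify_cell_type()].
#'
#' @param spikes Sorted spike times (seconds).
#' @param pulse_onsets Pulse onset times (seconds).
#' @param pulse_duration_s Pulse duration (default 0.010 s).
#' @return A list with `baseline_rates_per_trial` and `stim_rates_per_trial`.
#' @export
opto_trial_rates <- function(spikes, pulse_onsets, pulse_duration_s = 0.010) {
  list(
    baseline_rates_per_trial =
      count_in_windows(spikes, pulse_onsets - pulse_duration_s, pulse_duration_s) / pulse_duration_s,
    stim_rates_per_trial =
      count_in_windows(spikes, pulse_onsets, pulse_duration_s) / pulse_duration_s
  )
}
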