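#' Functional response archetypes
#'
#' Names of the firing-rate archetypes the generator can realise. The five
#' visual-cortex archetypes mirror the functional classes recovered by
#' clustering: a short transient at stimulus onset (`transient_on`), a
#' sustained response throughout the presentation (`sustained_on`), a ramp
#' peaking at stimulus offset that decays through the inter-stimulus interval
#' (`ramp_to_offset`), step-like OFF/ON activity that is suppressed by the
#' stimulus and elevated between stimuli (`step_off_on`), and a suppressed
#' unit whose rate ramps up through the inter-stimulus/omission interval,
#' peaking at the (expected) stimulus onset (`ramp_off`). `hippocampal_step`
#' has no image response but steps its rate at the expected onset of an
#' omitted image and holds it until the post-omission image is presented.
#' `unmodulated` fires at a constant rate.
#'
#' @return Character vector of archetype names.
#' @export
archetype_names <- function() {
  c("transient_on", "sustained_on", "ramp_to_offset",
    "step_off_on", "ramp_off", "hippocampal_step", "unmodulated")
}

# Instantaneous rate of one archetype, vectorised over evaluation times.
#   tau: time since current slot onset in [0, P)
#   om:  logical, current slot omitted
#   tso: time since the last actually presented stimulus' offset (defined
#        whenever the stimulus branch is not active)
#   b, a: baseline and amplitude (Hz); g: per-image gain (ON archetypes)
archetype_rate <- function(archetype, tau, om, tso, b, a, g, D, P) {
  stim <- !om & tau < D
  r <- rep(b, length(tau))
  switch(archetype,
    transient_on = {
      r[stim] <- b + a * g[stim] * exp(-tau[stim] / 0.04)
      r[!stim] <- b + 0.2 * a * g[!stim] * exp(-tso[!stim] / 0.05)
    },
    sustained_on = {
      r[stim] <- b + a * g[stim]
      r[!stim] <- b + 0.8 * a * g[!stim] * exp(-tso[!stim] / 0.25)
    },
    ramp_to_offset = {
      r[stim] <- b + a * g[stim] * tau[stim] / D
      r[!stim] <- b + a * g[!stim] * exp(-tso[!stim] / 0.12)
    },
    step_off_on = {
      r[stim] <- 0.2 * b
      r[!stim] <- b + a
    },
    ramp_off = {
      r[stim] <- 0.2 * b
      r[!stim] <- pmin(b + a * tso[!stim] / (P - D), b + 2.5 * a)
    },
    hippocampal_step = {
      r[om] <- b + a
    },
    unmodulated = {
    },
    abort(paste0("unknown archetype: ", archetype))
  )
  pmax(r, 0)
}

# Evaluate one unit's schedule-composed rate function at arbitrary times.
unit_rate <- function(t, schedule, archetype, b, a, gains) {
  P <- schedule_param(schedule, "cycle_period_s", 0.75)
  D <- schedule_param(schedule, "image_duration_s", 0.25)
  slot <- pmin(pmax(findInterval(t, schedule$onset_s), 1L), nrow(schedule))
  tau <- t - schedule$onset_s[slot]
  om <- schedule$omitted[slot]
  # Omitted slots always follow a presented slot (generator invariant), so the
  # last true offset is one full period back; in a gray period it is tau - D.
  tso <- ifelse(om, tau + (P - D), pmax(tau - D, 0))
  g <- if (is.null(gains)) rep(1, length(t)) else gains[schedule$image_id[slot] + 1L]
  archetype_rate(archetype, tau, om, tso, b, a, g, D, P)
}

# Archetypes whose stimulus response carries per-image multiplicative tuning.
stim_on_archetypes <- function() c("transient_on", "sustained_on", "ramp_to_offset")

#' Default archetype mix for a synthetic session
#'
#' One row per archetype group: archetype, number of units, area and layer
#' labels, baseline rate and response amplitude (Hz). STIM-OFF archetypes are
#' given higher baselines than STIM-ON ones, matching their higher spontaneous
#' rates.
#'
#' @param n_per Units per visual-cortex archetype (default 20).
#' @param n_hpc Units for the hippocampal step archetype (default 20).
#' @return A tibble usable as the `mix` argument of [generate_units()].
#' @export
default_unit_mix <- function(n_per = 20, n_hpc = 20) {
  tibble(
    archetype = c("transient_on", "sustained_on", "ramp_to_offset",
                  "step_off_on", "ramp_off", "hippocampal_step", "unmodulated"),
    n = c(rep(n_per, 5), n_hpc, max(5, n_per %/% 2)),
    area = c(rep("VISp", 5), "CA1", "CA1"),
    layer = c("L2/3", "L4", "L5", "L5", "L6", "", ""),
    baseline_rate = c(4, 5, 4, 6, 6, 3, 5),
    amplitude = c(12, 10, 8, 6, 8, 6, 0)
  )
}

#' Generate inhomogeneous-Poisson units from a schedule
#'
#' Each unit's spike train is a realisation of an inhomogeneous Poisson
#' process whose rate is its archetype's template composed with the stimulus
#' schedule (omitted slots drive the archetype's omission branch). STIM-ON
#' archetypes receive per-image multiplicative log-normal tuning gains;
#' STIM-OFF and hippocampal archetypes are image-agnostic. Spikes are sampled
#' by thinning a homogeneous process at the unit's rate ceiling.
#'
#' @param schedule Schedule from [generate_schedule()].
#' @param mix Archetype mix table as from [default_unit_mix()].
#' @param rate_jitter_sd Log-normal SD of per-unit baseline/amplitude jitter.
#' @param tuning_gain_sd Log-normal SD of per-image tuning gains for STIM-ON
#'   archetypes (0 disables tuning).
#' @param seed Integer seed.
#'
#' @return A tibble with one row per unit: `unit_id`, `archetype`, `area`,
#'   `layer`, waveform/QC metadata, `genotype_line`, `mean_rate_hz`, and a
#'   `spikes` list-column of sorted spike-time vectors (seconds).
#' @export
generate_units <- function(schedule,
                           mix = default_unit_mix(),
                           rate_jitter_sd = 0.2,
                           tuning_gain_sd = 0.3,
                           seed = 1) {
  assert_schedule(schedule)
  if (any(mix$n < 0)) abort("unit counts in `mix` must be non-negative.")
  bad <- setdiff(mix$archetype, archetype_names())
  if (length(bad)) abort(paste0("unknown archetype(s): ", paste(bad, collapse = ", ")))
  P <- schedule_param(schedule, "cycle_period_s", 0.75)
  n_images <- schedule_param(schedule, "n_images", max(schedule$image_id) + 1L)
  t_end <- max(schedule$onset_s) + P

  with_seed(seed, {
    rows <- purrr::pmap(mix, function(archetype, n, area, layer, baseline_rate, amplitude) {
      if (n == 0L) return(NULL)
      purrr::map(seq_len(n), function(i) {
        b <- baseline_rate * exp(rnorm(1, 0, rate_jitter_sd))
        a <- amplitude * exp(rnorm(1, 0, rate_jitter_sd))
        gains <- if (archetype %in% stim_on_archetypes() && tuning_gain_sd > 0) {
          exp(rnorm(n_images, 0, tuning_gain_sd))
        } else NULL
        gmax <- if (is.null(gains)) 1 else max(gains)
        rmax <- if (archetype == "ramp_off") {
          max(b + 2.5 * a, b, 1e-9)
        } else {
          max(b + a * gmax, b, 1e-9)
        }
        n_cand <- rpois(1, t_end * rmax)
        cand <- sort(runif(n_cand, 0, t_end))
        keep <- runif(n_cand) < unit_rate(cand, schedule, archetype, b, a, gains) / rmax
        sp <- cand[keep]
        list(
          archetype = archetype, area = area, layer = layer,
          baseline_rate = b, amplitude = a,
          gains = list(gains), spikes = list(sp)
        )
      })
    })
    rows <- purrr::compact(purrr::flatten(rows))
    units <- dplyr::bind_rows(purrr::map(rows, tibble::as_tibble_row))
    n_units <- nrow(units)
    units |>
      dplyr::mutate(
        unit_id = sprintf("u%04d", dplyr::row_number()),
        genotype_line = "wt",
        waveform_duration_ms = runif(n_units, 0.45, 0.8),
        isi_violation_rate = runif(n_units, 0, 0.004),
        presence_ratio = runif(n_units, 0.95, 1),
        amplitude_cutoff = runif(n_units, 0, 0.05),
        mean_rate_hz = purrr::map_dbl(.data$spikes, length) / t_end,
        .before = 1
      )
  })
}

#' Archetype template responses on the omission-aligned window
#'
#' Noise-free archetype rate profiles around an omission (flanked by presented
#' stimuli of the same image), z-scored across the window. Used to assign
#' semantic labels to fitted clusters and as a construction reference in
#' tests.
#'
#' @param archetypes Archetype names (default all).
#' @param window `c(pre, post)` in seconds relative to omission onset.
#' @param bin_s Bin width in seconds.
#' @param cycle_period_s,image_duration_s Schedule cadence.
#' @return A matrix with one row per archetype (rownames set) and one column
#'   per time bin.
#' @export
template_response <- function(archetypes = archetype_names(),
                              window = c(-0.75, 1.5),
                              bin_s = 0.010,
                              cycle_period_s = 0.75,
                              image_duration_s = 0.25) {
  times <- seq(window[1] + bin_s / 2, window[2] - bin_s / 2, by = bin_s)
  template_at(archetypes, times, cycle_period_s, image_duration_s)
}

# Archetype templates evaluated at arbitrary bin-centre times (seconds
# relative to the omission onset); supports non-contiguous grids.
template_at <- function(archetypes, times, cycle_period_s = 0.75,
                        image_duration_s = 0.25) {
  # Presented / omitted / presented, with the omission at the origin.
  sched <- tibble(
    onset_s = c(-1, 0, 1, 2) * cycle_period_s,
    image_id = 0L, omitted = c(FALSE, TRUE, FALSE, FALSE),
    eligible = c(FALSE, TRUE, FALSE, FALSE), trial_index = 1L
  )
  attr(sched, "cycle_period_s") <- cycle_period_s
  attr(sched, "image_duration_s") <- image_duration_s
  attr(sched, "n_images") <- 1L
  out <- t(vapply(archetypes, function(a) {
    r <- unit_rate(times, sched, a, b = 5, a = 10, gains = NULL)
    s <- sd(r)
    if (s < 1e-12) rep(0, length(r)) else (r - mean(r)) / s
  }, numeric(length(times))))
  rownames(out) <- archetypes
  out
}
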