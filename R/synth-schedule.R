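#' Generate a stimulus schedule with stochastic omissions
#'
#' Builds the presentation clock of a change-detection session: images drawn
#' from a fixed set are flashed at a regular cadence, the same image repeating
#' for a whole trial (trial lengths follow a truncated geometric distribution),
#' and interior presentations are stochastically omitted. Omissions are only
#' placed between two presented repetitions of the same image: the first and
#' last slot of a trial, and the slot immediately following a realized
#' omission, are never omitted, so every omitted slot has identical,
#' non-omitted flankers.
#'
#' @param n_images Number of distinct images (default 8).
#' @param image_duration_s Presentation duration in seconds (default 0.25).
#' @param cycle_period_s Onset-to-onset period in seconds (default 0.75,
#'   i.e. a 250-ms image followed by 500 ms of gray).
#' @param omission_prob Per-eligible-slot omission probability in `[0, 1)`
#'   (default 0.05).
#' @param repeats_min,repeats_max Trial-length support (defaults 5 and 11).
#' @param geom_p Success parameter of the truncated geometric trial-length
#'   distribution (default 0.3).
#' @param n_trials Number of trials to generate.
#' @param seed Integer seed; the schedule is a pure function of the
#'   configuration and the seed.
#'
#' @return A tibble with one row per presentation slot and columns
#'   `onset_s`, `image_id` (0-based), `omitted`, `eligible` (whether the slot
#'   received an omission draw) and `trial_index`, carrying the configuration
#'   as attributes (`cycle_period_s`, `image_duration_s`, `n_images`).
#' @export
#' @examples
#' sched <- generate_schedule(n_trials = 40, seed = 1)
#' mean(sched$omitted[sched$eligible])
generate_schedule <- function(n_images = 8,
                              image_duration_s = 0.25,
                              cycle_period_s = 0.75,
                              omission_prob = 0.05,
                              repeats_min = 5,
                              repeats_max = 11,
                              geom_p = 0.3,
                              n_trials = 100,
                              seed = 1) {
  if (omission_prob < 0 || omission_prob >= 1) {
    abort("`omission_prob` must lie in [0, 1).")
  }
  if (repeats_min > repeats_max) abort("`repeats_min` must not exceed `repeats_max`.")
  if (repeats_min < 3) abort("`repeats_min` must be at least 3 so omissions can have flankers.")
  if (n_images < 2) abort("`n_images` must be at least 2.")
  if (image_duration_s >= cycle_period_s) {
    abort("`image_duration_s` must be shorter than `cycle_period_s`.")
  }

  with_seed(seed, {
    support <- repeats_min:repeats_max
    pmf <- geom_p * (1 - geom_p)^(support - repeats_min)
    lens <- sample(support, n_trials, replace = TRUE, prob = pmf / sum(pmf))

    # Consecutive trials always change image identity.
    imgs <- integer(n_trials)
    imgs[1] <- sample.int(n_images, 1L) - 1L
    if (n_trials > 1) {
      for (i in 2:n_trials) {
        imgs[i] <- sample(setdiff(0:(n_images - 1L), imgs[i - 1L]), 1L)
      }
    }

    trial_index <- rep.int(seq_len(n_trials), lens)
    image_id <- rep.int(imgs, lens)
    n_slots <- length(trial_index)
    within <- sequence(lens)
    interior <- within > 1L & within < rep.int(lens, lens)

    omitted <- logical(n_slots)
    eligible <- logical(n_slots)
    u <- runif(n_slots)
    for (s in seq_len(n_slots)) {
      if (!interior[s]) next
      if (s > 1L && omitted[s - 1L]) next  # post-omission slot: ineligible
      eligible[s] <- TRUE
      omitted[s] <- u[s] < omission_prob
    }

    out <- tibble(
      onset_s = (seq_len(n_slots) - 1) * cycle_period_s,
      image_id = image_id,
      omitted = omitted,
      eligible = eligible,
      trial_index = trial_index
    )
    attr(out, "cycle_period_s") <- cycle_period_s
    attr(out, "image_duration_s") <- image_duration_s
    attr(out, "n_images") <- as.integer(n_images)
    class(out) <- c("omi_schedule", class(out))
    out
  })
}

#' Onset times of omitted (or presented) slots
#'
#' @param schedule A schedule from [generate_schedule()].
#' @param omitted If `TRUE` (default) return omission onsets, else presented
#'   stimulus onsets.
#' @return Numeric vector of onset times in seconds.
#' @export
event_onsets <- function(schedule, omitted = TRUE) {
  assert_schedule(schedule)
  schedule$onset_s[schedule$omitted == omitted]
}
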