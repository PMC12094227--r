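# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without touching the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Counter-based fan-out of one global seed into per-stage seeds.
stage_seed <- function(seed, index) {
  as.integer((as.double(seed) * 31L + index * 1009L) %% 2147483647)
}

round_half_up <- function(x) floor(x + 0.5)

#' Count spikes in aligned windows
#'
#' Number of spikes of a sorted train falling in each half-open window
#' `[starts[i], starts[i] + width)`.
#'
#' @param spikes Sorted spike times (seconds).
#' @param starts Window start times (seconds).
#' @param width Window width (seconds).
#' @return Numeric vector of per-window counts.
#' @export
count_in_windows <- function(spikes, starts, width) {
  if (length(spikes) == 0L) return(numeric(length(starts)))
  findInterval(starts + width, spikes) - findInterval(starts, spikes)
}

# Gaussian-kernel smoothing of a regularly sampled signal (edges renormalised).
gauss_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(rep(x[1], half), x, rep(x[n], half))
  stats::filter(pad, k, sides = 2)[(half + 1):(half + n)]
}

assert_schedule <- function(schedule) {
  need <- c("onset_s", "image_id", "omitted", "trial_index")
  if (!is.data.frame(schedule) || !all(need %in% names(schedule))) {
    abort("`schedule` must be a data frame with columns onset_s, image_id, omitted, trial_index.")
  }
  if (nrow(schedule) == 0L) abort("`schedule` is empty.")
  invisible(schedule)
}

schedule_param <- function(schedule, what, default) {
  attr(schedule, what, exact = TRUE) %||% default
}

assert_units <- function(units) {
  if (!is.data.frame(units) || !all(c("unit_id", "spikes") %in% names(units))) {
    abort("`units` must be a data frame with columns unit_id and spikes (list of spike-time vectors).")
  }
  invisible(units)
}
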