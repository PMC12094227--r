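# Binned spike-count matrix (units x bins) over a time range.
bin_counts_matrix <- function(spike_list, t_range, bin_s) {
  edges <- seq(t_range[1], t_range[2], by = bin_s)
  nb <- length(edges) - 1L
  t(vapply(spike_list, function(sp) {
    sp <- sp[sp >= t_range[1] & sp < edges[nb + 1L]]
    tabulate(findInterval(sp, edges), nbins = nb)
  }, numeric(nb)))
}

#' Population coupling and spike-triggered population rate
#'
#' For each unit, the summed firing rate of the remaining units is binned,
#' mean-centred and smoothed with a Gaussian kernel; the coupling index is
#' the Pearson correlation of the unit's own binned rate with that
#' leave-one-out population rate. The stPR is the spike-triggered average of
#' the smoothed population rate over lags of +-0.4 s.
#'
#' @param units Units tibble (at least 2 units).
#' @param t_range `c(start, end)` of the epoch in seconds (>= 60 s).
#' @param bin_s Bin width (default 0.010 s).
#' @param smooth_halfwidth_ms Gaussian kernel half-width in ms (default 6,
#'   used as the kernel SD).
#' @param stpr_lag_s Maximum stPR lag (default 0.4 s).
#' @return A tibble with `unit_id`, `coupling_index`, `flag`, plus an
#'   `stpr` attribute: a tibble of `unit_id`, `lag_s`, `stpr` (Hz).
#' @export
population_coupling <- function(units, t_range, bin_s = 0.010,
                                smooth_halfwidth_ms = 6, stpr_lag_s = 0.4) {
  assert_units(units)
  if (nrow(units) < 2L) abort("need at least 2 units.")
  if (diff(t_range) < 60) abort("epoch must span at least 60 s.")
  counts <- bin_counts_matrix(units$spikes, t_range, bin_s)
  sd_bins <- smooth_halfwidth_ms / 1000 / bin_s
  total <- colSums(counts)
  nlag <- round(stpr_lag_s / bin_s)
  lags <- (-nlag:nlag) * bin_s

  res <- purrr::map_dfr(seq_len(nrow(units)), function(i) {
    own <- counts[i, ]
    if (sum(own) == 0L) {
      return(tibble(unit_id = units$unit_id[i], coupling_index = NA_real_,
                    flag = "silent_unit"))
    }
    pop <- total - own
    pop <- gauss_smooth(pop - mean(pop), sd_bins)
    tibble(unit_id = units$unit_id[i],
           coupling_index = suppressWarnings(cor(own, pop)),
           flag = "")
  })

  stpr <- purrr::map_dfr(seq_len(nrow(units)), function(i) {
    own <- counts[i, ]
    if (sum(own) == 0L) return(NULL)
    pop_rate <- gauss_smooth(total - own, sd_bins) / bin_s  # Hz
    spike_bins <- which(own > 0)
    w <- own[spike_bins]
    acc <- vapply(-nlag:nlag, function(l) {
      j <- spike_bins + l
      ok <- j >= 1L & j <= length(pop_rate)
      sum(pop_rate[j[ok]] * w[ok]) / sum(w[ok])
    }, 0)
    tibble(unit_id = units$unit_id[i], lag_s = lags, stpr = acc)
  })
  attr(res, "stpr") <- stpr
  res
}

#' Behaviour scores: speed and pupil coupling of each unit
#'
#' Absolute Pearson correlation between a unit's binned firing rate and the
#' behaviour variable linearly interpolated onto the bin centres.
#'
#' @param units Units tibble.
#' @param trace Behaviour tibble from [generate_behavior()].
#' @param bin_s Rate bin width (default 0.25 s).
#' @return A tibble with `unit_id`, `speed_score`, `pupil_score`, `flag`.
#' @export
behavior_scores <- function(units, trace, bin_s = 0.25) {
  assert_units(units)
  t0 <- min(trace$time_s); t1 <- max(trace$time_s)
  counts <- bin_counts_matrix(units$spikes, c(t0, t1), bin_s)
  centers <- t0 + (seq_len(ncol(counts)) - 0.5) * bin_s
  sp <- stats::approx(trace$time_s, trace$running_speed, xout = centers)$y
  pu <- stats::approx(trace$time_s, trace$pupil_diameter, xout = centers)$y
  const_sp <- sd(sp) < 1e-12
  const_pu <- sd(pu) < 1e-12
  purrr::map_dfr(seq_len(nrow(units)), function(i) {
    r <- counts[i, ] / bin_s
    if (sd(r) < 1e-12) {
      return(tibble(unit_id = units$unit_id[i], speed_score = NA_real_,
                    pupil_score = NA_real_, flag = "constant_rate"))
    }
    tibble(
      unit_id = units$unit_id[i],
      speed_score = if (const_sp) NA_real_ else abs(cor(r, sp)),
      pupil_score = if (const_pu) NA_real_ else abs(cor(r, pu)),
      flag = if (const_sp || const_pu) "constant_behavior" else ""
    )
  })
}

#' Cluster multi-unit activity versus a target population: scaled CCG
#'
#' Merges each cluster's spikes into multi-unit activity (MUA), subsamples
#' every cluster to the same spike count, computes the cross-correlogram of
#' each cluster's MUA against the target-population MUA, min-max scales each
#' CCG, and reports the area under the scaled CCG within +-20 ms of zero.
#'
#' @param units Units tibble (cluster members).
#' @param model An `omi_clusters` object.
#' @param target_units Units tibble of the target population.
#' @param bin_s CCG bin width (default 0.010 s).
#' @param window_s CCG half-window (default 2 s).
#' @param auc_window_s Half-window of the AUC statistic (default 0.020 s).
#' @param min_spikes Minimum MUA spikes per cluster (default 100).
#' @param seed Subsampling seed.
#' @return A tibble with `cluster`, `lag_s`, `ccg_scaled` plus an `auc`
#'   attribute (tibble: cluster, auc).
#' @export
cluster_subcortical_ccg <- function(units, model, target_units,
                                    bin_s = 0.010, window_s = 2,
                                    auc_window_s = 0.020,
                                    min_spikes = 100, seed = 1) {
  asg <- model$assignments
  mua <- purrr::map(sort(unique(asg$cluster)), function(cl) {
    ids <- asg$unit_id[asg$cluster == cl]
    sort(unlist(units$spikes[units$unit_id %in% ids]))
  })
  names(mua) <- sort(unique(asg$cluster))
  keep <- vapply(mua, length, 0L) >= min_spikes
  if (any(!keep)) warn("cluster MUA below the minimum spike count skipped.")
  mua <- mua[keep]
  n_min <- min(vapply(mua, length, 0L))
  target <- sort(unlist(target_units$spikes))
  with_seed(seed, {
    out <- purrr::map_dfr(names(mua), function(cl) {
      sp <- sort(sample(mua[[cl]], n_min))
      cc <- compute_ccg(sp, target, bin_s = bin_s, window_s = window_s)
      rng <- range(cc$count)
      scaled <- if (diff(rng) < 1e-12) rep(0, nrow(cc)) else (cc$count - rng[1]) / diff(rng)
      tibble(cluster = as.integer(cl), lag_s = cc$lag_s, ccg_scaled = scaled)
    })
    auc <- out |>
      dplyr::filter(abs(.data$lag_s) <= auc_window_s + 1e-12) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(auc = sum(.data$ccg_scaled) * bin_s, .groups = "drop")
    attr(out, "auc") <- auc
    out
  })
}
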