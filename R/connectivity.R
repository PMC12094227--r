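#' Spike-pair cross-correlogram
#'
#' Counts (pre, post) spike pairs by lag `post - pre` in bins centred on
#' multiples of `bin_s` within `+-window_s`.
#'
#' @param pre_spikes,post_spikes Sorted spike times (seconds); both
#'   non-empty.
#' @param bin_s Bin width (default 0.0004 s, i.e. 0.4 ms).
#' @param window_s Half-window (default 0.05 s).
#' @return A tibble with `lag_s` (bin centres) and `count`.
#' @export
compute_ccg <- function(pre_spikes, post_spikes, bin_s = 0.0004, window_s = 0.05) {
  if (length(pre_spikes) == 0L || length(post_spikes) == 0L) {
    abort("both spike trains must be non-empty.")
  }
  counts <- ccg_count(as.numeric(pre_spikes), as.numeric(post_spikes), bin_s, window_s)
  nb <- (length(counts) - 1L) / 2L
  tibble(lag_s = (-nb:nb) * bin_s, count = as.numeric(counts))
}

#' Interval-jitter a spike train
#'
#' Resamples each spike uniformly within its own jitter interval
#' `[floor(t / interval) * interval, + interval)`, destroying
#' fine-timescale (monosynaptic) structure while preserving per-interval
#' spike counts and slow comodulation exactly.
#'
#' @param spikes Spike times (seconds).
#' @param interval_s Jitter interval (default 0.005 s).
#' @return Sorted jittered spike times.
#' @export
jitter_spikes <- function(spikes, interval_s = 0.005) {
  base <- floor(spikes / interval_s) * interval_s
  sort(base + runif(length(spikes)) * interval_s)
}

#' Detect a putative monosynaptic connection from a jitter-corrected CCG
#'
#' Compares the observed cross-correlogram with an acceptance band obtained
#' from interval-jitter surrogates of the post-synaptic train. An excitatory
#' edge is declared when the maximum observed count within the positive
#' excitatory lag window exceeds the (1 - alpha/2) quantile of the
#' surrogates' maximum statistic over the same bins (a global correction
#' across lag bins); an inhibitory edge when the minimum count falls below
#' the alpha/2 quantile of the surrogate minimum statistic over the
#' inhibitory lag window. The two one-sided tests split `alpha` evenly so
#' the family false-positive rate is at most `alpha`.
#'
#' @param pre_spikes,post_spikes Sorted spike times (seconds).
#' @param bin_s CCG bin width (default 0.4 ms).
#' @param window_s CCG half-window (default 0.05 s).
#' @param jitter_interval_s Surrogate jitter interval (default 0.005 s).
#' @param n_surrogates Number of jitter surrogates (default 200; at least
#'   100).
#' @param alpha Overall significance level (default 0.05).
#' @param exc_lag_ms,inh_lag_ms Monosynaptic lag windows in ms (defaults
#'   0.8-2.8 for excitatory peaks, 0.8-4 for inhibitory troughs).
#' @param min_spikes Minimum spikes in either train for a stable band
#'   (default 100).
#' @param seed Integer seed for the surrogates.
#' @return A one-row tibble: `sign` (`"excitatory"`, `"inhibitory"` or
#'   `"none"`), `peak_lag_ms`, `strength` (excess or deficit coincidences
#'   per presynaptic spike), `p_value`, `flag`.
#' @export
detect_monosynaptic <- function(pre_spikes, post_spikes,
                                bin_s = 0.0004, window_s = 0.05,
                                jitter_interval_s = 0.005,
                                n_surrogates = 200, alpha = 0.05,
                                exc_lag_ms = c(0.8, 2.8),
                                inh_lag_ms = c(0.8, 4),
                                min_spikes = 100,
                                seed = 1) {
  if (n_surrogates < 100) abort("need at least 100 surrogates.")
  none <- tibble(sign = "none", peak_lag_ms = NA_real_, strength = NA_real_,
                 p_value = NA_real_, flag = "")
  if (length(pre_spikes) < min_spikes || length(post_spikes) < min_spikes) {
    none$flag <- "too_few_spikes"
    return(none)
  }
  obs <- compute_ccg(pre_spikes, post_spikes, bin_s, window_s)
  lag_ms <- obs$lag_s * 1000
  exc_idx <- which(lag_ms >= exc_lag_ms[1] & lag_ms <= exc_lag_ms[2])
  inh_idx <- which(lag_ms >= inh_lag_ms[1] & lag_ms <= inh_lag_ms[2])
  with_seed(seed, {
    surr_max <- numeric(n_surrogates)
    surr_min <- numeric(n_surrogates)
    surr_mean <- numeric(length(lag_ms))
    for (s in seq_len(n_surrogates)) {
      js <- jitter_spikes(post_spikes, jitter_interval_s)
      cc <- ccg_count(pre_spikes, js, bin_s, window_s)
      surr_max[s] <- max(cc[exc_idx])
      surr_min[s] <- min(cc[inh_idx])
      surr_mean <- surr_mean + cc
    }
    surr_mean <- surr_mean / n_surrogates

    obs_max <- max(obs$count[exc_idx])
    obs_min <- min(obs$count[inh_idx])
    p_exc <- (1 + sum(surr_max >= obs_max)) / (n_surrogates + 1)
    p_inh <- (1 + sum(surr_min <= obs_min)) / (n_surrogates + 1)

    if (p_exc < alpha / 2) {
      i <- exc_idx[which.max(obs$count[exc_idx] - surr_mean[exc_idx])]
      tibble(sign = "excitatory", peak_lag_ms = lag_ms[i],
             strength = (obs$count[i] - surr_mean[i]) / length(pre_spikes),
             p_value = p_exc, flag = "")
    } else if (p_inh < alpha / 2) {
      i <- inh_idx[which.min(obs$count[inh_idx] - surr_mean[inh_idx])]
      tibble(sign = "inhibitory", peak_lag_ms = lag_ms[i],
             strength = (obs$count[i] - surr_mean[i]) / length(pre_spikes),
             p_value = p_inh, flag = "")
    } else {
      none$p_value <- min(1, 2 * min(p_exc, p_inh))
      none
    }
  })
}

#' Infer the monosynaptic graph over all unit pairs
#'
#' Runs [detect_monosynaptic()] for every ordered pair of units (optionally
#' restricted to within-area pairs) and assembles the directed signed edge
#' list.
#'
#' @param units Units tibble.
#' @param within_area Test only pairs within the same area (default TRUE,
#'   matching per-session cortical-pair testing).
#' @param seed Integer seed.
#' @param ... Passed to [detect_monosynaptic()].
#' @return A list of class `omi_graph`: `edges` (tibble: pre, post, sign,
#'   peak_lag_ms, strength, p_value), `tested` (tibble of tested pairs),
#'   `units` (unit ids).
#' @export
infer_connectivity <- function(units, within_area = TRUE, seed = 1, ...) {
  assert_units(units)
  ids <- units$unit_id
  area <- if ("area" %in% names(units)) units$area else rep("all", length(ids))
  pairs <- expand.grid(i = seq_along(ids), j = seq_along(ids))
  pairs <- pairs[pairs$i != pairs$j, ]
  if (within_area) pairs <- pairs[area[pairs$i] == area[pairs$j], ]
  res <- purrr::map2_dfr(pairs$i, pairs$j, function(i, j) {
    d <- detect_monosynaptic(units$spikes[[i]], units$spikes[[j]],
                             seed = stage_seed(seed, i * length(ids) + j), ...)
    dplyr::mutate(d, pre = ids[i], post = ids[j], .before = 1)
  })
  edges <- dplyr::filter(res, .data$sign != "none")
  structure(list(edges = edges,
                 tested = tibble(pre = ids[pairs$i], post = ids[pairs$j]),
                 units = ids),
            class = "omi_graph")
}

#' Summarise connectivity by functional cluster
#'
#' Fractions of units with at least one outgoing / incoming connection per
#' cluster (split by sign), mean divergence (out-degree) and convergence
#' (in-degree), and the cluster-pair connection probability matrices
#' (detected edges / tested pairs).
#'
#' @param graph An `omi_graph` from [infer_connectivity()].
#' @param model An `omi_clusters` object whose assignments cover the graph's
#'   units.
#' @return A list with `fractions` (tibble: cluster, sign, frac_outgoing,
#'   frac_incoming, mean_divergence, mean_convergence) and `probability`
#'   (named list of cluster x cluster matrices, `excitatory` and
#'   `inhibitory`).
#' @export
connectivity_summary <- function(graph, model) {
  asg <- model$assignments
  if (!all(graph$units %in% asg$unit_id)) {
    abort("cluster assignments must cover all graph units.")
  }
  cl_of <- stats::setNames(asg$cluster, asg$unit_id)
  clusters <- sort(unique(asg$cluster))
  edges <- graph$edges
  fractions <- purrr::map_dfr(c("excitatory", "inhibitory"), function(sg) {
    e <- edges[edges$sign == sg, ]
    purrr::map_dfr(clusters, function(cl) {
      members <- asg$unit_id[asg$cluster == cl]
      outdeg <- vapply(members, function(u) sum(e$pre == u), 0)
      indeg <- vapply(members, function(u) sum(e$post == u), 0)
      tibble(cluster = cl, sign = sg,
             frac_outgoing = mean(outdeg >= 1), frac_incoming = mean(indeg >= 1),
             mean_divergence = mean(outdeg), mean_convergence = mean(indeg))
    })
  })
  probability <- purrr::map(c(excitatory = "excitatory", inhibitory = "inhibitory"),
    function(sg) {
      e <- edges[edges$sign == sg, ]
      m <- matrix(NA_real_, length(clusters), length(clusters),
                  dimnames = list(clusters, clusters))
      for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
        tested <- sum(cl_of[graph$tested$pre] == clusters[a] &
                        cl_of[graph$tested$post] == clusters[b])
        if (tested > 0) {
          m[a, b] <- sum(cl_of[e$pre] == clusters[a] &
                           cl_of[e$post] == clusters[b]) / tested
        }
      }
      m
    })
  list(fractions = fractions, probability = probability)
}
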