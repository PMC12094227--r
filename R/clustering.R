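#' Build the unit-by-unit response correlation matrix
#'
#' Each unit's feature vector is its z-scored omission-aligned PSTH spanning
#' the omission and the immediately preceding and following stimuli; the
#' matrix of Pearson correlations between these feature vectors is what the
#' functional clustering operates on.
#'
#' @param units Units tibble.
#' @param schedule Schedule from [generate_schedule()].
#' @param window Feature window around omission onset; the default spans the
#'   preceding stimulus cycle, the omitted cycle and the following stimulus
#'   cycle at the default cadence (`c(-0.75, 1.5)`).
#' @param bin_s PSTH bin width (default 0.010 s).
#' @param exclude Optional `c(from, to)` interval (seconds relative to
#'   omission onset) whose bins are dropped from the feature vectors, e.g.
#'   `c(0, 0.75)` to cluster without the omission period.
#' @return An object of class `omi_respmat`: a list with `unit_id`,
#'   `features` (units x bins matrix of z-scored PSTHs), `time` (bin
#'   centres), `corr` (unit x unit correlation matrix), and `dropped`
#'   (zero-variance unit ids, excluded with a warning).
#' @export
build_response_matrix <- function(units, schedule, window = c(-0.75, 1.5),
                                  bin_s = 0.010, exclude = NULL) {
  assert_units(units)
  om <- event_onsets(schedule, omitted = TRUE)
  if (nrow(units) < 2L) abort("need at least 2 units.")
  if (length(om) < 2L) abort("need at least 2 omissions.")
  ps <- purrr::map(units$spikes, compute_psth, events = om, window = window, bin_s = bin_s)
  zero <- vapply(ps, function(p) isTRUE(attr(p, "zero_variance")), logical(1))
  if (any(zero)) {
    warn(paste0(sum(zero), " zero-variance unit(s) excluded from the response matrix."))
  }
  keep <- which(!zero)
  if (length(keep) < 2L) abort("fewer than 2 units with non-degenerate responses.")
  tm <- ps[[keep[1]]]$time
  bin_keep <- if (is.null(exclude)) rep(TRUE, length(tm)) else {
    !(tm >= exclude[1] & tm < exclude[2])
  }
  feats <- t(vapply(ps[keep], function(p) p$zrate[bin_keep], numeric(sum(bin_keep))))
  rownames(feats) <- units$unit_id[keep]
  structure(
    list(unit_id = units$unit_id[keep], features = feats, time = tm[bin_keep],
         corr = cor(t(feats)), dropped = units$unit_id[zero]),
    class = "omi_respmat"
  )
}

# Pooled within-cluster dispersion W_k (sum over clusters of within-cluster
# pairwise squared distances / (2 n_r), identical to the within-cluster sum
# of squares around centroids).
wk_dispersion <- function(x, k, nstart, iter.max = 50) {
  if (k == 1L) {
    sum(sweep(x, 2, colMeans(x))^2)
  } else {
    kmeans(x, centers = k, nstart = nstart, iter.max = iter.max)$tot.withinss
  }
}

#' Select the number of clusters by elbow and gap criteria
#'
#' Computes the pooled within-cluster dispersion `W_k` over a grid of `k`
#' (k-means), then (1) the elbow: the `k` where the discrete slope of
#' `log W_k` changes most drastically, measured as the ratio of the slope
#' into `k` over the slope out of `k` (a relative flattening detector); and
#' (2) the gap criterion `Gap_n(k) = E*_n{log W_k} - log W_k`, with the
#' expectation estimated by Monte-Carlo draws from a uniform reference over
#' the principal-component-aligned bounding box of the data (the rotated
#' reference tracks the strong correlations between response features; a
#' plain feature-range box is available via `reference = "range"`). The
#' per-session optimum is the mean of the two, rounded half-up.
#'
#' @param rm An `omi_respmat` (the correlation-matrix rows are clustered), or
#'   a plain numeric matrix of feature rows.
#' @param k_grid Candidate cluster numbers (default `2:10`; `k = 1` is always
#'   evaluated so the gap criterion can return 1).
#' @param B Number of Monte-Carlo reference draws (default 50).
#' @param seed Integer seed.
#' @param gap_rule `"one_se"` (default): smallest `k` with
#'   `Gap(k) >= Gap(k+1) - SE(k+1)`; `"max"`: argmax of the gap.
#' @param reference Reference distribution for the gap Monte Carlo:
#'   `"pca"` (default, uniform in the principal-component box) or `"range"`
#'   (uniform over each feature's observed range).
#' @param nstart k-means restarts (default 20 for the data, 5 for reference
#'   draws).
#' @param se_factor Multiplier on the Monte-Carlo standard error in the
#'   one-SE rule (default 2; small samples show a slow upward creep of the
#'   gap past the true k that one bare SE does not absorb).
#' @param elbow_ratio Slope-ratio threshold declaring a "drastic" flattening
#'   of the dispersion profile (default 2).
#' @return A list of class `omi_kselect`: `table` (tibble with k, W_k, log_W,
#'   E_log_W, gap, se), `k_elbow`, `k_gap`, `k_opt`, `flag`.
#' @export
choose_k <- function(rm, k_grid = 2:10, B = 50, seed = 1,
                     gap_rule = c("one_se", "max"),
                     reference = c("pca", "range"), nstart = 20,
                     se_factor = 2, elbow_ratio = 2) {
  gap_rule <- match.arg(gap_rule)
  reference <- match.arg(reference)
  x <- if (inherits(rm, "omi_respmat")) rm$corr else as.matrix(rm)
  if (nrow(x) <= max(k_grid)) abort("need more rows than the largest candidate k.")
  ks <- sort(unique(c(1L, as.integer(k_grid))))
  if (max(apply(x, 2, function(col) diff(range(col)))) < 1e-12) {
    return(structure(list(table = tibble(k = 1L), k_elbow = 1L, k_gap = 1L,
                          k_opt = 1L, flag = "degenerate"), class = "omi_kselect"))
  }
  with_seed(seed, {
    logW <- vapply(ks, function(k) log(wk_dispersion(x, k, nstart)), 0)
    ctr <- colMeans(x)
    xc <- sweep(x, 2, ctr)
    if (reference == "pca") {
      V <- svd(xc, nu = 0)$v
      xp <- xc %*% V
      lo <- apply(xp, 2, min); hi <- apply(xp, 2, max)
    } else {
      lo <- apply(xc, 2, min); hi <- apply(xc, 2, max)
    }
    ref <- matrix(NA_real_, nrow = B, ncol = length(ks))
    for (b in seq_len(B)) {
      zb <- matrix(runif(length(x), rep(lo, each = nrow(x)), rep(hi, each = nrow(x))),
                   nrow = nrow(x))
      xb <- if (reference == "pca") zb %*% t(V) else zb
      ref[b, ] <- vapply(ks, function(k) log(wk_dispersion(xb, k, nstart = 5)), 0)
    }
    e_logW <- colMeans(ref)
    se <- apply(ref, 2, sd) * sqrt(1 + 1 / B)
    gap <- e_logW - logW

    # Elbow: drastic relative flattening of the log-dispersion profile (slope
    # into k divided by slope out of k). A hierarchical structure can show
    # several such flattenings; the elbow is the LAST one exceeding
    # `elbow_ratio` (the onset of the plateau), falling back to the largest
    # ratio when none does.
    drops <- -diff(logW)                    # drops[i] = logW[ks[i]] - logW[ks[i+1]]
    ratio <- pmax(drops[-length(drops)], 0) / pmax(drops[-1], 1e-6)
    elbow_candidates <- ks[-c(1L, length(ks))]
    # a real elbow ends a material decline, not plateau jitter
    material <- drops[-length(drops)] >= 0.05 * (logW[1] - logW[length(logW)])
    strong <- which(ratio >= elbow_ratio & material)
    k_elbow <- if (length(strong)) {
      elbow_candidates[max(strong)]
    } else {
      elbow_candidates[which.max(ratio)]
    }

    k_gap <- if (gap_rule == "max") {
      ks[which.max(gap)]
    } else {
      hit <- which(gap[-length(ks)] >= gap[-1] - se_factor * se[-1])
      if (length(hit)) ks[min(hit)] else ks[which.max(gap)]
    }
    k_opt <- as.integer(round_half_up(mean(c(k_elbow, k_gap))))
    structure(
      list(table = tibble(k = ks, W_k = exp(logW), log_W = logW, E_log_W = e_logW,
                          gap = gap, se = se),
           k_elbow = as.integer(k_elbow), k_gap = as.integer(k_gap),
           k_opt = k_opt, flag = ""),
      class = "omi_kselect"
    )
  })
}

#' @export
print.omi_kselect <- function(x, ...) {
  cat("<omi_kselect> k_elbow =", x$k_elbow, " k_gap =", x$k_gap,
      " k_opt =", x$k_opt, "\n")
  invisible(x)
}

# Matching of cluster mean profiles to archetype templates by maximal total
# correlation: one-to-one (exhaustive for small k, greedy otherwise); when
# there are more clusters than templates, the surplus clusters take their
# nearest template and names are made unique.
match_templates <- function(profiles, templates) {
  cmat <- cor(t(profiles), t(templates))  # clusters x templates
  k <- nrow(cmat); m <- ncol(cmat)
  best <- integer(k)
  if (k <= m && k <= 7 && m <= 8) {
    perms <- gtools_permutations(m, k)
    scores <- apply(perms, 1, function(p) sum(cmat[cbind(seq_len(k), p)]))
    best <- perms[which.max(scores), ]
  } else {
    used <- logical(m)
    ord <- order(apply(cmat, 1, max), decreasing = TRUE)
    for (i in ord) {
      j <- order(cmat[i, ], decreasing = TRUE)
      jj <- j[!used[j]][1]
      if (is.na(jj)) jj <- j[1]          # more clusters than templates
      best[i] <- jj; used[jj] <- TRUE
    }
  }
  list(index = best, label = make.unique(colnames(cmat)[best]))
}

# Minimal permutations(n, r) so we do not depend on gtools.
gtools_permutations <- function(n, r) {
  if (r == 1L) return(matrix(seq_len(n), ncol = 1))
  sub <- gtools_permutations(n, r - 1L)
  out <- NULL
  for (v in seq_len(n)) {
    ok <- sub[rowSums(sub == v) == 0, , drop = FALSE]
    out <- rbind(out, cbind(v, ok))
  }
  unname(out)
}

#' Cluster units into functional classes
#'
#' k-means (multiple restarts) on the rows of the response correlation
#' matrix. Each fitted cluster receives a semantic archetype label by
#' one-to-one matching of its mean z-scored PSTH to the noise-free archetype
#' templates (highest total correlation), and a class: STIM-ON for
#' transient/sustained/ramp-to-offset profiles, STIM-OFF for step-OFF/ON and
#' ramp-to-onset profiles.
#'
#' @param rm An `omi_respmat` from [build_response_matrix()].
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param nstart k-means restarts (default 20).
#' @param label_archetypes Candidate archetypes for semantic labels.
#' @return A list of class `omi_clusters`: `assignments` (tibble: unit_id,
#'   cluster, semantic_label, class), `centroids`, `profiles` (cluster mean
#'   z-PSTHs), `k`.
#' @export
cluster_units <- function(rm, k, seed = 1, nstart = 20,
                          label_archetypes = c("transient_on", "sustained_on",
                                               "ramp_to_offset", "step_off_on",
                                               "ramp_off")) {
  if (!inherits(rm, "omi_respmat")) abort("`rm` must come from build_response_matrix().")
  if (k < 2) abort("`k` must be at least 2.")
  km <- with_seed(seed, kmeans(rm$corr, centers = k, nstart = nstart, iter.max = 100))
  profiles <- t(vapply(seq_len(k), function(cl) {
    colMeans(rm$features[km$cluster == cl, , drop = FALSE])
  }, numeric(ncol(rm$features))))
  tmpl <- template_at(label_archetypes, rm$time)
  matched <- match_templates(profiles, tmpl)
  labels <- matched$label
  off <- label_archetypes[matched$index] %in% c("step_off_on", "ramp_off")
  assignments <- tibble(
    unit_id = rm$unit_id,
    cluster = as.integer(km$cluster),
    semantic_label = labels[km$cluster],
    class = ifelse(off[km$cluster], "STIM_OFF", "STIM_ON")
  )
  structure(list(assignments = assignments, centroids = km$centers,
                 profiles = profiles, k = k),
            class = "omi_clusters")
}

#' @export
print.omi_clusters <- function(x, ...) {
  cat("<omi_clusters> k =", x$k, "\n")
  print(table(x$assignments$semantic_label))
  invisible(x)
}

#' Cluster composition by area, layer or cell type
#'
#' Fraction of units in each cluster within each stratum; fractions sum to 1
#' within a stratum. With a `session` column present, the mean and SEM across
#' sessions are reported.
#'
#' @param model An `omi_clusters` object.
#' @param units Units tibble with metadata columns.
#' @param by Stratifying column name (default `"area"`).
#' @return A tibble with stratum, cluster, `fraction` (and `sem` when
#'   sessions are present).
#' @export
cluster_composition <- function(model, units, by = "area") {
  if (!by %in% names(units)) abort(paste0("column `", by, "` not found in units."))
  df <- dplyr::inner_join(model$assignments, units, by = "unit_id")
  has_session <- "session" %in% names(units)
  grp <- if (has_session) c("session", by) else by
  comp <- df |>
    dplyr::count(dplyr::across(dplyr::all_of(c(grp, "cluster")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(grp)),
      cluster = sort(unique(df$cluster)),
      fill = list(n = 0L, fraction = 0)
    )
  if (has_session) {
    comp |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "cluster")))) |>
      dplyr::summarise(
        sem = sd(.data$fraction) / sqrt(dplyr::n()),
        fraction = mean(.data$fraction), .groups = "drop"
      )
  } else {
    dplyr::select(comp, -"n")
  }
}

#' Decode elapsed time within the omission from cluster activity
#'
#' For each cluster, a cross-validated linear regression predicts the
#' time-bin index within the omission window from the cluster members'
#' normalised (z-scored) spike counts in that bin. Performance is the
#' distribution of mean absolute error across folds, in bins.
#'
#' @param units Units tibble.
#' @param schedule Schedule from [generate_schedule()].
#' @param model An `omi_clusters` object.
#' @param om_window Omission window (default `c(0, 0.25)`).
#' @param bin_s Count bin width (default 0.05 s).
#' @param folds CV folds over omission events (default 10).
#' @param min_events Minimum omissions required (default 20).
#' @param permute_labels Shuffle the bin-index targets before decoding
#'   (permutation null; seeded).
#' @param seed Seed for the permutation.
#' @return A tibble with `cluster`, `semantic_label`, `fold`, `mae`, `flag`.
#' @export
decode_time_bin <- function(units, schedule, model, om_window = c(0, 0.25),
                            bin_s = 0.05, folds = 10, min_events = 20,
                            permute_labels = FALSE, seed = 1) {
  om <- event_onsets(schedule, omitted = TRUE)
  if (length(om) < min_events) abort("too few omission events.")
  nb <- floor(diff(om_window) / bin_s + 1e-9)
  starts <- om_window[1] + (seq_len(nb) - 1) * bin_s
  lab_of <- model$assignments |>
    dplyr::distinct(.data$cluster, .data$semantic_label)
  fold_of_event <- rep(seq_len(folds), length.out = length(om))

  purrr::map_dfr(sort(unique(model$assignments$cluster)), function(cl) {
    ids <- model$assignments$unit_id[model$assignments$cluster == cl]
    sub <- units[units$unit_id %in% ids, ]
    # Samples: (event, bin); features: per-unit counts in that bin.
    X <- vapply(sub$spikes, function(sp) {
      as.numeric(vapply(starts, function(s0) count_in_windows(sp, om + s0, bin_s),
                        numeric(length(om))))
    }, numeric(length(om) * nb))
    Xs <- scale(X)
    const <- is.na(colSums(Xs)) | apply(X, 2, sd) < 1e-12
    flag <- if (all(const)) "constant_rates" else ""
    Xs <- Xs[, !const, drop = FALSE]
    ybin <- rep(seq_len(nb), each = length(om))
    if (permute_labels) ybin <- with_seed(seed, sample(ybin))
    fold_id <- rep(fold_of_event, times = nb)
    mae <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (ncol(Xs) == 0L) return(mean(abs(ybin[!tr] - mean(ybin[tr]))))
      fit <- stats::lm.fit(cbind(1, Xs[tr, , drop = FALSE]), ybin[tr])
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred <- drop(cbind(1, Xs[!tr, , drop = FALSE]) %*% beta)
      mean(abs(ybin[!tr] - pred))
    }, 0)
    tibble(cluster = cl,
           semantic_label = lab_of$semantic_label[lab_of$cluster == cl],
           fold = seq_len(folds), mae = mae, flag = flag)
  })
}
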