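#' Session population response around the omission
#'
#' Mean z-scored PSTH across units significantly up-modulated during the
#' omission, on a uniform time grid spanning the omission window.
#'
#' @param units Units tibble.
#' @param schedule Schedule from [generate_schedule()].
#' @param modulation Output of [omission_modulation()] for the same units;
#'   computed internally when `NULL`.
#' @param window `c(pre, post)` in seconds around omission onset
#'   (default +-250 ms).
#' @param bin_s Bin width (default 0.010 s).
#' @return A tibble with `time` and `mean_zrate`; attribute `n_units`.
#' @export
population_response <- function(units, schedule, modulation = NULL,
                                window = c(-0.25, 0.25), bin_s = 0.010) {
  if (is.null(modulation)) modulation <- omission_modulation(units, schedule)
  up <- modulation$unit_id[modulation$sign_class == "up"]
  if (length(up) == 0L) abort("no significantly up-modulated units in this session.")
  om <- event_onsets(schedule, omitted = TRUE)
  keep <- units[units$unit_id %in% up, ]
  z <- purrr::map(keep$spikes, function(sp) {
    compute_psth(sp, om, window = c(-0.75, 0.75), bin_s = bin_s)
  })
  tm <- z[[1]]$time
  in_w <- tm >= window[1] & tm < window[2]
  mat <- vapply(z, function(p) p$zrate, numeric(length(tm)))
  out <- tibble(time = tm[in_w], mean_zrate = rowMeans(mat)[in_w])
  attr(out, "n_units") <- length(up)
  out
}

# Contiguous-block fold membership over n points (random folds would leak the
# smooth trend).
block_folds <- function(n, folds) {
  rep(seq_len(folds), each = ceiling(n / folds))[seq_len(n)]
}

# Held-out R²: SSE of predictions against total SS around the training mean
# (contiguous test blocks of a trending signal have little internal variance,
# so centring on the test mean would be degenerate).
cv_r2 <- function(y, yhat, center) {
  sst <- sum((y - center)^2)
  if (sst < 1e-300) return(0)
  1 - sum((y - yhat)^2) / sst
}

#' Cross-validated linear fit to a population response
#'
#' Least-squares line fit with coefficient-of-determination evaluated on
#' held-out contiguous time blocks.
#'
#' @param resp Tibble with `time` and `mean_zrate` (as from
#'   [population_response()]), or any tibble whose first two numeric columns
#'   are x and y.
#' @param folds Number of CV folds (default 8).
#' @return An object of class `omi_fit` with elements `model = "linear"`,
#'   `slope`, `intercept`, `R2_cv`.
#' @export
fit_linear <- function(resp, folds = 8) {
  x <- resp[[1]]; y <- resp[[2]]
  if (length(x) < folds) abort("need at least as many points as folds.")
  fit <- lm(y ~ x)
  fold_id <- block_folds(length(x), folds)
  r2 <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    m <- lm(y[tr] ~ x[tr])
    yhat <- coef(m)[1] + coef(m)[2] * x[!tr]
    cv_r2(y[!tr], yhat, mean(y[tr]))
  }, 0)
  structure(
    list(model = "linear", slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]), R2_cv = mean(r2),
         fitted = unname(stats::fitted(fit)), x = x, y = y, converged = TRUE),
    class = "omi_fit"
  )
}

sigmoid_fun <- function(x, Delta, A, sigma, c0) Delta + A / (1 + exp(-sigma * (x - c0)))

# Multi-start sigmoid least squares; returns best par by SSE (ties broken by
# smaller |sigma|) or NULL if nothing converged.
sigmoid_solve <- function(x, y, starts, lower, upper) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ Delta + A / (1 + exp(-sigma * (x - c0))),
        start = as.list(starts[s, ]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    par <- coef(fit)
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && abs(par["sigma"]) < abs(best$par["sigma"]))) {
      best <- list(par = par, sse = sse)
    }
  }
  best
}

sigmoid_starts <- function(x, y, sigma_grid = c(5, 50, 500)) {
  qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  rng <- diff(range(y))
  if (rng < 1e-12) rng <- 1
  expand.grid(Delta = min(y), A = rng, sigma = sigma_grid, c0 = qs)
}

#' Cross-validated sigmoid fit to a population response
#'
#' Fits `y = Delta + A / (1 + exp(-sigma (x - c)))` by multi-start
#' Levenberg-Marquardt least squares (slope constrained positive; ties across
#' restarts broken toward the shallower slope) and evaluates mean R-squared
#' on held-out contiguous time blocks.
#'
#' @inheritParams fit_linear
#' @param sigma_grid Slope initialisation grid in 1/s (default 5, 50, 500).
#' @param seed Unused placeholder kept for interface symmetry (the optimiser
#'   is deterministic).
#' @return An object of class `omi_fit` with `model = "sigmoid"` and elements
#'   `Delta`, `A`, `sigma`, `c`, `R2_cv`, `converged`.
#' @export
fit_sigmoid <- function(resp, folds = 8, sigma_grid = c(5, 50, 500), seed = NULL) {
  x <- resp[[1]]; y <- resp[[2]]
  if (length(x) < 8) abort("need at least 8 points to identify 4 sigmoid parameters.")
  lower <- c(Delta = -Inf, A = -Inf, sigma = 1e-3, c0 = min(x) - diff(range(x)))
  upper <- c(Delta = Inf, A = Inf, sigma = 1e4, c0 = max(x) + diff(range(x)))
  starts <- sigmoid_starts(x, y, sigma_grid)
  best <- sigmoid_solve(x, y, starts, lower, upper)
  if (is.null(best)) {
    return(structure(list(model = "sigmoid", Delta = NA_real_, A = NA_real_,
                          sigma = NA_real_, c = NA_real_, R2_cv = NA_real_,
                          x = x, y = y, converged = FALSE),
                     class = "omi_fit"))
  }
  # Per-fold fits warm-started at the full-data optimum plus the grid.
  fold_id <- block_folds(length(x), folds)
  warm <- rbind(as.data.frame(t(best$par)), sigmoid_starts(x, y, sigma_grid))
  r2 <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    bf <- sigmoid_solve(x[tr], y[tr], warm[1, , drop = FALSE], lower, upper)
    if (is.null(bf)) bf <- sigmoid_solve(x[tr], y[tr], warm, lower, upper)
    if (is.null(bf)) return(NA_real_)
    yhat <- sigmoid_fun(x[!tr], bf$par["Delta"], bf$par["A"], bf$par["sigma"], bf$par["c0"])
    cv_r2(y[!tr], yhat, mean(y[tr]))
  }, 0)
  p <- best$par
  structure(
    list(model = "sigmoid", Delta = unname(p["Delta"]), A = unname(p["A"]),
         sigma = unname(p["sigma"]), c = unname(p["c0"]),
         R2_cv = mean(r2, na.rm = TRUE),
         fitted = sigmoid_fun(x, p["Delta"], p["A"], p["sigma"], p["c0"]),
         x = x, y = y, converged = TRUE),
    class = "omi_fit"
  )
}

#' @export
print.omi_fit <- function(x, ...) {
  cat("<omi_fit>", x$model, "fit\n")
  if (x$model == "sigmoid") {
    cat(sprintf("  Delta=%.3f A=%.3f sigma=%.1f 1/s c=%.3f s\n",
                x$Delta, x$A, x$sigma, x$c))
  } else {
    cat(sprintf("  slope=%.3f intercept=%.3f\n", x$slope, x$intercept))
  }
  cat(sprintf("  cross-validated R2 = %.3f\n", x$R2_cv))
  invisible(x)
}

#' Compare sigmoid and linear fit quality across sessions
#'
#' One-sided Wilcoxon rank-sum test of per-session sigmoid R-squared values
#' against linear ones. An area is labelled `sigmoidal` when P < `alpha` and
#' the median sigmoid R-squared exceeds the median linear one.
#'
#' @param linear_R2s,sigmoid_R2s Per-session held-out R-squared values (same
#'   sessions, same order).
#' @param alpha Significance level (default 0.05).
#' @param area Optional area label carried into the result.
#' @return A one-row tibble: `area`, `p_value`, `label`, medians, `flag`.
#' @export
compare_models <- function(linear_R2s, sigmoid_R2s, alpha = 0.05, area = NA_character_) {
  if (length(linear_R2s) != length(sigmoid_R2s)) {
    abort("R2 lists must cover the same sessions.")
  }
  ok <- !is.na(linear_R2s) & !is.na(sigmoid_R2s)
  linear_R2s <- linear_R2s[ok]
  sigmoid_R2s <- sigmoid_R2s[ok]
  if (length(linear_R2s) < 3L) {
    return(tibble(area = area, p_value = NA_real_, label = NA_character_,
                  median_sigmoid = median(sigmoid_R2s), median_linear = median(linear_R2s),
                  flag = "too_few_sessions"))
  }
  p <- suppressWarnings(
    wilcox.test(sigmoid_R2s, linear_R2s, alternative = "greater")$p.value)
  if (is.na(p)) p <- 1
  lab <- if (p < alpha && median(sigmoid_R2s) > median(linear_R2s)) "sigmoidal" else "not_sigmoidal"
  tibble(area = area, p_value = p, label = lab,
         median_sigmoid = median(sigmoid_R2s), median_linear = median(linear_R2s),
         flag = "")
}

#' Classify areas by sigmoid-slope modes
#'
#' Pools fitted sigmoid slopes across areas and sessions, estimates their
#' density on a log10 axis (Silverman bandwidth), finds up to three dominant
#' modes, and uses the density troughs between them as boundaries. Each area
#' is labelled by the mode interval containing its median slope:
#' `linear_ramp` (shallowest mode), `intermediate`, `step_like` (steepest).
#'
#' @param sigma_tbl Tibble with columns `area` and `sigma` (1/s, positive).
#' @param max_modes Maximum number of modes to retain (default 3).
#' @return A list with `areas` (tibble: area, median_sigma, slope_mode),
#'   `boundaries` (slope values separating modes), `n_modes`, `flag`.
#' @export
classify_slope_modes <- function(sigma_tbl, max_modes = 3) {
  sig <- sigma_tbl$sigma
  if (length(sig) < 30L) abort("need at least 30 pooled slope values.")
  ls <- log10(sig[sig > 0])
  d <- density(ls, bw = "nrd0")
  y <- d$y
  n <- length(y)
  is_max <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  peaks <- is_max[order(y[is_max], decreasing = TRUE)]
  peaks <- sort(peaks[seq_len(min(max_modes, length(peaks)))])
  flag <- if (length(peaks) < 2L) "unimodal" else ""
  bounds <- numeric(0)
  if (length(peaks) >= 2L) {
    for (j in seq_len(length(peaks) - 1L)) {
      seg <- peaks[j]:peaks[j + 1L]
      bounds <- c(bounds, d$x[seg[which.min(y[seg])]])
    }
  }
  mode_names <- if (length(peaks) >= 3L) {
    c("linear_ramp", "intermediate", "step_like")
  } else if (length(peaks) == 2L) {
    c("linear_ramp", "step_like")
  } else "linear_ramp"
  areas <- sigma_tbl |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(median_sigma = median(.data$sigma), .groups = "drop") |>
    dplyr::mutate(
      slope_mode = mode_names[findInterval(log10(.data$median_sigma), bounds) + 1L]
    )
  list(areas = areas, boundaries = 10^bounds, n_modes = length(peaks), flag = flag)
}
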