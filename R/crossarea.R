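#' Trial-binned spike counts for one condition
#'
#' Counts each unit's spikes in fixed-width bins within the presentation (or
#' omission) window of every trial of one condition.
#'
#' @param units Units tibble.
#' @param schedule Schedule from [generate_schedule()].
#' @param condition `"stimulus"` or `"omission"`.
#' @param window Count window relative to slot onset (default `c(0, 0.25)`).
#' @param bin_s Bin width (default 0.05 s).
#' @param max_trials Optional cap on the number of trials (first `max_trials`
#'   slots used).
#' @return A 3-d array `trials x bins x units` with unit ids in dimnames.
#' @export
bin_trial_counts <- function(units, schedule, condition = c("stimulus", "omission"),
                             window = c(0, 0.25), bin_s = 0.05, max_trials = NULL) {
  condition <- match.arg(condition)
  onsets <- event_onsets(schedule, omitted = condition == "omission")
  if (!is.null(max_trials)) onsets <- onsets[seq_len(min(max_trials, length(onsets)))]
  nb <- floor(diff(window) / bin_s + 1e-9)
  starts <- window[1] + (seq_len(nb) - 1) * bin_s
  arr <- array(0, dim = c(length(onsets), nb, nrow(units)),
               dimnames = list(NULL, NULL, units$unit_id))
  for (u in seq_len(nrow(units))) {
    sp <- units$spikes[[u]]
    for (b in seq_len(nb)) {
      arr[, b, u] <- count_in_windows(sp, onsets + starts[b], bin_s)
    }
  }
  arr
}

#' Residualise trial counts against the condition PSTH
#'
#' Subtracts the per-unit, per-bin mean across trials (the PSTH) from every
#' single-trial response and z-scores each unit's residuals. Zero-variance
#' units are dropped with a warning.
#'
#' @param counts A `trials x bins x units` array from [bin_trial_counts()].
#' @return A `trials x (bins * units)` residual matrix (unit-major column
#'   order), with attribute `dropped` listing removed units.
#' @export
residualize <- function(counts) {
  if (dim(counts)[1] < 2L) abort("need at least 2 trials.")
  psth <- apply(counts, c(2, 3), mean)
  res <- sweep(counts, c(2, 3), psth)
  n_tr <- dim(counts)[1]
  keep <- logical(dim(counts)[3])
  for (u in seq_len(dim(counts)[3])) {
    s <- sd(res[, , u])
    keep[u] <- s > 1e-12
    if (keep[u]) res[, , u] <- res[, , u] / s
  }
  if (any(!keep)) {
    warn(paste0(sum(!keep), " zero-variance unit(s) dropped during residualisation."))
  }
  res <- res[, , keep, drop = FALSE]
  out <- matrix(res, nrow = n_tr)
  attr(out, "dropped") <- dimnames(counts)[[3]][!keep]
  out
}

#' Closed-form ridge regression solution
#'
#' `B = (X'X + lambda I)^{-1} X'Y`.
#'
#' @param X Predictor matrix (samples x features).
#' @param Y Response matrix (samples x targets).
#' @param lambda Non-negative ridge penalty.
#' @return The coefficient matrix `B` (features x targets).
#' @export
ridge_solve <- function(X, Y, lambda) {
  p <- ncol(X)
  solve(crossprod(X) + lambda * diag(p), crossprod(X, Y))
}

# Ridge predictions for several lambdas at once via one SVD of X_train.
ridge_predict_path <- function(Xtr, Ytr, Xte, lambdas) {
  sv <- svd(Xtr)
  d <- sv$d
  uty <- crossprod(sv$u, Ytr)
  lapply(lambdas, function(l) {
    shrink <- d / (d^2 + l)
    Xte %*% (sv$v %*% (shrink * uty))
  })
}

r2_pooled <- function(Y, Yhat) {
  sst <- sum(sweep(Y, 2, colMeans(Y))^2)
  if (sst < 1e-300) return(NA_real_)
  1 - sum((Y - Yhat)^2) / sst
}

#' Cross-area interaction strength via residual ridge prediction
#'
#' Fits, per condition (stimulus / omission), a ridge model predicting one
#' area's residual activity from another's. Trial counts are matched across
#' conditions by seeded subsampling of the larger set. The penalty is chosen
#' by inner cross-validation on each training fold; performance is pooled
#' held-out R-squared. The interaction strength is
#' `R2(stimulus) - R2(omission)`: positive means better prediction during
#' stimulus.
#'
#' @param units_x,units_y Units tibbles for source and target areas.
#' @param schedule Schedule from [generate_schedule()].
#' @param lambda_grid Ridge penalties (default 10 log-spaced values in
#'   1e-2..1e3).
#' @param folds Outer CV folds (default 10; reduced with a warning when there
#'   are fewer trials).
#' @param window,bin_s Passed to [bin_trial_counts()].
#' @param seed Integer seed (trial matching and fold assignment).
#' @return A one-row tibble: `r2_stimulus`, `r2_omission`, `difference`,
#'   `lambda_stimulus`, `lambda_omission`, `n_trials`.
#' @export
ridge_interaction <- function(units_x, units_y, schedule,
                              lambda_grid = 10^seq(-2, 3, length.out = 10),
                              folds = 10, window = c(0, 0.25), bin_s = 0.05,
                              seed = 1) {
  n_stim <- length(event_onsets(schedule, omitted = FALSE))
  n_om <- length(event_onsets(schedule, omitted = TRUE))
  n_match <- min(n_stim, n_om)
  res <- purrr::map(c("stimulus", "omission"), function(cond) {
    cx <- bin_trial_counts(units_x, schedule, cond, window, bin_s)
    cy <- bin_trial_counts(units_y, schedule, cond, window, bin_s)
    n_tr <- dim(cx)[1]
    sel <- if (n_tr > n_match) {
      with_seed(stage_seed(seed, 7L), sort(sample.int(n_tr, n_match)))
    } else seq_len(n_tr)
    X <- residualize(cx[sel, , , drop = FALSE])
    Y <- residualize(cy[sel, , , drop = FALSE])
    cv_ridge_r2(X, Y, lambda_grid, folds, seed = stage_seed(seed, 11L))
  })
  tibble(
    r2_stimulus = res[[1]]$r2, r2_omission = res[[2]]$r2,
    difference = res[[1]]$r2 - res[[2]]$r2,
    lambda_stimulus = res[[1]]$lambda, lambda_omission = res[[2]]$lambda,
    n_trials = n_match
  )
}

# Outer-CV ridge with per-fold inner lambda selection.
cv_ridge_r2 <- function(X, Y, lambda_grid, folds, seed = 1, inner_folds = 5) {
  n <- nrow(X)
  if (n < folds) {
    warn("fewer trials than folds; reducing fold count.")
    folds <- max(2L, n)
  }
  with_seed(seed, {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    sse <- 0; sst <- 0; lambda_used <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      Xtr <- X[tr, , drop = FALSE]; Ytr <- Y[tr, , drop = FALSE]
      inner_id <- sample(rep(seq_len(inner_folds), length.out = nrow(Xtr)))
      inner_sse <- numeric(length(lambda_grid))
      for (g in seq_len(inner_folds)) {
        itr <- inner_id != g
        preds <- ridge_predict_path(Xtr[itr, , drop = FALSE], Ytr[itr, , drop = FALSE],
                                    Xtr[!itr, , drop = FALSE], lambda_grid)
        inner_sse <- inner_sse + vapply(preds, function(p) sum((Ytr[!itr, ] - p)^2), 0)
      }
      lam <- lambda_grid[which.min(inner_sse)]
      lambda_used[f] <- lam
      pred <- ridge_predict_path(Xtr, Ytr, X[!tr, , drop = FALSE], lam)[[1]]
      Yte <- Y[!tr, , drop = FALSE]
      sse <- sse + sum((Yte - pred)^2)
      sst <- sst + sum(sweep(Yte, 2, colMeans(Yte))^2)
    }
    list(r2 = 1 - sse / sst, lambda = median(lambda_used))
  })
}

#' Canonical correlations between two areas
#'
#' Whitens each side (with a small diagonal loading when samples are scarce
#' relative to the joint dimensionality) and takes the singular values of the
#' whitened cross-covariance: the sample canonical correlations, clipped to
#' `[0, 1]` and non-increasing across dimensions.
#'
#' @param X,Y Activity matrices (samples x units), e.g. concatenated
#'   trial-window counts of one condition.
#' @param n_dims Number of leading canonical dimensions to report
#'   (default 3).
#' @param ridge Diagonal loading added to each covariance when
#'   `nrow(X) <= ncol(X) + ncol(Y)` (default 1e-3 of the mean variance);
#'   a flag marks regularised fits.
#' @return A list with `correlations` (length `n_dims`), `A`, `B`
#'   (canonical coefficient matrices), `regularized`.
#' @export
cca_interaction <- function(X, Y, n_dims = 3, ridge = 1e-3) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  n <- nrow(X)
  regularized <- n <= ncol(X) + ncol(Y)
  whiten <- function(M) {
    S <- crossprod(M) / (n - 1)
    if (regularized) S <- S + diag(ridge * mean(diag(S)) + 1e-12, ncol(M))
    e <- eigen(S, symmetric = TRUE)
    vals <- pmax(e$values, 1e-12)
    e$vectors %*% (t(e$vectors) / sqrt(vals))
  }
  Wx <- whiten(X); Wy <- whiten(Y)
  Sxy <- crossprod(X, Y) / (n - 1)
  sv <- svd(t(Wx) %*% Sxy %*% Wy)
  k <- min(n_dims, length(sv$d))
  list(
    correlations = pmin(pmax(sv$d[seq_len(k)], 0), 1),
    A = Wx %*% sv$u[, seq_len(k), drop = FALSE],
    B = Wy %*% sv$v[, seq_len(k), drop = FALSE],
    regularized = regularized
  )
}

#' Simulate two areas sharing a condition-specific latent
#'
#' Generates trial-binned counts for two areas whose residual (trial-to-
#' trial) fluctuations share a one-dimensional latent only during the chosen
#' condition, on top of independent Poisson-like noise. Used to exercise the
#' sign convention of the interaction strength.
#'
#' @param n_trials Trials per condition.
#' @param n_bins Bins per trial.
#' @param n_x,n_y Units per area.
#' @param latent_sd SD of the shared latent (in count units).
#' @param noise_sd SD of private noise.
#' @param shared_in Condition carrying the latent (`"stimulus"` or
#'   `"omission"`).
#' @param seed Integer seed.
#' @return A list with per-condition `trials x bins x units` arrays for both
#'   areas: `x_stimulus`, `y_stimulus`, `x_omission`, `y_omission`.
#' @export
simulate_coupled_areas <- function(n_trials = 60, n_bins = 5, n_x = 15, n_y = 15,
                                   latent_sd = 1.5, noise_sd = 1,
                                   shared_in = c("omission", "stimulus"),
                                   seed = 1) {
  shared_in <- match.arg(shared_in)
  with_seed(seed, {
    make <- function(n_units, shared) {
      base <- array(rnorm(n_trials * n_bins * n_units, 5, noise_sd),
                    dim = c(n_trials, n_bins, n_units),
                    dimnames = list(NULL, NULL, sprintf("u%03d", seq_len(n_units))))
      if (!is.null(shared)) {
        load <- runif(n_units, 0.5, 1.5)
        for (u in seq_len(n_units)) base[, , u] <- base[, , u] + outer(shared, rep(load[u], n_bins))
      }
      base
    }
    lat <- rnorm(n_trials, 0, latent_sd)
    if (shared_in == "omission") {
      list(x_stimulus = make(n_x, NULL), y_stimulus = make(n_y, NULL),
           x_omission = make(n_x, lat), y_omission = make(n_y, lat))
    } else {
      list(x_stimulus = make(n_x, lat), y_stimulus = make(n_y, lat),
           x_omission = make(n_x, NULL), y_omission = make(n_y, NULL))
    }
  })
}

#' Interaction strength from pre-binned condition arrays
#'
#' Residualises each condition's arrays and computes the held-out ridge
#' R-squared per condition and their difference (stimulus minus omission).
#'
#' @param arrays A list as returned by [simulate_coupled_areas()].
#' @inheritParams ridge_interaction
#' @return A one-row tibble like [ridge_interaction()]'s.
#' @export
ridge_interaction_arrays <- function(arrays,
                                     lambda_grid = 10^seq(-2, 3, length.out = 10),
                                     folds = 10, seed = 1) {
  res <- purrr::map(c("stimulus", "omission"), function(cond) {
    X <- residualize(arrays[[paste0("x_", cond)]])
    Y <- residualize(arrays[[paste0("y_", cond)]])
    cv_ridge_r2(X, Y, lambda_grid, folds, seed = stage_seed(seed, 11L))
  })
  tibble(
    r2_stimulus = res[[1]]$r2, r2_omission = res[[2]]$r2,
    difference = res[[1]]$r2 - res[[2]]$r2,
    lambda_stimulus = res[[1]]$lambda, lambda_omission = res[[2]]$lambda,
    n_trials = dim(arrays$x_stimulus)[1]
  )
}
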