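#' Tidy a population-response fit
#'
#' @param x An `omi_fit` from [fit_linear()] or [fit_sigmoid()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.omi_fit <- function(x, ...) {
  if (x$model == "sigmoid") {
    tibble(term = c("Delta", "A", "sigma", "c"),
           estimate = c(x$Delta, x$A, x$sigma, x$c))
  } else {
    tibble(term = c("intercept", "slope"),
           estimate = c(x$intercept, x$slope))
  }
}

#' Glance at a population-response fit
#'
#' @param x An `omi_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `r2_cv`, `n`, `converged`.
#' @export
glance.omi_fit <- function(x, ...) {
  tibble(model = x$model, r2_cv = x$R2_cv, n = length(x$x),
         converged = isTRUE(x$converged))
}

#' Tidy a cluster-number selection
#'
#' @param x An `omi_kselect` from [choose_k()].
#' @param ... Unused.
#' @return The per-k diagnostics tibble (k, W_k, gap, se, ...).
#' @export
tidy.omi_kselect <- function(x, ...) x$table

#' Glance at a cluster-number selection
#'
#' @param x An `omi_kselect`.
#' @param ... Unused.
#' @return A one-row tibble with `k_elbow`, `k_gap`, `k_opt`, `flag`.
#' @export
glance.omi_kselect <- function(x, ...) {
  tibble(k_elbow = x$k_elbow, k_gap = x$k_gap, k_opt = x$k_opt, flag = x$flag)
}

#' Tidy a cluster model
#'
#' @param x An `omi_clusters` from [cluster_units()].
#' @param ... Unused.
#' @return The assignments tibble (unit_id, cluster, semantic_label, class).
#' @export
tidy.omi_clusters <- function(x, ...) x$assignments
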