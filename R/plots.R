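#' Plot an event-aligned PSTH
#'
#' @param psth Tibble from [compute_psth()].
#' @param z Plot the z-scored rate instead of Hz.
#' @return A ggplot object.
#' @export
plot_psth <- function(psth, z = FALSE) {
  yvar <- if (z) "zrate" else "rate"
  ggplot2::ggplot(psth, ggplot2::aes(x = .data$time, y = .data[[yvar]])) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "time from event (s)",
                  y = if (z) "rate (z)" else "rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a population-response fit
#'
#' @param object An `omi_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the data and the fitted curve.
#' @export
autoplot.omi_fit <- function(object, ...) {
  df <- tibble(time = object$x, response = object$y, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$response), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "magenta") +
    ggplot2::labs(x = "time from omission onset (s)", y = "population rate (z)",
                  title = sprintf("%s fit, CV R² = %.2f", object$model, object$R2_cv)) +
    ggplot2::theme_minimal()
}

#' Plot the gap / dispersion diagnostics of cluster-number selection
#'
#' @param ks An `omi_kselect` from [choose_k()].
#' @return A ggplot object (gap curve with one-SE error bars).
#' @export
plot_gap <- function(ks) {
  ggplot2::ggplot(ks$table, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$se,
                                          ymax = .data$gap + .data$se)) +
    ggplot2::geom_vline(xintercept = ks$k_opt, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "number of clusters k", y = "Gap(k)") +
    ggplot2::theme_minimal()
}

#' Plot cluster mean response profiles
#'
#' @param model An `omi_clusters` from [cluster_units()].
#' @param time Bin-centre times (e.g. the `time` element of the response
#'   matrix).
#' @return A ggplot object, one facet per cluster.
#' @export
plot_cluster_profiles <- function(model, time) {
  df <- purrr::map_dfr(seq_len(model$k), function(cl) {
    tibble(cluster = cl,
           label = model$assignments$semantic_label[
             match(cl, model$assignments$cluster)],
           time = time, response = model$profiles[cl, ])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~ label) +
    ggplot2::labs(x = "time from omission onset (s)", y = "mean rate (z)") +
    ggplot2::theme_minimal()
}

#' Plot time-resolved decoding accuracy
#'
#' @param res Tibble from [decode_image_identity()].
#' @return A ggplot object with the chance level marked.
#' @export
plot_decoding <- function(res) {
  ggplot2::ggplot(res, ggplot2::aes(x = .data$time, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(res, "chance"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "time from omission onset (s)", y = "decoding accuracy") +
    ggplot2::theme_minimal()
}
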