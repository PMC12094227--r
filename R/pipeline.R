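#' Pipeline configuration
#'
#' Collects stage toggles and the parameters of a full synthetic
#' demonstration run. The configuration is an ordinary named list and is
#' fully serialisable; a run is a pure function of (config, seed).
#'
#' @param stages Character vector of stages to run, a subset of
#'   `c("synth", "qc", "psth", "fitting", "clustering", "coupling",
#'   "connectivity", "crossarea", "decoding")`. Later stages require the
#'   earlier ones they consume.
#' @param seed Global seed; per-stage seeds are derived by a counter scheme.
#' @param n_trials Trials in the generated schedule.
#' @param mix Archetype mix (default [default_unit_mix()]).
#' @param k_grid Candidate cluster numbers.
#' @param ... Additional overrides stored verbatim.
#' @return A named list of class `omi_config`.
#' @export
pipeline_config <- function(stages = c("synth", "qc", "psth", "fitting",
                                       "clustering", "coupling", "connectivity",
                                       "crossarea", "decoding"),
                            seed = 1, n_trials = 250,
                            mix = default_unit_mix(),
                            k_grid = 2:8, ...) {
  structure(
    c(list(stages = stages, seed = as.integer(seed), n_trials = n_trials,
           mix = mix, k_grid = k_grid), list(...)),
    class = "omi_config"
  )
}

stage_order <- c("synth", "qc", "psth", "fitting", "clustering", "coupling",
                 "connectivity", "crossarea", "decoding")

stage_requires <- list(
  qc = "synth", psth = "qc", fitting = "psth", clustering = "qc",
  coupling = c("qc", "clustering"), connectivity = c("qc", "clustering"),
  crossarea = "qc", decoding = "qc"
)

#' Run the end-to-end synthetic pipeline
#'
#' Executes the enabled stages in order (synthesis, quality control,
#' omission scoring, response fitting, clustering, coupling, connectivity,
#' cross-area interaction, decoding), returning all stage outputs plus a
#' machine-readable summary. Every output table carries the configuration
#' hash as attribute `config_hash`.
#'
#' @param config An `omi_config` from [pipeline_config()].
#' @return A list of stage outputs, `summary` (named list of headline
#'   numbers), `config`, `config_hash` and a `log` tibble of per-stage seeds.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "omi_config")) abort("`config` must come from pipeline_config().")
  stages <- config$stages
  for (st in stages) {
    missing <- setdiff(stage_requires[[st]], stages)
    if (length(missing)) {
      abort(paste0("stage `", st, "` requires disabled stage(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  hash <- rlang::hash(config)
  seeds <- stats::setNames(
    vapply(seq_along(stage_order), function(i) stage_seed(config$seed, i), 0L),
    stage_order
  )
  out <- list(config = config, config_hash = hash)
  summary <- list()
  stamp <- function(x) { attr(x, "config_hash") <- hash; x }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage `", name, "` failed: ", conditionMessage(e)))
    })
  }

  if ("synth" %in% stages) {
    out$schedule <- run_stage("synth", stamp(generate_schedule(
      n_trials = config$n_trials, seed = seeds[["synth"]])))
    out$units_raw <- run_stage("synth", stamp(generate_units(
      out$schedule, mix = config$mix, seed = seeds[["synth"]])))
    out$behavior <- run_stage("synth", stamp(generate_behavior(
      out$schedule, seed = seeds[["synth"]])))
    summary$n_slots <- nrow(out$schedule)
    summary$fraction_omitted <- mean(out$schedule$omitted[out$schedule$eligible])
  }
  if ("qc" %in% stages) {
    out$units <- run_stage("qc", stamp(classify_cell_type(filter_units(out$units_raw))))
    summary$n_units <- nrow(out$units)
  }
  if ("psth" %in% stages) {
    out$modulation <- run_stage("psth", stamp(omission_modulation(out$units, out$schedule)))
    summary$n_up <- sum(out$modulation$sign_class == "up")
    summary$n_down <- sum(out$modulation$sign_class == "down")
  }
  if ("fitting" %in% stages) {
    out$fits <- run_stage("fitting", {
      purrr::map_dfr(unique(out$units$area), function(ar) {
        sub <- out$units[out$units$area == ar, ]
        mod <- out$modulation[out$modulation$unit_id %in% sub$unit_id, ]
        if (sum(mod$sign_class == "up") < 2) return(NULL)
        resp <- population_response(sub, out$schedule, mod)
        lf <- fit_linear(resp)
        sf <- fit_sigmoid(resp)
        tibble(area = ar, linear_r2 = lf$R2_cv, sigmoid_r2 = sf$R2_cv,
               sigma = sf$sigma, A = sf$A, Delta = sf$Delta, c = sf$c)
      }) |> stamp()
    })
    summary$fit_areas <- out$fits$area
  }
  if ("clustering" %in% stages) {
    vis <- out$units[out$units$area == "VISp", ]
    out$respmat <- run_stage("clustering", build_response_matrix(vis, out$schedule))
    out$kselect <- run_stage("clustering", choose_k(
      out$respmat, k_grid = config$k_grid, seed = seeds[["clustering"]]))
    out$clusters <- run_stage("clustering", cluster_units(
      out$respmat, k = max(2L, out$kselect$k_opt), seed = seeds[["clustering"]]))
    out$composition <- stamp(cluster_composition(out$clusters, out$units, by = "layer"))
    summary$k_opt <- out$kselect$k_opt
  }
  if ("coupling" %in% stages) {
    vis <- out$units[out$units$area == "VISp", ]
    t_end <- max(out$schedule$onset_s)
    out$coupling <- run_stage("coupling", stamp(population_coupling(vis, c(0, t_end))))
    out$behavior_scores <- run_stage("coupling", stamp(behavior_scores(vis, out$behavior)))
    summary$median_coupling <- median(out$coupling$coupling_index, na.rm = TRUE)
  }
  if ("connectivity" %in% stages) {
    # Connectivity on a subsample keeps the demonstration run short.
    vis <- out$units[out$units$area == "VISp", ]
    vis <- vis[seq_len(min(12L, nrow(vis))), ]
    out$graph <- run_stage("connectivity", infer_connectivity(
      vis, seed = seeds[["connectivity"]], n_surrogates = 100))
    summary$n_edges <- nrow(out$graph$edges)
  }
  if ("crossarea" %in% stages) {
    vis <- out$units[out$units$area == "VISp", ]
    hpc <- out$units[out$units$area == "CA1", ]
    out$interaction <- run_stage("crossarea", stamp(ridge_interaction(
      vis, hpc, out$schedule, seed = seeds[["crossarea"]])))
    summary$interaction_difference <- out$interaction$difference
  }
  if ("decoding" %in% stages) {
    vis <- out$units[out$units$area == "VISp", ]
    out$decoding <- run_stage("decoding", stamp(decode_image_identity(
      vis, out$schedule, seed = seeds[["decoding"]])))
    summary$peak_decoding_accuracy <- max(out$decoding$accuracy)
  }
  out$summary <- summary
  out$log <- tibble(stage = stage_order, seed = unname(seeds),
                    enabled = stage_order %in% stages)
  out
}
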