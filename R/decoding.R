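#' Time-resolved decoding of image identity around omissions
#'
#' For each time bin around omission onset, trains a linear multiclass SVM
#' (one-vs-one linear maximum-margin classifiers with majority voting) on
#' min-max-normalised per-unit spike counts to predict the identity of the
#' image flanking the omission, and reports mean cross-validated accuracy.
#' Normalisation is fitted on the training folds only; out-of-range test
#' features are clipped to `[-0.5, 1.5]`.
#'
#' @param units Units tibble.
#' @param schedule Schedule from [generate_schedule()].
#' @param window Decoding window around omission onset (default one cycle
#'   either side).
#' @param bin_s Count bin width (default 0.05 s).
#' @param folds CV folds (default 10; reduced with a warning when the rarest
#'   class has fewer examples).
#' @param cost SVM regularisation constant (default 1).
#' @param permute_labels Shuffle labels before decoding (chance calibration).
#' @param seed Integer seed (fold assignment and permutation).
#' @return A tibble with `time` (bin centres), `accuracy`, `n_test`;
#'   attributes `chance` (1 / number of images) and `confusion` (list of
#'   per-bin confusion matrices summed over folds).
#' @export
decode_image_identity <- function(units, schedule, window = c(-0.75, 0.75),
                                  bin_s = 0.05, folds = 10, cost = 1,
                                  permute_labels = FALSE, seed = 1) {
  assert_units(units)
  om_slots <- which(schedule$omitted)
  if (length(om_slots) < folds) abort("need at least as many omissions as folds.")
  onsets <- schedule$onset_s[om_slots]
  labels <- factor(schedule$image_id[om_slots])
  if (nlevels(labels) < 2L) abort("need at least 2 image classes among omissions.")
  nb <- round(diff(window) / bin_s)
  starts <- window[1] + (seq_len(nb) - 1) * bin_s
  n_images <- schedule_param(schedule, "n_images", nlevels(labels))

  with_seed(seed, {
    if (permute_labels) labels <- sample(labels)
    min_class <- min(table(labels))
    if (min_class < folds) {
      warn("class with fewer examples than folds; reducing fold count.")
      folds <- max(2L, min_class)
    }
    # Stratified folds.
    fold_id <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }

    confusion <- vector("list", nb)
    out <- purrr::map_dfr(seq_len(nb), function(b) {
      X <- vapply(units$spikes, function(sp) count_in_windows(sp, onsets + starts[b], bin_s),
                  numeric(length(onsets)))
      correct <- 0L; total <- 0L
      cm <- matrix(0L, nlevels(labels), nlevels(labels),
                   dimnames = list(levels(labels), levels(labels)))
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        lo <- apply(X[tr, , drop = FALSE], 2, min)
        hi <- apply(X[tr, , drop = FALSE], 2, max)
        rngs <- pmax(hi - lo, 1e-12)
        norm <- function(M) {
          M <- sweep(sweep(M, 2, lo), 2, rngs, "/")
          pmin(pmax(M, -0.5), 1.5)
        }
        fit <- e1071::svm(norm(X[tr, , drop = FALSE]), labels[tr],
                          kernel = "linear", cost = cost, scale = FALSE)
        pred <- predict(fit, norm(X[!tr, , drop = FALSE]))
        correct <- correct + sum(pred == labels[!tr])
        total <- total + sum(!tr)
        cm <- cm + table(truth = labels[!tr], pred = pred)
      }
      confusion[[b]] <<- cm
      tibble(time = starts[b] + bin_s / 2,
             accuracy = correct / total, n_test = total)
    })
    attr(out, "chance") <- 1 / n_images
    attr(out, "confusion") <- confusion
    out
  })
}
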