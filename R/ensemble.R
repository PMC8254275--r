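# The anti-noise learner: bootstrap subsampling for noise smoothing.
#
# Hidden positives mislabeled as negatives are diluted by training S base
# learners on independent bootstrap resamples of the training set and
# averaging their predicted probabilities (soft voting): no single noisy
# example reaches every member, and the averaged decision boundary is less
# perturbed than any single fit.

#' Fit a subsampled (noise-smoothing) ensemble
#'
#' Draws `n_subsets` bootstrap subsets (sampling with replacement, each of
#' size `subset_size`) from the training pairs and fits one base learner per
#' subset. Prediction is the mean of member probabilities.
#'
#' @param data A pair tibble with a `label` column
#'   (`"positive"`/`"negative"`) and a `features` matrix column, as produced
#'   by [build_pair_features()] and [select_negatives()]; a plain matrix plus
#'   `labels` is also accepted.
#' @param learner Base learner kind: `"gbm"` (gradient-boosted trees, the
#'   default), `"knn"`, `"mlp"` or `"logistic"`.
#' @param n_subsets Number of bootstrap subsets S, default 10.
#' @param subset_size Size of each subset; default the training-set size
#'   (classic bootstrap).
#' @param params Named list of base-learner hyperparameters (e.g.
#'   `nrounds`, `eta`, `max_depth` for `"gbm"`; `k` for `"knn"`; `size`,
#'   `decay`, `maxit` for `"mlp"`).
#' @param labels Labels, when `data` is a plain feature matrix.
#' @param seed Integer seed; fixes the bootstrap draws and any learner
#'   randomness.
#' @return An object of class `anmda_model` with the fitted members and the
#'   subsampling metadata (including each member's training indices).
#' @examples
#' blobs <- make_blobs(n_per_class = 30, seed = 1)
#' fit <- anmda_fit(blobs, learner = "logistic", n_subsets = 5, seed = 1)
#' head(predict(fit, blobs))
#' @export
anmda_fit <- function(data, learner = "gbm", n_subsets = 10, subset_size = NULL,
                      params = list(), labels = NULL, seed = 1) {
  xy <- as_xy(data, labels)
  n <- nrow(xy$x)
  if (length(unique(xy$y)) < 2L) stop("training data contains a single class")
  if (is.null(subset_size)) subset_size <- n
  stopifnot(n_subsets >= 1, subset_size >= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  members <- vector("list", n_subsets)
  subsets <- vector("list", n_subsets)
  for (s in seq_len(n_subsets)) {
    repeat {  # redraw in the rare case a bootstrap subset is single-class
      idx <- sample.int(n, subset_size, replace = TRUE)
      if (length(unique(xy$y[idx])) == 2L) break
    }
    subsets[[s]] <- idx
    members[[s]] <- fit_base_learner(learner, xy$x[idx, , drop = FALSE],
                                     xy$y[idx], params)
  }
  structure(
    list(members = members, learner = learner, n_subsets = n_subsets,
         subset_size = subset_size, subsets = subsets, params = params,
         n_features = ncol(xy$x), seed = seed),
    class = "anmda_model"
  )
}

as_xy <- function(data, labels = NULL) {
  if (is.matrix(data)) {
    if (is.null(labels)) stop("labels required with a plain feature matrix")
    return(list(x = data, y = as_binary_label(labels)))
  }
  stopifnot(is.data.frame(data), "features" %in% names(data))
  lab <- if (!is.null(labels)) labels else data$label
  list(x = data$features, y = as_binary_label(lab))
}

#' Predict association probabilities with a fitted ensemble
#'
#' @param object An `anmda_model`.
#' @param newdata A pair tibble with a `features` matrix column, or a plain
#'   feature matrix.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`: the mean of member probabilities of
#'   the positive class.
#' @export
predict.anmda_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else {
    stopifnot(is.data.frame(newdata), "features" %in% names(newdata))
    newdata$features
  }
  preds <- vapply(object$members, predict_base_learner, numeric(nrow(x)),
                  x = x)
  if (nrow(x) == 1L) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' @export
print.anmda_model <- function(x, ...) {
  cat(sprintf(
    "<anmda_model> %d x %s base learner(s), subset size %d, %d features\n",
    x$n_subsets, x$learner, x$subset_size, x$n_features
  ))
  invisible(x)
}

#' @rdname anmda_fit
#' @param x An `anmda_model`.
#' @param ... Unused.
#' @return `tidy()`: one row per ensemble member (training indices summary);
#'   `glance()`: a one-row model summary.
#' @method tidy anmda_model
#' @export
tidy.anmda_model <- function(x, ...) {
  tibble::tibble(
    member = seq_len(x$n_subsets),
    learner = x$learner,
    n_train = lengths(x$subsets),
    n_unique_train = vapply(x$subsets, function(i) length(unique(i)), 0L)
  )
}

#' @rdname anmda_fit
#' @method glance anmda_model
#' @export
glance.anmda_model <- function(x, ...) {
  tibble::tibble(
    learner = x$learner, n_subsets = x$n_subsets,
    subset_size = x$subset_size, n_features = x$n_features, seed = x$seed
  )
}

#' Score and rank undetected miRNA-disease pairs
#'
#' Builds features for every undetected pair from the integrated similarity
#' matrices, scores them with a fitted ensemble, and ranks them descending
#' (ties broken by miRNA then disease identifier). Supports a global top-N
#' cut or a per-disease top-N cut.
#'
#' @param model A fitted `anmda_model`.
#' @param am The [association_matrix()] the model was trained from.
#' @param sm,sd Integrated miRNA and disease similarity matrices.
#' @param top_n Keep only the `top_n` highest-scoring pairs overall.
#' @param per_disease Keep the top `per_disease` pairs for each disease
#'   (applied instead of `top_n`).
#' @return A tibble `mirna`, `disease`, `score`, `rank` (rank is
#'   per-disease in per-disease mode).
#' @export
rank_novel_pairs <- function(model, am, sm, sd, top_n = NULL,
                             per_disease = NULL) {
  cand <- build_pair_features(undetected_pairs(am), sm, sd)
  if (nrow(cand) == 0L) {
    return(tibble::tibble(mirna = character(0), disease = character(0),
                          score = numeric(0), rank = integer(0)))
  }
  cand$score <- predict(model, cand)
  cand <- dplyr::arrange(cand, dplyr::desc(.data$score), .data$mirna,
                         .data$disease)
  if (!is.null(per_disease)) {
    cand <- cand |>
      dplyr::group_by(.data$disease) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::filter(.data$rank <= per_disease) |>
      dplyr::ungroup() |>
      dplyr::arrange(dplyr::desc(.data$score), .data$mirna, .data$disease)
  } else {
    cand$rank <- seq_len(nrow(cand))
    if (!is.null(top_n)) cand <- cand[seq_len(min(top_n, nrow(cand))), ]
  }
  cand[, c("mirna", "disease", "score", "rank")]
}
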