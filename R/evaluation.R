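# Repeated stratified k-fold cross-validation and the label-noise
# injection experiment.

make_folds <- function(y, n_folds, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

#' Repeated stratified cross-validation of a pair classifier
#'
#' Shuffles and splits the labeled pairs into stratified folds, trains on
#' k-1 folds and scores the held-out fold, pooling out-of-fold predictions
#' to compute one set of metrics per repeat. With `smooth = TRUE` the model
#' is the bootstrap-subsampled ensemble; with `smooth = FALSE` a single base
#' learner is fit on the untouched training folds.
#'
#' @param data A labeled pair tibble with `label` and `features` columns.
#' @param learner Base learner kind (see [anmda_fit()]).
#' @param n_folds Folds per repeat, default 5.
#' @param n_repeats CV repetitions, default 100.
#' @param smooth Use the subsampling ensemble (default `TRUE`).
#' @param n_subsets Ensemble size when `smooth = TRUE`, default 10.
#' @param params Base-learner hyperparameters.
#' @param stratified Stratify folds by class, default `TRUE`.
#' @param threshold Probability cut for precision/recall/F1, default 0.5.
#' @param seed Integer seed; repeat r uses the derived seed `seed + r`.
#' @return An `anmda_cv` object: per-repeat metric tibble plus protocol
#'   metadata. Use [tidy()] for per-repeat rows and [glance()] for the
#'   mean +/- sd summary.
#' @examples
#' blobs <- make_blobs(n_per_class = 30, seed = 1)
#' cv <- cross_validate(blobs, learner = "logistic", n_repeats = 2, seed = 1)
#' glance(cv)
#' @export
cross_validate <- function(data, learner = "gbm", n_folds = 5, n_repeats = 100,
                           smooth = TRUE, n_subsets = 10, params = list(),
                           stratified = TRUE, threshold = 0.5, seed = 1) {
  xy <- as_xy(data)
  n <- length(xy$y)
  if (n < n_folds) stop("fewer samples (", n, ") than folds (", n_folds, ")")
  stopifnot(n_folds >= 2)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  per_repeat <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    set.seed(seed + r)
    fold <- make_folds(xy$y, n_folds, stratified)
    scores <- numeric(n)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      if (length(unique(xy$y[tr])) < 2L) {
        stop("training folds contain a single class")
      }
      if (smooth) {
        fit <- anmda_fit(xy$x[tr, , drop = FALSE], labels = xy$y[tr],
                         learner = learner, n_subsets = n_subsets,
                         params = params, seed = seed + r * n_folds + f)
        scores[!tr] <- predict(fit, xy$x[!tr, , drop = FALSE])
      } else {
        fit <- fit_base_learner(learner, xy$x[tr, , drop = FALSE], xy$y[tr],
                                params)
        scores[!tr] <- predict_base_learner(fit, xy$x[!tr, , drop = FALSE])
      }
    }
    dplyr::bind_cols(tibble::tibble(repeat_id = r),
                     classification_metrics(scores, xy$y, threshold))
  })
  structure(
    list(metrics = per_repeat,
         protocol = list(learner = learner, n_folds = n_folds,
                         n_repeats = n_repeats, smooth = smooth,
                         n_subsets = n_subsets, stratified = stratified,
                         threshold = threshold, seed = seed, n = n)),
    class = "anmda_cv"
  )
}

#' @export
print.anmda_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<anmda_cv> %s, %d-fold x %d repeats%s\n  AUROC %.4f +/- %.4f, AUPR %.4f +/- %.4f, F1 %.4f\n",
    x$protocol$learner, x$protocol$n_folds, x$protocol$n_repeats,
    if (x$protocol$smooth) sprintf(", ensemble S=%d", x$protocol$n_subsets)
    else ", single model",
    g$auroc, g$auroc_sd, g$aupr, g$aupr_sd, g$f1
  ))
  invisible(x)
}

#' @rdname cross_validate
#' @param x An `anmda_cv` object.
#' @param ... Unused.
#' @method tidy anmda_cv
#' @export
tidy.anmda_cv <- function(x, ...) x$metrics

#' @rdname cross_validate
#' @method glance anmda_cv
#' @export
glance.anmda_cv <- function(x, ...) {
  m <- x$metrics[c("auroc", "aupr", "precision", "recall", "f1")]
  means <- colMeans(m)
  sds <- vapply(m, stats::sd, 0)
  sds[is.na(sds)] <- 0  # single repeat
  out <- tibble::as_tibble(as.list(means))
  names(sds) <- paste0(names(sds), "_sd")
  dplyr::bind_cols(out, tibble::as_tibble(as.list(sds)),
                   tibble::tibble(n_repeats = x$protocol$n_repeats))
}

#' Label-noise injection experiment
#'
#' Reproduces the flipped-label design: a balanced noise-free arm of
#' `n_per_class` positives and negatives, and a noisy arm in which `n_flip`
#' positives have their labels flipped to negative; to keep the arms
#' balanced at the same size, `n_flip` original negatives are removed and
#' `n_flip` reserve positives (positives beyond the first `n_per_class`)
#' are added. Each requested learner kind is cross-validated on both arms.
#'
#' @param data A labeled tibble with `label` and `features` columns holding
#'   at least `n_per_class + n_flip` positives and `n_per_class` negatives.
#' @param n_flip Number of positive labels flipped to negative, default 7.
#' @param learners Character vector of base-learner kinds to evaluate.
#' @param n_per_class Arm size per class; default the number of negatives.
#' @param smooth Logical vector: evaluate without (`FALSE`) and/or with
#'   (`TRUE`) subsampling noise smoothing.
#' @inheritParams cross_validate
#' @return A tibble with one row per (learner, arm, smooth) combination and
#'   the five aggregate metrics.
#' @export
label_noise_experiment <- function(data, n_flip = 7, learners = "logistic",
                                   n_per_class = NULL, smooth = FALSE,
                                   n_folds = 5, n_repeats = 1, n_subsets = 10,
                                   params = list(), seed = 1) {
  xy <- as_xy(data)
  pos <- which(xy$y == 1L)
  neg <- which(xy$y == 0L)
  if (is.null(n_per_class)) n_per_class <- length(neg)
  if (length(neg) < n_per_class) stop("not enough negatives for the arms")
  if (length(pos) < n_per_class + n_flip) {
    stop("need ", n_per_class + n_flip, " positives (",
         n_per_class, " + ", n_flip, " reserve), have ", length(pos))
  }
  base_pos <- pos[seq_len(n_per_class)]
  reserve <- pos[n_per_class + seq_len(n_flip)]
  base_neg <- neg[seq_len(n_per_class)]

  clean_idx <- c(base_pos, base_neg)
  clean_y <- xy$y[clean_idx]

  flipped <- base_pos[seq_len(n_flip)]          # positives relabeled negative
  kept_neg <- base_neg[seq_len(n_per_class - n_flip)]  # n_flip negatives out
  noisy_idx <- c(setdiff(base_pos, flipped), reserve, flipped, kept_neg)
  noisy_y <- c(rep(1L, n_per_class), rep(0L, n_per_class))

  arms <- list(
    `noise-free` = list(x = xy$x[clean_idx, , drop = FALSE], y = clean_y),
    noisy = list(x = xy$x[noisy_idx, , drop = FALSE], y = noisy_y)
  )
  grid <- expand.grid(learner = learners, arm = names(arms), smooth = smooth,
                      stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(learner, arm, smooth) {
    a <- arms[[arm]]
    d <- tibble::tibble(label = a$y)
    d$features <- a$x
    cv <- cross_validate(d, learner = learner, n_folds = n_folds,
                         n_repeats = n_repeats, smooth = smooth,
                         n_subsets = n_subsets, params = params, seed = seed)
    dplyr::bind_cols(
      tibble::tibble(learner = learner, arm = arm, smooth = smooth),
      glance(cv)[c("auroc", "aupr", "precision", "recall", "f1")]
    )
  })
}

#' Zero out test-fold associations before computing the interaction kernel
#'
#' In `fold_safe` cross-validation the Gaussian interaction-profile kernel is
#' recomputed per fold from an adjacency in which the held-out positive
#' pairs are set to 0, so test associations cannot leak into training
#' features. `full` mode (the conventional protocol) computes the kernel
#' once from the complete matrix.
#'
#' @param am An [association_matrix()] object.
#' @param pairs Tibble with `mirna_idx`, `disease_idx` of pairs to hide.
#' @return A new `assoc_matrix` with those entries zeroed.
#' @export
mask_associations <- function(am, pairs) {
  stopifnot(inherits(am, "assoc_matrix"))
  adj <- am$adjacency
  adj[cbind(pairs$mirna_idx, pairs$disease_idx)] <- 0L
  if (sum(adj) == 0L) stop("masking removed every association")
  structure(list(mirna_ids = am$mirna_ids, disease_ids = am$disease_ids,
                 adjacency = adj), class = "assoc_matrix")
}

#' Association-level cross-validation of the full pipeline
#'
#' Cross-validates at the level of the association matrix rather than a
#' fixed feature table: positives are the verified associations, negatives
#' come from [select_negatives()], and, in `gip_mode = "fold_safe"`, the
#' similarity matrices and pair features are rebuilt inside every fold with
#' the held-out positive pairs masked out of the adjacency. The conventional
#' `"full"` mode computes similarities once from the complete matrix, which
#' reuses information across folds; a message notes this.
#'
#' @param am An [association_matrix()] object.
#' @param tree Optional [tree_table()] for semantic similarity.
#' @param k Number of k-means clusters for negative selection.
#' @param gip_mode `"full"` or `"fold_safe"`.
#' @param delta,gamma_prime Similarity parameters.
#' @inheritParams cross_validate
#' @return An `anmda_cv` object.
#' @export
anmda_cross_validate <- function(am, tree = NULL, learner = "gbm",
                                 n_folds = 5, n_repeats = 1, smooth = TRUE,
                                 n_subsets = 10, k = 23, params = list(),
                                 gip_mode = c("full", "fold_safe"),
                                 delta = 0.5, gamma_prime = 1,
                                 threshold = 0.5, seed = 1) {
  gip_mode <- match.arg(gip_mode)
  if (gip_mode == "full") {
    message("gip_mode = 'full': interaction kernels are computed once from ",
            "the complete association matrix and shared across folds")
  }
  sims <- build_similarities(am, tree, delta, gamma_prime)
  pos <- positive_pairs(am)
  undet <- build_pair_features(undetected_pairs(am), sims$sm, sims$sd)
  neg <- select_negatives(undet, n_negatives = nrow(pos), k = k, seed = seed)
  pairs <- dplyr::bind_rows(pos, neg[names(pos)])
  y <- as_binary_label(pairs$label)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  per_repeat <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    set.seed(seed + r)
    fold <- make_folds(y, n_folds, stratified = TRUE)
    scores <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      if (gip_mode == "fold_safe") {
        test_pos <- pairs[!tr & y == 1L, ]
        am_f <- mask_associations(am, test_pos)
        sims_f <- build_similarities(am_f, tree, delta, gamma_prime)
      } else {
        sims_f <- sims
      }
      feats <- build_pair_features(pairs[c("mirna_idx", "disease_idx")],
                                   sims_f$sm, sims_f$sd)$features
      if (smooth) {
        fit <- anmda_fit(feats[tr, , drop = FALSE], labels = y[tr],
                         learner = learner, n_subsets = n_subsets,
                         params = params, seed = seed + r * n_folds + f)
        scores[!tr] <- predict(fit, feats[!tr, , drop = FALSE])
      } else {
        fit <- fit_base_learner(learner, feats[tr, , drop = FALSE], y[tr],
                                params)
        scores[!tr] <- predict_base_learner(fit, feats[!tr, , drop = FALSE])
      }
    }
    dplyr::bind_cols(tibble::tibble(repeat_id = r),
                     classification_metrics(scores, y, threshold))
  })
  structure(
    list(metrics = per_repeat,
         protocol = list(learner = learner, n_folds = n_folds,
                         n_repeats = n_repeats, smooth = smooth,
                         n_subsets = n_subsets, stratified = TRUE,
                         threshold = threshold, seed = seed,
                         n = length(y), gip_mode = gip_mode, k = k)),
    class = "anmda_cv"
  )
}
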