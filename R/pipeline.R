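# End-to-end pipeline: similarities -> negative sampling -> ensemble ->
# cross-validation and candidate ranking, with every intermediate persisted.

#' Run the full anti-noise association-prediction pipeline
#'
#' Executes the stages in order -- similarity construction, feature
#' building, k-means negative selection, ensemble training, optional
#' cross-validation, and novel-pair ranking -- and persists every
#' intermediate artifact (similarity TSVs, negative-set TSV, metric report
#' JSON, ranking TSV, fitted model RDS, and a manifest of all parameters and
#' seeds) under `out_dir`.
#'
#' @param am An [association_matrix()], or path to an association TSV.
#' @param tree Optional [tree_table()] or path to a tree-number TSV.
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @param learner,n_subsets,params Ensemble configuration ([anmda_fit()]).
#' @param k Number of negative-sampling clusters, default 23.
#' @param n_negatives Negatives to draw; default = number of positives.
#' @param delta,gamma_prime Similarity parameters.
#' @param cv_repeats Cross-validation repeats (0 skips CV).
#' @param n_folds CV folds, default 5.
#' @param top_n Size of the emitted global ranking, default 200.
#' @param seed Master seed; stage seeds derive from it.
#' @return A list with `model`, `cv` (or `NULL`), `ranking`, `negatives`,
#'   `similarities` and `manifest`, invisibly writable to `out_dir`.
#' @export
run_pipeline <- function(am, tree = NULL, out_dir = NULL, learner = "gbm",
                         n_subsets = 10, params = list(), k = 23,
                         n_negatives = NULL, delta = 0.5, gamma_prime = 1,
                         cv_repeats = 0, n_folds = 5, top_n = 200, seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.character(am)) am <- stage("read-associations", read_associations(am))
  if (is.character(tree)) tree <- stage("read-tree", read_tree_numbers(tree))

  sims <- stage("build-similarity",
                build_similarities(am, tree, delta, gamma_prime))
  pos <- positive_pairs(am)
  pos_feat <- stage("build-features", build_pair_features(pos, sims$sm, sims$sd))
  undet <- stage("build-features",
                 build_pair_features(undetected_pairs(am), sims$sm, sims$sd))
  if (is.null(n_negatives)) n_negatives <- nrow(pos)
  neg <- stage("sample-negatives",
               select_negatives(undet, n_negatives, k = k, seed = seed))
  train <- bind_pairs(pos_feat, neg[names(pos_feat)])
  cv <- NULL
  if (cv_repeats > 0) {
    cv <- stage("cv", cross_validate(train, learner = learner,
                                     n_folds = n_folds,
                                     n_repeats = cv_repeats,
                                     n_subsets = n_subsets, params = params,
                                     seed = seed + 1))
  }
  model <- stage("train", anmda_fit(train, learner = learner,
                                    n_subsets = n_subsets, params = params,
                                    seed = seed + 2))
  ranking <- stage("rank", rank_novel_pairs(model, am, sims$sm, sims$sd,
                                            top_n = top_n))
  manifest <- list(
    n_mirna = length(am$mirna_ids), n_disease = length(am$disease_ids),
    n_positive = nrow(pos), n_negative = n_negatives, k = k,
    learner = learner, n_subsets = n_subsets, params = params,
    delta = delta, gamma_prime = gamma_prime, n_folds = n_folds,
    cv_repeats = cv_repeats, top_n = top_n, seed = seed,
    package_version = as.character(utils::packageVersion("anmda"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_similarity_matrix(sims$sm, file.path(out_dir, "mirna_similarity.tsv"))
    write_similarity_matrix(sims$sd, file.path(out_dir, "disease_similarity.tsv"))
    utils::write.table(neg[setdiff(names(neg), "features")],
                       file.path(out_dir, "negatives.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_ranking(ranking, file.path(out_dir, "ranking.tsv"))
    saveRDS(model, file.path(out_dir, "model.rds"))
    report <- manifest
    if (!is.null(cv)) report$cv <- as.list(glance(cv))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(model = model, cv = cv, ranking = ranking, negatives = neg,
                 similarities = sims, manifest = manifest))
}
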