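test_that("every learner kind separates linearly separable blobs", {
  blobs <- make_blobs(n_per_class = 25, n_features = 4, separation = 12,
                      seed = 1)
  for (kind in c("gbm", "knn", "mlp", "logistic")) {
    fit <- anmda_fit(blobs, learner = kind, n_subsets = 3, seed = 2)
    expect_equal(auroc(predict(fit, blobs), blobs$label), 1.0,
                 info = kind)
  }
})

test_that("bootstrap subsets are reproducible and sized correctly", {
  blobs <- make_blobs(n_per_class = 20, seed = 3)
  a <- anmda_fit(blobs, learner = "logistic", n_subsets = 5, seed = 7)
  b <- anmda_fit(blobs, learner = "logistic", n_subsets = 5, seed = 7)
  expect_identical(a$subsets, b$subsets)
  expect_true(all(lengths(a$subsets) == 40))
  c <- anmda_fit(blobs, learner = "logistic", n_subsets = 5, seed = 8)
  expect_false(identical(a$subsets, c$subsets))

  td <- tidy(a)
  expect_equal(nrow(td), 5)
  expect_true(all(td$n_unique_train < td$n_train))  # bootstrap has repeats
  expect_equal(glance(a)$n_features, 10)
})

test_that("ensemble prediction is the mean of member probabilities", {
  blobs <- make_blobs(n_per_class = 15, seed = 4)
  fit <- anmda_fit(blobs, learner = "logistic", n_subsets = 4, seed = 1)
  member_scores <- vapply(
    fit$members,
    function(m) anmda:::predict_base_learner(m, blobs$features),
    numeric(nrow(blobs))
  )
  expect_equal(predict(fit, blobs), rowMeans(member_scores))
  # and therefore bounded by the member extremes
  expect_true(all(predict(fit, blobs) <= apply(member_scores, 1, max) + 1e-12))
  expect_true(all(predict(fit, blobs) >= apply(member_scores, 1, min) - 1e-12))
})

test_that("prediction is permutation-equivariant over pairs", {
  blobs <- make_blobs(n_per_class = 15, seed = 5)
  fit <- anmda_fit(blobs, learner = "gbm", n_subsets = 3, seed = 1,
                   params = list(nrounds = 20))
  p <- predict(fit, blobs$features)
  perm <- sample(nrow(blobs))
  expect_equal(predict(fit, blobs$features[perm, ]), p[perm])
})

test_that("degenerate and invalid inputs are rejected", {
  blobs <- make_blobs(n_per_class = 10, seed = 6)
  one_class <- blobs[blobs$label == "positive", ]
  expect_error(anmda_fit(one_class, learner = "logistic", n_subsets = 1),
               "single class")
  fit <- anmda_fit(blobs, learner = "logistic", n_subsets = 2, seed = 1)
  expect_error(predict(fit, blobs$features[, 1:3]), "dimension mismatch")
  expect_error(anmda_fit(blobs, learner = "logistic", n_subsets = 0), "n_subsets")
})

test_that("subsampling reduces across-seed variance for a kNN base learner", {
  res <- purrr::map_dfr(1:30, function(s) {
    b <- make_blobs(n_per_class = 207, seed = 700 + s)
    r <- label_noise_experiment(b, n_flip = 7, learners = "knn",
                                n_per_class = 200, smooth = c(FALSE, TRUE),
                                seed = s)
    r$seed <- s
    r[r$arm == "noisy", ]
  })
  sd_single <- sd(res$auroc[!res$smooth])
  sd_ens <- sd(res$auroc[res$smooth])
  expect_lte(sd_ens, sd_single)
})

test_that("novel-pair ranking orders, truncates and breaks ties lexically", {
  am <- association_matrix(data.frame(m = c("m1", "m2", "m2"),
                                      d = c("d1", "d1", "d2")))
  sims <- build_similarities(am)
  train <- bind_pairs(
    build_pair_features(positive_pairs(am), sims$sm, sims$sd),
    {
      u <- build_pair_features(undetected_pairs(am), sims$sm, sims$sd)
      u$label <- "negative"
      u
    }
  )
  fit <- anmda_fit(train, learner = "logistic", n_subsets = 2, seed = 1)
  rk <- rank_novel_pairs(fit, am, sims$sm, sims$sd)
  expect_equal(nrow(rk), 1)  # only (m1, d2) is undetected
  expect_identical(rk$rank, 1L)

  # per-disease truncation on a wider fixture
  am2 <- random_assoc(6, 5, density = 0.25, seed = 9)
  sims2 <- build_similarities(am2)
  pos2 <- build_pair_features(positive_pairs(am2), sims2$sm, sims2$sd)
  und2 <- build_pair_features(undetected_pairs(am2), sims2$sm, sims2$sd)
  neg2 <- select_negatives(und2, nrow(pos2), k = 2, seed = 1)
  fit2 <- anmda_fit(bind_pairs(pos2, neg2[names(pos2)]), learner = "logistic",
                    n_subsets = 2, seed = 1)
  top2 <- rank_novel_pairs(fit2, am2, sims2$sm, sims2$sd, per_disease = 2)
  per <- table(top2$disease)
  expect_true(all(per <= 2))
  full <- rank_novel_pairs(fit2, am2, sims2$sm, sims2$sd)
  expect_equal(nrow(full), nrow(und2))
  expect_true(all(diff(full$score) <= 1e-12))  # descending
})

test_that("held-out positives rank above true negatives on planted data", {
  scores_h <- c(); scores_n <- c()
  for (s in 1:5) {
    tree <- make_tree_table(25, seed = 800 + s)
    sim <- make_associations(n_m = 30, n_d = 25, density = 0.08,
                             hidden_fraction = 0.25, tree = tree,
                             seed = 800 + s)
    res <- run_pipeline(sim$am, tree, learner = "gbm", k = 10, seed = s,
                        top_n = NULL)
    hid <- paste(sim$hidden$mirna, sim$hidden$disease)
    is_hidden <- paste(res$ranking$mirna, res$ranking$disease) %in% hid
    scores_h <- c(scores_h, res$ranking$score[is_hidden])
    scores_n <- c(scores_n, res$ranking$score[!is_hidden])
  }
  wt <- stats::wilcox.test(scores_h, scores_n, alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
})
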