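test_that("metrics match hand-computed confusion-table values", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1)
  y <- c(1, 1, 0, 1, 0, 1, 0, 0)
  # positives outrank negatives in 13 of 16 comparisons
  expect_equal(auroc(s, y), 13 / 16)
  # average precision over positives at ranks 1, 2, 4, 6
  expect_equal(aupr(s, y), (1 + 1 + 3 / 4 + 4 / 6) / 4)
  m <- classification_metrics(s, y, threshold = 0.5)
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$recall, 3 / 4)
  expect_equal(m$f1, 3 / 4)
})

test_that("rank-form AUROC equals the pairwise Mann-Whitney count", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding makes ties
    expect_lt(abs(auroc(s, y) - oracle_auroc(s, y)), 1e-12)
  }
})

test_that("curve tibbles agree with their scalar areas at the endpoints", {
  set.seed(12)
  y <- rbinom(40, 1, 0.5); s <- runif(40) + y * 0.5
  rc <- roc_curve(s, y)
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
  pc <- pr_curve(s, y)
  expect_equal(pc$recall[nrow(pc)], 1)
  expect_true(all(pc$precision >= 0 & pc$precision <= 1))
})

test_that("fold assignment partitions samples with stratification", {
  set.seed(13)
  y <- rep(c(1L, 0L), c(30, 50))
  fold <- anmda:::make_folds(y, 5)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 80)
  expect_equal(as.integer(table(fold[y == 1])), rep(6L, 5))
  expect_equal(as.integer(table(fold[y == 0])), rep(10L, 5))
})

test_that("separable data scores a perfect, zero-variance CV", {
  blobs <- make_blobs(n_per_class = 30, n_features = 4, separation = 14,
                      seed = 14)
  cv <- cross_validate(blobs, learner = "logistic", n_repeats = 3,
                       smooth = FALSE, seed = 1)
  g <- glance(cv)
  expect_equal(g$auroc, 1.0)
  expect_equal(g$auroc_sd, 0)
  expect_equal(nrow(tidy(cv)), 3)
})

test_that("uninformative features give chance-level AUROC", {
  # independent zero-separation datasets: per-dataset null AUROC has
  # sd ~ sqrt((n+1)/(12 n1 n0)) ~ 0.041, so the mean of 8 sits within
  # 3 * 0.041/sqrt(8) ~ 0.044 of 1/2
  m <- vapply(1:8, function(s) {
    blobs <- make_blobs(n_per_class = 100, separation = 0, seed = 50 + s)
    glance(cross_validate(blobs, learner = "logistic", n_repeats = 1,
                          smooth = FALSE, seed = s))$auroc
  }, 0)
  expect_lt(abs(mean(m) - 0.5), 0.05)
})

test_that("reported spread is the sample standard deviation over repeats", {
  blobs <- make_blobs(n_per_class = 40, separation = 2, seed = 16)
  cv <- cross_validate(blobs, learner = "logistic", n_repeats = 4,
                       smooth = FALSE, seed = 3)
  expect_equal(glance(cv)$auroc_sd, sd(tidy(cv)$auroc))
})

test_that("flipping zero labels leaves both experiment arms identical", {
  blobs <- make_blobs(n_per_class = 60, seed = 17)
  res <- label_noise_experiment(blobs, n_flip = 0, learners = "logistic",
                                n_per_class = 50, seed = 4)
  clean <- res[res$arm == "noise-free", -(1:3)]
  noisy <- res[res$arm == "noisy", -(1:3)]
  expect_equal(as.numeric(clean), as.numeric(noisy))
})

test_that("the noise experiment validates its reserve requirements", {
  blobs <- make_blobs(n_per_class = 50, seed = 18)
  expect_error(
    label_noise_experiment(blobs, n_flip = 7, n_per_class = 50, seed = 1),
    "reserve"
  )
})

test_that("masking removes exactly the requested associations", {
  am <- random_assoc(6, 5, density = 0.4, seed = 19)
  pos <- positive_pairs(am)
  masked <- mask_associations(am, pos[1:2, ])
  expect_equal(sum(am$adjacency) - sum(masked$adjacency), 2)
  expect_equal(masked$adjacency[cbind(pos$mirna_idx[1:2],
                                      pos$disease_idx[1:2])], c(0L, 0L))
  expect_error(mask_associations(am, pos), "every association")
})

test_that("fold-safe kernels differ across folds while full mode reuses one", {
  tree <- make_tree_table(15, seed = 20)
  sim <- make_associations(n_m = 20, n_d = 15, density = 0.12, tree = tree,
                           seed = 20)
  # full mode announces the cross-fold information reuse
  expect_message(
    cv_full <- anmda_cross_validate(sim$am, tree, learner = "logistic",
                                    smooth = FALSE, k = 5, n_repeats = 1,
                                    gip_mode = "full", seed = 1),
    "complete association matrix"
  )
  cv_safe <- anmda_cross_validate(sim$am, tree, learner = "logistic",
                                  smooth = FALSE, k = 5, n_repeats = 1,
                                  gip_mode = "fold_safe", seed = 1)
  expect_s3_class(cv_full, "anmda_cv")
  # masking a test fold's positives changes the kernel input by construction
  pos <- positive_pairs(sim$am)
  masked <- mask_associations(sim$am, pos[1:3, ])
  expect_false(identical(gip_similarity(sim$am, "mirna"),
                         gip_similarity(masked, "mirna")))
})

test_that("computing kernels inside folds does not inflate the AUROC", {
  aucs <- purrr::map_dfr(1:8, function(s) {
    tree <- make_tree_table(15, seed = 900 + s)
    sim <- make_associations(n_m = 20, n_d = 15, density = 0.12, tree = tree,
                             seed = 900 + s)
    full <- suppressMessages(
      anmda_cross_validate(sim$am, tree, learner = "logistic", smooth = FALSE,
                           k = 5, n_repeats = 1, gip_mode = "full", seed = s)
    )
    safe <- anmda_cross_validate(sim$am, tree, learner = "logistic",
                                 smooth = FALSE, k = 5, n_repeats = 1,
                                 gip_mode = "fold_safe", seed = s)
    tibble::tibble(full = glance(full)$auroc, safe = glance(safe)$auroc)
  })
  expect_gte(mean(aucs$full), mean(aucs$safe))
})
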