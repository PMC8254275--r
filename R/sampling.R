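# Negative-sample selection from the undetected-pair pool.
#
# Undetected pairs are unlabeled, not confirmed negatives: a fraction of them
# are future true positives (label noise). Clustering the pool and drawing
# equal quotas per cluster avoids concentrating the draw in the
# positive-looking region of feature space.

# k-means++ seeding: spread initial centers by D^2-weighted sampling
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- colSums((t(x) - centers[1L, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
    }
  }
  centers
}

#' Cluster-balanced negative sampling from undetected pairs
#'
#' Runs seeded k-means (k-means++ initialization, up to 300 iterations) on
#' the feature vectors of all undetected pairs, then draws an equal quota
#' from each cluster uniformly without replacement: `floor(n/k)` each, with
#' the remainder distributed one per cluster in descending cluster-size
#' order. A cluster smaller than its quota contributes everything it has and
#' the deficit is redistributed proportionally to the remaining clusters'
#' unused sizes.
#'
#' @param features A pair tibble with a `features` matrix column, containing
#'   only undetected pairs (see [build_pair_features()]).
#' @param n_negatives Number of negatives to draw; conventionally the number
#'   of positives, to give a balanced training set.
#' @param k Number of k-means clusters, default 23.
#' @param seed Integer seed making clustering and the draw reproducible.
#' @return A tibble of `n_negatives` rows: the selected pairs with `label`
#'   set to `"negative"` and a `cluster` column.
#' @export
select_negatives <- function(features, n_negatives, k = 23, seed = 1) {
  stopifnot(is.data.frame(features), "features" %in% names(features))
  n <- nrow(features)
  if (n == 0L) stop("no undetected pairs to sample from")
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds the number of undetected pairs (", n, ")")
  if (n_negatives > n) {
    stop("cannot draw ", n_negatives, " negatives from ", n, " undetected pairs")
  }
  x <- features$features
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  if (k == 1L) {
    cl <- rep(1L, n)
  } else {
    km <- stats::kmeans(x, centers = kmeanspp_centers(x, k),
                        iter.max = 300L, algorithm = "Lloyd")
    cl <- km$cluster
  }
  sizes <- tabulate(cl, nbins = k)
  quota <- rep(n_negatives %/% k, k)
  extra <- n_negatives %% k
  if (extra > 0L) {
    by_size <- order(sizes, decreasing = TRUE)
    quota[by_size[seq_len(extra)]] <- quota[by_size[seq_len(extra)]] + 1L
  }
  # clusters smaller than their quota give all they have; redistribute the
  # deficit proportionally to the remaining spare capacity
  repeat {
    short <- sizes < quota
    deficit <- sum((quota - sizes)[short])
    quota[short] <- sizes[short]
    if (deficit == 0L) break
    spare <- pmax(sizes - quota, 0L)
    if (sum(spare) < deficit) stop("internal quota accounting error")
    add <- pmin(floor(deficit * spare / sum(spare)), spare)
    left <- deficit - sum(add)
    while (left > 0L) {
      j <- which.max(spare - add)
      add[j] <- add[j] + 1L
      left <- left - 1L
    }
    quota <- quota + add
  }
  picked <- unlist(lapply(seq_len(k), function(j) {
    members <- which(cl == j)
    if (quota[j] == 0L) return(integer(0))
    if (quota[j] == length(members)) members
    else members[sample.int(length(members), quota[j])]
  }))
  out <- features[sort(picked), setdiff(names(features), "features"),
                  drop = FALSE]
  out$features <- features$features[sort(picked), , drop = FALSE]
  out$label <- "negative"
  out$cluster <- cl[sort(picked)]
  out
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Estimate the hidden-positive (noise) rate among random negatives
#'
#' When negatives are drawn uniformly from undetected pairs, some are future
#' true positives. Given the number of verified pairs in an older snapshot
#' and in a newer one over the same universe, the expected fraction of noisy
#' negatives is `(n_known_new - n_pos_old) / (n_m * n_d - n_pos_old)`.
#'
#' @param n_pos_old Verified pairs in the snapshot used for training.
#' @param n_known_new Verified pairs in the newer snapshot.
#' @param n_m,n_d Numbers of miRNAs and diseases spanning the pair universe.
#' @return The estimated noise fraction.
#' @examples
#' estimate_noise_rate(5430, 12034, 495, 383) # ~0.0359
#' @export
estimate_noise_rate <- function(n_pos_old, n_known_new, n_m, n_d) {
  stopifnot(n_known_new >= n_pos_old, n_pos_old >= 0)
  universe <- as.numeric(n_m) * as.numeric(n_d)
  if (universe <= n_pos_old) {
    stop("pair universe must exceed the number of known positives")
  }
  (n_known_new - n_pos_old) / (universe - n_pos_old)
}
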