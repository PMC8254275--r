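# Synthetic fixtures: a MeSH-like tree-number table, association matrices
# with planted latent structure and hidden positives, and two-blob
# classification data for the label-noise experiments. Everything is
# generated in code so the full pipeline runs with no downloads.

#' Generate a random MeSH-like tree-number table
#'
#' Grows a rooted forest of dot-separated hierarchy codes: each new disease
#' either starts a new root or extends a randomly chosen existing code by
#' one segment (up to `max_depth` segments, at most `branching` children per
#' code). A fraction of diseases receives a second code from elsewhere in
#' the forest, exercising multi-code DAG unions. Every code's whole prefix
#' chain belongs to some disease, so the resulting DAGs are prefix-closed.
#'
#' @param n_diseases Number of diseases, named `D001`, `D002`, ...
#' @param max_depth Maximum code depth (number of segments), default 4.
#' @param branching Maximum children per code, default 3.
#' @param second_code_prob Probability a disease gets a second code,
#'   default 0.2.
#' @param seed Integer seed.
#' @return A [tree_table()].
#' @export
make_tree_table <- function(n_diseases, max_depth = 4, branching = 3,
                            second_code_prob = 0.2, seed = 1) {
  stopifnot(n_diseases >= 1, max_depth >= 1, branching >= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  ids <- sprintf("D%03d", seq_len(n_diseases))
  codes <- character(n_diseases)
  n_children <- integer(0)  # children count per existing code
  n_roots <- 0L
  for (i in seq_len(n_diseases)) {
    depth_of <- function(code) length(strsplit(code, ".", fixed = TRUE)[[1]])
    open <- if (i > 1L) {
      which(vapply(codes[1:(i - 1L)], depth_of, 0L) < max_depth &
              n_children[1:(i - 1L)] < branching)
    } else integer(0)
    if (length(open) == 0L || stats::runif(1) < 0.15) {
      n_roots <- n_roots + 1L
      codes[i] <- sprintf("C%02d", n_roots)
    } else {
      parent <- open[sample.int(length(open), 1L)]
      n_children[parent] <- n_children[parent] + 1L
      codes[i] <- sprintf("%s.%03d", codes[parent], n_children[parent] * 100L)
    }
    n_children <- c(n_children, 0L)
  }
  tab <- as.list(codes)
  names(tab) <- ids
  if (n_diseases > 2L) {
    extra <- which(stats::runif(n_diseases) < second_code_prob)
    for (i in extra) {
      # a donor descending from one of i's codes would make i its own
      # descendant (a hierarchy cycle); exclude such donors
      own <- unlist(tab[[i]])
      ok <- vapply(seq_len(n_diseases), function(j) {
        j != i && !any(codes[j] == own |
                         startsWith(codes[j], paste0(own, ".")))
      }, TRUE)
      if (!any(ok)) next
      donor <- which(ok)[sample.int(sum(ok), 1L)]
      # borrow the donor's code extended by a fresh segment
      tab[[i]] <- unique(c(tab[[i]], paste0(codes[donor], ".901")))
    }
  }
  tree_table(tab)
}

#' Generate an association matrix with planted latent structure
#'
#' Draws latent factors `u_i, v_j ~ N(0, I_r)` for miRNAs and diseases and
#' samples associations with probability
#' `plogis(scale * u_i . v_j + bias)`, the bias solved by bisection so the
#' expected density hits the target within 10 percent. The low-rank logistic
#' model makes similar miRNAs associate with similar diseases, so the
#' similarity-based features carry real signal. When a tree-number table is
#' supplied, disease latent vectors are built from independent Gaussian
#' increments shared along each code's ancestor chain, so diseases that are
#' close in the hierarchy get correlated association patterns -- the
#' property that makes semantic similarity informative on real data. A
#' fraction of true positives is then demoted to undetected status and
#' returned separately: these hidden positives emulate associations that a
#' later database snapshot would verify, i.e. the label noise the pipeline
#' is designed to resist.
#'
#' @param n_m,n_d Numbers of miRNAs (`M001`, ...) and diseases (`D001`, ...,
#'   matching [make_tree_table()] names).
#' @param r Latent dimension, default 4.
#' @param density Target association density in (0, 1), default 0.05.
#' @param hidden_fraction Fraction of true positives demoted to undetected,
#'   default 0.
#' @param latent_scale Multiplier on the latent inner product, default 4;
#'   larger values give cleaner block structure.
#' @param tree Optional [tree_table()] over `n_d` diseases (names must match
#'   `D001`, ...); hierarchy-correlated disease latents are used when given.
#' @param seed Integer seed.
#' @return A list: `am` (the visible [association_matrix()]), `hidden`
#'   (tibble of demoted pairs with indices), and `truth` (the full 0/1
#'   matrix including hidden positives).
#' @export
make_associations <- function(n_m = 50, n_d = 40, r = 4, density = 0.05,
                              hidden_fraction = 0, latent_scale = 4,
                              tree = NULL, seed = 1) {
  stopifnot(density > 0, density < 1,
            hidden_fraction >= 0, hidden_fraction < 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  u <- matrix(stats::rnorm(n_m * r), n_m, r)
  v <- if (is.null(tree)) {
    matrix(stats::rnorm(n_d * r), n_d, r)
  } else {
    stopifnot(length(tree) == n_d)
    tree_latents(tree, r)
  }
  eta <- latent_scale * tcrossprod(u, v)
  lo <- -50; hi <- 50
  for (it in 1:100) {  # bisection on the bias to hit the target density
    mid <- (lo + hi) / 2
    if (mean(stats::plogis(eta + mid)) > density) hi <- mid else lo <- mid
  }
  bias <- (lo + hi) / 2
  p <- stats::plogis(eta + bias)
  truth <- matrix(stats::rbinom(length(p), 1L, p), n_m, n_d,
                  dimnames = list(sprintf("M%03d", seq_len(n_m)),
                                  sprintf("D%03d", seq_len(n_d))))
  pos <- which(truth == 1L)
  if (length(pos) == 0L) stop("degenerate configuration produced no positives")
  n_hide <- floor(hidden_fraction * length(pos))
  hide <- if (n_hide > 0L) sample(pos, n_hide) else integer(0)
  visible <- truth
  visible[hide] <- 0L
  if (sum(visible) == 0L) stop("hiding removed every visible positive")
  am <- structure(
    list(mirna_ids = rownames(truth), disease_ids = colnames(truth),
         adjacency = visible),
    class = "assoc_matrix"
  )
  hi_idx <- arrayInd(hide, dim(truth))
  hidden <- tibble::tibble(
    mirna = rownames(truth)[hi_idx[, 1]], disease = colnames(truth)[hi_idx[, 2]],
    mirna_idx = hi_idx[, 1], disease_idx = hi_idx[, 2],
    label = rep("hidden_positive", nrow(hi_idx))
  )
  list(am = am, hidden = hidden, truth = truth)
}

# disease latents correlated along the hierarchy: each ancestor code carries
# an iid N(0, I_r) increment; a disease's vector is the normalized sum over
# its code's prefix chain (averaged over codes), so shared ancestors imply
# similar vectors while marginals stay standard normal
tree_latents <- function(tree, r) {
  ids <- names(tree)
  chains <- lapply(ids, function(id) lapply(tree[[id]], code_prefixes))
  all_codes <- unique(unlist(chains))
  inc <- matrix(stats::rnorm(length(all_codes) * r), length(all_codes), r,
                dimnames = list(all_codes, NULL))
  t(vapply(chains, function(ch) {
    vs <- lapply(ch, function(chain)
      colSums(inc[chain, , drop = FALSE]) / sqrt(length(chain)))
    Reduce(`+`, vs) / length(vs)
  }, numeric(r)))
}

#' Generate two-Gaussian-blob classification data
#'
#' Two spherical Gaussian classes whose means sit `separation` apart in
#' Euclidean distance. The default separation of 3.5 puts the Bayes AUROC
#' at `pnorm(3.5 / sqrt(2)) ~ 0.993`, so a logistic regression on the
#' default 200-per-class sample scores a noise-free cross-validated AUROC
#' in the high 0.97-1.0 range -- the regime of the flipped-label experiment.
#'
#' @param n_per_class Samples per class, default 200.
#' @param n_features Feature dimension, default 10.
#' @param separation Distance between class means, default 3.5.
#' @param seed Integer seed.
#' @return A tibble with `label` (`"positive"`/`"negative"`) and a
#'   `features` matrix column.
#' @export
make_blobs <- function(n_per_class = 200, n_features = 10, separation = 3.5,
                       seed = 1) {
  stopifnot(n_per_class >= 1, n_features >= 1, separation >= 0)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  shift <- separation / sqrt(n_features)
  x <- rbind(
    matrix(stats::rnorm(n_per_class * n_features, mean = shift),
           n_per_class, n_features),
    matrix(stats::rnorm(n_per_class * n_features, mean = 0),
           n_per_class, n_features)
  )
  colnames(x) <- paste0("f", seq_len(n_features))
  out <- tibble::tibble(
    label = rep(c("positive", "negative"), each = n_per_class)
  )
  out$features <- x
  out
}
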