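# Independent brute-force oracles used to cross-check the implementation.

# model-1 semantic contribution by exhaustive path enumeration: D(v) is the
# maximum over all directed v -> target paths of delta^(path length)
oracle_semantic_model1 <- function(dag, delta) {
  kids <- list()
  for (v in dag$vertices) kids[[v]] <- character(0)
  if (nrow(dag$edges)) {
    for (r in seq_len(nrow(dag$edges))) {
      kids[[dag$edges[r, 1]]] <- c(kids[[dag$edges[r, 1]]], dag$edges[r, 2])
    }
  }
  paths_to_target <- function(v, seen = character(0)) {
    if (v == dag$target) return(list(v))
    out <- list()
    for (ch in setdiff(kids[[v]], seen)) {
      for (p in paths_to_target(ch, c(seen, v))) out <- c(out, list(c(v, p)))
    }
    out
  }
  vals <- vapply(dag$vertices, function(v) {
    ps <- paths_to_target(v)
    if (length(ps) == 0L) stop("no path from ", v)
    max(vapply(ps, function(p) delta^(length(p) - 1L), 0))
  }, 0)
  list(values = vals, total = sum(vals))
}

# naive double-loop Gaussian interaction-profile kernel
oracle_gip <- function(adj, axis, gamma_prime = 1) {
  prof <- if (axis == "mirna") adj else t(adj)
  n <- nrow(prof)
  gamma <- gamma_prime / mean(rowSums(prof^2))
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- exp(-gamma * sum((prof[i, ] - prof[j, ])^2))
    }
  }
  out
}

# pairwise-comparison AUROC (Mann-Whitney with half credit for ties)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# small random association matrix (guaranteed at least one 1)
random_assoc <- function(n_m, n_d, density = 0.3, seed = 1) {
  set.seed(seed)
  adj <- matrix(rbinom(n_m * n_d, 1L, density), n_m, n_d)
  if (sum(adj) == 0L) adj[1L, 1L] <- 1L
  pairs <- which(adj == 1L, arr.ind = TRUE)
  association_matrix(data.frame(
    mirna = sprintf("m%02d", pairs[, 1]), disease = sprintf("d%02d", pairs[, 2])
  ))
}

# toy hand-worked fixtures: chain A -> B -> C plus an extra leaf E so the
# model-2 census is 4/2/1 with N = 4
toy_chain_tree <- function() {
  tree_table(list(A = "C01", B = "C01.100", C = "C01.100.200", E = "C01.900"))
}
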