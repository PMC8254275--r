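# Interaction-profile kernels, miRNA functional similarity, and the
# integrated similarity matrices that supply pair features.

#' Gaussian interaction-profile kernel similarity
#'
#' Each entity's binary interaction profile is its row (miRNA axis) or column
#' (disease axis) of the adjacency. Similarity between two entities is
#' `exp(-gamma * ||IP_i - IP_j||^2)` with bandwidth
#' `gamma = gamma_prime / mean(||IP||^2)`, i.e. normalized by the average
#' number of associations per entity.
#'
#' @param am An [association_matrix()] object.
#' @param axis `"mirna"` or `"disease"`.
#' @param gamma_prime Raw bandwidth, default 1.
#' @return A labeled symmetric similarity matrix with unit diagonal.
#' @export
gip_similarity <- function(am, axis = c("mirna", "disease"), gamma_prime = 1) {
  axis <- match.arg(axis)
  stopifnot(inherits(am, "assoc_matrix"), gamma_prime > 0)
  prof <- if (axis == "mirna") am$adjacency else t(am$adjacency)
  sq <- rowSums(prof^2)
  mean_sq <- mean(sq)
  if (mean_sq == 0) {
    stop("all interaction profiles are zero; kernel bandwidth undefined")
  }
  gamma <- gamma_prime / mean_sq
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(prof)
  d2[d2 < 0] <- 0
  gs <- exp(-gamma * d2)
  diag(gs) <- 1
  gs <- (gs + t(gs)) / 2
  dimnames(gs) <- list(rownames(prof), rownames(prof))
  gs
}

#' miRNA functional similarity from disease semantic similarity
#'
#' Best-match averaging: for miRNAs `m_i`, `m_j` with associated disease sets
#' `MD_i`, `MD_j`, each disease in one set contributes its maximum semantic
#' similarity to any disease in the other set; the contributions are summed
#' both ways and divided by `n_i + n_j`. miRNAs with no associations, or
#' whose associated diseases all lack semantic rows, have no functional
#' similarity: their rows are `NA` (absence, not zero), so integration can
#' fall back to the kernel.
#'
#' @param am An [association_matrix()] object.
#' @param ss Disease semantic similarity matrix (possibly covering only a
#'   subset of the diseases).
#' @return A labeled symmetric matrix over all miRNAs, `NA` where undefined.
#' @export
mirna_functional_similarity <- function(am, ss) {
  stopifnot(inherits(am, "assoc_matrix"))
  covered <- intersect(am$disease_ids, rownames(ss))
  md <- lapply(seq_along(am$mirna_ids), function(i) {
    d <- am$disease_ids[am$adjacency[i, ] == 1L]
    intersect(d, covered)
  })
  n <- length(am$mirna_ids)
  fsm <- matrix(NA_real_, n, n, dimnames = list(am$mirna_ids, am$mirna_ids))
  defined <- which(lengths(md) > 0L)
  for (a in defined) {
    block_a <- ss[md[[a]], , drop = FALSE]
    for (b in defined[defined >= a]) {
      sub <- block_a[, md[[b]], drop = FALSE]
      # best match of each disease into the opposite set, both directions
      s <- (sum(apply(sub, 2L, max)) + sum(apply(sub, 1L, max))) /
        (length(md[[a]]) + length(md[[b]]))
      fsm[a, b] <- s
      fsm[b, a] <- s
    }
  }
  fsm
}

#' Integrate semantic/functional similarity with the interaction kernel
#'
#' Entrywise average of the two similarity sources where the semantic (or
#' functional) value exists; plain kernel similarity where it does not.
#'
#' @param partial Semantic (disease) or functional (miRNA) similarity matrix;
#'   may cover a subset of labels and may contain `NA` for undefined entries.
#' @param gs Kernel similarity matrix covering every entity.
#' @return A labeled symmetric matrix over `rownames(gs)`.
#' @export
integrate_similarity <- function(partial, gs) {
  labs <- rownames(gs)
  full <- matrix(NA_real_, length(labs), length(labs),
                 dimnames = list(labs, labs))
  common <- intersect(labs, rownames(partial))
  if (length(common)) full[common, common] <- partial[common, common]
  out <- ifelse(is.na(full), gs, (gs + full) / 2)
  dimnames(out) <- dimnames(gs)
  out
}

#' @rdname integrate_similarity
#' @export
integrate_disease_similarity <- integrate_similarity

#' @rdname integrate_similarity
#' @export
integrate_mirna_similarity <- integrate_similarity

#' Build feature vectors for (miRNA, disease) pairs
#'
#' The feature vector of a pair is the concatenation of the miRNA's full row
#' of the integrated miRNA similarity matrix and the disease's full row of
#' the integrated disease similarity matrix, giving `n_mirna + n_disease`
#' dimensions.
#'
#' @param pairs A tibble with `mirna_idx`, `disease_idx` and `label` columns
#'   (see [undetected_pairs()]).
#' @param sm Integrated miRNA similarity matrix (`n_mirna` square).
#' @param sd Integrated disease similarity matrix (`n_disease` square).
#' @return The `pairs` tibble with an added `features` matrix column.
#' @export
build_pair_features <- function(pairs, sm, sd) {
  stopifnot(is.data.frame(pairs),
            all(c("mirna_idx", "disease_idx") %in% names(pairs)))
  if (any(pairs$mirna_idx < 1L | pairs$mirna_idx > nrow(sm)) ||
      any(pairs$disease_idx < 1L | pairs$disease_idx > nrow(sd))) {
    stop("pair index out of similarity-matrix bounds")
  }
  feat <- cbind(sm[pairs$mirna_idx, , drop = FALSE],
                sd[pairs$disease_idx, , drop = FALSE])
  colnames(feat) <- c(paste0("m_", seq_len(ncol(sm))),
                      paste0("d_", seq_len(ncol(sd))))
  rownames(feat) <- NULL
  out <- tibble::as_tibble(pairs)
  out$features <- feat
  out
}

#' Full feature construction from raw inputs
#'
#' Convenience wrapper running the whole similarity stage: disease semantic
#' similarity from the tree table, interaction-profile kernels on both axes,
#' miRNA functional similarity, and the two integrated matrices.
#'
#' @inheritParams gip_similarity
#' @inheritParams combined_semantic_similarity
#' @param tree A [tree_table()] (or `NULL` to use kernels only).
#' @return A list with `ss`, `fsm`, `gs_m`, `gs_d`, `sm`, `sd`.
#' @export
build_similarities <- function(am, tree = NULL, delta = 0.5, gamma_prime = 1,
                               quiet = TRUE) {
  gs_m <- gip_similarity(am, "mirna", gamma_prime)
  gs_d <- gip_similarity(am, "disease", gamma_prime)
  if (is.null(tree)) {
    ss <- matrix(numeric(0), 0, 0)
    fsm <- matrix(NA_real_, nrow(gs_m), nrow(gs_m), dimnames = dimnames(gs_m))
  } else {
    ss <- combined_semantic_similarity(tree, delta = delta, quiet = quiet)
    fsm <- mirna_functional_similarity(am, ss)
  }
  list(ss = ss, fsm = fsm, gs_m = gs_m, gs_d = gs_d,
       sm = integrate_similarity(fsm, gs_m),
       sd = integrate_similarity(ss, gs_d))
}
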