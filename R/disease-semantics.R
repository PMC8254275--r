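# Disease semantic similarity over MeSH-style hierarchy codes.
#
# Each disease carries one or more dot-separated tree numbers; whole-segment
# prefixes of a code identify ancestor headings. A disease's DAG contains the
# disease plus every table disease sitting on a prefix of one of its codes,
# with edges from each vertex's nearest present ancestor (missing intermediate
# headings are skipped).

code_prefixes <- function(code) {
  seg <- strsplit(code, ".", fixed = TRUE)[[1]]
  vapply(seq_along(seg), function(k) paste(seg[1:k], collapse = "."), "")
}

#' Build ancestor DAGs for every disease in a tree-number table
#'
#' @param tree A [tree_table()] (or named list of tree-number vectors).
#' @param quiet Suppress the message listing codes whose ancestors are absent
#'   from the table.
#' @return A named list of DAGs, one per disease. Each DAG is a list with
#'   `target` (the disease id), `vertices` (character vector including the
#'   target) and `edges` (two-column character matrix, parent then child).
#' @export
build_dags <- function(tree, quiet = FALSE) {
  if (!inherits(tree, "tree_table")) tree <- tree_table(tree)
  ids <- names(tree)
  code_owner <- list()  # normalized code -> disease id
  for (id in ids) {
    for (code in tree[[id]]) code_owner[[code]] <- id
  }
  missing_anc <- character(0)
  dags <- lapply(ids, function(id) {
    vertices <- id
    edges <- matrix(character(0), 0, 2)
    for (code in tree[[id]]) {
      chain <- code_prefixes(code)
      owners <- unlist(lapply(chain, function(p) {
        o <- code_owner[[p]]
        if (is.null(o)) NA_character_ else o
      }))
      # the full code belongs to this disease even if another disease shares
      # it, so each prefix chain terminates at the DAG target
      owners[length(owners)] <- id
      if (anyNA(owners)) {
        missing_anc <<- c(missing_anc, chain[is.na(owners)])
      }
      present <- owners[!is.na(owners)]
      # the deepest prefix is the target's own code; walk parent -> child
      # linking each vertex to its nearest present ancestor
      present <- unique(present)
      vertices <- union(vertices, present)
      if (length(present) > 1L) {
        edges <- rbind(edges, cbind(present[-length(present)], present[-1]))
      }
    }
    edges <- unique(edges)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    list(target = id, vertices = vertices, edges = edges)
  })
  if (length(missing_anc) && !quiet) {
    message("skipping ", length(unique(missing_anc)),
            " ancestor code(s) absent from the tree table")
  }
  setNames(dags, ids)
}

dag_children <- function(dag) {
  kids <- setNames(vector("list", length(dag$vertices)), dag$vertices)
  if (nrow(dag$edges)) {
    for (r in seq_len(nrow(dag$edges))) {
      p <- dag$edges[r, 1]
      kids[[p]] <- c(kids[[p]], dag$edges[r, 2])
    }
  }
  kids
}

#' Semantic contribution values within a disease DAG
#'
#' Two models of the contribution `D(d)` of each DAG vertex `d` to the target
#' disease. Model 1 is the layer-decay recursion: the target contributes 1 and
#' every other vertex contributes `delta` times its best (maximum) child
#' contribution, so a vertex `k` layers above the target contributes
#' `delta^k`. Model 2 is information-content-like and target-independent:
#' `D(d) = -log(N_d / N)` where `N_d` counts how many diseases' DAGs contain
#' `d` and `N` is the number of diseases in the table. The semantic value
#' `V` of the target is the sum of contributions over the DAG.
#'
#' @param dag One DAG from [build_dags()].
#' @param delta Semantic contribution (decay) factor in (0, 1); default 0.5.
#' @return A list with `values` (named contributions) and `total` (`V`),
#'   class `semantic_values`.
#' @export
semantic_values_model1 <- function(dag, delta = 0.5) {
  stopifnot(delta > 0, delta < 1)
  kids <- dag_children(dag)
  memo <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  rec <- function(v) {
    if (v == dag$target) return(1)
    if (!is.null(memo[[v]])) return(memo[[v]])
    if (!is.null(visiting[[v]])) stop("cycle detected in DAG at '", v, "'")
    visiting[[v]] <- TRUE
    ch <- kids[[v]]
    if (length(ch) == 0L) {
      stop("vertex '", v, "' has no path to target '", dag$target, "'")
    }
    val <- delta * max(vapply(ch, rec, 0))
    rm(list = v, envir = visiting)
    memo[[v]] <- val
    val
  }
  vals <- vapply(dag$vertices, rec, 0)
  structure(list(values = vals, total = sum(vals)), class = "semantic_values")
}

#' @rdname semantic_values_model1
#' @param census Named integer vector: for each disease, the number of DAGs
#'   that contain it (see [dag_census()]).
#' @param n_total Total number of diseases `N` in the table.
#' @export
semantic_values_model2 <- function(dag, census, n_total) {
  nd <- census[dag$vertices]
  if (anyNA(nd) || any(nd < 1)) {
    stop("every DAG vertex must appear in at least its own DAG")
  }
  if (any(nd > n_total)) stop("census exceeds the number of diseases")
  vals <- setNames(-log(nd / n_total), dag$vertices)
  structure(list(values = vals, total = sum(vals)), class = "semantic_values")
}

#' Count how many disease DAGs contain each disease
#'
#' @param dags The list returned by [build_dags()].
#' @return Named integer vector over all diseases.
#' @export
dag_census <- function(dags) {
  tab <- table(unlist(lapply(dags, `[[`, "vertices")))
  setNames(as.integer(tab), names(tab))
}

#' Semantic similarity between two diseases
#'
#' The shared-information score: the contributions that the common ancestors
#' make to each disease, summed and normalized by the two semantic values.
#' Returns 0 when the DAGs share no vertex or when both totals are 0
#' (degenerate model-2 census).
#'
#' @param values_i,values_j `semantic_values` for the two diseases, computed
#'   under the same model and parameters.
#' @return A similarity score in `[0, 1]` (model 1; model 2 scores are
#'   clamped the same way by construction of the census).
#' @export
semantic_similarity <- function(values_i, values_j) {
  shared <- intersect(names(values_i$values), names(values_j$values))
  denom <- values_i$total + values_j$total
  if (length(shared) == 0L || denom == 0) return(0)
  sum(values_i$values[shared] + values_j$values[shared]) / denom
}

#' Combined disease semantic similarity matrix
#'
#' Computes both semantic-value models for every disease in the tree table
#' and returns the elementwise average of the two similarity matrices. Only
#' diseases present in the table get rows; downstream integration falls back
#' to the interaction-profile kernel for the rest.
#'
#' @param tree A [tree_table()].
#' @param delta Model-1 decay factor, default 0.5.
#' @param quiet Passed to [build_dags()].
#' @return A labeled symmetric similarity matrix over the table's diseases.
#' @export
combined_semantic_similarity <- function(tree, delta = 0.5, quiet = FALSE) {
  if (!inherits(tree, "tree_table")) tree <- tree_table(tree)
  dags <- build_dags(tree, quiet = quiet)
  ids <- names(dags)
  census <- dag_census(dags)
  v1 <- lapply(dags, semantic_values_model1, delta = delta)
  v2 <- lapply(dags, semantic_values_model2, census = census,
               n_total = length(ids))
  n <- length(ids)
  ss <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- (semantic_similarity(v1[[i]], v1[[j]]) +
              semantic_similarity(v2[[i]], v2[[j]])) / 2
      ss[i, j] <- s
      ss[j, i] <- s
    }
  }
  ss
}
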