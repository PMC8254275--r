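test_that("DAGs follow the whole-segment prefix rule", {
  dags <- build_dags(tree_table(list(A = "C01", B = "C01.100",
                                     C = "C01.100.200")))
  expect_setequal(dags$C$vertices, c("A", "B", "C"))
  expect_setequal(apply(dags$C$edges, 1, paste, collapse = ">"),
                  c("A>B", "B>C"))
  expect_identical(dags$A$vertices, "A")
  expect_equal(nrow(dags$A$edges), 0)

  # multi-code disease: union of the per-code ancestor sets
  dags2 <- build_dags(tree_table(list(A = "C01", Y = "C02",
                                      X = c("C01.100", "C02.200"))),
                      quiet = TRUE)
  expect_setequal(dags2$X$vertices, c("A", "Y", "X"))
})

test_that("missing intermediate ancestors are skipped, not fatal", {
  # C01.100 has no owner; C links straight to A
  expect_message(
    dags <- build_dags(tree_table(list(A = "C01", C = "C01.100.200"))),
    "skipping"
  )
  expect_setequal(dags$C$vertices, c("A", "C"))
  expect_equal(unname(dags$C$edges[1, ]), c("A", "C"))
})

test_that("model-1 contributions follow the layer-decay recursion", {
  dags <- build_dags(toy_chain_tree())
  v <- semantic_values_model1(dags$C, 0.5)
  expect_equal(v$values[c("C", "B", "A")], c(C = 1, B = 0.5, A = 0.25))
  expect_equal(v$total, 1.75)
  expect_equal(semantic_values_model1(dags$A, 0.5)$total, 1)

  # diamond: two paths of equal decay, max rule
  diamond <- list(target = "D", vertices = c("A", "B", "C", "D"),
                  edges = rbind(c("A", "B"), c("B", "D"),
                                c("A", "C"), c("C", "D")))
  vd <- semantic_values_model1(diamond, 0.5)
  expect_equal(vd$values[c("B", "C", "A")], c(B = 0.5, C = 0.5, A = 0.25))
  expect_equal(vd$total, 2.25)
})

test_that("model-1 recursion matches path-enumeration oracle on random DAGs", {
  n_checked <- 0
  for (s in 1:12) {
    tree <- make_tree_table(n_diseases = 10, max_depth = 4, branching = 2,
                            seed = s)
    dags <- build_dags(tree, quiet = TRUE)
    for (dag in dags) {
      if (length(dag$vertices) > 12) next
      got <- semantic_values_model1(dag, 0.5)
      want <- oracle_semantic_model1(dag, 0.5)
      expect_lt(max(abs(got$values[dag$vertices] -
                          want$values[dag$vertices])), 1e-12)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 50)
})

test_that("model-2 contributions are -log census frequencies", {
  dags <- build_dags(toy_chain_tree())
  cen <- dag_census(dags)
  expect_equal(cen[c("A", "B", "C", "E")], c(A = 4L, B = 2L, C = 1L, E = 1L))
  v <- semantic_values_model2(dags$C, cen, 4)
  expect_equal(unname(v$values[c("A", "B", "C")]), c(0, log(2), log(4)))
  # disease present in every DAG contributes 0; singleton table total is 0
  single <- build_dags(tree_table(list(Z = "C09")))
  expect_equal(semantic_values_model2(single$Z, dag_census(single), 1)$total, 0)
  expect_error(semantic_values_model2(dags$C, c(A = 4L, B = 2L), 4), "own DAG")
})

test_that("semantic similarity reproduces the hand-worked toy values", {
  dags <- build_dags(toy_chain_tree())
  v1 <- lapply(dags, semantic_values_model1, delta = 0.5)
  expect_equal(semantic_similarity(v1$B, v1$C), 2.25 / 3.25)
  expect_equal(semantic_similarity(v1$C, v1$C), 1)  # self-similarity

  cen <- dag_census(dags)
  v2 <- lapply(dags, semantic_values_model2, census = cen, n_total = 4)
  expect_equal(semantic_similarity(v2$B, v2$C), 0.5)

  ss <- combined_semantic_similarity(toy_chain_tree())
  expect_equal(ss["B", "C"], (2.25 / 3.25 + 0.5) / 2)
  expect_equal(ss["B", "C"], 0.5962, tolerance = 1e-4)
})

test_that("combined similarity matrices are symmetric, unit-diagonal, in [0,1]", {
  for (s in 1:5) {
    tree <- make_tree_table(n_diseases = 12, seed = s)
    dags <- build_dags(tree, quiet = TRUE)
    cen <- dag_census(dags)
    ss <- combined_semantic_similarity(tree, quiet = TRUE)
    expect_lt(max(abs(ss - t(ss))), 1e-12)
    expect_true(all(ss >= 0 & ss <= 1 + 1e-12))
    # model-2 self-similarity needs a positive information total: a disease
    # whose every ancestor is shared by every DAG carries no information and
    # halves its own diagonal (no correction is applied)
    v2_pos <- vapply(names(dags), function(id)
      semantic_values_model2(dags[[id]], cen, length(dags))$total > 0, TRUE)
    expect_equal(unname(diag(ss)[v2_pos]), rep(1, sum(v2_pos)))
    expect_equal(unname(diag(ss)[!v2_pos]),
                 rep(0.5, sum(!v2_pos)))
  }
  # disjoint roots share nothing
  ss2 <- combined_semantic_similarity(
    tree_table(list(A = "C01", B = "C02")), quiet = TRUE
  )
  expect_equal(ss2["A", "B"], 0)
})

test_that("an added shared ancestor never decreases model-1 similarity", {
  # X and Y share the unowned prefix C09; giving it an owner R adds a
  # common vertex to both DAGs
  without <- combined_tree <- list(X = "C09.100", Y = "C09.200")
  with_anc <- c(without, list(R = "C09"))
  ss_without <- {
    dags <- build_dags(tree_table(without), quiet = TRUE)
    v <- lapply(dags, semantic_values_model1, delta = 0.5)
    semantic_similarity(v$X, v$Y)
  }
  ss_with <- {
    dags <- build_dags(tree_table(with_anc), quiet = TRUE)
    v <- lapply(dags, semantic_values_model1, delta = 0.5)
    semantic_similarity(v$X, v$Y)
  }
  expect_gte(ss_with, ss_without)
  expect_equal(ss_without, 0)
})
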