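# Ranking and threshold metrics. AUROC uses the rank (Mann-Whitney) form,
# which handles tied scores by midranks; AUPR is average precision.

#' Classification metrics for scored pairs
#'
#' `auroc()` is the probability that a random positive outscores a random
#' negative (ties count half), computed from midranks. `aupr()` is average
#' precision: precision at each positive, averaged over positives, with tied
#' scores processed as one block. `classification_metrics()` returns all five
#' headline metrics at a score threshold.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Binary labels: 1/0, `TRUE`/`FALSE`, or
#'   `"positive"`/`"negative"`.
#' @return `auroc()`/`aupr()`: a single number in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("auroc needs both classes")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname auroc
#' @export
aupr <- function(scores, labels) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1L)
  if (n1 == 0L || all(y == 1L)) stop("aupr needs both classes")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  # process tied-score blocks together
  block <- cumsum(!duplicated(s))
  tp_in_block <- tapply(y, block, sum)
  n_in_block <- tapply(y, block, length)
  tp <- cumsum(tp_in_block)
  n_seen <- cumsum(n_in_block)
  prec <- tp / n_seen
  sum(prec * tp_in_block) / n1
}

#' @rdname auroc
#' @param threshold Score cut for calling a pair positive; default 0.5.
#' @return `classification_metrics()`: a tibble with `auroc`, `aupr`,
#'   `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_label(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(
    auroc = auroc(scores, y), aupr = aupr(scores, y),
    precision = precision, recall = recall, f1 = f1
  )
}

as_binary_label <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    lab <- as.character(labels)
    bad <- setdiff(unique(lab), c("positive", "negative"))
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
    as.integer(lab == "positive")
  } else {
    y <- as.integer(labels)
    if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
    y
  }
}

#' ROC and precision-recall curves as tibbles
#'
#' @inheritParams auroc
#' @return A tibble of curve points (`fpr`/`tpr` or `recall`/`precision`),
#'   one row per distinct score threshold.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_label(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  dplyr::bind_rows(
    tibble::tibble(threshold = Inf, fpr = 0, tpr = 0),
    tibble::tibble(threshold = s[keep], fpr = fp / sum(1 - y),
                   tpr = tp / sum(y))
  )
}

#' @rdname roc_curve
#' @export
pr_curve <- function(scores, labels) {
  y <- as_binary_label(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[keep]
  n <- seq_along(y)[keep]
  tibble::tibble(
    threshold = s[keep],
    recall = tp / sum(y),
    precision = tp / n
  )
}
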