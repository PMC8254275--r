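# Base learners behind the subsampling ensemble. Each kind exposes the same
# two-function surface: fit on (x, y) and return P(positive) on new x.
# The gradient-boosted tree learner is the default; kNN, MLP and logistic
# regression exist for the noise-robustness comparisons.

learner_kinds <- c("gbm", "knn", "mlp", "logistic")

fit_base_learner <- function(kind, x, y, params = list()) {
  kind <- match.arg(kind, learner_kinds)
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  fitted <- switch(kind,
    gbm = {
      p <- utils::modifyList(
        list(nrounds = 100L, max_depth = 6L, eta = 0.1, nthread = 1L), params
      )
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = p$max_depth,
                      eta = p$eta, nthread = p$nthread),
        data = dtrain, nrounds = p$nrounds, verbose = 0
      )
    },
    knn = {
      p <- utils::modifyList(list(k = 5L), params)
      list(x = x, y = y, k = p$k)  # lazy learner: keep the training set
    },
    mlp = {
      p <- utils::modifyList(
        list(size = 8L, decay = 0.01, maxit = 200L), params
      )
      nnet::nnet(x, y, size = p$size, decay = p$decay, maxit = p$maxit,
                 entropy = TRUE, trace = FALSE)
    },
    logistic = {
      df <- data.frame(y = y, x)
      g <- suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial())
      )
      # keep only the coefficients: aliased terms count 0, and scoring by
      # hand below stays finite when separation inflates the fit
      co <- stats::coef(g)
      co[is.na(co)] <- 0
      co
    }
  )
  structure(list(kind = kind, fit = fitted, n_features = ncol(x)),
            class = "base_learner")
}

predict_base_learner <- function(object, x) {
  stopifnot(inherits(object, "base_learner"), is.matrix(x))
  if (ncol(x) != object$n_features) {
    stop("feature dimension mismatch: model has ", object$n_features,
         ", input has ", ncol(x))
  }
  switch(object$kind,
    gbm = as.numeric(predict(object$fit, xgboost::xgb.DMatrix(x))),
    knn = {
      pred <- class::knn(object$fit$x, x, factor(object$fit$y),
                         k = object$fit$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    mlp = as.numeric(predict(object$fit, x)),
    logistic = {
      eta <- drop(cbind(1, x) %*% object$fit)
      eta[is.nan(eta)] <- 0  # Inf - Inf under complete separation
      stats::plogis(eta)
    }
  )
}
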