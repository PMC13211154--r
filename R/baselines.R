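BASELINE_NAMES <- c("LDA", "LR", "SVM", "AdaBoost", "GBoost")

#' Reference-classifier specifications
#'
#' The five classical baselines with their selected hyperparameters:
#' LDA (SVD solver); ridge (l2) multinomial logistic regression with
#' C = 97.2 (the printed l1 ratio of 0.07 is inert under a pure l2
#' penalty and is kept for record only); polynomial-kernel SVM of degree 4
#' with "auto" kernel coefficient (1/p); AdaBoost (SAMME, 227 stumps,
#' learning rate 0.78); gradient boosting (438 trees, learning rate 0.52,
#' squared-error split criterion).
#'
#' @param name One of `"LDA"`, `"LR"`, `"SVM"`, `"AdaBoost"`, `"GBoost"`.
#' @param hyperparameters Named list overriding the defaults above.
#' @param seed Integer seed for the stochastic ensemble methods.
#' @return A `BaselineSpec` list.
#' @examples
#' baselineSpec("SVM")
#' @export
baselineSpec <- function(name, hyperparameters = list(), seed = 1L) {
  if (!name %in% BASELINE_NAMES) {
    stopf("unknown baseline '%s'; valid: %s", name,
          paste(BASELINE_NAMES, collapse = ", "))
  }
  defaults <- switch(name,
    LDA = list(solver = "svd"),
    LR = list(penalty = "l2", C = 97.2, solver = "newton-cholesky",
              l1_ratio = 0.07),
    SVM = list(kernel = "polynomial", degree = 4, gamma = "auto"),
    AdaBoost = list(n_estimators = 227L, learning_rate = 0.78),
    GBoost = list(n_estimators = 438L, learning_rate = 0.52,
                  criterion = "squared_error", max_depth = 3L)
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  extra <- setdiff(names(hp), names(defaults))
  if (length(extra)) {
    stopf("%s: unknown hyperparameter(s) %s; valid: %s", name,
          paste(extra, collapse = ", "), paste(names(defaults), collapse = ", "))
  }
  schemaCheck <- switch(name,
    LDA = function(h) h$solver %in% c("svd", "lsqr", "eigen"),
    LR = function(h) h$penalty %in% c("l1", "l2", "elasticnet", "none") &&
      is.numeric(h$C) && h$C > 0,
    SVM = function(h) h$kernel %in% c("linear", "polynomial", "radial") &&
      h$degree >= 1,
    AdaBoost = function(h) h$n_estimators >= 1 && h$learning_rate > 0,
    GBoost = function(h) h$n_estimators >= 1 && h$learning_rate > 0 &&
      h$criterion %in% c("squared_error", "friedman_mse")
  )
  if (!isTRUE(schemaCheck(hp))) {
    stopf("%s: hyperparameters failed schema validation: %s", name,
          paste(sprintf("%s=%s", names(hp), unlist(lapply(hp, format))),
                collapse = ", "))
  }
  if (name == "LR" && hp$penalty != "l2") {
    stopf("LR: only the selected l2 penalty is implemented (got '%s')",
          hp$penalty)
  }
  structure(list(name = name, hyperparameters = hp, seed = as.integer(seed)),
            class = "BaselineSpec")
}

#' Construct a classical classifier handle
#'
#' Returns a handle with `$fit(x, y)` and `$predict(x)` closures around the
#' established implementations (MASS::lda, nnet::multinom with ridge decay
#' 1/(2C), e1071::svm, in-package SAMME AdaBoost over rpart stumps,
#' xgboost). Predictions are factor labels on the training levels.
#'
#' @param spec A [baselineSpec()].
#' @return A `BaselineHandle` (list of closures; `$fitted()` reports state).
#' @export
makeBaseline <- function(spec) {
  stopifnot(inherits(spec, "BaselineSpec"))
  hp <- spec$hyperparameters
  env <- new.env(parent = emptyenv())
  env$model <- NULL
  env$levels <- NULL
  fit <- switch(spec$name,
    LDA = function(x, y) {
      env$model <- MASS::lda(x, grouping = y)
      env$levels <- levels(y)
    },
    LR = function(x, y) {
      df <- data.frame(.y = y, x)
      env$model <- withSeed(spec$seed,
        nnet::multinom(.y ~ ., data = df, decay = 1 / (2 * hp$C),
                       maxit = 500, trace = FALSE))
      env$levels <- levels(y)
    },
    SVM = function(x, y) {
      gamma <- if (identical(hp$gamma, "auto")) 1 / ncol(x) else hp$gamma
      env$model <- withSeed(spec$seed,
        e1071::svm(x, y, kernel = hp$kernel, degree = hp$degree,
                   gamma = gamma, coef0 = 1))
      env$levels <- levels(y)
    },
    AdaBoost = function(x, y) {
      env$model <- withSeed(spec$seed,
        adaboostFit(x, y, n_estimators = hp$n_estimators,
                    learning_rate = hp$learning_rate))
      env$levels <- levels(y)
    },
    GBoost = function(x, y) {
      ncls <- nlevels(y)
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                     label = as.integer(y) - 1L)
      env$model <- xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = ncls,
                      eta = hp$learning_rate, max_depth = hp$max_depth,
                      nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = hp$n_estimators, verbose = 0)
      env$levels <- levels(y)
    }
  )
  predictFun <- switch(spec$name,
    LDA = function(x) predict(env$model, x)$class,
    LR = function(x) {
      p <- predict(env$model, newdata = data.frame(x), type = "probs")
      if (is.null(dim(p))) p <- matrix(p, nrow = nrow(x))
      factor(env$levels[max.col(p, ties.method = "first")],
             levels = env$levels)
    },
    SVM = function(x) predict(env$model, x),
    AdaBoost = function(x) adaboostPredict(env$model, x),
    GBoost = function(x) {
      p <- predict(env$model, xgboost::xgb.DMatrix(as.matrix(x)))
      if (is.null(dim(p))) {  # flat row-major vector in older interfaces
        p <- matrix(p, ncol = length(env$levels), byrow = TRUE)
      }
      factor(env$levels[max.col(p, ties.method = "first")],
             levels = env$levels)
    }
  )
  structure(list(
    spec = spec,
    fit = function(x, y) {
      x <- as.matrix(x)
      y <- droplevels(as.factor(y))
      if (nlevels(y) < 2L) {
        # degenerate single-class training set: constant predictor
        env$model <- NULL
        env$levels <- levels(y)
        env$constant <- levels(y)[1]
      } else {
        env$constant <- NULL
        fit(x, y)
      }
      invisible(NULL)
    },
    predict = function(x) {
      x <- as.matrix(x)
      if (!is.null(env$constant)) {
        return(factor(rep(env$constant, nrow(x)), levels = env$levels))
      }
      if (is.null(env$model)) stopf("baseline %s is not fitted", spec$name)
      factor(as.character(predictFun(x)), levels = env$levels)
    },
    fitted = function() !is.null(env$model) || !is.null(env$constant)
  ), class = "BaselineHandle")
}

# SAMME AdaBoost over depth-1 rpart stumps (multi-class discrete AdaBoost).
adaboostFit <- function(x, y, n_estimators, learning_rate) {
  n <- nrow(x)
  K <- nlevels(y)
  df <- data.frame(.y = y, x)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = -1, minsplit = 2,
                          minbucket = 1, xval = 0))
    pred <- predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w * miss) / sum(w)
    if (err >= 1 - 1 / K) break  # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- learning_rate * (log((1 - err) / err) + log(K - 1))
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-10) break  # perfect stump
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

adaboostPredict <- function(model, x) {
  df <- data.frame(x)
  votes <- matrix(0, nrow(df), length(model$levels))
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], df, type = "class")
    idx <- cbind(seq_len(nrow(df)), as.integer(pred))
    votes[idx] <- votes[idx] + model$alphas[m]
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}

#' Train a baseline on training features and score it on test features
#'
#' Guards against subject leakage: the train and test subject sets must be
#' disjoint.
#'
#' @param spec A [baselineSpec()].
#' @param x_train,x_test Feature matrices.
#' @param y_train,y_test Label factors.
#' @param subjects_train,subjects_test Subject ids per row (leakage check;
#'   optional).
#' @return A `MetricsReport` from [evaluateMetrics()].
#' @export
trainAndEvalBaseline <- function(spec, x_train, y_train, x_test, y_test,
                                 subjects_train = NULL,
                                 subjects_test = NULL) {
  if (!is.null(subjects_train) && !is.null(subjects_test)) {
    overlap <- intersect(unique(subjects_train), unique(subjects_test))
    if (length(overlap)) {
      stopf("subject leakage between train and test sets: %s",
            paste(overlap, collapse = ", "))
    }
  }
  h <- makeBaseline(spec)
  h$fit(x_train, y_train)
  pred <- h$predict(x_test)
  evaluateMetrics(y_test, factor(as.character(pred), levels = levels(y_test)))
}
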