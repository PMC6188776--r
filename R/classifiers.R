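# Classifier adapters.
#
# The cross-validation harness is classifier-agnostic: a classifier spec is
# a fit/predict pair over a numeric feature matrix and a factor label, plus
# a small hyperparameter grid and a flag saying whether the learner is
# scale-sensitive (in which case the harness standardizes fold-wise).  The
# default roster mirrors the families commonly run over morphometric
# feature tables; every member is backed by a standard implementation.

classifier_registry <- function() {
  list(
    pda = list(
      label = "Penalized discriminant analysis (ridge multinomial)",
      scale = TRUE,
      grid = list(list(lambda = 0.01)),
      fit = function(x, y, params) {
        lam <- sort(unique(c(5, 1, 0.2, 0.05, params$lambda)), decreasing = TRUE)
        # glmnet warns whenever a class has < 8 observations, which is the
        # normal state of a cultivar design's training folds
        fit <- withCallingHandlers(
          glmnet::glmnet(x, y, family = "multinomial", alpha = 0, lambda = lam),
          warning = function(w) {
            if (grepl("fewer than 8", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          })
        list(fit = fit, lambda = params$lambda, classes = levels(y))
      },
      predict = function(model, x) {
        p <- predict(model$fit, newx = x, s = model$lambda, type = "class")
        factor(as.character(p), levels = model$classes)
      }
    ),
    lda = list(
      label = "Linear discriminant analysis",
      scale = TRUE,
      grid = list(list()),
      fit = function(x, y, params) MASS::lda(x, grouping = y),
      predict = function(model, x) predict(model, x)$class
    ),
    fsrf = list(
      label = "Feature-selection random forest",
      scale = FALSE,
      grid = list(list(top_frac = 0.75, ntree = 300)),
      fit = function(x, y, params) {
        rf0 <- randomForest::randomForest(x, y, ntree = params$ntree,
                                          importance = TRUE)
        imp <- randomForest::importance(rf0, type = 1)
        keep <- colnames(x)
        n_keep <- max(2L, floor(ncol(x) * params$top_frac))
        if (n_keep < ncol(x)) {
          keep <- rownames(imp)[order(imp[, 1], decreasing = TRUE)][seq_len(n_keep)]
          rf0 <- randomForest::randomForest(x[, keep, drop = FALSE], y,
                                            ntree = params$ntree)
        }
        list(fit = rf0, keep = keep)
      },
      predict = function(model, x) {
        predict(model$fit, x[, model$keep, drop = FALSE])
      }
    ),
    rf = list(
      label = "Random forest",
      scale = FALSE,
      grid = list(list(ntree = 300)),
      fit = function(x, y, params) randomForest::randomForest(x, y, ntree = params$ntree),
      predict = function(model, x) predict(model, x)
    ),
    bcart = list(
      label = "Bagged trees (random forest, mtry = p)",
      scale = FALSE,
      grid = list(list(ntree = 300)),
      fit = function(x, y, params) {
        randomForest::randomForest(x, y, ntree = params$ntree, mtry = ncol(x))
      },
      predict = function(model, x) predict(model, x)
    ),
    cart = list(
      label = "Classification tree",
      scale = FALSE,
      grid = list(list(cp = 0.01)),
      fit = function(x, y, params) {
        df <- data.frame(.y = y, x, check.names = FALSE)
        # cultivar designs have ~15 training fruit per class, far below
        # rpart's default minsplit of 20; allow splits down to small leaves
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = params$cp, xval = 0,
                                                    minsplit = 5, minbucket = 2))
      },
      predict = function(model, x) {
        p <- predict(model, data.frame(x, check.names = FALSE), type = "class")
        p
      }
    ),
    knn = list(
      label = "K-nearest neighbours",
      scale = TRUE,
      grid = list(list(k = 3), list(k = 5)),
      fit = function(x, y, params) list(x = x, y = y, k = params$k),
      predict = function(model, x) {
        class::knn(model$x, x, model$y, k = model$k)
      }
    ),
    nb = list(
      label = "Naive Bayes",
      scale = FALSE,
      grid = list(list()),
      fit = function(x, y, params) e1071::naiveBayes(x, y),
      predict = function(model, x) predict(model, x)
    ),
    svm = list(
      label = "Support vector machine (radial)",
      scale = TRUE,
      grid = list(list(cost = 4)),
      fit = function(x, y, params) {
        e1071::svm(x, y, kernel = "radial", cost = params$cost, scale = FALSE)
      },
      predict = function(model, x) predict(model, x)
    ),
    nn = list(
      label = "Neural network (single hidden layer)",
      scale = TRUE,
      grid = list(list(size = 6, decay = 0.01)),
      fit = function(x, y, params) {
        nnet::nnet(x, class_indicator(y), size = params$size,
                   decay = params$decay, maxit = 300, trace = FALSE,
                   MaxNWts = 5000, softmax = TRUE)
      },
      predict = function(model, x) {
        p <- predict(model, x, type = "class")
        factor(p, levels = colnames(model$fitted.values))
      }
    )
  )
}

class_indicator <- function(y) {
  m <- stats::model.matrix(~ y - 1)
  colnames(m) <- levels(y)
  m
}

#' Look up one classifier specification
#'
#' @param id one of `"pda"`, `"lda"`, `"fsrf"`, `"rf"`, `"bcart"`,
#'   `"cart"`, `"knn"`, `"nb"`, `"svm"`, `"nn"`.
#' @param grid optional replacement hyperparameter grid: a list of named
#'   parameter lists, searched by mean cross-validated accuracy.
#' @return a classifier spec: list with `id`, `label`, `scale`, `grid`,
#'   `fit(x, y, params)`, `predict(model, x)`.
#' @export
classifier_spec <- function(id, grid = NULL) {
  reg <- classifier_registry()
  if (!id %in% names(reg)) {
    abort(sprintf("unknown classifier '%s'; available: %s",
                  id, paste(names(reg), collapse = ", ")))
  }
  spec <- reg[[id]]
  spec$id <- id
  if (!is.null(grid)) spec$grid <- grid
  spec
}

#' The default classifier suite
#'
#' @param ids classifier identifiers, in suite order (the order is the last
#'   tie-breaker in [select_best()]).
#' @return a named list of classifier specs.
#' @export
classifier_suite <- function(ids = c("pda", "lda", "fsrf", "rf", "bcart",
                                     "cart", "knn", "nb", "svm", "nn")) {
  setNames(lapply(ids, classifier_spec), ids)
}
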