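# Partitioning, repeated stratified cross-validation, metrics, classifier
# comparison and selection.

#' Stratified train/test split of a feature table
#'
#' Samples, within every cultivar, `floor(n * (1 - train_fraction))` fruit
#' into the test set and the remainder into training (so 20 fruit at the
#' default 0.75 give 15 training and 5 test fruit per cultivar).  Because
#' the plan is expressed in fruit ids it can be reused across all dataset
#' flavours, which keeps their test-set accuracies directly comparable.
#'
#' @param table a feature table (or any frame with `fruit_id`, `cultivar`).
#' @param train_fraction fraction allocated to training.
#' @param seed RNG seed for the within-cultivar sampling.
#' @return an object of class `split_plan`: tibble with `fruit_id`,
#'   `cultivar`, `set` (`"train"`/`"test"`), carrying `seed` and
#'   `train_fraction` attributes.
#' @export
stratified_split <- function(table, train_fraction = 0.75, seed = 1L) {
  if (!all(c("fruit_id", "cultivar") %in% names(table))) {
    abort("`table` needs fruit_id and cultivar columns")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1")
  }
  counts <- table(table$cultivar)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    abort(sprintf("cultivar(s) with fewer than 2 fruit cannot be split: %s",
                  paste(small, collapse = ", ")))
  }
  out <- withr::with_seed(seed, {
    dplyr::group_by(tibble::as_tibble(table[c("fruit_id", "cultivar")]),
                    .data$cultivar) |>
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        n_test <- max(1L, floor(n * (1 - train_fraction)))
        test_rows <- sample.int(n, n_test)
        df$set <- "train"
        df$set[test_rows] <- "test"
        df
      }) |>
      dplyr::ungroup()
  })
  out <- out[match(table$fruit_id, out$fruit_id), c("fruit_id", "cultivar", "set")]
  attr(out, "seed") <- seed
  attr(out, "train_fraction") <- train_fraction
  class(out) <- c("split_plan", class(out))
  out
}

split_ids <- function(plan, which = c("train", "test")) {
  which <- match.arg(which)
  plan$fruit_id[plan$set == which]
}

take_split <- function(table, plan, which) {
  if (is.null(plan)) return(table)
  table[table$fruit_id %in% split_ids(plan, which), , drop = FALSE]
}

# --- confusion matrices and metrics ----------------------------------------

#' Build a confusion matrix (reference rows, prediction columns)
#'
#' @param reference,prediction label vectors of equal length.
#' @param classes ordered class set; defaults to the sorted union of both.
#' @return an integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(reference, prediction, classes = NULL) {
  if (length(reference) != length(prediction)) {
    abort("`reference` and `prediction` must have equal length")
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(as.character(reference), as.character(prediction))))
  }
  ref <- factor(as.character(reference), levels = classes)
  prd <- factor(as.character(prediction), levels = classes)
  if (anyNA(ref) || anyNA(prd)) {
    abort("labels outside the declared class set")
  }
  m <- unclass(table(Reference = ref, Prediction = prd))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d classes, %d observations), accuracy %.3f\n",
              nrow(x), sum(x), sum(diag(unclass(x))) / sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: (observed - chance) / (1 - chance), where
#' chance agreement is computed from the row and column marginals.  When
#' chance agreement is 1 (a single class in both margins) kappa is
#' undefined and `NA` is returned with a warning.
#'
#' @param cm a [confusion_matrix()] (any square counts matrix works).
#' @return a single number in \[-1, 1\], or `NA` when undefined.
#' @export
cohen_kappa <- function(cm) {
  m <- unclass(cm)
  n <- sum(m)
  if (n <= 0) abort("confusion matrix has no observations")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warn("Cohen's kappa undefined: chance agreement is 1 (single class)")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' One-vs-rest classification metrics from a confusion matrix
#'
#' Overall accuracy and kappa plus, per class, sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), positive predictive value TP/(TP+FP) and
#' negative predictive value TN/(TN+FN).  Ratios with a zero denominator
#' (e.g. the PPV of a never-predicted class) are reported as `NA`, never
#' silently zeroed.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `metric_set`: list with `accuracy`, `kappa`,
#'   `per_class` (tibble: class, sensitivity, specificity, ppv, npv), `n`.
#' @export
confusion_metrics <- function(cm) {
  m <- unclass(cm)
  n <- sum(m)
  if (n <= 0) abort("confusion matrix has no observations")
  classes <- rownames(m)
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- n - tp - fn - fp
  per_class <- tibble::tibble(
    class = classes,
    sensitivity = unname(rate(tp, tp + fn)),
    specificity = unname(rate(tn, tn + fp)),
    ppv = unname(rate(tp, tp + fp)),
    npv = unname(rate(tn, tn + fn))
  )
  structure(
    list(accuracy = sum(tp) / n,
         kappa = suppressWarnings(cohen_kappa(m)),
         per_class = per_class,
         n = n),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("accuracy %.3f, kappa %.3f over %d observations (%d classes)\n",
              x$accuracy, x$kappa, x$n, nrow(x$per_class)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.metric_set <- function(x, ...) x$per_class

#' @exportS3Method generics::glance
glance.metric_set <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, kappa = x$kappa, n = x$n)
}

# --- cross-validation harness ----------------------------------------------

scale_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

scale_apply <- function(x, sc) {
  if (is.null(sc)) return(x)
  sweep(sweep(x, 2, sc$center), 2, sc$scale, `/`)
}

# stratified fold assignments: one integer vector per repeat
make_folds <- function(y, folds, repeats, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      assignment <- integer(length(y))
      for (cl in levels(y)) {
        rows <- which(y == cl)
        # when a class has fewer rows than folds, which folds it skips must
        # itself be random, or one fold would end up empty for every class
        fold_seq <- rep(sample.int(folds), length.out = length(rows))
        assignment[rows] <- sample(fold_seq)
      }
      assignment
    })
  })
}

feature_matrix <- function(table) {
  cols <- feature_cols(table)
  m <- as.matrix(as.data.frame(table)[cols])
  storage.mode(m) <- "double"
  m
}

#' Repeated stratified cross-validation of one classifier
#'
#' Runs `repeats` x `folds` cross-validation (folds stratified by cultivar)
#' on the training part of a feature table, for every candidate in the
#' classifier's hyperparameter grid; the candidate with the highest mean
#' cross-validated accuracy is retained and refit on the full training
#' part.  All preprocessing with fitted parameters (the fold-wise z-score
#' standardization used for scale-sensitive learners) is fit inside each
#' training fold only, never on held-out rows.  A classifier failure on a
#' fold marks that resample invalid; more than 20% invalid resamples
#' aborts.
#'
#' @param spec a [classifier_spec()] (or an id string).
#' @param table a feature table.
#' @param split an optional [stratified_split()] plan; when supplied only
#'   its training rows are used.
#' @param repeats,folds the resampling design.
#' @param seed RNG seed for fold assignment and any stochastic learner.
#' @return an object of class `trained_classifier`: the refit model plus
#'   `cv_record` (one row per resample: repeat, fold, accuracy, kappa,
#'   valid), `per_class_cv_accuracy` (recall per cultivar pooled over all
#'   held-out predictions), `overall_cv_accuracy`, `overall_cv_kappa`,
#'   the chosen `params`, and the resample plan (for paired comparisons).
#' @export
cross_validate <- function(spec, table, split = NULL, repeats = 3L,
                           folds = 10L, seed = 1L) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  train_tbl <- take_split(table, split, "train")
  x <- feature_matrix(train_tbl)
  y <- factor(train_tbl$cultivar)
  if (nrow(x) < folds) abort("fewer training rows than folds")
  assignments <- make_folds(y, folds, repeats, seed)

  run_grid_point <- function(params) {
    recs <- list()
    pooled_pred <- factor(rep(NA_character_, 0), levels = levels(y))
    pooled_ref <- pooled_pred
    for (r in seq_len(repeats)) {
      for (f in seq_len(folds)) {
        hold <- assignments[[r]] == f
        if (!any(hold)) {
          recs[[length(recs) + 1L]] <- tibble::tibble(
            repeat_ = r, fold = f, accuracy = NA_real_, kappa = NA_real_,
            valid = FALSE)
          next
        }
        res <- tryCatch({
          sc <- if (isTRUE(spec$scale)) scale_fit(x[!hold, , drop = FALSE]) else NULL
          xtr <- scale_apply(x[!hold, , drop = FALSE], sc)
          xte <- scale_apply(x[hold, , drop = FALSE], sc)
          # both fitting and prediction sit inside one seeded block: some
          # learners (e.g. random forests) break prediction ties at random
          pred <- withr::with_seed(derive_seed(seed, r * 1000L + f), {
            fit <- spec$fit(xtr, droplevels(y[!hold]), params)
            spec$predict(fit, xte)
          })
          pred <- factor(as.character(pred), levels = levels(y))
          list(pred = pred, ok = TRUE)
        }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
        if (isTRUE(res$ok)) {
          ref <- y[hold]
          cm <- confusion_matrix(ref, res$pred, classes = levels(y))
          recs[[length(recs) + 1L]] <- tibble::tibble(
            repeat_ = r, fold = f,
            accuracy = sum(diag(unclass(cm))) / sum(cm),
            kappa = suppressWarnings(cohen_kappa(cm)),
            valid = TRUE)
          pooled_pred <- c(pooled_pred, res$pred)
          pooled_ref <- c(pooled_ref, ref)
        } else {
          recs[[length(recs) + 1L]] <- tibble::tibble(
            repeat_ = r, fold = f, accuracy = NA_real_, kappa = NA_real_,
            valid = FALSE)
        }
      }
    }
    rec <- dplyr::bind_rows(recs)
    n_invalid <- sum(!rec$valid)
    if (n_invalid > 0.2 * nrow(rec)) {
      abort(sprintf("classifier '%s' failed on %d of %d resamples",
                    spec$id, n_invalid, nrow(rec)),
            class = "pomometrics_cv_failure")
    }
    list(rec = rec, pred = pooled_pred, ref = pooled_ref,
         mean_acc = mean(rec$accuracy, na.rm = TRUE))
  }

  grid_runs <- lapply(spec$grid, run_grid_point)
  best_i <- which.max(vapply(grid_runs, `[[`, double(1), "mean_acc"))
  best <- grid_runs[[best_i]]
  params <- spec$grid[[best_i]]

  per_class <- tibble::tibble(cultivar = levels(y)) |>
    dplyr::mutate(
      accuracy = vapply(.data$cultivar, function(cl) {
        sel <- best$ref == cl
        if (!any(sel)) return(NA_real_)
        mean(best$pred[sel] == cl)
      }, double(1)),
      n_heldout = vapply(.data$cultivar, function(cl) sum(best$ref == cl),
                         double(1))
    )

  sc <- if (isTRUE(spec$scale)) scale_fit(x) else NULL
  final_model <- withr::with_seed(derive_seed(seed, 999999L),
                                  spec$fit(scale_apply(x, sc), y, params))

  structure(
    list(
      spec = spec,
      params = params,
      grid_accuracies = vapply(grid_runs, `[[`, double(1), "mean_acc"),
      model = final_model,
      scaling = sc,
      feature_cols = feature_cols(table),
      flavour = table_flavour(table),
      classes = levels(y),
      cv_record = best$rec,
      per_class_cv_accuracy = per_class,
      overall_cv_accuracy = mean(best$rec$accuracy, na.rm = TRUE),
      overall_cv_kappa = mean(best$rec$kappa, na.rm = TRUE),
      resample_plan = list(seed = seed, repeats = repeats, folds = folds,
                           assignments = assignments,
                           fruit_id = train_tbl$fruit_id)
    ),
    class = "trained_classifier"
  )
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("%s [%s], trained on %d fruit (%s features)\n",
              x$spec$label, x$spec$id, length(x$resample_plan$fruit_id),
              x$flavour))
  cat(sprintf("  CV (%d x %d-fold): accuracy %.3f, kappa %.3f\n",
              x$resample_plan$repeats, x$resample_plan$folds,
              x$overall_cv_accuracy, x$overall_cv_kappa))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trained_classifier <- function(x, ...) x$cv_record

#' @exportS3Method generics::glance
glance.trained_classifier <- function(x, ...) {
  tibble::tibble(
    classifier = x$spec$id,
    flavour = x$flavour,
    cv_accuracy = x$overall_cv_accuracy,
    cv_kappa = x$overall_cv_kappa,
    n_resamples = nrow(x$cv_record),
    n_invalid = sum(!x$cv_record$valid)
  )
}

#' Predict cultivars for new fruit
#'
#' @param object a [cross_validate()] fit.
#' @param newdata a feature table (or data frame) carrying the model's
#'   feature columns.
#' @param ... unused.
#' @return a factor of predicted cultivars.
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_cols, names(newdata))
  if (length(miss) > 0) {
    abort(sprintf("newdata lacks feature column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "pomometrics_feature_mismatch")
  }
  x <- as.matrix(as.data.frame(newdata)[object$feature_cols])
  storage.mode(x) <- "double"
  # seeded: some learners break prediction ties using the global RNG
  pred <- withr::with_seed(
    derive_seed(object$resample_plan$seed, 777777L),
    object$spec$predict(object$model, scale_apply(x, object$scaling)))
  factor(as.character(pred), levels = object$classes)
}

#' Paired t-test comparison of two cross-validated classifiers
#'
#' Pairs the two classifiers' per-resample accuracy (and kappa) values by
#' resample index and applies a two-sided paired t-test.  Both fits must
#' share one resample plan (same training rows, folds and seed) or the
#' pairing would be meaningless.  A zero-variance difference is flagged
#' degenerate: identical records give t = 0, p = 1; a constant non-zero
#' difference has no finite t statistic.
#'
#' @param a,b two [cross_validate()] fits with identical resample plans.
#' @return a tibble with one row per metric (`accuracy`, `kappa`):
#'   `estimate` (mean difference a - b), `statistic`, `p.value`,
#'   `degenerate`.
#' @export
compare_classifiers <- function(a, b) {
  pa <- a$resample_plan; pb <- b$resample_plan
  if (!identical(pa$assignments, pb$assignments) ||
      !identical(pa$fruit_id, pb$fruit_id)) {
    abort("classifiers were not cross-validated on identical resample plans",
          class = "pomometrics_plan_mismatch")
  }
  one <- function(metric) {
    d <- a$cv_record[[metric]] - b$cv_record[[metric]]
    d <- d[!is.na(d)]
    if (sd(d) < 1e-12) {
      tibble::tibble(metric = metric, estimate = mean(d),
                     statistic = if (abs(mean(d)) < 1e-12) 0 else NA_real_,
                     p.value = if (abs(mean(d)) < 1e-12) 1 else NA_real_,
                     degenerate = TRUE)
    } else {
      tt <- stats::t.test(a$cv_record[[metric]], b$cv_record[[metric]],
                          paired = TRUE)
      tibble::tibble(metric = metric, estimate = unname(tt$estimate),
                     statistic = unname(tt$statistic),
                     p.value = tt$p.value, degenerate = FALSE)
    }
  }
  dplyr::bind_rows(one("accuracy"), one("kappa"))
}

#' Select the best classifier from a list of cross-validated fits
#'
#' Highest mean cross-validated accuracy wins; exact ties are broken by
#' mean cross-validated kappa, then by position in the list (the declared
#' suite order).
#'
#' @param models a non-empty list of [cross_validate()] fits.
#' @return the winning `trained_classifier`.
#' @export
select_best <- function(models) {
  if (length(models) == 0) abort("`models` is empty")
  acc <- vapply(models, `[[`, double(1), "overall_cv_accuracy")
  kap <- vapply(models, `[[`, double(1), "overall_cv_kappa")
  best <- order(-acc, -kap, seq_along(models))[1]
  models[[best]]
}

#' Evaluate a trained classifier on the held-out test set
#'
#' @param model a [cross_validate()] fit.
#' @param table the feature table of the model's flavour.
#' @param split the [stratified_split()] plan whose test rows to use
#'   (`NULL` evaluates every row of `table`).
#' @return an object of class `classification_eval`: `predictions` (tibble
#'   fruit_id, cultivar, predicted, correct), `confusion` (a
#'   [confusion_matrix()]), `metrics` (a [confusion_metrics()] result),
#'   `accuracy`.
#' @export
evaluate <- function(model, table, split = NULL) {
  test_tbl <- take_split(table, split, "test")
  if (nrow(test_tbl) == 0) abort("no test rows to evaluate")
  pred <- predict(model, test_tbl)
  classes <- union(model$classes, unique(test_tbl$cultivar))
  cm <- confusion_matrix(test_tbl$cultivar, pred, classes = classes)
  structure(
    list(
      predictions = tibble::tibble(
        fruit_id = test_tbl$fruit_id,
        cultivar = test_tbl$cultivar,
        predicted = as.character(pred),
        correct = as.character(pred) == test_tbl$cultivar
      ),
      confusion = cm,
      metrics = confusion_metrics(cm),
      accuracy = mean(as.character(pred) == test_tbl$cultivar),
      classifier = model$spec$id,
      flavour = model$flavour
    ),
    class = "classification_eval"
  )
}

#' @export
print.classification_eval <- function(x, ...) {
  cat(sprintf("Test-set evaluation of %s (%s): accuracy %.3f over %d fruit\n",
              x$classifier, x$flavour, x$accuracy, nrow(x$predictions)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.classification_eval <- function(x, ...) x$predictions

#' @exportS3Method generics::glance
glance.classification_eval <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, flavour = x$flavour,
                 accuracy = x$accuracy, kappa = x$metrics$kappa,
                 n = nrow(x$predictions))
}
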