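test_that("stratified split: paper-shaped counts, determinism, partition property", {
  labels <- tibble::tibble(
    fruit_id = sprintf("f%04d", 1:540),
    cultivar = rep(sprintf("c%02d", 1:27), each = 20)
  )
  plan <- stratified_split(labels, train_fraction = 0.75, seed = 4)
  expect_equal(sum(plan$set == "train"), 405L)
  expect_equal(sum(plan$set == "test"), 135L)
  per <- table(plan$cultivar, plan$set)
  expect_true(all(per[, "train"] == 15L))
  expect_true(all(per[, "test"] == 5L))

  expect_identical(stratified_split(labels, seed = 4), plan)
  expect_false(identical(stratified_split(labels, seed = 5)$set, plan$set))

  # per cultivar: train and test partition the cultivar's fruit
  for (cl in c("c01", "c19")) {
    sub <- plan[plan$cultivar == cl, ]
    expect_length(intersect(sub$fruit_id[sub$set == "train"],
                            sub$fruit_id[sub$set == "test"]), 0)
    expect_setequal(sub$fruit_id, labels$fruit_id[labels$cultivar == cl])
  }

  expect_error(stratified_split(tibble::tibble(fruit_id = "a", cultivar = "x")),
               "fewer than 2")
})

test_that("Cohen's kappa: closed forms, label-permutation invariance, caret oracle", {
  perfect <- diag(c(5L, 7L, 3L))
  expect_equal(cohen_kappa(perfect), 1.0)

  m <- matrix(c(4, 1, 2, 3), 2, 2, byrow = TRUE)
  expect_equal(cohen_kappa(m), 0.4, tolerance = 1e-12)

  withr::with_seed(8, {
    r <- matrix(rpois(16, 5), 4, 4)
  })
  perm <- c(3, 1, 4, 2)
  expect_equal(cohen_kappa(r[perm, perm]), cohen_kappa(r), tolerance = 1e-12)

  skip_if_not_installed("caret")
  dimnames(r) <- list(letters[1:4], letters[1:4])
  oracle <- unname(caret::confusionMatrix(as.table(r))$overall["Kappa"])
  expect_equal(cohen_kappa(r), oracle, tolerance = 1e-9)

  expect_warning(k1 <- cohen_kappa(matrix(5)), "undefined")
  expect_true(is.na(k1))
})

test_that("confusion metrics: perfect case, undefined PPV, exhaustive oracle", {
  cm <- confusion_matrix(rep(c("a", "b"), c(3, 4)), rep(c("a", "b"), c(3, 4)))
  ms <- confusion_metrics(cm)
  expect_equal(ms$accuracy, 1)
  expect_true(all(as.matrix(ms$per_class[-1]) == 1))

  # class "c" present in references but never predicted: PPV undefined
  cm2 <- confusion_matrix(c("a", "b", "c"), c("a", "b", "a"))
  ms2 <- confusion_metrics(cm2)
  expect_true(is.na(ms2$per_class$ppv[ms2$per_class$class == "c"]))
  expect_equal(ms2$per_class$sensitivity[ms2$per_class$class == "c"], 0)

  # random 3-class matrix vs a direct one-vs-rest tabulation over raw labels
  withr::with_seed(21, {
    ref <- sample(c("a", "b", "c"), 60, replace = TRUE)
    prd <- sample(c("a", "b", "c"), 60, replace = TRUE)
  })
  ms3 <- confusion_metrics(confusion_matrix(ref, prd))
  for (cl in c("a", "b", "c")) {
    tp <- sum(ref == cl & prd == cl); fn <- sum(ref == cl & prd != cl)
    fp <- sum(ref != cl & prd == cl); tn <- sum(ref != cl & prd != cl)
    row <- ms3$per_class[ms3$per_class$class == cl, ]
    expect_equal(row$sensitivity, tp / (tp + fn))
    expect_equal(row$specificity, tn / (tn + fp))
    expect_equal(row$ppv, tp / (tp + fp))
    expect_equal(row$npv, tn / (tn + fn))
  }
})

test_that("cross-validation records 30 resamples and reproduces with the seed", {
  tab <- blob_table(classes = 3, n_per = 20, p = 3, sep = 5, seed = 6)
  fit <- cross_validate("lda", tab, repeats = 3, folds = 10, seed = 11)
  expect_equal(nrow(fit$cv_record), 30L)
  expect_true(all(fit$cv_record$valid))
  expect_equal(nrow(fit$per_class_cv_accuracy), 3L)
  expect_true(all(fit$per_class_cv_accuracy$n_heldout == 60L))  # 3 repeats x 20

  fit2 <- cross_validate("lda", tab, repeats = 3, folds = 10, seed = 11)
  expect_identical(fit$cv_record, fit2$cv_record)
  expect_identical(fit$per_class_cv_accuracy, fit2$per_class_cv_accuracy)
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  tab <- blob_table(classes = 8, n_per = 10, p = 3, sep = 5, seed = 14)
  withr::with_seed(15, {
    tab$cultivar <- sample(tab$cultivar)
  })
  fit <- cross_validate("knn", tab, repeats = 3, folds = 10, seed = 16)
  p <- 1 / 8
  n_pooled <- 3 * nrow(tab)
  three_sd <- 3 * sqrt(p * (1 - p) / n_pooled)
  expect_lt(abs(fit$overall_cv_accuracy - p), three_sd)
})

test_that("fold-wise standardization never leaks test-set statistics", {
  # two classes separated on feature 1; feature 2 is an arbitrary tag.
  train <- tibble::tibble(
    fruit_id = sprintf("tr%02d", 1:10),
    cultivar = rep(c("A", "B"), each = 5),
    feat_1 = c(0, 0.1, -0.1, 0.05, -0.05, 3, 3.1, 2.9, 3.05, 2.95),
    feat_2 = c(10, 11, 12, 13, 14, 20, 21, 22, 23, 24)
  )
  train <- pomometrics:::new_feature_table(train, "linear")
  # test set: one fruit on the A side of feature 1 whose tag matches a B row,
  # plus extreme outliers that wreck any pooled scaling of feature 1
  test <- tibble::tibble(
    fruit_id = c("te1", "te2", "te3"),
    cultivar = c("A", "B", "A"),
    feat_1 = c(0.5, 1000, -1000),
    feat_2 = c(20, 15, 15)
  )
  spec1nn <- classifier_spec("knn", grid = list(list(k = 1)))
  fit <- cross_validate(spec1nn, train, repeats = 1, folds = 2, seed = 3)
  got <- as.character(predict(fit, test))

  xtr <- as.matrix(train[c("feat_1", "feat_2")])
  xte <- as.matrix(test[c("feat_1", "feat_2")])
  zs <- function(x, ref) sweep(sweep(x, 2, colMeans(ref)), 2, apply(ref, 2, sd), "/")
  correct <- as.character(class::knn(zs(xtr, xtr), zs(xte, xtr), train$cultivar, k = 1))
  leaked <- as.character(class::knn(zs(xtr, rbind(xtr, xte)),
                                    zs(xte, rbind(xtr, xte)),
                                    train$cultivar, k = 1))
  expect_identical(got, correct)
  expect_false(identical(correct, leaked))  # the canary actually discriminates
  expect_identical(got[1], "A")             # leaked scaling would say "B"
  expect_identical(leaked[1], "B")
})

test_that("paired comparison: self-test, textbook oracle, plan mismatch", {
  tab <- blob_table(classes = 4, n_per = 12, p = 3, sep = 2.5, sd = 1.5, seed = 26)
  a <- cross_validate("lda", tab, repeats = 2, folds = 5, seed = 7)
  b <- cross_validate("cart", tab, repeats = 2, folds = 5, seed = 7)

  self <- compare_classifiers(a, a)
  expect_equal(self$statistic, c(0, 0))
  expect_equal(self$p.value, c(1, 1))
  expect_true(all(self$degenerate))

  cmp <- compare_classifiers(a, b)
  d <- a$cv_record$accuracy - b$cv_record$accuracy
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), length(d) - 1)
  expect_equal(cmp$statistic[cmp$metric == "accuracy"], t_oracle, tolerance = 1e-9)
  expect_equal(cmp$p.value[cmp$metric == "accuracy"], p_oracle, tolerance = 1e-9)

  # constant non-zero difference is degenerate with no finite statistic
  shifted <- a
  shifted$cv_record$accuracy <- a$cv_record$accuracy + 0.01
  sh <- compare_classifiers(shifted, a)
  expect_true(sh$degenerate[sh$metric == "accuracy"])
  expect_true(is.na(sh$statistic[sh$metric == "accuracy"]))

  c_other <- cross_validate("cart", tab, repeats = 2, folds = 5, seed = 8)
  expect_error(compare_classifiers(a, c_other),
               class = "pomometrics_plan_mismatch")
})

test_that("model selection follows accuracy, then kappa, then suite order", {
  mk <- function(acc, kap, id) {
    structure(list(overall_cv_accuracy = acc, overall_cv_kappa = kap,
                   spec = list(id = id)), class = "trained_classifier")
  }
  m1 <- mk(0.73, 0.70, "one"); m2 <- mk(0.66, 0.72, "two")
  expect_identical(select_best(list(m1))$spec$id, "one")
  expect_identical(select_best(list(m1, m2))$spec$id, "one")
  expect_identical(select_best(list(mk(0.7, 0.70, "one"),
                                    mk(0.7, 0.72, "two")))$spec$id, "two")
  expect_identical(select_best(list(mk(0.7, 0.7, "one"),
                                    mk(0.7, 0.7, "two")))$spec$id, "one")
  expect_error(select_best(list()), "empty")
})

test_that("test-set evaluation: counts, balanced identity, feature checks", {
  tab <- blob_table(classes = 4, n_per = 8, p = 3, sep = 6, seed = 33)
  plan <- stratified_split(tab, seed = 2)
  fit <- cross_validate("lda", tab, plan, repeats = 2, folds = 5, seed = 3)
  ev <- evaluate(fit, tab, plan)
  expect_equal(nrow(ev$predictions), 8L)  # 2 test fruit x 4 cultivars
  expect_equal(sum(ev$confusion), 8L)
  # balanced classes: accuracy is the mean per-class sensitivity
  expect_equal(ev$accuracy, mean(ev$metrics$per_class$sensitivity))

  bad <- tab
  names(bad)[names(bad) == "feat_2"] <- "feat_9"
  expect_error(predict(fit, bad), class = "pomometrics_feature_mismatch")
})

test_that("a failing classifier is caught and reported per resample", {
  tab <- blob_table(classes = 3, n_per = 8, p = 2, seed = 40)
  broken <- classifier_spec("lda")
  broken$fit <- function(x, y, params) stop("boom")
  broken$id <- "broken"
  expect_error(cross_validate(broken, tab, repeats = 1, folds = 4, seed = 1),
               class = "pomometrics_cv_failure")
})
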