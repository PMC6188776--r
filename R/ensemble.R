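# The manual ensemble: arbitration between a linear-dataset classifier
# (slot a) and a geometric-dataset classifier (slot b) using each
# classifier's own cross-validation accuracy for the class it predicts.

as_acc_lookup <- function(acc, arg) {
  if (is.data.frame(acc)) {
    if (!all(c("cultivar", "accuracy") %in% names(acc))) {
      abort(sprintf("`%s` must have cultivar and accuracy columns", arg))
    }
    return(setNames(acc$accuracy, acc$cultivar))
  }
  if (is.numeric(acc) && !is.null(names(acc))) return(acc)
  abort(sprintf("`%s` must be a named numeric vector or a cultivar/accuracy frame", arg))
}

#' Manual ensemble arbitration between two classifiers' predictions
#'
#' For each fruit: if both classifiers predict the same cultivar, that is
#' the answer.  If they disagree, each classifier is scored by its own
#' cross-validation accuracy *for the class it predicted*, and the strictly
#' higher score wins — the ensemble trusts each classifier for the
#' cultivars it has proven good at.  An exact tie falls back to the higher
#' overall cross-validation accuracy, and a still-exact tie to slot a (by
#' convention the linear-dataset classifier).  Only training-phase
#' cross-validation accuracies enter the rule; no test-set information is
#' consulted.
#'
#' @param pred_a,pred_b predicted cultivars (character vectors of equal
#'   length) from the linear-dataset (a) and geometric-dataset (b)
#'   classifiers.
#' @param per_class_acc_a,per_class_acc_b per-cultivar cross-validation
#'   accuracies: named numeric vectors or `cultivar`/`accuracy` frames
#'   (e.g. the `per_class_cv_accuracy` of a [cross_validate()] fit).  Every
#'   predicted class must be present in its own classifier's table.
#' @param overall_a,overall_b overall cross-validation accuracies used for
#'   tie-breaking.
#' @param fruit_id optional fruit identifiers carried into the output.
#' @return a tibble with one row per fruit: `fruit_id`, `pred_linear`,
#'   `pred_geometric`, `acc_linear_at_pred`, `acc_geometric_at_pred`,
#'   `final`, `rule_fired` (one of `agreement`, `linear_wins`,
#'   `geometric_wins`, `tie_break`).
#' @export
manual_ensemble <- function(pred_a, pred_b, per_class_acc_a, per_class_acc_b,
                            overall_a = NA_real_, overall_b = NA_real_,
                            fruit_id = NULL) {
  pred_a <- as.character(pred_a)
  pred_b <- as.character(pred_b)
  if (length(pred_a) != length(pred_b)) {
    abort("`pred_a` and `pred_b` must have equal length")
  }
  acc_a <- as_acc_lookup(per_class_acc_a, "per_class_acc_a")
  acc_b <- as_acc_lookup(per_class_acc_b, "per_class_acc_b")
  miss_a <- setdiff(unique(pred_a), names(acc_a))
  miss_b <- setdiff(unique(pred_b), names(acc_b))
  if (length(miss_a) > 0 || length(miss_b) > 0) {
    abort(sprintf("predicted class(es) absent from the accuracy table(s): %s",
                  paste(union(miss_a, miss_b), collapse = ", ")),
          class = "pomometrics_acc_missing")
  }
  a_at <- unname(acc_a[pred_a])
  b_at <- unname(acc_b[pred_b])
  n <- length(pred_a)
  final <- character(n)
  rule <- character(n)
  for (i in seq_len(n)) {
    if (pred_a[i] == pred_b[i]) {
      final[i] <- pred_a[i]; rule[i] <- "agreement"
    } else if (a_at[i] > b_at[i]) {
      final[i] <- pred_a[i]; rule[i] <- "linear_wins"
    } else if (b_at[i] > a_at[i]) {
      final[i] <- pred_b[i]; rule[i] <- "geometric_wins"
    } else {
      rule[i] <- "tie_break"
      final[i] <- if (!is.na(overall_b) && !is.na(overall_a) &&
                      overall_b > overall_a) pred_b[i] else pred_a[i]
    }
  }
  tibble::tibble(
    fruit_id = if (is.null(fruit_id)) sprintf("fruit_%d", seq_len(n)) else as.character(fruit_id),
    pred_linear = pred_a,
    pred_geometric = pred_b,
    acc_linear_at_pred = a_at,
    acc_geometric_at_pred = b_at,
    final = final,
    rule_fired = rule
  )
}

#' Evaluate the manual ensemble on a test set
#'
#' Runs both trained classifiers on their own flavour's test rows (the two
#' tables must describe the same fruit, and both models must come from the
#' same training plan), arbitrates each fruit with [manual_ensemble()]
#' using the models' per-cultivar cross-validation accuracies, and scores
#' the arbitrated predictions.
#'
#' @param model_a,model_b [cross_validate()] fits: slot a on the linear
#'   table, slot b on the geometric table.
#' @param table_a,table_b the corresponding feature tables.
#' @param split the shared [stratified_split()] plan (`NULL` uses all rows).
#' @return an object of class `ensemble_eval`: `decisions` (the
#'   [manual_ensemble()] tibble plus the true cultivar and `correct`),
#'   `confusion`, `metrics`, `accuracy`.
#' @export
evaluate_ensemble <- function(model_a, table_a, model_b, table_b,
                              split = NULL) {
  ta <- take_split(table_a, split, "test")
  tb <- take_split(table_b, split, "test")
  if (!setequal(ta$fruit_id, tb$fruit_id)) {
    abort("the two test tables do not index the same fruit",
          class = "pomometrics_id_mismatch")
  }
  tb <- tb[match(ta$fruit_id, tb$fruit_id), , drop = FALSE]
  if (!identical(ta$cultivar, tb$cultivar)) {
    abort("cultivar labels disagree between the two test tables")
  }
  pred_a <- predict(model_a, ta)
  pred_b <- predict(model_b, tb)
  decisions <- manual_ensemble(
    pred_a, pred_b,
    model_a$per_class_cv_accuracy,
    model_b$per_class_cv_accuracy,
    overall_a = model_a$overall_cv_accuracy,
    overall_b = model_b$overall_cv_accuracy,
    fruit_id = ta$fruit_id
  )
  decisions$cultivar <- ta$cultivar
  decisions$correct <- decisions$final == decisions$cultivar
  classes <- union(union(model_a$classes, model_b$classes), unique(ta$cultivar))
  cm <- confusion_matrix(ta$cultivar, decisions$final, classes = classes)
  structure(
    list(decisions = decisions,
         confusion = cm,
         metrics = confusion_metrics(cm),
         accuracy = mean(decisions$correct)),
    class = "ensemble_eval"
  )
}

#' @export
print.ensemble_eval <- function(x, ...) {
  tab <- table(x$decisions$rule_fired)
  cat(sprintf("Manual ensemble: accuracy %.3f over %d fruit\n",
              x$accuracy, nrow(x$decisions)))
  cat("  rules fired:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ensemble_eval <- function(x, ...) x$decisions

#' @exportS3Method generics::glance
glance.ensemble_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, kappa = x$metrics$kappa,
                 n = nrow(x$decisions),
                 prop_agreement = mean(x$decisions$rule_fired == "agreement"))
}

#' Per-cultivar correct-prediction rates for several methods
#'
#' @param evaluations a named list of evaluation results
#'   ([evaluate()]/[evaluate_ensemble()] objects, or prediction frames with
#'   `fruit_id`, `cultivar` and a prediction column `predicted`/`final`);
#'   all must cover the same test fruit.
#' @return a tibble: one row per cultivar, one column per method holding
#'   the fraction of that cultivar's test fruit predicted correctly.
#' @export
per_cultivar_summary <- function(evaluations) {
  if (length(evaluations) == 0) abort("`evaluations` is empty")
  if (is.null(names(evaluations)) || any(names(evaluations) == "")) {
    abort("`evaluations` must be a *named* list of methods")
  }
  get_preds <- function(e) {
    df <- if (inherits(e, "classification_eval")) e$predictions
          else if (inherits(e, "ensemble_eval")) e$decisions
          else e
    pcol <- intersect(c("predicted", "final"), names(df))[1]
    if (is.na(pcol) || !all(c("fruit_id", "cultivar") %in% names(df))) {
      abort("each evaluation needs fruit_id, cultivar and a predicted/final column")
    }
    tibble::tibble(fruit_id = df$fruit_id, cultivar = df$cultivar,
                   correct = df[[pcol]] == df$cultivar)
  }
  preds <- lapply(evaluations, get_preds)
  ref <- sort(preds[[1]]$fruit_id)
  for (p in preds[-1]) {
    if (!identical(sort(p$fruit_id), ref)) {
      abort("evaluations do not share the same test fruit",
            class = "pomometrics_id_mismatch")
    }
  }
  out <- NULL
  for (nm in names(preds)) {
    s <- preds[[nm]] |>
      dplyr::group_by(.data$cultivar) |>
      dplyr::summarise(!!nm := mean(.data$correct), .groups = "drop")
    out <- if (is.null(out)) s else dplyr::left_join(out, s, by = "cultivar")
  }
  out
}

#' Confusion matrix as row percentages
#'
#' The heat-map format: each reference row rescaled to percentages of that
#' cultivar's test fruit.
#'
#' @param cm a [confusion_matrix()].
#' @return a numeric matrix of percentages (rows sum to 100 where the
#'   reference class occurs).
#' @export
confusion_percentages <- function(cm) {
  m <- unclass(cm)
  rs <- rowSums(m)
  sweep(m, 1, ifelse(rs > 0, rs, 1), `/`) * 100
}
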