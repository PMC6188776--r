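# End-to-end orchestration: from a study (synthetic or loaded from fixture
# files) to the three feature tables, and from feature tables to trained
# classifiers, test evaluations and the manual ensemble.

#' Extract the three analysis datasets from a study
#'
#' The full geometric + linear morphometrics feature pipeline:
#' \enumerate{
#'   \item the two digitisation replicates of each view are averaged in the
#'     raw image frame (both digitise the same photograph);
#'   \item all fruit x view configurations enter one joint generalized
#'     Procrustes superimposition;
#'   \item each fruit's two superimposed views are averaged
#'     ([average_views()]) into one shape (re-normalized to unit centroid
#'     size), and its centroid size is the mean of the two views' original
#'     centroid sizes;
#'   \item shape PCA over the fruit shapes yields the geometric shape
#'     descriptors;
#'   \item per-image RGB means are reduced to the first colour principal
#'     component; calyx and eye outline polygons give their areas;
#'   \item the linear, geometric and kitchen-sink feature tables are
#'     assembled.
#' }
#'
#' @param study a [generate_study()] result or a compatible list with
#'   `fruit`, `landmarks`, `outlines`, `rgb`.
#' @param gpa_tol,gpa_max_iter superimposition controls (see [gpa()]).
#' @return an object of class `study_features`: list with `linear`,
#'   `geometric`, `kitchen_sink` feature tables plus the intermediate
#'   `gpa`, `shape_pca`, `colour`, `centroid_sizes`, `areas`.
#' @export
study_features <- function(study, gpa_tol = 1e-8, gpa_max_iter = 100L) {
  lmk <- study$landmarks
  # replicate average per (fruit, view): both digitisations share one image
  per_view <- lmk |>
    dplyr::group_by(.data$fruit_id, .data$view, .data$landmark) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop") |>
    dplyr::arrange(.data$fruit_id, .data$view, .data$landmark)

  g <- gpa(per_view, tol = gpa_tol, max_iter = gpa_max_iter)

  fruit_ids <- unique(per_view$fruit_id)
  aligned <- g$aligned
  fruit_shapes <- dplyr::bind_rows(lapply(fruit_ids, function(fid) {
    views <- aligned[aligned$fruit_id == fid, ]
    vn <- unique(views$view)
    if (length(vn) != 2L) {
      abort(sprintf("fruit %s does not have exactly 2 views", fid))
    }
    m <- average_views(views[views$view == vn[1], ],
                       views[views$view == vn[2], ], same_frame = TRUE)
    # project the average back onto the unit-centroid-size shape sphere, so
    # fruit shapes stay proper Procrustes coordinates (the average of two
    # unit-size configurations is slightly smaller than unit size)
    m <- center_config(m) / centroid_size(m)
    tibble::tibble(fruit_id = fid, landmark = seq_len(nrow(m)),
                   x = m[, 1], y = m[, 2])
  }))
  attr(fruit_shapes, "procrustes_frame") <- TRUE

  cs <- g$centroid_sizes |>
    dplyr::group_by(.data$fruit_id) |>
    dplyr::summarise(centroid_size = mean(.data$centroid_size), .groups = "drop")

  pca <- shape_pca(fruit_shapes)
  colour <- colour_pc1(study$rgb)

  areas <- study$outlines |>
    dplyr::group_by(.data$fruit_id, .data$kind) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(area = polygon_area(df[order(df$vertex), c("x", "y")]))
    }) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "kind", values_from = "area") |>
    dplyr::rename(calyx_area = "calyx", eye_area = "eye")

  labels <- study$fruit[c("fruit_id", "cultivar")]
  linear <- assemble_linear(study$fruit, colour, areas, labels)
  geometric <- assemble_geometric(study$fruit, colour, areas, pca, cs, labels)
  structure(
    list(
      linear = linear,
      geometric = geometric,
      kitchen_sink = concat_kitchen_sink(linear, geometric),
      gpa = g,
      shape_pca = pca,
      colour = colour,
      centroid_sizes = cs,
      areas = areas
    ),
    class = "study_features"
  )
}

#' @export
print.study_features <- function(x, ...) {
  cat(sprintf("Study features: %d fruit; linear %d, geometric %d, kitchen-sink %d columns\n",
              nrow(x$linear), length(feature_cols(x$linear)),
              length(feature_cols(x$geometric)),
              length(feature_cols(x$kitchen_sink))))
  cat(sprintf("  shape PCA retained %d components; colour PC1 explains %.1f%% of variance\n",
              x$shape_pca$n_retained, 100 * explained_fraction(x$colour)))
  invisible(x)
}

#' Procrustes ANOVA of digitisation error for a study
#'
#' Treats every photographed image (fruit x view) as the individual and its
#' two digitisations as replicates, and decomposes the Procrustes variance
#' accordingly.  A large F = MS(individual)/MS(error) means digitisation
#' error is negligible next to real among-image shape variation.
#'
#' @param study a study object with a `landmarks` frame (fruit_id, view,
#'   replicate, landmark, x, y).
#' @param ... passed to [procrustes_anova()].
#' @return a [procrustes_anova()] table.
#' @export
digitisation_error_anova <- function(study, ...) {
  lmk <- study$landmarks
  lmk$image_id <- paste(lmk$fruit_id, lmk$view, sep = "_")
  procrustes_anova(lmk[c("image_id", "replicate", "landmark", "x", "y")],
                   individual = "image_id", replicate = "replicate", ...)
}

#' Train, evaluate and ensemble classifiers over the three datasets
#'
#' The complete comparison the package exists for: one shared stratified
#' 75/25 split; repeated cross-validation of a linear-dataset classifier
#' and a geometric-dataset classifier (optionally a kitchen-sink
#' classifier); test-set evaluation of each; and the manual ensemble of
#' the linear and geometric classifiers.
#'
#' @param features a [study_features()] result (or a list with `linear`,
#'   `geometric` and optionally `kitchen_sink` feature tables).
#' @param classifier_linear,classifier_geometric,classifier_kitchen_sink
#'   classifier ids or [classifier_spec()]s; `classifier_kitchen_sink =
#'   NULL` skips the kitchen-sink arm.
#' @param split_seed seed of the shared [stratified_split()].
#' @param cv_seed seed of the shared resampling plan.
#' @param repeats,folds the cross-validation design.
#' @param train_fraction passed to [stratified_split()].
#' @return an object of class `study_analysis`: the split plan, the
#'   trained classifiers (`models`), the test evaluations (`evals`,
#'   including `$ensemble`), and a `summary` tibble of CV and test
#'   accuracy/kappa per method.
#' @export
run_study_analysis <- function(features,
                               classifier_linear = "pda",
                               classifier_geometric = "fsrf",
                               classifier_kitchen_sink = NULL,
                               split_seed = 1L, cv_seed = 1L,
                               repeats = 3L, folds = 10L,
                               train_fraction = 0.75) {
  split <- stratified_split(features$linear, train_fraction = train_fraction,
                            seed = split_seed)
  models <- list(
    linear = cross_validate(classifier_linear, features$linear, split,
                            repeats = repeats, folds = folds, seed = cv_seed),
    geometric = cross_validate(classifier_geometric, features$geometric, split,
                               repeats = repeats, folds = folds, seed = cv_seed)
  )
  evals <- list(
    linear = evaluate(models$linear, features$linear, split),
    geometric = evaluate(models$geometric, features$geometric, split)
  )
  if (!is.null(classifier_kitchen_sink) && !is.null(features$kitchen_sink)) {
    models$kitchen_sink <- cross_validate(classifier_kitchen_sink,
                                          features$kitchen_sink, split,
                                          repeats = repeats, folds = folds,
                                          seed = cv_seed)
    evals$kitchen_sink <- evaluate(models$kitchen_sink, features$kitchen_sink,
                                   split)
  }
  evals$ensemble <- evaluate_ensemble(models$linear, features$linear,
                                      models$geometric, features$geometric,
                                      split)
  summary <- dplyr::bind_rows(lapply(names(evals), function(nm) {
    e <- evals[[nm]]
    tibble::tibble(
      method = nm,
      cv_accuracy = if (nm %in% names(models)) models[[nm]]$overall_cv_accuracy else NA_real_,
      cv_kappa = if (nm %in% names(models)) models[[nm]]$overall_cv_kappa else NA_real_,
      test_accuracy = e$accuracy,
      test_kappa = e$metrics$kappa
    )
  }))
  structure(
    list(split = split, models = models, evals = evals, summary = summary),
    class = "study_analysis"
  )
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("Study analysis (shared split, shared resampling plan)\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.study_analysis <- function(x, ...) x$summary

#' Re-run the harness on deposited feature tables
#'
#' Reproduction mode: loads a linear and a geometric morphometrics dataset
#' from deposited files (CSV or XLSX; column names adapted via `aliases`),
#' rebuilds the kitchen-sink concatenation, and runs
#' [run_study_analysis()] with a fresh stratified 75/25 split.  Because the
#' original partition and fold seeds are unpublished, results are expected
#' to land near — not on — previously reported values.
#'
#' @param linear_path,geometric_path deposited dataset files.
#' @param aliases column-name alias table passed to [read_feature_table()].
#' @param label_col cultivar label column name.
#' @param ... passed to [run_study_analysis()].
#' @return a `study_analysis` object.
#' @export
reproduce_study_analysis <- function(linear_path, geometric_path,
                                     aliases = NULL, label_col = "cultivar",
                                     ...) {
  linear <- read_feature_table(linear_path, "linear", label_col = label_col,
                               aliases = aliases)
  geometric <- read_feature_table(geometric_path, "geometric",
                                  label_col = label_col, aliases = aliases)
  features <- list(linear = linear, geometric = geometric,
                   kitchen_sink = concat_kitchen_sink(linear, geometric))
  run_study_analysis(features, ...)
}
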