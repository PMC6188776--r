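# Assembly of the three analysis datasets (linear, geometric, kitchen-sink)
# from measurements, colour, outline areas and shape descriptors.

#' First principal component of fruit colour
#'
#' Averages each fruit's per-image RGB means, then performs a PCA across
#' fruit on the three channel means and retains the first component as the
#' overall colour measurement.  The component is oriented so that redder
#' fruit (larger red minus green) score positive.  If all fruit have
#' identical colour the component is undefined: the result is flagged
#' degenerate and all scores are 0.
#'
#' @param rgb_means a data frame with columns `fruit_id`, `r`, `g`, `b`
#'   (one row per image; multiple images per fruit are averaged first).
#' @return an object of class `colour_summary`: a tibble with `fruit_id`
#'   and `colour_pc1` (zero mean over the fitted set), carrying attributes
#'   `explained_fraction`, `loadings` and `degenerate`.
#' @export
colour_pc1 <- function(rgb_means) {
  need <- c("fruit_id", "r", "g", "b")
  if (!is.data.frame(rgb_means) || !all(need %in% names(rgb_means))) {
    abort("`rgb_means` needs columns fruit_id, r, g, b")
  }
  if (nrow(rgb_means) == 0L) abort("`rgb_means` is empty")
  chans <- as.matrix(rgb_means[c("r", "g", "b")])
  if (anyNA(chans) || any(chans < 0) || any(chans > 255)) {
    abort("RGB channel values must lie in [0, 255]")
  }
  per_fruit <- rgb_means |>
    dplyr::group_by(.data$fruit_id) |>
    dplyr::summarise(r = mean(.data$r), g = mean(.data$g), b = mean(.data$b),
                     .groups = "drop")
  m <- as.matrix(per_fruit[c("r", "g", "b")])
  centered <- scale(m, scale = FALSE)
  total_var <- sum(apply(m, 2, var))
  if (total_var < 1e-12) {
    out <- tibble::tibble(fruit_id = per_fruit$fruit_id, colour_pc1 = 0)
    attr(out, "explained_fraction") <- NA_real_
    attr(out, "degenerate") <- TRUE
    attr(out, "loadings") <- NULL
    class(out) <- c("colour_summary", class(out))
    return(out)
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  loading <- pc$rotation[, 1]
  # sign convention: redder fruit score positive
  redness <- m[, "r"] - m[, "g"]
  if (sum(scores * (redness - mean(redness))) < 0) {
    scores <- -scores
    loading <- -loading
  }
  out <- tibble::tibble(fruit_id = per_fruit$fruit_id, colour_pc1 = unname(scores))
  attr(out, "explained_fraction") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  attr(out, "degenerate") <- FALSE
  attr(out, "loadings") <- loading
  class(out) <- c("colour_summary", class(out))
  out
}

#' Fraction of colour variance explained by the first component
#' @param colour a [colour_pc1()] result.
#' @export
explained_fraction <- function(colour) {
  attr(colour, "explained_fraction", exact = TRUE)
}

check_matching_ids <- function(sources) {
  ids <- lapply(sources, function(s) sort(unique(s$fruit_id)))
  ref <- ids[[1]]
  for (i in seq_along(ids)[-1]) {
    extra <- setdiff(ids[[i]], ref)
    missing <- setdiff(ref, ids[[i]])
    if (length(extra) > 0 || length(missing) > 0) {
      bad <- union(extra, missing)
      abort(sprintf(
        "fruit present in one source but not another (%s vs %s): %s",
        names(sources)[1], names(sources)[i],
        paste(head(bad, 10), collapse = ", ")),
        class = "pomometrics_id_mismatch")
    }
  }
  invisible(TRUE)
}

join_feature_sources <- function(base, ...) {
  extra <- list(...)
  out <- base
  for (e in extra) out <- dplyr::left_join(out, e, by = "fruit_id")
  out
}

#' Assemble the linear morphometrics dataset
#'
#' Six classical features per fruit: maximum length, maximum diameter,
#' weight, the first colour principal component, calyx area and calyx
#' "eye" aperture area, in that fixed column order.
#'
#' @param measurements data frame with `fruit_id`, `max_length`,
#'   `max_diameter`, `weight`.
#' @param colour a [colour_pc1()] result (or any frame with `fruit_id`,
#'   `colour_pc1`).
#' @param areas data frame with `fruit_id`, `calyx_area`, `eye_area`.
#' @param labels data frame with `fruit_id`, `cultivar`.
#' @return a `feature_table` of flavour `"linear"`; row order follows
#'   `measurements`.
#' @export
assemble_linear <- function(measurements, colour, areas, labels) {
  need <- c("fruit_id", "max_length", "max_diameter", "weight")
  if (!all(need %in% names(measurements))) {
    abort("`measurements` needs fruit_id, max_length, max_diameter, weight")
  }
  for (src in list(colour = colour, areas = areas, labels = labels)) {
    if (!"fruit_id" %in% names(src)) abort("every source needs a fruit_id column")
  }
  check_matching_ids(list(measurements = measurements, colour = colour,
                          areas = areas, labels = labels))
  out <- join_feature_sources(
    measurements[need],
    tibble::as_tibble(colour)[c("fruit_id", "colour_pc1")],
    areas[c("fruit_id", "calyx_area", "eye_area")],
    labels[c("fruit_id", "cultivar")]
  )
  miss <- which(!stats::complete.cases(out))
  if (length(miss) > 0) {
    abort(sprintf("missing values for fruit: %s",
                  paste(head(out$fruit_id[miss], 10), collapse = ", ")))
  }
  new_feature_table(
    out[c("fruit_id", "cultivar", "max_length", "max_diameter", "weight",
          "colour_pc1", "calyx_area", "eye_area")],
    "linear"
  )
}

#' Assemble the geometric morphometrics dataset
#'
#' Per fruit: weight, colour PC1, calyx and eye areas, every retained shape
#' principal component score, and centroid size, in that fixed column
#' order.
#'
#' @inheritParams assemble_linear
#' @param shape_scores shape PC scores per fruit: a [shape_pca()] fit whose
#'   configurations are identified by `fruit_id`, or a frame with
#'   `fruit_id` and `shape_pc_<i>` columns (possibly none when shape
#'   variance is zero).
#' @param centroid_sizes data frame with `fruit_id`, `centroid_size`.
#' @return a `feature_table` of flavour `"geometric"`.
#' @export
assemble_geometric <- function(measurements, colour, areas, shape_scores,
                               centroid_sizes, labels) {
  if (inherits(shape_scores, "shape_pca")) shape_scores <- shape_scores$scores
  if (!all(c("fruit_id", "weight") %in% names(measurements))) {
    abort("`measurements` needs fruit_id and weight")
  }
  if (!"fruit_id" %in% names(shape_scores)) {
    abort("`shape_scores` must identify configurations by fruit_id")
  }
  check_matching_ids(list(measurements = measurements, colour = colour,
                          areas = areas, shape_scores = shape_scores,
                          centroid_sizes = centroid_sizes, labels = labels))
  pc_cols <- sort_shape_cols(grep("^shape_pc_[0-9]+$", names(shape_scores),
                                  value = TRUE))
  out <- join_feature_sources(
    measurements[c("fruit_id", "weight")],
    tibble::as_tibble(colour)[c("fruit_id", "colour_pc1")],
    areas[c("fruit_id", "calyx_area", "eye_area")],
    tibble::as_tibble(shape_scores)[c("fruit_id", pc_cols)],
    centroid_sizes[c("fruit_id", "centroid_size")],
    labels[c("fruit_id", "cultivar")]
  )
  miss <- which(!stats::complete.cases(out))
  if (length(miss) > 0) {
    abort(sprintf("missing values for fruit: %s",
                  paste(head(out$fruit_id[miss], 10), collapse = ", ")))
  }
  new_feature_table(
    out[c("fruit_id", "cultivar", "weight", "colour_pc1", "calyx_area",
          "eye_area", pc_cols, "centroid_size")],
    "geometric"
  )
}

#' Concatenate the linear and geometric datasets ("kitchen sink")
#'
#' The naive union of both feature sets: the four columns the flavours
#' share (weight, colour PC1, calyx area, eye area) are verified to be
#' numerically identical and included once; all other columns are appended.
#'
#' @param linear,geometric feature tables of the respective flavours over
#'   the same fruit.
#' @return a `feature_table` of flavour `"kitchen_sink"`.
#' @export
concat_kitchen_sink <- function(linear, geometric) {
  if (!identical(table_flavour(linear), "linear") ||
      !identical(table_flavour(geometric), "geometric")) {
    abort("arguments must be feature tables of flavour 'linear' and 'geometric'")
  }
  if (!identical(linear$fruit_id, geometric$fruit_id)) {
    check_matching_ids(list(linear = linear, geometric = geometric))
    geometric <- geometric[match(linear$fruit_id, geometric$fruit_id), ]
  }
  if (!identical(linear$cultivar, geometric$cultivar)) {
    abort("cultivar labels disagree between the linear and geometric tables")
  }
  shared <- c("weight", "colour_pc1", "calyx_area", "eye_area")
  for (cn in shared) {
    if (max(abs(linear[[cn]] - geometric[[cn]])) > 1e-9) {
      abort(sprintf("shared column `%s` differs between the two tables", cn),
            class = "pomometrics_shared_col")
    }
  }
  pc_cols <- sort_shape_cols(grep("^shape_pc_[0-9]+$", names(geometric),
                                  value = TRUE))
  out <- dplyr::bind_cols(
    linear[c("fruit_id", "cultivar", "max_length", "max_diameter")],
    linear[shared],
    geometric[c(pc_cols, "centroid_size")]
  )
  new_feature_table(
    out[c("fruit_id", "cultivar", "max_length", "max_diameter", shared,
          pc_cols, "centroid_size")],
    "kitchen_sink"
  )
}
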