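# Internal representation helpers.
#
# The user-facing currency for landmark data is a tidy "landmark frame": a
# data frame with one row per digitised landmark, columns `landmark` (ordinal
# position within the configuration), `x`, `y`, and any number of identifier
# columns (fruit_id, view, replicate, ...).  A *configuration* is the set of
# rows sharing one combination of identifier values.  Geometry code works on
# plain k x 2 matrices internally.

LANDMARK_COLS <- c("landmark", "x", "y")

#' Names of the six apple landmarks, in their fixed semantic order
#'
#' Order: crown-left, crown-right, calyx, pedicel, shoulder-left,
#' shoulder-right.  All landmark frames produced by this package use this
#' ordering for `landmark` 1..6.
#' @export
apple_landmark_names <- c(
  "crown_left", "crown_right", "calyx", "pedicel",
  "shoulder_left", "shoulder_right"
)

is_landmark_frame <- function(df) {
  is.data.frame(df) && all(LANDMARK_COLS %in% names(df))
}

landmark_id_cols <- function(df) {
  setdiff(names(df), LANDMARK_COLS)
}

#' Coerce a single configuration to a k x 2 coordinate matrix
#'
#' Accepts a numeric matrix with two columns, or a data frame with `x` and
#' `y` columns (ordered by `landmark` when present).
#' @param config matrix or data frame holding one landmark configuration.
#' @return a k x 2 numeric matrix.
#' @keywords internal
as_landmark_matrix <- function(config) {
  if (is.matrix(config)) {
    if (ncol(config) != 2L) {
      abort("a landmark configuration matrix must have exactly 2 columns (x, y)")
    }
    m <- config
  } else if (is.data.frame(config)) {
    if (!all(c("x", "y") %in% names(config))) {
      abort("a landmark configuration data frame needs `x` and `y` columns")
    }
    if ("landmark" %in% names(config)) {
      config <- config[order(config$landmark), , drop = FALSE]
    }
    m <- cbind(config$x, config$y)
  } else {
    abort("cannot interpret this object as a landmark configuration")
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    abort("landmark coordinates must be finite")
  }
  dimnames(m) <- NULL
  m
}

# Split a landmark frame into a named list of k x 2 matrices, keyed by the
# identifier columns.  Key order follows first appearance in the frame.
lm_split <- function(df) {
  if (!is_landmark_frame(df)) {
    abort("expected a landmark frame with columns `landmark`, `x`, `y`")
  }
  id_cols <- landmark_id_cols(df)
  if (length(id_cols) == 0L) {
    keys <- tibble::tibble(.config = "config_1")
    mats <- list(config_1 = as_landmark_matrix(df))
    return(list(keys = keys, mats = mats, id_cols = character()))
  }
  key_str <- do.call(paste, c(unname(df[id_cols]), sep = "\r"))
  key_levels <- unique(key_str)
  pieces <- split(df[c("landmark", "x", "y")], factor(key_str, levels = key_levels))
  mats <- lapply(pieces, as_landmark_matrix)
  k <- vapply(mats, nrow, integer(1))
  if (length(unique(k)) > 1L) {
    abort("all configurations must have the same number of landmarks")
  }
  keys <- dplyr::distinct(df[id_cols])
  list(keys = tibble::as_tibble(keys), mats = unname(mats), id_cols = id_cols)
}

# Rebuild a tidy landmark frame from keys + a list of matrices.
lm_bind <- function(keys, mats) {
  k <- nrow(mats[[1]])
  out <- keys[rep(seq_len(nrow(keys)), each = k), , drop = FALSE]
  coords <- do.call(rbind, mats)
  out$landmark <- rep.int(seq_len(k), length(mats))
  out$x <- coords[, 1]
  out$y <- coords[, 2]
  tibble::as_tibble(out)
}

center_config <- function(m) {
  sweep(m, 2, colMeans(m))
}
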