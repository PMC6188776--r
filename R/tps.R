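# File formats: TPS landmark files (tpsDig dialect), feature-table CSV/XLSX.

#' Read a TPS landmark file
#'
#' Parses the tpsDig dialect: each record is a `LM=n` header followed by `n`
#' whitespace-separated `x y` coordinate lines and optional `IMAGE=`, `ID=`
#' and `SCALE=` lines.  When a `SCALE=` line is present its factor is
#' applied multiplicatively to that record's coordinates.  Record order is
#' preserved and no record is ever silently dropped: malformed records are
#' an error naming the record index.
#'
#' @param path path to a TPS file.
#' @return a tidy landmark frame: one row per landmark with columns
#'   `record` (1-based record index), `id`, `image`, `landmark`, `x`, `y`.
#' @seealso [write_tps()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) abort(sprintf("TPS file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  out <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    line <- lines[i]
    if (line == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", line, ignore.case = TRUE)) {
      abort(sprintf("TPS parse error before record %d: expected 'LM=' header, got '%s'",
                    rec + 1L, line))
    }
    rec <- rec + 1L
    n_lm <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", line, ignore.case = TRUE)))
    if (is.na(n_lm) || n_lm < 1L) {
      abort(sprintf("TPS record %d: malformed LM= header '%s'", rec, line))
    }
    i <- i + 1L
    coords <- matrix(NA_real_, n_lm, 2)
    for (j in seq_len(n_lm)) {
      if (i > length(lines) || grepl("^(LM|IMAGE|ID|SCALE)\\s*=", lines[i], ignore.case = TRUE)) {
        abort(sprintf("TPS record %d: declared LM=%d but found only %d coordinate line(s)",
                      rec, n_lm, j - 1L))
      }
      parts <- strsplit(lines[i], "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2L || anyNA(vals)) {
        abort(sprintf("TPS record %d, landmark %d: non-numeric coordinate line '%s'",
                      rec, j, lines[i]))
      }
      coords[j, ] <- vals
      i <- i + 1L
    }
    id <- NA_character_; image <- NA_character_; scale <- 1
    while (i <= length(lines) && lines[i] != "" &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      l <- lines[i]
      if (grepl("^IMAGE\\s*=", l, ignore.case = TRUE)) {
        image <- sub("^IMAGE\\s*=\\s*", "", l, ignore.case = TRUE)
      } else if (grepl("^ID\\s*=", l, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", l, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", l, ignore.case = TRUE)) {
        scale <- suppressWarnings(as.numeric(sub("^SCALE\\s*=\\s*", "", l, ignore.case = TRUE)))
        if (is.na(scale)) abort(sprintf("TPS record %d: malformed SCALE line '%s'", rec, l))
      } else {
        abort(sprintf("TPS record %d: unrecognized line '%s'", rec, l))
      }
      i <- i + 1L
    }
    out[[rec]] <- tibble::tibble(
      record = rec, id = id, image = image,
      landmark = seq_len(n_lm),
      x = coords[, 1] * scale, y = coords[, 2] * scale
    )
  }
  if (length(out) == 0L) {
    return(tibble::tibble(record = integer(), id = character(),
                          image = character(), landmark = integer(),
                          x = double(), y = double()))
  }
  dplyr::bind_rows(out)
}

#' Write landmark configurations to a TPS file
#'
#' One `LM=` record per configuration, with coordinates printed at a fixed
#' 9 decimal places so that a write/read round trip preserves values far
#' below digitisation precision, followed by `IMAGE=` and `ID=` lines when
#' the frame carries `image`/`id` columns.  Output is byte-deterministic
#' for identical input.
#'
#' @param landmarks a tidy landmark frame (see [read_tps()]); identifier
#'   columns other than `image`/`id` are folded into the `ID=` line.
#'   An empty frame (or `NULL`) produces an empty file.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(landmarks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (is.null(landmarks) || nrow(landmarks) == 0L) return(invisible(path))
  sp <- lm_split(landmarks)
  keys <- sp$keys
  for (i in seq_along(sp$mats)) {
    m <- sp$mats[[i]]
    writeLines(sprintf("LM=%d", nrow(m)), con)
    writeLines(sprintf("%.9f %.9f", m[, 1], m[, 2]), con)
    if ("image" %in% names(keys) && !is.na(keys$image[i])) {
      writeLines(paste0("IMAGE=", keys$image[i]), con)
    }
    id_cols <- setdiff(names(keys), "image")
    if (length(id_cols) > 0) {
      idv <- paste(vapply(id_cols, function(cn) as.character(keys[[cn]][i]),
                          character(1)), collapse = "_")
      writeLines(paste0("ID=", idv), con)
    } else {
      writeLines(paste0("ID=", i - 1L), con)
    }
  }
  invisible(path)
}

# --- feature tables ---------------------------------------------------------

flavour_feature_cols <- function(flavour, n_shape_pcs = NULL) {
  base <- c("weight", "colour_pc1", "calyx_area", "eye_area")
  switch(
    flavour,
    linear = c("max_length", "max_diameter", base),
    geometric = c(base,
                  if (!is.null(n_shape_pcs) && n_shape_pcs > 0)
                    paste0("shape_pc_", seq_len(n_shape_pcs)),
                  "centroid_size"),
    kitchen_sink = c("max_length", "max_diameter", base,
                     if (!is.null(n_shape_pcs) && n_shape_pcs > 0)
                       paste0("shape_pc_", seq_len(n_shape_pcs)),
                     "centroid_size"),
    abort(sprintf("unknown dataset flavour '%s'", flavour))
  )
}

new_feature_table <- function(df, flavour) {
  df <- tibble::as_tibble(df)
  attr(df, "flavour") <- flavour
  class(df) <- c("feature_table", class(df))
  df
}

#' Feature columns of a feature table (everything but identifiers/label)
#' @param table a feature table.
#' @return character vector of feature column names.
#' @export
feature_cols <- function(table) {
  setdiff(names(table), c("fruit_id", "cultivar"))
}

#' Dataset flavour of a feature table
#' @param table a feature table.
#' @return `"linear"`, `"geometric"` or `"kitchen_sink"` (or `NA`).
#' @export
table_flavour <- function(table) {
  fl <- attr(table, "flavour", exact = TRUE)
  if (is.null(fl)) NA_character_ else fl
}

#' Read a feature table from CSV or XLSX
#'
#' Loads one dataset flavour (`linear`, `geometric` or `kitchen_sink`) from
#' a delimited or spreadsheet file, checks that the cultivar label column
#' and every flavour-required numeric column are present, and drops (with a
#' report) any row containing missing values.  Because deposited
#' spreadsheets rarely advertise their column headers, an `aliases` table
#' maps file column names to the canonical names used here.
#'
#' @param path a `.csv`, `.xlsx` or `.xls` file.
#' @param flavour which dataset this file holds: `"linear"` requires
#'   `max_length`, `max_diameter`, `weight`, `colour_pc1`, `calyx_area`,
#'   `eye_area`; `"geometric"` requires `weight`, `colour_pc1`,
#'   `calyx_area`, `eye_area`, `centroid_size` plus at least one
#'   `shape_pc_<i>` column; `"kitchen_sink"` the union of both.
#' @param label_col name of the cultivar label column (after aliasing).
#' @param aliases optional named character vector, `c(file_name = "canonical_name")`.
#' @return a `feature_table` tibble: `fruit_id` (generated when absent),
#'   `cultivar`, then the flavour's feature columns.  Rows dropped for
#'   missing values are reported via a warning and recorded in the
#'   `"dropped_rows"` attribute.
#' @export
read_feature_table <- function(path, flavour = c("linear", "geometric", "kitchen_sink"),
                               label_col = "cultivar", aliases = NULL) {
  flavour <- match.arg(flavour)
  if (!file.exists(path)) abort(sprintf("feature table file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("reading XLSX feature tables requires the readxl package")
    }
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!is.null(aliases)) {
    hit <- names(raw) %in% names(aliases)
    names(raw)[hit] <- unname(aliases[names(raw)[hit]])
  }
  if (!label_col %in% names(raw)) {
    abort(sprintf("label column `%s` not found in %s", label_col, path))
  }
  shape_cols <- grep("^shape_pc_[0-9]+$", names(raw), value = TRUE)
  required <- flavour_feature_cols(flavour, n_shape_pcs = 0L)
  required <- setdiff(required, "centroid_size")
  if (flavour %in% c("geometric", "kitchen_sink")) {
    required <- c(required, "centroid_size")
    if (length(shape_cols) == 0L) {
      abort(sprintf("%s flavour requires at least one shape_pc_<i> column in %s",
                    flavour, path))
    }
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("feature table %s is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  feat <- c(setdiff(required, "centroid_size"),
            sort_shape_cols(shape_cols),
            intersect("centroid_size", required))
  for (cn in feat) {
    if (!is.numeric(raw[[cn]])) {
      coerced <- suppressWarnings(as.numeric(raw[[cn]]))
      bad <- which(!is.na(raw[[cn]]) & is.na(coerced))
      if (length(bad) > 0) {
        abort(sprintf("column `%s` has non-numeric cell(s) at row(s) %s",
                      cn, paste(head(bad, 5), collapse = ", ")))
      }
      raw[[cn]] <- coerced
    }
  }
  fruit_id <- if ("fruit_id" %in% names(raw)) as.character(raw$fruit_id) else {
    sprintf("row_%04d", seq_len(nrow(raw)))
  }
  out <- tibble::tibble(fruit_id = fruit_id,
                        cultivar = as.character(raw[[label_col]]))
  for (cn in feat) out[[cn]] <- raw[[cn]]
  dropped <- which(!stats::complete.cases(out))
  if (length(dropped) > 0) {
    warn(sprintf("dropping %d row(s) with missing values: %s",
                 length(dropped), paste(head(dropped, 10), collapse = ", ")))
    out <- out[-dropped, , drop = FALSE]
  }
  out <- new_feature_table(out, flavour)
  attr(out, "dropped_rows") <- dropped
  out
}

sort_shape_cols <- function(cols) {
  if (length(cols) == 0) return(character())
  cols[order(as.integer(sub("^shape_pc_", "", cols)))]
}

#' Write a feature table to CSV (plus a sidecar flavour file)
#'
#' Fixed column order and plain CSV formatting make repeated exports of the
#' same table byte-identical.  The dataset flavour is recorded next to the
#' CSV in `<path>.json`.
#'
#' @param table a feature table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  fl <- table_flavour(table)
  if (!is.na(fl)) {
    writeLines(sprintf("{\"flavour\": \"%s\"}", fl), paste0(path, ".json"))
  }
  invisible(path)
}
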