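# Synthetic study generator.
#
# Emulates the sampling design of a cultivar-identification imaging study:
# n cultivars x m fruit, each fruit photographed six times (calyx end,
# pedicel end, four side views of which two carry unique shape information),
# each shape-informative view digitised twice.  Cultivars get their own mean
# shape, linear-trait means and red/green colour balance; fruit add
# within-cultivar noise; digitisation replicates add much smaller noise.

#' Configuration for a synthetic cultivar study
#'
#' All noise magnitudes on landmarks are expressed in shape units, i.e. as
#' fractions of the template's (unit) centroid size.  `within_cultivar_cv`
#' is the coefficient of variation of the multiplicative lognormal noise on
#' linear traits, and also drives outline-area and colour noise so that a
#' zero value collapses every fruit of a cultivar onto identical features.
#'
#' With `complementary_mode = TRUE` the first half of the cultivars differ
#' only in mean shape (sharing one common set of linear-trait means, colour
#' and image scale) while the second half differ only in their
#' length/diameter means (sharing the template mean shape): the regime in
#' which a shape classifier and a linear-trait classifier succeed on
#' disjoint halves of the label set.
#'
#' @param n_cultivars,fruit_per_cultivar study size.
#' @param landmark_noise_sd within-cultivar landmark noise sd (shape units).
#' @param digitisation_noise_sd replicate-digitisation noise sd (shape units).
#' @param between_cultivar_shape_sd sd of cultivar mean-shape displacement
#'   from the template (shape units).
#' @param linear_trait_means_range named list of `c(lo, hi)` ranges for the
#'   per-cultivar means of `max_length` (mm), `max_diameter` (mm),
#'   `weight` (g).
#' @param within_cultivar_cv coefficient of variation of within-cultivar
#'   trait noise.
#' @param colour_mix_range range of the per-cultivar red fraction (0 = pure
#'   green skin, 1 = pure red).
#' @param complementary_mode see above.
#' @param seed master seed; per-fruit substreams are derived
#'   deterministically from it, so the whole study (and any single fruit)
#'   is bit-reproducible.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cultivars = 27L,
                             fruit_per_cultivar = 20L,
                             landmark_noise_sd = 0.02,
                             digitisation_noise_sd = 0.002,
                             between_cultivar_shape_sd = 0.015,
                             linear_trait_means_range = list(
                               max_length = c(50, 90),
                               max_diameter = c(55, 95),
                               weight = c(100, 250)
                             ),
                             within_cultivar_cv = 0.06,
                             colour_mix_range = c(0.1, 0.9),
                             complementary_mode = FALSE,
                             seed = 1L) {
  stopifnot(length(n_cultivars) == 1, length(fruit_per_cultivar) == 1)
  if (n_cultivars < 1 || fruit_per_cultivar < 1) {
    abort("n_cultivars and fruit_per_cultivar must be positive")
  }
  for (nm in c("landmark_noise_sd", "digitisation_noise_sd",
               "between_cultivar_shape_sd", "within_cultivar_cv")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      abort(sprintf("`%s` must be a single non-negative number", nm))
    }
  }
  need <- c("max_length", "max_diameter", "weight")
  if (!all(need %in% names(linear_trait_means_range))) {
    abort("linear_trait_means_range needs max_length, max_diameter and weight ranges")
  }
  if (length(colour_mix_range) != 2 || any(colour_mix_range < 0) ||
      any(colour_mix_range > 1) || colour_mix_range[1] > colour_mix_range[2]) {
    abort("colour_mix_range must be an increasing pair within [0, 1]")
  }
  structure(
    list(
      n_cultivars = as.integer(n_cultivars),
      fruit_per_cultivar = as.integer(fruit_per_cultivar),
      landmark_noise_sd = landmark_noise_sd,
      digitisation_noise_sd = digitisation_noise_sd,
      between_cultivar_shape_sd = between_cultivar_shape_sd,
      linear_trait_means_range = linear_trait_means_range,
      within_cultivar_cv = within_cultivar_cv,
      colour_mix_range = colour_mix_range,
      complementary_mode = isTRUE(complementary_mode),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# deterministic substream seeds (< 2^31, never 0)
derive_seed <- function(seed, i) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + i * 16807) %% 2147483647 + 1)
}

#' The six-landmark apple silhouette template
#'
#' A fixed side-view template with landmarks in the package's semantic
#' order (crown-left, crown-right, calyx, pedicel, shoulder-left,
#' shoulder-right), bilaterally symmetric about the vertical axis, centered
#' at the origin and normalized to unit centroid size.  Only the
#' six-landmark scheme is supported.
#'
#' @param n_landmarks must be 6.
#' @return a tidy configuration: tibble with `landmark`, `name`, `x`, `y`.
#' @export
apple_template <- function(n_landmarks = 6L) {
  if (!identical(as.integer(n_landmarks), 6L)) {
    abort("only the 6-landmark apple scheme is supported")
  }
  raw <- rbind(
    c(-0.55, -0.90),  # crown_left
    c( 0.55, -0.90),  # crown_right
    c( 0.00, -0.75),  # calyx
    c( 0.00,  1.00),  # pedicel
    c(-0.85,  0.55),  # shoulder_left
    c( 0.85,  0.55)   # shoulder_right
  )
  raw <- center_config(raw)
  raw <- raw / centroid_size(raw)
  tibble::tibble(
    landmark = 1:6,
    name = apple_landmark_names,
    x = raw[, 1], y = raw[, 2]
  )
}

#' Draw per-cultivar parameter bundles
#'
#' Samples, from the configuration's master seed, each cultivar's mean
#' shape (template plus Gaussian displacement), linear-trait means, red
#' fraction and relative image scale.  In complementary mode the first
#' `ceiling(n/2)` cultivars share one common set of linear-trait means and
#' colour (differing only in shape) while the rest share the template mean
#' shape and differ only in length/diameter means, which are spread evenly
#' across their configured ranges.
#'
#' @param config a [synthetic_config()].
#' @return a tibble with one row per cultivar: `cultivar`, `mean_shape`
#'   (list column of 6 x 2 matrices), `max_length`, `max_diameter`,
#'   `weight`, `red_fraction`, `size_scale`.
#' @export
sample_cultivar_means <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cultivars
  template <- as_landmark_matrix(apple_template())
  rng <- config$linear_trait_means_range
  withr::with_seed(derive_seed(config$seed, 1L), {
    shapes <- lapply(seq_len(n), function(i) {
      template + matrix(rnorm(12, 0, config$between_cultivar_shape_sd), 6, 2)
    })
    lens <- runif(n, rng$max_length[1], rng$max_length[2])
    dias <- runif(n, rng$max_diameter[1], rng$max_diameter[2])
    wts  <- runif(n, rng$weight[1], rng$weight[2])
    reds <- runif(n, config$colour_mix_range[1], config$colour_mix_range[2])
    if (config$complementary_mode) {
      n_shape <- ceiling(n / 2)
      shape_half <- seq_len(n_shape)
      linear_half <- setdiff(seq_len(n), shape_half)
      # shape-only half: one common linear phenotype
      lens[shape_half] <- mean(rng$max_length)
      dias[shape_half] <- mean(rng$max_diameter)
      wts[shape_half]  <- mean(rng$weight)
      # linear-only half: one common mean shape, traits spread across range
      for (i in linear_half) shapes[[i]] <- template
      m <- length(linear_half)
      if (m > 0) {
        lens[linear_half] <- rng$max_length[1] +
          (seq_len(m) - 0.5) / m * diff(rng$max_length)
        dias[linear_half] <- rng$max_diameter[1] +
          (rev(seq_len(m)) - 0.5) / m * diff(rng$max_diameter)
        wts[linear_half] <- mean(rng$weight)
      }
      # colour and scale carry no cultivar signal in this mode
      reds <- rep(mean(config$colour_mix_range), n)
    }
    ref_size <- mean(rng$max_length) + mean(rng$max_diameter)
    scale_rel <- if (config$complementary_mode) rep(1, n) else (lens + dias) / ref_size
    tibble::tibble(
      cultivar = sprintf("c%02d", seq_len(n)),
      mean_shape = shapes,
      max_length = lens,
      max_diameter = dias,
      weight = wts,
      red_fraction = reds,
      size_scale = scale_rel
    )
  })
}

# image-frame constants (pixels): 4928 x 3264 sensor, fruit spanning ~1100 px
PX_SCALE <- 1100
IMG_CENTER <- c(2464, 1632)

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

regular_polygon <- function(n, radius, center) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' Generate one synthetic fruit
#'
#' Draws, from a deterministic per-fruit substream, the fruit's linear
#' traits (lognormal multiplicative noise around the cultivar means, with a
#' shared size factor so length, diameter and weight co-vary), its two
#' shape-informative side views (cultivar mean shape plus independent
#' landmark noise, embedded in the image frame with a random small rotation
#' and translation at the fruit's pixel scale), two digitisation replicates
#' per view (additive noise of sd `digitisation_noise_sd`), calyx and eye
#' outline polygons whose radii scale with the fruit's image scale, and six
#' per-image RGB means mixing pure red and pure green by the cultivar red
#' fraction.
#'
#' @param cultivar_params one row of [sample_cultivar_means()] output.
#' @param fruit_index index of this fruit within the whole study.
#' @param config the [synthetic_config()].
#' @return a list with `record` (one-row tibble: fruit_id, cultivar,
#'   max_length, max_diameter, weight), `landmarks` (tidy frame, 4
#'   configurations: 2 views x 2 replicates), `outlines`, `rgb`.
#' @export
generate_fruit <- function(cultivar_params, fruit_index, config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- cultivar_params
  cv <- config$within_cultivar_cv
  sdlog <- sqrt(log(1 + cv^2))
  fruit_id <- sprintf("f%04d", fruit_index)
  withr::with_seed(derive_seed(config$seed, 100L + fruit_index), {
    size_factor <- rlnorm(1, -sdlog^2 / 2, sdlog)
    resid <- rlnorm(3, -(sdlog / 2)^2 / 2, sdlog / 2)
    max_length <- p$max_length * size_factor * resid[1]
    max_diameter <- p$max_diameter * size_factor * resid[2]
    weight <- p$weight * size_factor^3 * resid[3]

    px <- PX_SCALE * p$size_scale *
      (if (config$complementary_mode) rlnorm(1, -sdlog^2 / 2, sdlog) else size_factor)

    mean_shape <- p$mean_shape[[1]]
    lmk <- list()
    for (v in c("side0", "side90")) {
      view_shape <- mean_shape +
        matrix(rnorm(12, 0, config$landmark_noise_sd), 6, 2)
      theta <- rnorm(1, 0, 0.05)
      shift <- IMG_CENTER + rnorm(2, 0, 40)
      pix <- sweep(view_shape %*% rot2(theta) * px, 2, shift, `+`)
      for (d in c("d1", "d2")) {
        digit <- pix + matrix(rnorm(12, 0, config$digitisation_noise_sd * px), 6, 2)
        lmk[[paste(v, d, sep = "_")]] <- tibble::tibble(
          fruit_id = fruit_id, view = v, replicate = d,
          landmark = 1:6, x = digit[, 1], y = digit[, 2]
        )
      }
    }

    calyx_r <- 0.16 * px * rlnorm(1, -sdlog^2 / 2, sdlog)
    eye_r <- 0.06 * px * rlnorm(1, -sdlog^2 / 2, sdlog)
    calyx <- regular_polygon(12, calyx_r, IMG_CENTER)
    eye <- regular_polygon(8, eye_r, IMG_CENTER)
    outlines <- dplyr::bind_rows(
      tibble::tibble(fruit_id = fruit_id, kind = "calyx",
                     vertex = 1:12, x = calyx[, 1], y = calyx[, 2]),
      tibble::tibble(fruit_id = fruit_id, kind = "eye",
                     vertex = 1:8, x = eye[, 1], y = eye[, 2])
    )

    red_f <- min(max(p$red_fraction + rnorm(1, 0, cv), 0), 1)
    base <- c(red_f * 255, (1 - red_f) * 255, 20)
    rgb <- t(vapply(1:6, function(img) {
      pmin(pmax(base + rnorm(3, 0, 130 * cv), 0), 255)
    }, double(3)))
    rgb_tbl <- tibble::tibble(
      fruit_id = fruit_id, image = 1:6,
      r = rgb[, 1], g = rgb[, 2], b = rgb[, 3]
    )

    list(
      record = tibble::tibble(
        fruit_id = fruit_id, cultivar = p$cultivar,
        max_length = max_length, max_diameter = max_diameter, weight = weight
      ),
      landmarks = dplyr::bind_rows(lmk),
      outlines = outlines,
      rgb = rgb_tbl
    )
  })
}

#' Generate a complete synthetic study
#'
#' Assembles [generate_fruit()] output for every cultivar and fruit into a
#' study object mirroring what a real imaging campaign plus digitisation
#' would deposit: a truth table, linear measurements, landmark files and
#' per-image colour means.  Identical `(config, seed)` produce bit-identical
#' studies.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_study`: list with `fruit`
#'   (fruit_id, cultivar, max_length, max_diameter, weight), `landmarks`
#'   (tidy frame: fruit_id, view, replicate, landmark, x, y), `outlines`,
#'   `rgb`, `cultivar_params`, `config`, `n_images` (six photographs per
#'   fruit: calyx end, pedicel end, four side views).
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  params <- sample_cultivar_means(config)
  n_fruit <- config$n_cultivars * config$fruit_per_cultivar
  idx <- 0L
  pieces <- vector("list", n_fruit)
  for (ci in seq_len(config$n_cultivars)) {
    for (fi in seq_len(config$fruit_per_cultivar)) {
      idx <- idx + 1L
      pieces[[idx]] <- generate_fruit(params[ci, ], idx, config)
    }
  }
  structure(
    list(
      fruit = dplyr::bind_rows(lapply(pieces, `[[`, "record")),
      landmarks = dplyr::bind_rows(lapply(pieces, `[[`, "landmarks")),
      outlines = dplyr::bind_rows(lapply(pieces, `[[`, "outlines")),
      rgb = dplyr::bind_rows(lapply(pieces, `[[`, "rgb")),
      cultivar_params = params,
      config = config,
      n_images = 6L * n_fruit
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic cultivar study: %d cultivars x %d fruit = %d fruit\n",
              x$config$n_cultivars, x$config$fruit_per_cultivar, nrow(x$fruit)))
  cat(sprintf("  %d images, %d landmark configurations (2 views x 2 digitisations)\n",
              x$n_images, nrow(dplyr::distinct(x$landmarks[c("fruit_id", "view", "replicate")]))))
  invisible(x)
}

#' Write a synthetic study to fixture files
#'
#' One TPS file per (view, digitisation replicate), plus CSV tables for
#' measurements, per-image RGB means, outline vertices and the cultivar
#' truth.  Output is byte-deterministic for a given study.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in c("side0", "side90")) {
    for (d in c("d1", "d2")) {
      sub <- dplyr::filter(study$landmarks, .data$view == v, .data$replicate == d)
      sub <- tibble::tibble(
        image = paste0(sub$fruit_id, "_", v, ".jpg"),
        id = sub$fruit_id,
        landmark = sub$landmark, x = sub$x, y = sub$y
      )
      write_tps(sub, file.path(dir, sprintf("landmarks_%s_%s.tps", v, d)))
    }
  }
  wr <- function(df, name) {
    df <- as.data.frame(df)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(col) sprintf("%.9f", col))
    write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(study$fruit[c("fruit_id", "max_length", "max_diameter", "weight")],
     "measurements.csv")
  wr(study$rgb, "rgb_means.csv")
  wr(study$outlines, "outlines.csv")
  write.csv(as.data.frame(study$fruit[c("fruit_id", "cultivar")]),
            file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
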