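test_that("apple template is centered, unit-size, bilaterally symmetric", {
  tpl <- apple_template()
  m <- as_mat(tpl)
  expect_equal(nrow(m), 6L)
  expect_lt(max(abs(colMeans(m))), 1e-12)
  expect_equal(centroid_size(m), 1, tolerance = 1e-12)

  # mirror about the vertical axis and swap the left/right landmark labels
  mirrored <- m %*% diag(c(-1, 1))
  swap <- c(2, 1, 3, 4, 6, 5)
  expect_coords_equal(mirrored[swap, ], m, tol = 1e-12)

  expect_error(apple_template(5), "6-landmark")
})

test_that("synthetic_config validates its fields", {
  expect_error(synthetic_config(landmark_noise_sd = -0.1), "non-negative")
  expect_error(synthetic_config(colour_mix_range = c(0.5, 1.3)), "within")
  expect_error(synthetic_config(n_cultivars = 0), "positive")
})

test_that("cultivar parameter sampling: zero variance, complementary structure, determinism", {
  cfg0 <- synthetic_config(n_cultivars = 3, between_cultivar_shape_sd = 0, seed = 5)
  means0 <- sample_cultivar_means(cfg0)
  tpl <- as_mat(apple_template())
  for (m in means0$mean_shape) expect_coords_equal(m, tpl, tol = 1e-12)

  cfgc <- synthetic_config(n_cultivars = 4, complementary_mode = TRUE, seed = 5)
  mc <- sample_cultivar_means(cfgc)
  # first half: identical linear-trait means, distinct shapes
  expect_equal(mc$max_length[1], mc$max_length[2])
  expect_equal(mc$weight[1], mc$weight[2])
  expect_gt(max(abs(mc$mean_shape[[1]] - mc$mean_shape[[2]])), 0)
  # second half: identical mean shapes, distinct linear traits
  expect_coords_equal(mc$mean_shape[[3]], mc$mean_shape[[4]], tol = 1e-12)
  expect_false(mc$max_length[3] == mc$max_length[4])

  expect_identical(sample_cultivar_means(cfgc), mc)
})

test_that("fruit generation: replicate and trait noise collapse at zero", {
  cfg <- synthetic_config(n_cultivars = 2, fruit_per_cultivar = 3,
                          digitisation_noise_sd = 0, seed = 11)
  means <- sample_cultivar_means(cfg)
  fr <- generate_fruit(means[1, ], 1L, cfg)
  for (v in c("side0", "side90")) {
    reps <- split(fr$landmarks[fr$landmarks$view == v, ],
                  fr$landmarks$replicate[fr$landmarks$view == v])
    expect_coords_equal(reps[[1]], reps[[2]], tol = 1e-12)
  }

  cfg_cv0 <- synthetic_config(n_cultivars = 2, fruit_per_cultivar = 4,
                              within_cultivar_cv = 0, seed = 11)
  st <- generate_study(cfg_cv0)
  traits <- split(st$fruit[c("max_length", "max_diameter", "weight")],
                  st$fruit$cultivar)
  for (tr in traits) {
    expect_equal(max(tr$max_length) - min(tr$max_length), 0)
    expect_equal(max(tr$weight) - min(tr$weight), 0)
  }
})

test_that("study counts follow the sampling design", {
  cfg <- synthetic_config(seed = 42)  # 27 cultivars x 20 fruit
  st <- generate_study(cfg)
  expect_equal(nrow(st$fruit), 540L)
  expect_equal(st$n_images, 3240L)
  n_configs <- nrow(dplyr::distinct(st$landmarks[c("fruit_id", "view", "replicate")]))
  expect_equal(n_configs, 4L * 540L)
  expect_true(all(st$fruit$cultivar %in% sprintf("c%02d", 1:27)))

  tiny <- generate_study(synthetic_config(n_cultivars = 2, fruit_per_cultivar = 1,
                                          seed = 1))
  expect_equal(nrow(tiny$fruit), 2L)
  expect_setequal(tiny$fruit$cultivar, c("c01", "c02"))
})

test_that("identical config and seed give identical studies and fixture files", {
  cfg <- synthetic_config(n_cultivars = 3, fruit_per_cultivar = 2, seed = 23)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$fruit, s2$fruit)
  expect_identical(s1$landmarks, s2$landmarks)
  expect_identical(s1$rgb, s2$rgb)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(s1, d1)
  write_study(s2, d2)
  files <- list.files(d1)
  expect_gt(length(files), 4L)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }

  # per-fruit substreams: fruit 1 is unaffected by the study being larger
  cfg_big <- synthetic_config(n_cultivars = 3, fruit_per_cultivar = 5, seed = 23)
  means <- sample_cultivar_means(cfg)
  expect_identical(generate_fruit(means[1, ], 1L, cfg),
                   generate_fruit(means[1, ], 1L, cfg_big))
})

test_that("zero-noise studies collapse to identical features and perfect CV", {
  cfg <- synthetic_config(n_cultivars = 3, fruit_per_cultivar = 6,
                          landmark_noise_sd = 0, digitisation_noise_sd = 0,
                          within_cultivar_cv = 0, seed = 31)
  st <- generate_study(cfg)
  fe <- study_features(st)
  # within a cultivar every fruit is identical in every feature
  for (fl in c("linear", "geometric")) {
    tab <- fe[[fl]]
    spread <- tab |>
      dplyr::group_by(cultivar) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric),
                                     ~ max(.x) - min(.x)))
    expect_lt(max(as.matrix(spread[-1])), 1e-8)
  }
  # any classifier reaches perfect cross-validated accuracy
  split <- stratified_split(fe$linear, seed = 1)
  for (id in c("knn", "cart")) {
    fit <- cross_validate(id, fe$linear, split, repeats = 1, folds = 3, seed = 2)
    expect_equal(fit$overall_cv_accuracy, 1.0)
  }
  fitg <- cross_validate("knn", fe$geometric, split, repeats = 1, folds = 3, seed = 2)
  expect_equal(fitg$overall_cv_accuracy, 1.0)
  ev <- evaluate(fitg, fe$geometric, split)
  expect_equal(ev$accuracy, 1.0)
})

test_that("digitisation noise 1/10 of landmark noise gives a large ANOVA F ratio", {
  cfg <- synthetic_config(n_cultivars = 5, fruit_per_cultivar = 4,
                          landmark_noise_sd = 0.02,
                          digitisation_noise_sd = 0.002, seed = 61)
  st <- generate_study(cfg)
  an <- digitisation_error_anova(st)
  f_ratio <- an$table$ms[1] / an$table$ms[2]
  expect_gt(f_ratio, 10)
  expect_lt(an$table$ms[2] / an$table$ms[1], 0.2)

  # cross-check against direct variance bookkeeping on the aligned shapes
  g <- gpa(st$landmarks |>
             dplyr::mutate(image_id = paste(fruit_id, view, sep = "_")) |>
             dplyr::select(image_id, replicate, landmark, x, y))
  sp <- pomometrics:::lm_split(g$aligned)
  flat <- t(vapply(sp$mats, as.vector, double(12)))
  ind <- sp$keys$image_id
  im <- rowsum(flat, ind) / 2
  ss_err <- sum((flat - im[ind, ])^2)
  expect_equal(an$table$ss[2], ss_err, tolerance = 1e-6)
})
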