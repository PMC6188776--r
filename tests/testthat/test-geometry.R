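test_that("centroid size: closed form, homogeneity, direct-summation oracle", {
  square <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(centroid_size(square), 2 * sqrt(2), tolerance = 1e-12)

  cfg <- rand_config(11)
  for (s in c(0.5, 3.7)) {
    expect_equal(centroid_size(cfg * s), s * centroid_size(cfg), tolerance = 1e-10)
  }

  # brute force: explicit sum of squared landmark-centroid distances
  ctr <- colMeans(cfg)
  brute <- sqrt(sum(vapply(seq_len(nrow(cfg)), function(i) {
    (cfg[i, 1] - ctr[1])^2 + (cfg[i, 2] - ctr[2])^2
  }, double(1))))
  expect_equal(centroid_size(cfg), brute, tolerance = 1e-12)

  expect_error(centroid_size(matrix(1, 6, 2)), class = "pomometrics_degenerate")
})

test_that("ordinary Procrustes alignment recovers exact and mirrored matches", {
  cfg <- rand_config(21)
  moved <- sim_transform(cfg, theta = 37 * pi / 180, shift = c(5, -2))
  expect_lt(opa_align(cfg, moved)$residual, 1e-18)

  mirrored <- sim_transform(cfg, reflect = TRUE)
  expect_gt(opa_align(cfg, mirrored, allow_reflection = FALSE)$residual, 1e-6)
  expect_lt(opa_align(cfg, mirrored, allow_reflection = TRUE)$residual, 1e-18)
})

test_that("OPA residual matches a grid search over rotation angle", {
  for (seed in c(31, 32)) {
    moving <- rand_config(seed)
    target <- rand_config(seed + 100)
    fit <- opa_align(moving, target)

    xt <- sweep(target, 2, colMeans(target))
    xm <- sweep(moving, 2, colMeans(moving)) *
      (centroid_size(target) / centroid_size(moving))
    thetas <- seq(0, 2 * pi, by = 1e-4)
    resid <- vapply(thetas, function(th) sum((xm %*% rot_mat(th) - xt)^2),
                    double(1))
    expect_equal(fit$residual, min(resid), tolerance = 1e-5)
    expect_lte(fit$residual, min(resid) + 1e-10)
  }
})

test_that("GPA superimposes exact copies and satisfies its frame invariants", {
  cfg <- rand_config(41)
  mats <- list(
    a = cfg,
    b = sim_transform(cfg, theta = 1.1, scale = 2.5, shift = c(10, 4)),
    c = sim_transform(cfg, theta = -0.4, scale = 0.2, shift = c(-3, 7))
  )
  fit <- gpa(configs_frame(mats))
  sp <- pomometrics:::lm_split(fit$aligned)
  for (m in sp$mats) {
    expect_lt(max(abs(colMeans(m))), 1e-9)            # centered
    expect_equal(centroid_size(m), 1, tolerance = 1e-9)  # unit size
    expect_coords_equal(m, sp$mats[[1]], tol = 1e-9)  # identical shapes align
  }
  expect_coords_equal(fit$mean_shape, sp$mats[[1]], tol = 1e-9)
  expect_equal(centroid_size(fit$mean_shape), 1, tolerance = 1e-9)
  expect_equal(fit$centroid_sizes$centroid_size,
               vapply(mats, centroid_size, double(1)), ignore_attr = TRUE)
})

test_that("GPA output is invariant to similarity transforms and input order", {
  mats <- lapply(1:5, function(i) rand_config(50 + i))
  names(mats) <- paste0("cfg", 1:5)
  base <- gpa(configs_frame(mats), tol = 1e-12, max_iter = 500)

  withr::with_seed(99, {
    moved <- lapply(mats, function(m) {
      sim_transform(m, theta = runif(1, 0, 2 * pi), scale = runif(1, 0.3, 4),
                    shift = rnorm(2, sd = 20))
    })
  })
  fit_moved <- gpa(configs_frame(moved), tol = 1e-12, max_iter = 500)
  expect_coords_equal(fit_moved$mean_shape, base$mean_shape, tol = 1e-9)
  expect_lt(max(abs(as_mat(fit_moved$aligned) - as_mat(base$aligned))), 1e-9)

  perm <- c(3, 1, 5, 2, 4)
  fit_perm <- gpa(configs_frame(mats[perm]), tol = 1e-12, max_iter = 500)
  expect_coords_equal(fit_perm$mean_shape, base$mean_shape, tol = 1e-9)
})

test_that("GPA agrees with an independent alternating-minimization oracle", {
  skip_if_not_installed("vegan")
  mats <- lapply(1:5, function(i) rand_config(70 + i))
  names(mats) <- paste0("cfg", 1:5)
  # vegan's rotation solver permits improper rotations, so compare in the
  # reflection-allowed regime on both sides
  fit <- gpa(configs_frame(mats), tol = 1e-12, allow_reflection = TRUE)
  my_stat <- sum(vapply(mats, procrustes_distance, double(1),
                        target = fit$mean_shape, allow_reflection = TRUE))

  # oracle: alternate vegan::procrustes rotations with mean re-estimation
  unit <- lapply(mats, function(m) {
    c <- sweep(m, 2, colMeans(m))
    c / sqrt(sum(c^2))
  })
  consensus <- unit[[1]]
  aligned <- unit
  repeat {
    aligned <- lapply(aligned, function(m) {
      vegan::procrustes(consensus, m, scale = FALSE)$Yrot
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    if (sqrt(sum((new_mean - consensus)^2)) < 1e-12) break
    consensus <- new_mean
  }
  oracle_stat <- sum(vapply(aligned, function(m) {
    sqrt(vegan::procrustes(consensus, m, scale = FALSE)$ss)
  }, double(1)))
  expect_equal(my_stat, oracle_stat, tolerance = 1e-6)
})

test_that("view averaging is the landmark-wise mean and reduces noise", {
  cfg <- rand_config(81)
  expect_error(average_views(cfg, cfg), "same_frame")
  expect_coords_equal(average_views(cfg, cfg, same_frame = TRUE), cfg)

  a <- rbind(c(1, 0), c(0, 0), c(2, 2))
  b <- rbind(c(0, 1), c(0, 0), c(2, 2))
  expect_equal(average_views(a, b, same_frame = TRUE)[1, ], c(0.5, 0.5))

  # averaging two noisy views halves the error variance; error grows with sd
  template <- as_mat(apple_template())
  mean_dist <- function(noise_sd, seed) {
    withr::with_seed(seed, {
      mean(vapply(1:200, function(i) {
        v1 <- template + matrix(rnorm(12, 0, noise_sd), 6, 2)
        v2 <- template + matrix(rnorm(12, 0, noise_sd), 6, 2)
        procrustes_distance(average_views(v1, v2, same_frame = TRUE), template)
      }, double(1)))
    })
  }
  d_small <- mean_dist(0.01, 1)
  d_large <- mean_dist(0.04, 1)
  expect_lt(d_small, 0.02)
  expect_lt(d_small, d_large)
})

test_that("Procrustes ANOVA decomposes variance and flags clean replicates", {
  # zero digitisation noise: replicate SS is exactly the GPA residual noise, ~0
  mats <- list()
  withr::with_seed(7, {
    for (i in 1:6) {
      m <- as_mat(apple_template()) + matrix(rnorm(12, 0, 0.05), 6, 2)
      mats[[paste0("ind", i, "_r1")]] <- m
      mats[[paste0("ind", i, "_r2")]] <- sim_transform(m, theta = 0.3, shift = c(2, 2))
    }
  })
  df <- configs_frame(mats)
  df$individual <- sub("_r[12]$", "", df$config)
  df$replicate <- sub("^.*_", "", df$config)
  df$config <- NULL
  an <- procrustes_anova(df, individual = "individual", replicate = "replicate")
  expect_lt(an$table$ss[2], 1e-15)
  expect_equal(sum(an$table$ss), an$total_ss, tolerance = 1e-12)
  expect_equal(an$table$ms, an$table$ss / an$table$df)
  expect_equal(an$table$df, c((6 - 1) * 8, 6 * 1 * 8))
})

test_that("Procrustes ANOVA sums of squares match direct per-cell bookkeeping", {
  withr::with_seed(17, {
    mats <- list()
    for (i in 1:8) {
      m <- as_mat(apple_template()) + matrix(rnorm(12, 0, 0.04), 6, 2)
      for (r in 1:2) {
        mats[[sprintf("i%02d_r%d", i, r)]] <- m + matrix(rnorm(12, 0, 0.004), 6, 2)
      }
    }
  })
  df <- configs_frame(mats)
  df$individual <- sub("_r[12]$", "", df$config)
  df$replicate <- sub("^.*_", "", df$config)
  an <- procrustes_anova(df[, setdiff(names(df), "config")],
                         individual = "individual", replicate = "replicate")

  # independent bookkeeping: joint GPA, then explicit deviation sums
  g <- gpa(df[c("individual", "replicate", "landmark", "x", "y")], tol = 1e-10)
  sp <- pomometrics:::lm_split(g$aligned)
  flat <- t(vapply(sp$mats, as.vector, double(12)))
  ind <- sp$keys$individual
  grand <- colMeans(flat)
  ss_ind <- 0; ss_err <- 0; ss_tot <- 0
  for (lev in unique(ind)) {
    rows <- flat[ind == lev, , drop = FALSE]
    im <- colMeans(rows)
    ss_ind <- ss_ind + nrow(rows) * sum((im - grand)^2)
    ss_err <- ss_err + sum(sweep(rows, 2, im)^2)
    ss_tot <- ss_tot + sum(sweep(rows, 2, grand)^2)
  }
  expect_equal(an$table$ss[1], ss_ind, tolerance = 1e-9)
  expect_equal(an$table$ss[2], ss_err, tolerance = 1e-9)
  expect_equal(an$total_ss, ss_tot, tolerance = 1e-9)
})

test_that("shape PCA: degenerate input, variance completeness, eigensolver oracle", {
  cfg <- rand_config(91)
  same <- configs_frame(list(a = cfg, b = cfg, c = cfg, d = cfg))
  fit_same <- shape_pca(gpa(same))
  expect_identical(fit_same$n_retained, 0L)

  mats <- lapply(1:10, function(i) rand_config(200 + i))
  names(mats) <- paste0("cfg", 1:10)
  g <- gpa(configs_frame(mats), tol = 1e-12, max_iter = 500)
  pca <- shape_pca(g)

  # eigenvalue sum equals total variance of the centered coordinates
  expect_equal(sum(pca$eigenvalues), pca$total_variance, tolerance = 1e-9)
  # retained components carry all of it (discarded ones are numerically zero)
  expect_equal(sum(pca$eigenvalues[seq_len(pca$n_retained)]) / sum(pca$eigenvalues),
               1, tolerance = 1e-9)
  # superimposition removes 4 dof: never more than 2k - 4 = 8 components
  expect_lte(pca$n_retained, 8L)
  expect_lte(sum(pca$eigenvalues > 1e-12 * max(pca$eigenvalues)), 8L)

  # oracle: eigen() on the covariance of the flattened aligned coordinates,
  # after the same tangent projection at the mean direction
  sp <- pomometrics:::lm_split(g$aligned)
  flat <- t(vapply(sp$mats, as.vector, double(12)))
  u <- colMeans(flat); u <- u / sqrt(sum(u^2))
  flat <- flat - outer(drop(flat %*% u), u)
  ev <- eigen(stats::cov(flat), symmetric = TRUE)$values
  nr <- pca$n_retained
  expect_equal(pca$eigenvalues[seq_len(nr)], ev[seq_len(nr)], tolerance = 1e-8)

  # scores are centered
  sc <- as.matrix(pca$scores[paste0("shape_pc_", seq_len(pca$n_retained))])
  expect_lt(max(abs(colMeans(sc))), 1e-9)
})

test_that("Procrustes distance behaves like a metric near zero", {
  a <- rand_config(301)
  b <- rand_config(302)
  expect_lt(procrustes_distance(a, a), 1e-12)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
               tolerance = 1e-9)
})

test_that("polygon area: closed forms, triangulation oracle, invalid input", {
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)

  # random convex octagon: fan triangulation from vertex 1
  withr::with_seed(5, {
    th <- sort(runif(8, 0, 2 * pi))
    v <- cbind(3 * cos(th), 2 * sin(th))
  })
  fan <- sum(vapply(2:7, function(i) {
    abs((v[i, 1] - v[1, 1]) * (v[i + 1, 2] - v[1, 2]) -
        (v[i + 1, 1] - v[1, 1]) * (v[i, 2] - v[1, 2])) / 2
  }, double(1)))
  expect_equal(polygon_area(v), fan, tolerance = 1e-9)
  expect_equal(polygon_area(v[rev(seq_len(8)), ]), fan, tolerance = 1e-9)

  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon_area(bowtie), class = "pomometrics_polygon")
})
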