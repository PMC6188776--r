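# Shared test utilities: random configurations, similarity transforms, and
# tidy-frame builders.  All randomness is seeded at the call site.

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

rand_config <- function(seed, k = 6) {
  withr::with_seed(seed, matrix(rnorm(k * 2), k, 2))
}

# apply a similarity transform (rotation, isotropic scale, translation)
sim_transform <- function(m, theta = 0, scale = 1, shift = c(0, 0),
                          reflect = FALSE) {
  if (reflect) m <- m %*% diag(c(-1, 1))
  sweep(m %*% rot_mat(theta) * scale, 2, shift, `+`)
}

# tidy landmark frame from a named list of k x 2 matrices
configs_frame <- function(mats, id_col = "config") {
  dplyr::bind_rows(lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    tibble::tibble(!!id_col := nm, landmark = seq_len(nrow(m)),
                   x = m[, 1], y = m[, 2])
  }))
}

# a small labelled feature table for harness tests: `classes` Gaussian blobs
# in `p` dimensions, `n_per` rows each, blob separation `sep`
blob_table <- function(classes = 4, n_per = 10, p = 3, sep = 4, sd = 1,
                       seed = 1, flavour = "linear") {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(classes * p, sd = sep), classes, p)
    rows <- do.call(rbind, lapply(seq_len(classes), function(ci) {
      centers[rep(ci, n_per), , drop = FALSE] + matrix(rnorm(n_per * p, sd = sd), n_per, p)
    }))
    df <- tibble::as_tibble(as.data.frame(rows))
    names(df) <- paste0("feat_", seq_len(p))
    df <- dplyr::bind_cols(
      tibble::tibble(
        fruit_id = sprintf("f%03d", seq_len(classes * n_per)),
        cultivar = rep(sprintf("c%02d", seq_len(classes)), each = n_per)
      ), df)
    pomometrics:::new_feature_table(df, flavour)
  })
}

expect_coords_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(as_mat(a) - as_mat(b))), tol)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else cbind(x$x, x$y)
}
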