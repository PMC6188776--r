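# Shape computation: centroid size, ordinary and generalized Procrustes
# superimposition, view averaging, Procrustes ANOVA for digitisation error,
# shape PCA, polygon areas.

#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometrics size measure: the square root of the
#' summed squared distances of the landmarks from their centroid.  It is in
#' the same units as the coordinates and scales linearly with the
#' configuration.
#'
#' @param config a landmark configuration: a k x 2 numeric matrix or a data
#'   frame with `x`/`y` (and optionally `landmark`) columns.
#' @return a single non-negative number.
#' @examples
#' centroid_size(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))  # 2 * sqrt(2)
#' @export
centroid_size <- function(config) {
  m <- as_landmark_matrix(config)
  if (nrow(m) < 2L) abort("centroid size needs at least 2 landmarks")
  cs <- sqrt(sum(center_config(m)^2))
  if (cs < 1e-12 * max(1, max(abs(m)))) {
    abort("degenerate configuration: all landmarks coincide",
          class = "pomometrics_degenerate")
  }
  cs
}

# Optimal rotation (2-D, special orthogonal unless reflection allowed) that
# maps centered configuration `xm` onto centered `xt` in the least-squares
# sense; returns the matrix R to use as xm %*% R.
optimal_rotation <- function(xm, xt, allow_reflection = FALSE) {
  s <- svd(crossprod(xm, xt))
  r <- s$u %*% t(s$v)
  reflected <- det(r) < 0
  if (reflected && !allow_reflection) {
    d <- diag(c(1, -1))
    r <- s$u %*% d %*% t(s$v)
    reflected <- FALSE
  }
  list(rotation = r, reflected = reflected)
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Centers both configurations, scales the moving one so its centroid size
#' matches the target's, and rotates it (an orthogonal transform with
#' determinant +1 unless `allow_reflection = TRUE`) to minimize the summed
#' squared distances between corresponding landmarks.
#'
#' @param moving,target landmark configurations with equal landmark counts.
#' @param allow_reflection should an improper rotation (mirror) be permitted?
#' @return a list with elements `aligned` (the transformed moving
#'   configuration, centered at the origin in the target's centered frame),
#'   `residual` (the minimized sum of squared distances), `rotation`,
#'   `scale`, and `reflected`.
#' @export
opa_align <- function(moving, target, allow_reflection = FALSE) {
  xm <- as_landmark_matrix(moving)
  xt <- as_landmark_matrix(target)
  if (nrow(xm) != nrow(xt)) {
    abort("`moving` and `target` must have the same number of landmarks")
  }
  cs_m <- centroid_size(xm)
  cs_t <- centroid_size(xt)
  xm_c <- center_config(xm) * (cs_t / cs_m)
  xt_c <- center_config(xt)
  rot <- optimal_rotation(xm_c, xt_c, allow_reflection)
  aligned <- xm_c %*% rot$rotation
  list(
    aligned = aligned,
    residual = sum((aligned - xt_c)^2),
    rotation = rot$rotation,
    scale = cs_t / cs_m,
    reflected = rot$reflected
  )
}

#' Procrustes distance between two configurations
#'
#' The square root of the minimized summed squared distances after both
#' configurations are centered and scaled to unit centroid size and the
#' first is rotated onto the second (partial Procrustes distance).
#' @inheritParams opa_align
#' @export
procrustes_distance <- function(moving, target, allow_reflection = FALSE) {
  xm <- as_landmark_matrix(moving)
  xt <- as_landmark_matrix(target)
  um <- center_config(xm) / centroid_size(xm)
  ut <- center_config(xt) / centroid_size(xt)
  rot <- optimal_rotation(um, ut, allow_reflection)
  sqrt(sum((um %*% rot$rotation - ut)^2))
}

# Rotate a consensus (and anything sharing its frame) into a canonical
# orientation: principal axes of the consensus, with a 180-degree flip chosen
# so the first landmark with a clearly non-zero first coordinate is positive.
# Makes GPA output invariant to rigid transforms of the inputs.
canonical_rotation <- function(consensus) {
  e <- eigen(crossprod(consensus), symmetric = TRUE)
  v <- e$vectors
  if (det(v) < 0) v[, 2] <- -v[, 2]
  rotated <- consensus %*% v
  pick <- which(abs(rotated[, 1]) > 1e-8)
  flip <- if (length(pick) > 0) {
    rotated[pick[1], 1] < 0
  } else {
    j <- which(abs(rotated[, 2]) > 1e-8)
    length(j) > 0 && rotated[j[1], 2] < 0
  }
  if (flip) v <- -v
  v
}

# Core generalized Procrustes algorithm on a list of k x 2 matrices.
gpa_core <- function(mats, allow_reflection = FALSE, tol = 1e-8,
                     max_iter = 100L) {
  n <- length(mats)
  if (n < 2L) abort("generalized Procrustes analysis needs at least 2 configurations")
  k <- vapply(mats, nrow, integer(1))
  if (length(unique(k)) != 1L) {
    abort("all configurations must have the same number of landmarks")
  }
  sizes <- vapply(mats, centroid_size, double(1))
  unit <- lapply(seq_len(n), function(i) center_config(mats[[i]]) / sizes[i])

  mean_of <- function(lst) {
    m <- Reduce(`+`, lst) / length(lst)
    m <- center_config(m)
    m / sqrt(sum(m^2))
  }

  consensus <- unit[[1]]
  aligned <- unit
  final_change <- Inf
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    aligned <- lapply(aligned, function(m) {
      m %*% optimal_rotation(m, consensus, allow_reflection)$rotation
    })
    new_consensus <- mean_of(aligned)
    final_change <- procrustes_distance(new_consensus, consensus,
                                        allow_reflection = allow_reflection)
    consensus <- new_consensus
    if (final_change < tol) break
    if (iterations >= max_iter) {
      abort(
        sprintf("generalized Procrustes analysis did not converge in %d iterations (last change %.3g)",
                max_iter, final_change),
        class = "pomometrics_gpa_nonconvergence",
        aligned = aligned, consensus = consensus
      )
    }
  }
  # final pass so every configuration is rotated onto the converged consensus
  aligned <- lapply(aligned, function(m) {
    m %*% optimal_rotation(m, consensus, allow_reflection)$rotation
  })
  rot <- canonical_rotation(consensus)
  consensus <- consensus %*% rot
  aligned <- lapply(aligned, function(m) m %*% rot)
  list(
    aligned = aligned,
    consensus = consensus,
    centroid_sizes = sizes,
    iterations = iterations,
    final_change = final_change
  )
}

#' Generalized Procrustes analysis of a set of landmark configurations
#'
#' Iteratively superimposes all configurations on their consensus: each is
#' centered and scaled to unit centroid size, rotated onto the current mean
#' shape, and the mean is re-estimated (and re-normalized to unit centroid
#' size) until it changes by less than `tol` in Procrustes distance.  The
#' output frame is canonicalized to the consensus' principal axes, so the
#' result is invariant (to numerical tolerance) under rigid transforms or
#' relabeling of the input configurations.
#'
#' @param landmarks a tidy landmark frame: one row per landmark with columns
#'   `landmark`, `x`, `y`, and identifier columns (e.g. `fruit_id`, `view`,
#'   `replicate`) whose distinct combinations define the configurations.
#' @param allow_reflection permit improper rotations during fitting.
#' @param tol convergence tolerance on the Procrustes distance between
#'   successive mean shapes.
#' @param max_iter maximum number of superimposition sweeps.
#' @return an object of class `gpa` with components `aligned` (tidy frame of
#'   Procrustes coordinates, unit centroid size and centered per
#'   configuration), `mean_shape` (tidy, unit centroid size),
#'   `centroid_sizes` (tibble of identifier columns plus `centroid_size` in
#'   the original units), `iterations` and `final_change`.
#' @seealso [shape_pca()], [average_views()], [procrustes_anova()]
#' @export
gpa <- function(landmarks, allow_reflection = FALSE, tol = 1e-8,
                max_iter = 100L) {
  sp <- lm_split(landmarks)
  fit <- gpa_core(sp$mats, allow_reflection = allow_reflection, tol = tol,
                  max_iter = max_iter)
  aligned <- lm_bind(sp$keys, fit$aligned)
  attr(aligned, "procrustes_frame") <- TRUE
  cs <- sp$keys
  cs$centroid_size <- fit$centroid_sizes
  structure(
    list(
      aligned = aligned,
      mean_shape = tibble::tibble(
        landmark = seq_len(nrow(fit$consensus)),
        x = fit$consensus[, 1],
        y = fit$consensus[, 2]
      ),
      centroid_sizes = cs,
      iterations = fit$iterations,
      final_change = fit$final_change,
      id_cols = sp$id_cols
    ),
    class = "gpa"
  )
}

#' @export
print.gpa <- function(x, ...) {
  n <- nrow(x$centroid_sizes)
  k <- nrow(x$mean_shape)
  cat(sprintf(
    "Generalized Procrustes fit: %d configurations, %d landmarks\n", n, k))
  cat(sprintf("  converged after %d sweeps (last mean-shape change %.3g)\n",
              x$iterations, x$final_change))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gpa <- function(x, ...) x$aligned

#' @exportS3Method generics::glance
glance.gpa <- function(x, ...) {
  tibble::tibble(
    n_configurations = nrow(x$centroid_sizes),
    n_landmarks = nrow(x$mean_shape),
    iterations = x$iterations,
    final_change = x$final_change
  )
}

#' Average two views of the same fruit in a common Procrustes frame
#'
#' The landmark-wise arithmetic mean of two superimposed configurations of
#' one specimen (e.g. its 0-degree and 90-degree side views), pooling the
#' shape information both views carry.  Both inputs must already live in one
#' common superimposition frame — typically rows of the `aligned` component
#' of a single [gpa()] fit; set `same_frame = TRUE` to assert this.
#'
#' @param view0,view90 the two configurations (matrices or data frames).
#' @param same_frame flag asserting that both views are expressed in the
#'   same Procrustes frame.  Averaging configurations from unrelated frames
#'   is meaningless, so `FALSE` is an error.
#' @return a k x 2 matrix of averaged landmark coordinates.
#' @export
average_views <- function(view0, view90, same_frame = FALSE) {
  if (!isTRUE(same_frame)) {
    abort(paste0("`same_frame` must be TRUE: average_views() only makes sense ",
                 "for configurations in one common superimposition frame"))
  }
  a <- as_landmark_matrix(view0)
  b <- as_landmark_matrix(view90)
  if (nrow(a) != nrow(b)) abort("views must have the same number of landmarks")
  (a + b) / 2
}

#' Procrustes ANOVA for digitisation (measurement) error
#'
#' Decomposes the Procrustes sums of squares of repeatedly digitised
#' configurations into an among-individual component and an
#' among-replicate-within-individual (digitisation error) component, after a
#' joint generalized Procrustes superimposition of all configurations.
#' Degrees of freedom follow the Goodall-style convention: the conventional
#' factor degrees of freedom times the shape-space dimension 2k - 4 for k
#' two-dimensional landmarks.  The F ratio MS(individual)/MS(error) is large
#' when digitisation error is negligible relative to real among-individual
#' shape variation.
#'
#' @param landmarks a tidy landmark frame containing all replicate
#'   digitisations.
#' @param individual,replicate names of the columns identifying the
#'   individual (specimen or image) and the digitisation replicate.
#' @param ... passed to the internal [gpa()] fit (`tol`, `max_iter`, ...).
#' @return an object of class `procrustes_anova`: a list with `table` (a
#'   tibble with terms `individual` and `replicate (error)`: sums of
#'   squares, degrees of freedom, mean squares, F, p), `n_individuals`,
#'   `n_replicates`, `total_ss`.
#' @export
procrustes_anova <- function(landmarks, individual = "fruit_id",
                             replicate = "replicate", ...) {
  if (!is_landmark_frame(landmarks)) {
    abort("expected a landmark frame with columns `landmark`, `x`, `y`")
  }
  miss <- setdiff(c(individual, replicate), names(landmarks))
  if (length(miss) > 0) {
    abort(sprintf("column(s) %s not found in the landmark frame",
                  paste0("`", miss, "`", collapse = ", ")))
  }
  df <- landmarks[c(individual, replicate, LANDMARK_COLS)]
  sp <- lm_split(df)
  ind <- sp$keys[[individual]]
  tab <- table(ind)
  if (length(tab) < 2L) {
    abort("Procrustes ANOVA needs at least 2 individuals")
  }
  r <- unique(as.integer(tab))
  if (length(r) != 1L || r < 2L) {
    abort("every individual must have the same replicate count r >= 2 (balanced design)")
  }
  fit <- gpa_core(sp$mats, ...)
  k <- nrow(fit$consensus)
  flat <- t(vapply(fit$aligned, as.vector, double(2L * k)))
  grand <- colMeans(flat)
  ind_f <- factor(ind, levels = unique(ind))
  ind_means <- rowsum(flat, ind_f) / as.vector(table(ind_f))
  n <- nlevels(ind_f)
  ss_ind <- r * sum(sweep(ind_means, 2, grand)^2)
  ss_err <- sum((flat - ind_means[as.integer(ind_f), , drop = FALSE])^2)
  m <- 2L * k - 4L
  df_ind <- (n - 1L) * m
  df_err <- n * (r - 1L) * m
  ms_ind <- ss_ind / df_ind
  ms_err <- ss_err / df_err
  f <- ms_ind / ms_err
  structure(
    list(
      table = tibble::tibble(
        term = c("individual", "replicate (error)"),
        ss = c(ss_ind, ss_err),
        df = c(df_ind, df_err),
        ms = c(ms_ind, ms_err),
        statistic = c(f, NA_real_),
        p.value = c(pf(f, df_ind, df_err, lower.tail = FALSE), NA_real_)
      ),
      n_individuals = n,
      n_replicates = r,
      n_landmarks = k,
      total_ss = ss_ind + ss_err
    ),
    class = "procrustes_anova"
  )
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat(sprintf("Procrustes ANOVA: %d individuals x %d replicates, %d landmarks\n",
              x$n_individuals, x$n_replicates, x$n_landmarks))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.procrustes_anova <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.procrustes_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$table$statistic[1],
    p.value = x$table$p.value[1],
    ms_ratio_error_over_individual = x$table$ms[2] / x$table$ms[1],
    total_ss = x$total_ss
  )
}

#' Principal component analysis of Procrustes coordinates
#'
#' Eigendecomposition of the covariance of the flattened, superimposed
#' landmark coordinates, computed in Procrustes tangent space: each
#' configuration is first orthogonally projected onto the hyperplane
#' orthogonal to the mean-shape direction (the standard tangent-space
#' linearization; unit-centroid-size shapes live on a curved sphere whose
#' radial direction carries no shape information).  Because
#' superimposition removes 4 degrees of freedom (2 translation, 1
#' rotation, 1 scale), at most 2k - 4 components of k two-dimensional
#' landmarks carry variance; components whose eigenvalue falls below
#' `1e-12` times the largest are dropped.  Each retained component's sign
#' is fixed so its largest-magnitude loading is positive.
#'
#' @param x a [gpa()] fit, or a tidy landmark frame of configurations
#'   already expressed in one common Procrustes frame.
#' @return an object of class `shape_pca`: `scores` (tibble of identifier
#'   columns plus `shape_pc_1` ... `shape_pc_n`), `eigenvalues` (all
#'   non-negative eigenvalues, descending), `components` (orthonormal
#'   loadings for the retained components), `n_retained`, `center`,
#'   `total_variance`.
#' @export
shape_pca <- function(x) {
  if (inherits(x, "gpa")) {
    aligned <- x$aligned
  } else if (is_landmark_frame(x)) {
    aligned <- x
  } else {
    abort("`x` must be a gpa fit or a tidy landmark frame")
  }
  sp <- lm_split(aligned)
  n <- length(sp$mats)
  if (n < 2L) abort("shape PCA needs at least 2 configurations")
  k <- nrow(sp$mats[[1]])
  flat <- t(vapply(sp$mats, as.vector, double(2L * k)))
  # tangent-space projection at the mean direction
  mu <- colMeans(flat)
  mu_norm <- sqrt(sum(mu^2))
  if (mu_norm > 1e-12) {
    u <- mu / mu_norm
    flat <- flat - outer(drop(flat %*% u), u)
  }
  pc <- prcomp(flat, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  total_var <- sum(apply(scale(flat, scale = FALSE), 2, function(v) sum(v^2))) / (n - 1)
  retained <- which(eig > 1e-12 * max(eig) & eig > 0)
  n_retained <- if (max(eig) <= .Machine$double.eps * 10) 0L else length(retained)
  comp <- pc$rotation[, seq_len(n_retained), drop = FALSE]
  scores <- pc$x[, seq_len(n_retained), drop = FALSE]
  if (n_retained > 0) {
    # sign convention: dominant loading of each component is positive
    flips <- vapply(seq_len(n_retained), function(j) {
      l <- comp[, j]
      sign(l[which.max(abs(l))])
    }, double(1))
    comp <- sweep(comp, 2, flips, `*`)
    scores <- sweep(scores, 2, flips, `*`)
    colnames(comp) <- colnames(scores) <- paste0("shape_pc_", seq_len(n_retained))
  }
  score_tbl <- dplyr::bind_cols(sp$keys, tibble::as_tibble(scores))
  structure(
    list(
      scores = score_tbl,
      eigenvalues = eig,
      components = comp,
      n_retained = n_retained,
      center = pc$center,
      total_variance = total_var,
      id_cols = sp$id_cols,
      n_landmarks = k
    ),
    class = "shape_pca"
  )
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("Shape PCA: %d configurations, %d retained components\n",
              nrow(x$scores), x$n_retained))
  if (x$n_retained > 0) {
    pct <- 100 * x$eigenvalues[seq_len(min(x$n_retained, 5))] / sum(x$eigenvalues)
    cat("  leading variance %:", paste(sprintf("%.1f", pct), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.shape_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.shape_pca <- function(x, ...) {
  tibble::tibble(
    n_retained = x$n_retained,
    total_variance = x$total_variance,
    prop_pc1 = if (x$n_retained > 0) x$eigenvalues[1] / sum(x$eigenvalues) else NA_real_
  )
}

# --- polygon areas ----------------------------------------------------------

# do segments p1-p2 and p3-p4 properly intersect (excluding shared endpoints)?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

is_simple_polygon <- function(v) {
  n <- nrow(v)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2L)) {
    last <- if (i == 1L) n - 1L else n
    for (j in seq.int(i + 2L, last)) {
      if (segments_cross(v[idx[i, 1], ], v[idx[i, 2], ],
                         v[idx[j, 1], ], v[idx[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Area of a simple polygon (shoelace formula)
#'
#' Absolute enclosed area of an outline polygon, independent of vertex
#' orientation.  Self-intersecting outlines are rejected.
#'
#' @param outline polygon vertices in order: an n x 2 matrix or a data frame
#'   with `x`/`y` columns, n >= 3.
#' @return the enclosed area in squared coordinate units.
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(outline) {
  v <- if (is.matrix(outline)) outline else {
    if (!all(c("x", "y") %in% names(outline))) {
      abort("an outline data frame needs `x` and `y` columns")
    }
    if ("vertex" %in% names(outline)) outline <- outline[order(outline$vertex), ]
    cbind(outline$x, outline$y)
  }
  storage.mode(v) <- "double"
  if (nrow(v) < 3L) abort("a polygon needs at least 3 vertices")
  if (anyNA(v) || any(!is.finite(v))) abort("polygon vertices must be finite")
  if (!is_simple_polygon(v)) {
    abort("outline polygon is self-intersecting", class = "pomometrics_polygon")
  }
  xs <- v[, 1]; ys <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2
}
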