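# Generalized Procrustes analysis: iterative least-squares removal of
# translation, scale and rotation across a sample of configurations,
# producing centroid sizes and superimposed (optionally tangent-projected)
# shape coordinates.

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard geometric-morphometrics size proxy. It is
#' invariant to rotation and translation and scales linearly with the
#' configuration.
#'
#' @param config A k x 2 coordinate matrix (k >= 2) or a flat 2k vector in
#'   `x1, y1, ...` order.
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  if (is.vector(config)) config <- as_config(config)
  if (nrow(config) < 2L || any(!is.finite(config))) {
    abort("centroid_size needs >= 2 finite landmarks.", class = "wingmorph_validation_error")
  }
  centered <- sweep(config, 2L, colMeans(config))
  cs <- sqrt(sum(centered^2))
  if (cs == 0) {
    abort("Degenerate configuration: all landmarks coincide.",
          class = "wingmorph_degenerate_error")
  }
  cs
}

#' Centroid sizes of every record in a landmark table
#'
#' @param data Landmark tibble.
#' @return Numeric vector, one centroid size per row.
#' @export
centroid_sizes <- function(data) {
  mat <- coord_matrix(data)
  vapply(seq_len(nrow(mat)), function(i) centroid_size(as_config(mat[i, ])), numeric(1))
}

# center a k x 2 configuration and return list(config, cs)
center_scale <- function(cfg) {
  centered <- sweep(cfg, 2L, colMeans(cfg))
  cs <- sqrt(sum(centered^2))
  if (cs == 0) {
    abort("Degenerate configuration: all landmarks coincide.",
          class = "wingmorph_degenerate_error")
  }
  list(config = centered / cs, cs = cs)
}

# optimal rotation (det = +1) taking `moving` onto `target`, row convention:
# minimizes ||moving %*% R - target||_F^2. No reflections.
rotation_onto <- function(moving, target) {
  cc <- crossprod(moving, target) # 2 x 2
  sv <- svd(cc)
  s <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, s)) %*% t(sv$v)
}

#' Ordinary Procrustes rotation of one configuration onto another
#'
#' Finds the proper rotation (determinant +1; reflections are never used)
#' minimizing the summed squared distance between corresponding landmarks of
#' two centered, unit-centroid-size configurations, via SVD of the 2 x 2
#' cross-covariance with determinant sign correction.
#'
#' @param moving,target k x 2 matrices, centered and scaled to unit centroid
#'   size (enforced; violation is an error).
#' @return List with `aligned` (rotated `moving`), `rotation` (2 x 2), and
#'   `rss` (the minimized residual sum of squares).
#' @export
align_pair <- function(moving, target) {
  for (nm in c("moving", "target")) {
    m <- get(nm)
    if (!is.matrix(m) || ncol(m) != 2L) {
      abort(paste0(nm, " must be a k x 2 matrix."), class = "wingmorph_validation_error")
    }
    if (max(abs(colMeans(m))) > 1e-6 || abs(sqrt(sum(m^2)) - 1) > 1e-6) {
      abort(paste0("align_pair contract violation: ", nm,
                   " must be centered with unit centroid size."),
            class = "wingmorph_contract_error")
    }
  }
  if (nrow(moving) != nrow(target)) {
    abort("Configurations differ in landmark count.", class = "wingmorph_validation_error")
  }
  r <- rotation_onto(moving, target)
  aligned <- moving %*% r
  list(aligned = aligned, rotation = r, rss = sum((aligned - target)^2))
}

#' Generalized Procrustes analysis of a landmark dataset
#'
#' Removes translation (centering), size (scaling to unit centroid size) and
#' orientation (iterative least-squares rotation onto an evolving consensus)
#' from every configuration. The consensus is the coordinate-wise mean,
#' re-centered and rescaled to unit centroid size each sweep; iteration stops
#' when the decrease in the total sum of squared deviations from the
#' consensus falls below `tol`. The final consensus (and all aligned
#' configurations with it) is rigidly rotated to best match the first
#' specimen's original orientation, so output is deterministic rather than
#' defined only up to rotation. With `project = TRUE` (default) the aligned
#' shapes are orthogonally projected onto the tangent space at the consensus,
#' licensing the downstream linear statistics.
#'
#' @param data Landmark tibble (homogeneous k >= 3, n >= 1).
#' @param tol Convergence threshold on the decrease of the total deviation Q.
#' @param max_iter Maximum number of alignment sweeps.
#' @param project Apply tangent-space projection to the aligned coordinates.
#' @return An object of class `wing_gpa`: `$data` is the input metadata with
#'   the coordinate columns replaced by superimposed coordinates plus a
#'   `centroid_size` column; `$consensus` the k x 2 mean shape (centered,
#'   unit centroid size); `$q_trace` the per-iteration total deviation
#'   (non-increasing); `$iterations`, `$converged`, `$projected`.
#' @export
gpa <- function(data, tol = 1e-10, max_iter = 100L, project = TRUE) {
  n <- nrow(data)
  if (is.null(n) || n == 0L) {
    abort("Empty dataset.", class = "wingmorph_empty_error")
  }
  k <- landmark_count(data)
  if (k < 3L) abort("GPA needs k >= 3 landmarks.", class = "wingmorph_validation_error")
  mat <- coord_matrix(data)

  configs <- vector("list", n)
  cs <- numeric(n)
  for (i in seq_len(n)) {
    z <- center_scale(as_config(mat[i, ]))
    configs[[i]] <- z$config
    cs[i] <- z$cs
  }
  first_orig <- configs[[1L]] # centered, unit CS, original orientation

  consensus <- configs[[1L]]
  q_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  if (n == 1L) {
    q_trace <- 0
    converged <- TRUE
  } else {
    q_prev <- Inf
    while (iter < max_iter) {
      iter <- iter + 1L
      for (i in seq_len(n)) {
        configs[[i]] <- configs[[i]] %*% rotation_onto(configs[[i]], consensus)
      }
      mean_cfg <- Reduce(`+`, configs) / n
      q <- sum(vapply(configs, function(cfg) sum((cfg - mean_cfg)^2), numeric(1)))
      q_trace <- c(q_trace, q)
      mean_cfg <- sweep(mean_cfg, 2L, colMeans(mean_cfg))
      consensus <- mean_cfg / sqrt(sum(mean_cfg^2))
      if (is.finite(q_prev) && (q_prev - q) < tol) {
        converged <- TRUE
        break
      }
      q_prev <- q
    }
    if (!converged) {
      warn(sprintf("GPA did not converge in %d iterations (last Q decrease %.3g).",
                   max_iter, q_prev - q_trace[length(q_trace)]))
    }
  }

  # orientation gauge: rotate everything to best match specimen 1's original
  # orientation
  rg <- rotation_onto(consensus, first_orig)
  consensus <- consensus %*% rg
  aligned <- matrix(0, n, 2L * k)
  for (i in seq_len(n)) aligned[i, ] <- flatten_config(configs[[i]] %*% rg)

  if (project) {
    vc <- flatten_config(consensus) # unit norm: consensus has unit CS
    dev <- sweep(aligned, 2L, vc)
    aligned <- sweep(dev - (dev %*% vc) %*% t(vc), 2L, vc, `+`)
  }

  out_data <- set_coords(data, aligned)
  out_data$centroid_size <- cs
  structure(
    list(data = tibble::as_tibble(out_data), consensus = consensus,
         centroid_sizes = cs, iterations = iter, q_trace = q_trace,
         converged = converged, projected = project, k = k, n = n,
         tol = tol),
    class = "wing_gpa"
  )
}

#' @export
print.wing_gpa <- function(x, ...) {
  cat(sprintf("Generalized Procrustes analysis: %d configurations, %d landmarks\n",
              x$n, x$k))
  cat(sprintf("  iterations: %d (%s), tangent projection: %s\n", x$iterations,
              if (x$converged) "converged" else "NOT converged",
              if (x$projected) "on" else "off"))
  if (length(x$q_trace)) {
    cat(sprintf("  final total deviation Q = %.6g\n", x$q_trace[length(x$q_trace)]))
  }
  invisible(x)
}

#' Tidy superimposed coordinates from a GPA fit
#'
#' @param x A `wing_gpa` object.
#' @param ... Unused.
#' @return Tibble of metadata, superimposed coordinates and centroid sizes.
#' @exportS3Method generics::tidy
tidy.wing_gpa <- function(x, ...) x$data

#' One-row summary of a GPA fit
#'
#' @param x A `wing_gpa` object.
#' @param ... Unused.
#' @return One-row tibble (n, k, iterations, final Q, convergence flags).
#' @exportS3Method generics::glance
glance.wing_gpa <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, iterations = x$iterations,
    q_final = if (length(x$q_trace)) x$q_trace[length(x$q_trace)] else NA_real_,
    converged = x$converged, projected = x$projected
  )
}

#' Procrustes distance between two superimposed shapes
#'
#' Euclidean norm of the difference of two shape vectors from a common
#' superimposition.
#'
#' @param a,b Flat shape vectors (or k x 2 matrices) of equal length.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  if (is.matrix(a)) a <- flatten_config(a)
  if (is.matrix(b)) b <- flatten_config(b)
  if (length(a) != length(b)) {
    abort("Shape vectors differ in length.", class = "wingmorph_validation_error")
  }
  sqrt(sum((a - b)^2))
}

#' Mean shape of a set of superimposed shape vectors
#'
#' @param vectors An n x 2k matrix (rows are shape vectors) or a list of
#'   equal-length vectors, from a common superimposition.
#' @return The coordinate-wise mean shape vector.
#' @export
mean_shape <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.vector(vectors)) vectors <- matrix(vectors, nrow = 1L)
  if (nrow(vectors) == 0L) {
    abort("mean_shape of an empty set.", class = "wingmorph_empty_error")
  }
  colMeans(vectors)
}
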