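# Shape PCA, two-class linear discriminant analysis, leave-one-out
# cross-validated species assignment, and per-landmark difference summaries.

#' Principal component analysis of superimposed shape coordinates
#'
#' Eigendecomposition of the covariance of the centered shape vectors.
#' Components are ordered by decreasing eigenvalue; only components whose
#' eigenvalue exceeds 1e-12 times the largest are retained (superimposition
#' leaves the shape matrix rank-deficient: 2k - 4 non-null dimensions at
#' most). Sign gauge: each loading vector's largest-magnitude element is made
#' positive, so scores are reproducible.
#'
#' @param data Superimposed landmark tibble (n >= 3 rows).
#' @return Object of class `wing_pca`: `$scores` (n x m), `$loadings`
#'   (2k x m), `$explained_variance_ratio` (m proportions of the total,
#'   including any discarded null variance), `$center`, and `$meta` (the
#'   non-coordinate columns of the input).
#' @export
shape_pca <- function(data) {
  y <- coord_matrix(data)
  n <- nrow(y)
  if (n < 3L) abort("PCA needs n >= 3.", class = "wingmorph_validation_error")
  pr <- prcomp(y, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  keep <- which(ev > 1e-12 * ev[1L] & ev > 0)
  loadings <- pr$rotation[, keep, drop = FALSE]
  scores <- pr$x[, keep, drop = FALSE]
  # sign gauge
  for (j in seq_along(keep)) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(keep))
  k <- landmark_count(data)
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_ratio = ev[keep] / sum(ev),
         center = pr$center, k = k, n = n,
         meta = data[setdiff(names(data), coord_cols(k))]),
    class = "wing_pca"
  )
}

#' @export
print.wing_pca <- function(x, ...) {
  m <- ncol(x$scores)
  cat(sprintf("Shape PCA: %d specimens, %d components retained\n", x$n, m))
  shown <- head(x$explained_variance_ratio, 5L)
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_along(shown), 100 * shown), collapse = ", "),
      if (m > 5L) "..." else "", "\n")
  invisible(x)
}

#' Tidy PCA scores with specimen metadata
#'
#' @param x A `wing_pca` object.
#' @param ... Unused.
#' @return Tibble of metadata columns plus PC scores.
#' @exportS3Method generics::tidy
tidy.wing_pca <- function(x, ...) {
  dplyr::bind_cols(x$meta, tibble::as_tibble(x$scores))
}

#' @exportS3Method generics::glance
glance.wing_pca <- function(x, ...) {
  evr <- x$explained_variance_ratio
  tibble::tibble(n = x$n, n_components = ncol(x$scores),
                 pc1 = evr[1L], pc2 = if (length(evr) > 1L) evr[2L] else NA_real_,
                 pc12 = sum(head(evr, 2L)))
}

#' Fit a two-class linear discriminant
#'
#' Classical LDA from the pooled within-class covariance (divisor n - 2):
#' discriminant direction w = W^-1 (mu1 - mu2), linear decision score
#' `x . w - w . (mu1 + mu2)/2 + log(p1/p2)` (positive scores assign the first
#' factor level), posterior from the equal-covariance two-Gaussian model.
#'
#' @param x Feature matrix (use full-rank PCA scores: raw superimposed
#'   coordinates are rank-deficient and make W singular).
#' @param labels Two-level factor, >= 2 specimens per class.
#' @param priors `"proportional"` (class frequencies, default) or `"equal"`.
#' @return Object of class `wing_lda`.
#' @export
lda_fit <- function(x, labels, priors = c("proportional", "equal")) {
  priors <- match.arg(priors)
  labels <- droplevels(factor(labels))
  x <- as.matrix(x)
  if (nlevels(labels) != 2L) {
    abort("lda_fit is strictly two-class.", class = "wingmorph_validation_error")
  }
  ns <- tabulate(labels)
  if (any(ns < 2L)) {
    abort("Each class needs >= 2 specimens.", class = "wingmorph_validation_error")
  }
  n <- nrow(x)
  lev <- levels(labels)
  mu1 <- colMeans(x[labels == lev[1L], , drop = FALSE])
  mu2 <- colMeans(x[labels == lev[2L], , drop = FALSE])
  c1 <- sweep(x[labels == lev[1L], , drop = FALSE], 2L, mu1)
  c2 <- sweep(x[labels == lev[2L], , drop = FALSE], 2L, mu2)
  w_cov <- (crossprod(c1) + crossprod(c2)) / (n - 2L)
  wv <- tryCatch(solve(w_cov, mu1 - mu2), error = function(e) {
    abort(paste0("Pooled within-class covariance is singular; reduce the ",
                 "feature space with PCA before LDA (shape coordinates lose ",
                 "4 dimensions to superimposition)."),
          class = "wingmorph_rank_error")
  })
  pr <- if (priors == "proportional") ns / n else c(0.5, 0.5)
  structure(
    list(w = wv, mu1 = mu1, mu2 = mu2, levels = lev, priors = pr,
         threshold = sum(wv * (mu1 + mu2)) / 2 - log(pr[1L] / pr[2L]),
         n = n),
    class = "wing_lda"
  )
}

#' Predict species from a fitted linear discriminant
#'
#' @param object A `wing_lda` fit.
#' @param newdata Feature matrix with the same columns the model was fit on.
#' @param ... Unused.
#' @return Tibble with `.pred` (assigned label; ties at score exactly 0 go to
#'   the first level), `score` (signed discriminant score) and `posterior`
#'   (posterior probability of the first level).
#' @export
predict.wing_lda <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = length(object$w))
  score <- drop(newdata %*% object$w) - object$threshold
  tibble::tibble(
    .pred = ifelse(score >= 0, object$levels[1L], object$levels[2L]),
    score = score,
    posterior = plogis(score),
    tie = score == 0
  )
}

#' @export
print.wing_lda <- function(x, ...) {
  cat(sprintf("Two-class LDA: %s vs %s (n = %d, %d features)\n",
              x$levels[1L], x$levels[2L], x$n, length(x$w)))
  cat(sprintf("  priors: %.3f / %.3f\n", x$priors[1L], x$priors[2L]))
  invisible(x)
}

#' Accuracy implied by a confusion matrix
#'
#' The proportion of correct assignments: the trace of the (true x predicted)
#' confusion matrix divided by its total.
#'
#' @param confusion Square numeric matrix of non-negative counts.
#' @return Proportion in `[0, 1]`.
#' @export
accuracy_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0) ||
      any(confusion != round(confusion))) {
    abort("Confusion matrix must be square with non-negative integer counts.",
          class = "wingmorph_validation_error")
  }
  total <- sum(confusion)
  if (total == 0) abort("Empty confusion matrix.", class = "wingmorph_validation_error")
  sum(diag(confusion)) / total
}

#' Leave-one-out cross-validated LDA species classification
#'
#' Projects the superimposed shapes onto the full-sample PCA basis (all
#' components above the rank tolerance, capped at min(n - 2, 2k - 4)), then,
#' for each specimen, fits the linear discriminant on all other specimens and
#' predicts the held-out one. The superimposition and PCA basis are computed
#' once on the full sample, matching how cross-validation is usually run on
#' precomputed shape coordinates; this is mildly optimistic, and
#' `refit_basis = TRUE` recomputes the PCA basis within every fold instead.
#'
#' @param data Superimposed landmark tibble with a two-level label column
#'   (n >= 6, each class >= 3).
#' @param label Bare column name of the class label (default `species`).
#' @param priors Passed to [lda_fit()].
#' @param n_components Number of PCA components to use (default: full rank).
#' @param refit_basis Recompute the PCA basis per fold (strict mode).
#' @return Object of class `classification_report`: `$confusion` (2 x 2,
#'   true x predicted), `$accuracy`, `$per_specimen` tibble, `$ld_vector`
#'   (discriminant direction mapped back to shape space), `$priors`,
#'   `$n_ties`.
#' @export
loocv_classify <- function(data, label = species,
                           priors = c("proportional", "equal"),
                           n_components = NULL, refit_basis = FALSE) {
  priors <- match.arg(priors)
  labels <- droplevels(factor(dplyr::pull(data, {{ label }})))
  n <- nrow(data)
  if (n < 6L || nlevels(labels) != 2L || any(tabulate(labels) < 3L)) {
    abort("LOOCV classification needs two classes with >= 3 specimens each (n >= 6).",
          class = "wingmorph_validation_error")
  }
  y <- coord_matrix(data)
  k <- landmark_count(data)
  # the pooled covariance inside a fold has rank n - 3, which caps the usable
  # feature count below the full-sample bound min(n - 2, 2k - 4)
  cap <- min(n - 3L, 2L * k - 4L)
  pca_full <- shape_pca(data)
  m <- min(ncol(pca_full$scores), cap, n_components %||% Inf)
  scores <- pca_full$scores[, seq_len(m), drop = FALSE]

  pred <- character(n)
  sc <- numeric(n)
  post <- numeric(n)
  ties <- 0L
  for (i in seq_len(n)) {
    if (refit_basis) {
      ytr <- y[-i, , drop = FALSE]
      ctr <- colMeans(ytr)
      pr <- prcomp(ytr, center = TRUE, scale. = FALSE)
      ev <- pr$sdev^2
      keep <- which(ev > 1e-12 * ev[1L] & ev > 0)
      mm <- min(length(keep), n - 4L, 2L * k - 4L, n_components %||% Inf)
      basis <- pr$rotation[, seq_len(mm), drop = FALSE]
      tr_scores <- pr$x[, seq_len(mm), drop = FALSE]
      te_scores <- matrix(y[i, ] - ctr, 1L) %*% basis
    } else {
      tr_scores <- scores[-i, , drop = FALSE]
      te_scores <- scores[i, , drop = FALSE]
    }
    if (any(tabulate(droplevels(labels[-i])) < 2L) || nlevels(droplevels(labels[-i])) < 2L) {
      abort("A leave-one-out fold left a class with fewer than 2 members.",
            class = "wingmorph_validation_error")
    }
    fit <- lda_fit(tr_scores, labels[-i], priors = priors)
    p <- predict(fit, te_scores)
    pred[i] <- p$.pred
    sc[i] <- p$score
    post[i] <- p$posterior
    ties <- ties + sum(p$tie)
  }

  lev <- levels(labels)
  confusion <- table(factor(labels, levels = lev),
                     factor(pred, levels = lev))
  confusion <- matrix(as.integer(confusion), 2L, 2L,
                      dimnames = list(true = lev, predicted = lev))
  full_fit <- lda_fit(scores, labels, priors = priors)
  structure(
    list(
      confusion = confusion,
      accuracy = accuracy_from_confusion(confusion),
      per_specimen = tibble::tibble(
        specimen_id = data$specimen_id %||% as.character(seq_len(n)),
        true = as.character(labels), predicted = pred,
        score = sc, posterior = post),
      ld_vector = drop(pca_full$loadings[, seq_len(m), drop = FALSE] %*% full_fit$w),
      priors = full_fit$priors,
      n_components = m,
      n_ties = ties,
      refit_basis = refit_basis
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  lev <- rownames(x$confusion)
  cat("Leave-one-out cross-validated LDA classification\n")
  cat(sprintf("  accuracy: %.1f%% (%d / %d)\n", 100 * x$accuracy,
              sum(diag(x$confusion)), sum(x$confusion)))
  cat("  confusion (rows = true, cols = predicted):\n")
  cat(sprintf("    %12s %10s %10s\n", "", lev[1L], lev[2L]))
  for (i in 1:2) {
    cat(sprintf("    %12s %10d %10d\n", lev[i], x$confusion[i, 1L], x$confusion[i, 2L]))
  }
  if (x$n_ties > 0L) cat(sprintf("  ties at threshold: %d\n", x$n_ties))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.classification_report <- function(x, ...) x$per_specimen

#' @exportS3Method generics::glance
glance.classification_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, n = sum(x$confusion),
    n_misclassified = sum(x$confusion) - sum(diag(x$confusion)),
    n_components = x$n_components, n_ties = x$n_ties
  )
}

#' Per-landmark shape differences between two groups
#'
#' Displacement vector between the two group mean shapes at every landmark,
#' its magnitude, and the descending magnitude ranking. Optionally also a
#' per-landmark leave-one-out LDA accuracy using only that landmark's two
#' coordinates, quantifying whether any single landmark suffices for
#' classification.
#'
#' @param data Superimposed landmark tibble.
#' @param label Bare column name of the two-level group factor.
#' @param single_landmark_loocv Also compute the per-landmark two-feature
#'   LOOCV accuracy (slower).
#' @return Object of class `landmark_diff`; `tidy()` gives one row per
#'   landmark.
#' @export
landmark_differences <- function(data, label = species, single_landmark_loocv = FALSE) {
  labels <- droplevels(factor(dplyr::pull(data, {{ label }})))
  if (nlevels(labels) != 2L) {
    abort("landmark_differences needs exactly two groups.",
          class = "wingmorph_validation_error")
  }
  y <- coord_matrix(data)
  k <- landmark_count(data)
  lev <- levels(labels)
  m1 <- as_config(colMeans(y[labels == lev[1L], , drop = FALSE]))
  m2 <- as_config(colMeans(y[labels == lev[2L], , drop = FALSE]))
  disp <- m1 - m2
  mag <- sqrt(rowSums(disp^2))
  rank_desc <- as.integer(rank(-mag, ties.method = "first"))

  single_acc <- rep(NA_real_, k)
  if (single_landmark_loocv) {
    for (lm in seq_len(k)) {
      cols <- c(paste0("x", lm), paste0("y", lm))
      xlm <- as.matrix(data[cols])
      n <- nrow(xlm)
      ok <- 0L
      for (i in seq_len(n)) {
        fit <- lda_fit(xlm[-i, , drop = FALSE], labels[-i])
        p <- predict(fit, xlm[i, , drop = FALSE])
        ok <- ok + (p$.pred == as.character(labels[i]))
      }
      single_acc[lm] <- ok / n
    }
  }
  structure(
    list(
      table = tibble::tibble(
        landmark = seq_len(k), dx = disp[, 1L], dy = disp[, 2L],
        magnitude = mag, rank = rank_desc, single_landmark_accuracy = single_acc),
      groups = lev,
      mean_shapes = list(m1, m2)
    ),
    class = "landmark_diff"
  )
}

#' @export
print.landmark_diff <- function(x, ...) {
  cat(sprintf("Mean-shape differences: %s vs %s\n", x$groups[1L], x$groups[2L]))
  top <- dplyr::arrange(x$table, .data$rank)
  top <- head(top, 3L)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  #%d landmark %d: |d| = %.5f\n", top$rank[i], top$landmark[i],
                top$magnitude[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.landmark_diff <- function(x, ...) x$table
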