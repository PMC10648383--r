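# Inferential statistics on centroid size and superimposed shape:
# one-way size ANOVA (parametric + permutation), Procrustes regression of
# shape on size (allometry), group Procrustes-variance disparity, and the
# observer-effect analyses on replicated digitizations.
#
# Permutation convention throughout: the predictor (group labels or the size
# covariate) is fully randomized, the observed statistic is counted among the
# permutations, p = (#{F_perm >= F_obs} + 1) / (N + 1), and the standardized
# effect size is Z = (F_obs - mean(F_perm)) / sd(F_perm).

new_perm_test <- function(method, term, statistic_F, df_model, df_resid,
                          r_squared, z_score, p_value, parametric_p,
                          n_permutations) {
  structure(
    list(method = method, term = term, statistic_F = statistic_F,
         df_model = df_model, df_resid = df_resid, r_squared = r_squared,
         z_score = z_score, p_value = p_value, parametric_p = parametric_p,
         n_permutations = n_permutations),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s (term: %s)\n", x$method, x$term))
  cat(sprintf("  F(%d, %d) = %.2f, R^2 = %.3f\n",
              x$df_model, x$df_resid, x$statistic_F, x$r_squared))
  if (!is.na(x$parametric_p)) cat(sprintf("  parametric P = %.4g\n", x$parametric_p))
  if (x$n_permutations > 0L) {
    cat(sprintf("  permutation P = %.4g, Z = %.3f (%d permutations)\n",
                x$p_value, x$z_score, x$n_permutations))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, term = x$term, statistic_F = x$statistic_F,
    df_model = x$df_model, df_resid = x$df_resid, r_squared = x$r_squared,
    z_score = x$z_score, p_value = x$p_value, parametric_p = x$parametric_p,
    n_permutations = x$n_permutations
  )
}

#' @exportS3Method generics::glance
glance.perm_test <- tidy.perm_test

# one-way ANOVA sums of squares; x numeric, g factor
anova_F <- function(x, g) {
  grand <- mean(x)
  means <- tapply(x, g, mean)
  ns <- tabulate(g)
  ss_total <- sum((x - grand)^2)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- ss_total - ss_between
  df1 <- nlevels(g) - 1L
  df2 <- length(x) - nlevels(g)
  f <- if (ss_within <= 0) {
    if (ss_between <= 0) 0 else Inf
  } else {
    (ss_between / df1) / (ss_within / df2)
  }
  list(F = f, df1 = df1, df2 = df2,
       r_squared = if (ss_total > 0) ss_between / ss_total else 0)
}

perm_summary <- function(obs, perms) {
  p <- (sum(perms >= obs) + 1) / (length(perms) + 1)
  z <- if (sd(perms) > 0) (obs - mean(perms)) / sd(perms) else NA_real_
  list(p = p, z = z)
}

#' One-way ANOVA of centroid size on a grouping factor
#'
#' Classical one-way ANOVA of a size variable on a factor, with the
#' F-distribution (parametric) p-value and, when `n_permutations > 0`, a
#' permutation p-value from shuffling the group labels.
#'
#' @param data Data frame of per-specimen values (one row per specimen).
#' @param group Bare column name of the grouping factor (>= 2 specimens per
#'   level).
#' @param size Bare column name of the positive size variable (default
#'   `centroid_size`).
#' @param n_permutations Number of label permutations (0 = parametric only).
#' @return A `perm_test` object.
#' @export
size_anova <- function(data, group, size = centroid_size, n_permutations = 0L) {
  g <- droplevels(factor(dplyr::pull(data, {{ group }})))
  x <- dplyr::pull(data, {{ size }})
  term <- as_name(enquo(group))
  if (nlevels(g) < 2L) {
    abort("Grouping factor must have at least two levels.",
          class = "wingmorph_validation_error")
  }
  if (any(tabulate(g) < 2L)) {
    abort("Every group needs at least two specimens.",
          class = "wingmorph_validation_error")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("Sizes must be finite and positive.", class = "wingmorph_validation_error")
  }
  obs <- anova_F(x, g)
  parametric_p <- pf(obs$F, obs$df1, obs$df2, lower.tail = FALSE)
  p <- NA_real_
  z <- NA_real_
  if (n_permutations > 0L) {
    perms <- vapply(seq_len(n_permutations),
                    function(i) anova_F(x, sample(g))$F, numeric(1))
    s <- perm_summary(obs$F, perms)
    p <- s$p
    z <- s$z
  }
  new_perm_test("size ANOVA", term, obs$F, obs$df1, obs$df2, obs$r_squared,
                z, p, parametric_p, as.integer(n_permutations))
}

#' Procrustes regression of shape on size (allometry test)
#'
#' Regresses every superimposed coordinate on the centroid-size covariate by
#' least squares. Sums of squares are totalled across coordinates (i.e. they
#' are squared Procrustes deviations), giving a single R-squared and
#' goodness-of-fit F with df (1, n - 2). Significance comes from full
#' randomization of the specimen-to-size assignment.
#'
#' @param data Superimposed landmark tibble with a `centroid_size` column
#'   (e.g. `tidy(gpa(x))`), or any table with coordinate columns plus the
#'   size column.
#' @param size Bare column name of the size covariate.
#' @param n_permutations Number of permutations (study default 1000).
#' @param log_size Regress on log centroid size instead of raw.
#' @return A `perm_test` object.
#' @export
allometry_regression <- function(data, size = centroid_size,
                                 n_permutations = 1000L, log_size = FALSE) {
  y <- coord_matrix(data)
  s <- dplyr::pull(data, {{ size }})
  n <- nrow(y)
  if (n <= 2L) abort("Allometry regression needs n > 2.", class = "wingmorph_validation_error")
  if (log_size) s <- log(s)
  if (max(s) - min(s) <= 0) {
    abort("Size covariate is constant: slope undefined.",
          class = "wingmorph_validation_error")
  }
  y <- sweep(y, 2L, colMeans(y))
  s <- s - mean(s)
  sts <- sum(s^2)
  ss_total <- sum(y^2)
  ss_model_of <- function(sv) sum(crossprod(y, sv)^2) / sts
  ss_model <- ss_model_of(s)
  df1 <- 1L
  df2 <- n - 2L
  ss_resid <- ss_total - ss_model
  f_of <- function(ssm) (ssm / df1) / ((ss_total - ssm) / df2)
  f_obs <- f_of(ss_model)
  r2 <- ss_model / ss_total
  p <- NA_real_
  z <- NA_real_
  if (n_permutations > 0L) {
    sp <- vapply(seq_len(n_permutations), function(i) sample(s), numeric(n))
    ssm_perm <- colSums(crossprod(y, sp)^2) / sts
    perms <- f_of(ssm_perm)
    sm <- perm_summary(f_obs, perms)
    p <- sm$p
    z <- sm$z
  }
  new_perm_test("Procrustes shape ~ size regression",
                if (log_size) "log(centroid size)" else "centroid size",
                f_obs, df1, df2, r2, z, p, NA_real_, as.integer(n_permutations))
}

#' Morphological disparity (Procrustes variance) per group
#'
#' For each group, the mean squared Procrustes distance of its members from
#' the group mean shape (denominator n, the "mean Procrustes variance"
#' convention). Pairwise absolute differences between group variances are
#' reported, with optional permutation p-values from shuffling group labels.
#'
#' @param data Superimposed landmark tibble.
#' @param group Bare column name of the grouping factor (groups nonempty).
#' @param n_permutations Number of permutations for the pairwise contrasts
#'   (0 = none).
#' @return An object of class `disparity` with `$variances` (group, n, pv)
#'   and `$pairwise` (group1, group2, abs_diff, p_value) tibbles.
#' @export
morphological_disparity <- function(data, group, n_permutations = 0L) {
  y <- coord_matrix(data)
  g <- droplevels(factor(dplyr::pull(data, {{ group }})))
  if (nlevels(g) < 1L || any(tabulate(g) == 0L)) {
    abort("Every group must be nonempty.", class = "wingmorph_validation_error")
  }
  pv_by_group <- function(g) {
    vapply(levels(g), function(lev) {
      yy <- y[g == lev, , drop = FALSE]
      sum(sweep(yy, 2L, colMeans(yy))^2) / nrow(yy)
    }, numeric(1))
  }
  pv <- pv_by_group(g)
  pairs <- if (nlevels(g) >= 2L) combn(levels(g), 2L) else matrix(character(), 2L, 0L)
  abs_diff <- apply(pairs, 2L, function(pr) abs(pv[pr[1L]] - pv[pr[2L]]))
  p_vals <- rep(NA_real_, ncol(pairs))
  if (n_permutations > 0L && ncol(pairs) > 0L) {
    exceed <- numeric(ncol(pairs))
    for (b in seq_len(n_permutations)) {
      pvp <- pv_by_group(sample(g))
      dp <- apply(pairs, 2L, function(pr) abs(pvp[pr[1L]] - pvp[pr[2L]]))
      exceed <- exceed + (dp >= abs_diff)
    }
    p_vals <- (exceed + 1) / (n_permutations + 1)
  }
  structure(
    list(
      variances = tibble::tibble(group = levels(g), n = as.integer(tabulate(g)),
                                 pv = unname(pv)),
      pairwise = tibble::tibble(group1 = pairs[1L, ], group2 = pairs[2L, ],
                                abs_diff = as.numeric(abs_diff),
                                p_value = p_vals),
      n_permutations = as.integer(n_permutations)
    ),
    class = "disparity"
  )
}

#' @export
print.disparity <- function(x, ...) {
  cat("Morphological disparity (Procrustes variance, denominator n)\n")
  for (i in seq_len(nrow(x$variances))) {
    cat(sprintf("  %-12s n = %3d  PV = %.6f\n", x$variances$group[i],
                x$variances$n[i], x$variances$pv[i]))
  }
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  |%s - %s| = %.6f%s\n", x$pairwise$group1[i], x$pairwise$group2[i],
                x$pairwise$abs_diff[i],
                if (is.na(x$pairwise$p_value[i])) "" else
                  sprintf("  (P = %.4g)", x$pairwise$p_value[i])))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.disparity <- function(x, ...) x$variances

#' @exportS3Method generics::glance
glance.disparity <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$variances),
                 n_permutations = x$n_permutations,
                 max_abs_diff = if (nrow(x$pairwise)) max(x$pairwise$abs_diff) else NA_real_)
}

#' Observer effect on centroid size
#'
#' One-way permutation ANOVA of centroid size on the observer factor in a
#' replicated-digitization design (every selected specimen measured by every
#' observer).
#'
#' @param data Per-measurement table (one row per specimen x observer).
#' @param observer Bare column name of the observer factor (>= 2 levels).
#' @param size Bare column name of the size variable.
#' @param n_permutations Number of permutations (study default 500).
#' @return A `perm_test` object.
#' @export
observer_size_effect <- function(data, observer = observer,
                                 size = centroid_size, n_permutations = 500L) {
  tab <- table(dplyr::pull(data, specimen_id), dplyr::pull(data, {{ observer }}))
  if (ncol(tab) >= 2L && any(tab == 0L)) {
    warn("Replicated design is unbalanced: not every specimen was measured by every observer.")
  }
  out <- size_anova(data, {{ observer }}, {{ size }}, n_permutations)
  out$method <- "observer size ANOVA"
  out
}

#' Observer repeatability of superimposed shape
#'
#' Compares digitization noise against biological variation. Within-specimen
#' Procrustes variance is the mean, over replicated specimens, of the
#' Procrustes variance of that specimen's replicate digitizations;
#' within-species Procrustes variance is computed on one measurement per
#' specimen (the first observer/replicate in the table). A within-specimen
#' variance well below the within-species variance indicates low observer
#' bias. Specimens with a single measurement are excluded from the
#' within-specimen term with a warning.
#'
#' @param data Superimposed landmark tibble of the replicated subset (and,
#'   optionally, additional single-measurement rows).
#' @param min_replicates Minimum measurements per specimen for inclusion in
#'   the within-specimen term.
#' @return Object of class `repeatability` with the two variances, their
#'   ratio, per-species variances and counts.
#' @export
observer_repeatability <- function(data, min_replicates = 2L) {
  y <- coord_matrix(data)
  ids <- data$specimen_id
  counts <- table(ids)
  replicated <- names(counts)[counts >= min_replicates]
  if (length(replicated) == 0L) {
    abort("No specimen has replicated measurements.", class = "wingmorph_validation_error")
  }
  if (any(counts < min_replicates)) {
    warn(sprintf("%d unreplicated specimen(s) excluded from the within-specimen term.",
                 sum(counts < min_replicates)))
  }
  pv_of <- function(yy) sum(sweep(yy, 2L, colMeans(yy))^2) / nrow(yy)
  within_specimen <- mean(vapply(replicated, function(id) {
    pv_of(y[ids == id, , drop = FALSE])
  }, numeric(1)))

  # one measurement per specimen for the between-individual (within-species)
  # variance
  first_rows <- !duplicated(ids)
  sub <- data[first_rows, , drop = FALSE]
  ysub <- y[first_rows, , drop = FALSE]
  sp_fac <- factor(sub$species)
  per_species <- tibble::tibble(
    species = levels(sp_fac),
    n = as.integer(tabulate(sp_fac)),
    pv = vapply(levels(sp_fac), function(sp) {
      yy <- ysub[sp_fac == sp, , drop = FALSE]
      if (nrow(yy) < 2L) NA_real_ else pv_of(yy)
    }, numeric(1))
  )
  within_species <- mean(per_species$pv, na.rm = TRUE)
  structure(
    list(within_specimen_pv = within_specimen,
         within_species_pv = within_species,
         ratio = within_specimen / within_species,
         per_species = per_species,
         n_replicated = length(replicated),
         n_excluded = sum(counts < min_replicates)),
    class = "repeatability"
  )
}

#' @export
print.repeatability <- function(x, ...) {
  cat("Observer repeatability (Procrustes variances)\n")
  cat(sprintf("  within-specimen (replicates): %.6f  [%d specimens]\n",
              x$within_specimen_pv, x$n_replicated))
  cat(sprintf("  within-species  (individuals): %.6f\n", x$within_species_pv))
  cat(sprintf("  ratio (observer / biological): %.3f\n", x$ratio))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.repeatability <- function(x, ...) {
  tibble::tibble(
    within_specimen_pv = x$within_specimen_pv,
    within_species_pv = x$within_species_pv,
    ratio = x$ratio,
    n_replicated = x$n_replicated,
    n_excluded = x$n_excluded
  )
}
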