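# Per-sex analysis pipeline: load -> validate -> GPA -> size ANOVA ->
# allometry -> PCA -> LOOCV-LDA -> disparity -> observer analyses -> report.

#' Analysis configuration
#'
#' Defaults follow the study design: sexes are always analysed separately,
#' allometry uses 1000 permutations and the observer analyses 500, GPA uses
#' tangent projection with tol 1e-10, LDA priors are proportional to class
#' frequencies, and the PCA basis is computed once on the full sample.
#'
#' @param gpa_tol,gpa_max_iter,tangent_project GPA settings (see [gpa()]).
#' @param size_permutations Permutations for the species size ANOVA
#'   (0 = parametric only).
#' @param allometry_permutations,observer_permutations,disparity_permutations
#'   Permutation counts for the respective tests.
#' @param lda_priors `"proportional"` or `"equal"`.
#' @param refit_basis Strict per-fold PCA basis in LOOCV.
#' @param log_size Regress shape on log centroid size.
#' @param single_landmark_loocv Compute per-landmark single-landmark LOOCV
#'   accuracies (slower).
#' @param pooled Analyse the sexes together (discouraged; prints a prominent
#'   warning because sex-specific wing shape differences confound
#'   species-level analyses).
#' @param seed Integer seed controlling every permutation test.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(gpa_tol = 1e-10, gpa_max_iter = 100L,
                            tangent_project = TRUE,
                            size_permutations = 0L,
                            allometry_permutations = 1000L,
                            observer_permutations = 500L,
                            disparity_permutations = 500L,
                            lda_priors = "proportional",
                            refit_basis = FALSE,
                            log_size = FALSE,
                            single_landmark_loocv = FALSE,
                            pooled = FALSE,
                            seed = 1L) {
  stopifnot(size_permutations >= 0L, allometry_permutations >= 0L,
            observer_permutations >= 0L, disparity_permutations >= 0L)
  structure(
    list(gpa_tol = gpa_tol, gpa_max_iter = as.integer(gpa_max_iter),
         tangent_project = isTRUE(tangent_project),
         size_permutations = as.integer(size_permutations),
         allometry_permutations = as.integer(allometry_permutations),
         observer_permutations = as.integer(observer_permutations),
         disparity_permutations = as.integer(disparity_permutations),
         lda_priors = match.arg(lda_priors, c("proportional", "equal")),
         refit_basis = isTRUE(refit_basis),
         log_size = isTRUE(log_size),
         single_landmark_loocv = isTRUE(single_landmark_loocv),
         pooled = isTRUE(pooled),
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return Object of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", ")),
          class = "wingmorph_config_error")
  }
  do.call(analysis_config, vals)
}

perm_test_json <- function(pt) {
  out <- list(statistic_F = pt$statistic_F, df_model = pt$df_model,
              df_resid = pt$df_resid, r_squared = pt$r_squared)
  if (!is.na(pt$parametric_p)) out$parametric_p <- pt$parametric_p
  if (pt$n_permutations > 0L) {
    out$p_value <- pt$p_value
    out$z_score <- pt$z_score
    out$n_permutations <- pt$n_permutations
  }
  out
}

analyse_one_sex <- function(data, config) {
  block <- list(n = nrow(data),
                n_by_species = as.list(table(data$species)))
  g <- gpa(data, tol = config$gpa_tol, max_iter = config$gpa_max_iter,
           project = config$tangent_project)
  aligned <- tidy(g)
  block$gpa <- list(iterations = g$iterations, converged = g$converged,
                    projected = g$projected,
                    q_final = g$q_trace[length(g$q_trace)])

  two_species <- length(unique(data$species)) == 2L &&
    all(table(data$species) >= 2L)
  if (two_species) {
    block$size_anova <- perm_test_json(
      size_anova(aligned, species, n_permutations = config$size_permutations))
  } else {
    warn("Size ANOVA skipped: need two species with >= 2 specimens each.")
  }

  block$allometry <- perm_test_json(
    allometry_regression(aligned, n_permutations = config$allometry_permutations,
                         log_size = config$log_size))

  pca <- shape_pca(aligned)
  evr <- pca$explained_variance_ratio
  block$pca <- list(n_components = ncol(pca$scores),
                    pc1_pct = 100 * evr[1L],
                    pc2_pct = 100 * evr[2L],
                    pc12_pct = 100 * sum(evr[1:2]))

  if (two_species && nrow(data) >= 6L && all(table(data$species) >= 3L)) {
    cls <- loocv_classify(aligned, species, priors = config$lda_priors,
                          refit_basis = config$refit_basis)
    block$classification <- list(
      accuracy_pct = 100 * cls$accuracy,
      n = sum(cls$confusion),
      n_misclassified = sum(cls$confusion) - sum(diag(cls$confusion)),
      confusion = list(
        true_labels = rownames(cls$confusion),
        counts = lapply(seq_len(2L), function(i) as.list(
          setNames(as.integer(cls$confusion[i, ]), colnames(cls$confusion))))),
      n_components = cls$n_components,
      n_ties = cls$n_ties)
    attr(block, "classification_report") <- cls
  } else {
    warn("Classification skipped: needs two species with >= 3 specimens each and n >= 6.")
  }

  if (two_species) {
    disp <- morphological_disparity(aligned, species,
                                    n_permutations = config$disparity_permutations)
    block$disparity <- list(
      variances = lapply(seq_len(nrow(disp$variances)), function(i) list(
        group = disp$variances$group[i], n = disp$variances$n[i],
        pv = disp$variances$pv[i])),
      pairwise = lapply(seq_len(nrow(disp$pairwise)), function(i) {
        pr <- list(group1 = disp$pairwise$group1[i],
                   group2 = disp$pairwise$group2[i],
                   abs_diff = disp$pairwise$abs_diff[i])
        if (!is.na(disp$pairwise$p_value[i])) pr$p_value <- disp$pairwise$p_value[i]
        pr
      }))

    ld <- landmark_differences(aligned, species,
                               single_landmark_loocv = config$single_landmark_loocv)
    block$landmark_differences <- list(
      top_landmark = ld$table$landmark[ld$table$rank == 1L],
      magnitudes = ld$table$magnitude)
  }
  attr(block, "gpa") <- g
  attr(block, "pca") <- pca
  block
}

analyse_observers <- function(repl_data, config) {
  g <- gpa(repl_data, tol = config$gpa_tol, max_iter = config$gpa_max_iter,
           project = config$tangent_project)
  aligned <- tidy(g)
  out <- list(n_measurements = nrow(aligned),
              n_specimens = length(unique(aligned$specimen_id)),
              n_observers = length(unique(aligned$observer)))
  out$size_effect <- perm_test_json(
    observer_size_effect(aligned, n_permutations = config$observer_permutations))
  rep_stats <- observer_repeatability(aligned)
  out$repeatability <- list(
    within_specimen_pv = rep_stats$within_specimen_pv,
    within_species_pv = rep_stats$within_species_pv,
    ratio = rep_stats$ratio)
  two_species <- length(unique(aligned$species)) == 2L &&
    all(table(aligned$species) >= 3L) && nrow(aligned) >= 6L
  if (two_species) {
    cls <- loocv_classify(aligned, species, priors = config$lda_priors,
                          refit_basis = config$refit_basis)
    out$classification <- list(accuracy_pct = 100 * cls$accuracy,
                               n = sum(cls$confusion))
  }
  out
}

#' Run the full per-sex wing morphometrics analysis
#'
#' Executes, separately for each sex present: generalized Procrustes
#' superimposition, species centroid-size ANOVA, allometry permutation
#' regression, shape PCA, leave-one-out cross-validated LDA species
#' classification, species Procrustes-variance disparity and per-landmark
#' differences; plus, when replicated digitizations are present (replicate
#' column > 1), the observer-effect analyses (size ANOVA on observer,
#' within-specimen repeatability, replicated-set LOOCV). Everything is
#' deterministic under the config seed.
#'
#' @param data Landmark tibble (raw coordinates).
#' @param config An [analysis_config()].
#' @return Object of class `study_report`: a JSON-serializable list with one
#'   block per sex and a provenance block (seed, config hash, package
#'   version).
#' @export
run_analysis <- function(data, config = analysis_config()) {
  set.seed(config$seed)
  if (!all(META_COLS %in% names(data))) {
    abort("Input is missing metadata columns.", class = "wingmorph_schema_error")
  }
  report <- list(
    schema_version = "1.0",
    provenance = list(
      package = "wingmorph",
      version = as.character(packageVersion("wingmorph")),
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      n_input_records = nrow(data),
      landmarks = landmark_count(data))
  )

  if (config$pooled) {
    warn(paste0("POOLED ANALYSIS REQUESTED: sexes are being mixed. Mosquito wings ",
                "are sexually dimorphic; species-level results from pooled sexes ",
                "are confounded and not comparable to the per-sex analysis."))
    groups <- list(pooled = data)
  } else {
    sexes <- intersect(c("female", "male"), unique(data$sex))
    if (length(sexes) == 0L) {
      abort("No rows with sex 'female' or 'male'.", class = "wingmorph_validation_error")
    }
    groups <- lapply(sexes, function(sx) data[data$sex == sx, , drop = FALSE])
    names(groups) <- sexes
  }

  fits <- list()
  for (nm in names(groups)) {
    dat <- groups[[nm]]
    base <- dat[dat$replicate == 1L, , drop = FALSE]
    if (nrow(base) == 0L) base <- dat
    block <- analyse_one_sex(base, config)
    fits[[nm]] <- list(gpa = attr(block, "gpa"), pca = attr(block, "pca"),
                       classification = attr(block, "classification_report"))
    attributes(block) <- list(names = names(block))

    repl_ids <- unique(dat$specimen_id[dat$replicate > 1L])
    if (length(repl_ids) > 0L) {
      repl <- dat[dat$replicate > 1L, , drop = FALSE]
      block$observer <- analyse_observers(repl, config)
    }
    report[[nm]] <- block
  }
  structure(report, class = "study_report", fits = fits)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Wing morphometrics study report (wingmorph %s, seed %d)\n",
              x$provenance$version, x$provenance$seed))
  for (nm in setdiff(names(x), c("schema_version", "provenance"))) {
    b <- x[[nm]]
    cat(sprintf("\n== %s (n = %d) ==\n", nm, b$n))
    if (!is.null(b$size_anova)) {
      cat(sprintf("  size ANOVA: F(%d,%d) = %.2f, parametric P = %.3g\n",
                  b$size_anova$df_model, b$size_anova$df_resid,
                  b$size_anova$statistic_F, b$size_anova$parametric_p))
    }
    cat(sprintf("  allometry: F(%d,%d) = %.2f, R^2 = %.3f%s\n",
                b$allometry$df_model, b$allometry$df_resid,
                b$allometry$statistic_F, b$allometry$r_squared,
                if (!is.null(b$allometry$p_value))
                  sprintf(", P = %.3g", b$allometry$p_value) else ""))
    cat(sprintf("  PCA: PC1+PC2 explain %.1f%%\n", b$pca$pc12_pct))
    if (!is.null(b$classification)) {
      cat(sprintf("  LOOCV LDA accuracy: %.1f%% (%d misclassified of %d)\n",
                  b$classification$accuracy_pct, b$classification$n_misclassified,
                  b$classification$n))
    }
    if (!is.null(b$disparity)) {
      for (v in b$disparity$variances) {
        cat(sprintf("  Procrustes variance %s: %.6f\n", v$group, v$pv))
      }
    }
    if (!is.null(b$observer)) {
      cat(sprintf("  observer: within-specimen PV = %.6f, size F = %.3f (P = %.3g)%s\n",
                  b$observer$repeatability$within_specimen_pv,
                  b$observer$size_effect$statistic_F,
                  b$observer$size_effect$p_value %||% b$observer$size_effect$parametric_p,
                  if (!is.null(b$observer$classification))
                    sprintf(", replicated-set accuracy = %.1f%%",
                            b$observer$classification$accuracy_pct) else ""))
    }
  }
  invisible(x)
}

#' Serialize a study report and its tables to disk
#'
#' Writes `report.json` (full precision, stable field order — identical
#' inputs, config and seed give byte-identical files) and per-sex CSV tables:
#' superimposed coordinates with centroid sizes, PCA scores, and per-specimen
#' LOOCV assignments.
#'
#' @param report A `study_report` from [run_analysis()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  writeLines(json, file.path(dir, "report.json"), useBytes = TRUE)
  fits <- attr(report, "fits")
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (!is.null(f$gpa)) {
      write_superimposed_csv(tidy(f$gpa),
                             file.path(dir, paste0("superimposed_", nm, ".csv")))
    }
    if (!is.null(f$pca)) {
      utils::write.csv(tidy(f$pca), file.path(dir, paste0("pca_scores_", nm, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(f$classification)) {
      utils::write.csv(tidy(f$classification),
                       file.path(dir, paste0("loocv_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

# landmark_io wide CSV plus a centroid_size column
write_superimposed_csv <- function(data, path) {
  k <- landmark_count(data)
  mat <- coord_matrix(data)
  header <- paste(c("id", "species", "sex", "observer", "site", "replicate",
                    coord_cols(k), "centroid_size"), collapse = ",")
  coord_txt <- apply(mat, 1L, function(v) paste(sprintf("%.9f", v), collapse = ","))
  rows <- paste(data$specimen_id, data$species, data$sex, data$observer,
                ifelse(is.na(data$site), "", data$site), data$replicate,
                coord_txt, sprintf("%.9f", data$centroid_size), sep = ",")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}
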